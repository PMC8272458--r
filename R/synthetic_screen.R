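#' Phenotype parameters for synthetic well images
#'
#' Describes one well phenotype as a population of fluorescent colony-like
#' objects over a noisy background. Active-control wells (+DOX) carry many
#' compact bright colonies; negative-control wells (-DOX) carry sparse,
#' small, dim debris after the reporter phenotype collapses.
#'
#' @param objects_per_well Poisson mean of the object count per well.
#' @param radius_log_mean,radius_log_sd Log-space colony radius (pixels).
#' @param intensity_mean,intensity_sd Foreground fluorescence amplitude
#'   (16-bit counts).
#' @param eccentricity_mean Mean shape elongation in \[0, 1).
#' @param background_mean,background_sd Background fluorescence (counts).
#' @return Object of class `phenotype_params`.
#' @export
phenotype_params <- function(objects_per_well,
                             radius_log_mean, radius_log_sd,
                             intensity_mean, intensity_sd,
                             eccentricity_mean,
                             background_mean, background_sd) {
  p <- list(objects_per_well = objects_per_well,
            radius_log_mean = radius_log_mean,
            radius_log_sd = radius_log_sd,
            intensity_mean = intensity_mean,
            intensity_sd = intensity_sd,
            eccentricity_mean = eccentricity_mean,
            background_mean = background_mean,
            background_sd = background_sd)
  stopifnot(objects_per_well >= 0, radius_log_sd >= 0, intensity_sd >= 0,
            background_sd >= 0, eccentricity_mean >= 0,
            eccentricity_mean < 1)
  structure(p, class = "phenotype_params")
}

#' Default phenotypes and simulation configuration
#'
#' `default_ac_params()`/`default_nc_params()` are the documented default
#' phenotypes: AC wells average 25 compact colonies of radius ~12 px with
#' foreground about 8x background; NC wells average 4 small dim elongated
#' debris objects. `screen_sim_config()` bundles them with the fast
#' feature-space simulator settings.
#'
#' The feature-space simulator draws well profiles directly from
#' multivariate normals: NC wells from `N(0, Sigma)`, AC wells from
#' `N(delta * w, Sigma)` where `w` is a fixed decaying weight pattern over
#' the first `n_informative` features (the rest are pure noise), and
#' `Sigma` has unit variances with AR(1) correlation `feature_rho`. Planted
#' active compound wells sit at `active_effect` of the NC-to-AC offset; a
#' fraction of actives follows a "larger but dimmer" variant of the active
#' phenotype. `separation` (delta) is calibrated once so that the default
#' pipeline's plate-level Z' lands in the performance band of a
#' well-behaved screen (about 0.6); it is a documented constant, not a
#' per-run knob.
#'
#' @param ac_params,nc_params [phenotype_params()] for the two control roles.
#' @param active_fraction Probability a compound well is a planted active.
#' @param active_effect Scalar in \[0, 1\] interpolating a planted active's
#'   phenotype from NC (0) toward AC (1).
#' @param dimmer_active_fraction Fraction of actives drawn with the
#'   enlarged-but-dimmer phenotype variant.
#' @param feature_dim,n_informative,separation,feature_rho Fast-path
#'   feature-space settings (see Details).
#' @param image_size Square field image side in pixels (>= 64).
#' @param fields_per_well Imaging fields per well; object counts are split
#'   evenly across fields.
#' @param seed Default seed for generator calls that do not pass one.
#' @return `screen_sim_config()` returns an object of class
#'   `screen_sim_config`.
#' @export
screen_sim_config <- function(ac_params = default_ac_params(),
                              nc_params = default_nc_params(),
                              active_fraction = 0.05,
                              active_effect = 1,
                              dimmer_active_fraction = 0.15,
                              feature_dim = 20L,
                              n_informative = 12L,
                              separation = 8,
                              feature_rho = 0.3,
                              image_size = 256L,
                              fields_per_well = 4L,
                              seed = 1L) {
  stopifnot(active_fraction >= 0, active_fraction <= 1,
            active_effect >= 0, active_effect <= 1,
            dimmer_active_fraction >= 0, dimmer_active_fraction <= 1,
            image_size >= 64L, fields_per_well >= 1L,
            feature_dim >= 1L, n_informative >= 1L,
            n_informative <= feature_dim,
            feature_rho > -1, feature_rho < 1, separation >= 0)
  structure(list(ac_params = ac_params, nc_params = nc_params,
                 active_fraction = active_fraction,
                 active_effect = active_effect,
                 dimmer_active_fraction = dimmer_active_fraction,
                 feature_dim = as.integer(feature_dim),
                 n_informative = as.integer(n_informative),
                 separation = separation,
                 feature_rho = feature_rho,
                 image_size = as.integer(image_size),
                 fields_per_well = as.integer(fields_per_well),
                 seed = as.integer(seed)),
            class = "screen_sim_config")
}

#' @rdname screen_sim_config
#' @export
default_ac_params <- function() {
  phenotype_params(objects_per_well = 25,
                   radius_log_mean = log(12), radius_log_sd = 0.25,
                   intensity_mean = 3200, intensity_sd = 500,
                   eccentricity_mean = 0.15,
                   background_mean = 400, background_sd = 30)
}

#' @rdname screen_sim_config
#' @export
default_nc_params <- function() {
  phenotype_params(objects_per_well = 4,
                   radius_log_mean = log(5), radius_log_sd = 0.35,
                   intensity_mean = 900, intensity_sd = 150,
                   eccentricity_mean = 0.5,
                   background_mean = 400, background_sd = 30)
}

# Fixed feature-space population parameters implied by a config:
# means for NC, AC and the dimmer-active variant, plus the shared
# upper-Cholesky factor of the AR(1) covariance.
sim_population <- function(config) {
  d <- config$feature_dim
  k <- config$n_informative
  w <- numeric(d)
  w[seq_len(k)] <- seq(1, 0.4, length.out = k)
  mu_nc <- numeric(d)
  mu_ac <- config$separation * w
  # "larger but dimmer" variant: size-like half of the informative block is
  # amplified, intensity-like half attenuated
  half <- ceiling(k / 2)
  dim_mod <- rep(1, d)
  dim_mod[seq_len(half)] <- 1.15
  dim_mod[seq(half + 1, k)] <- 0.75
  mu_dim <- mu_ac * dim_mod
  sigma <- config$feature_rho ^ abs(outer(seq_len(d), seq_len(d), `-`))
  feat <- feature_catalog()
  nm <- if (d <= length(feat)) feat[seq_len(d)] else sprintf("f%03d",
                                                             seq_len(d))
  list(mu_nc = mu_nc, mu_ac = mu_ac, mu_dim = mu_dim,
       chol = chol(sigma), sigma = sigma, feature_names = nm)
}

#' Simulate a per-well feature table (fast path)
#'
#' Bypasses image rendering: draws well feature vectors directly from the
#' multivariate-normal populations described in [screen_sim_config()].
#' AC wells come from `N(mu_A, Sigma)`, NC wells from `N(mu_N, Sigma)`, and
#' planted actives from `N(mu_N + active_effect * (mu_A - mu_N), Sigma)`
#' (with the dimmer variant for a configured fraction). The generating
#' parameters are attached as `attr(, "params")` for parameter-recovery
#' tests.
#'
#' @param config A [screen_sim_config()].
#' @param n_ac,n_nc,n_compound Wells per role.
#' @param seed Integer seed; the table is a pure function of
#'   (config, sizes, seed).
#' @return data.frame with columns `well`, `role`, `compound_id`,
#'   `is_active`, `phenotype` and one column per feature; attributes
#'   `params` (population parameters) and `truth` (per-compound-well truth).
#' @export
simulate_feature_table <- function(config, n_ac = 16L, n_nc = 16L,
                                   n_compound = 352L, seed = config$seed) {
  stopifnot(inherits(config, "screen_sim_config"))
  pop <- sim_population(config)
  with_seed(seed, {
    is_active <- stats::runif(n_compound) < config$active_fraction
    dimmer <- is_active & (stats::runif(n_compound) <
                             config$dimmer_active_fraction)
    draw <- function(n, mu) rmvn_chol(n, mu, pop$chol)
    e <- config$active_effect
    mu_act <- pop$mu_nc + e * (pop$mu_ac - pop$mu_nc)
    mu_act_dim <- pop$mu_nc + e * (pop$mu_dim - pop$mu_nc)
    xc <- matrix(NA_real_, n_compound, config$feature_dim)
    if (any(!is_active)) xc[!is_active, ] <- draw(sum(!is_active), pop$mu_nc)
    if (any(is_active & !dimmer)) {
      xc[is_active & !dimmer, ] <- draw(sum(is_active & !dimmer), mu_act)
    }
    if (any(dimmer)) xc[dimmer, ] <- draw(sum(dimmer), mu_act_dim)
    x <- rbind(draw(n_ac, pop$mu_ac), draw(n_nc, pop$mu_nc), xc)
    colnames(x) <- pop$feature_names
    role <- c(rep("active_control", n_ac), rep("negative_control", n_nc),
              rep("compound", n_compound))
    compound_id <- c(rep(NA_character_, n_ac + n_nc),
                     sprintf("cmp%03d", seq_len(n_compound)))
    phenotype <- c(rep("ac", n_ac), rep("nc", n_nc),
                   ifelse(is_active, ifelse(dimmer, "active_dim", "active"),
                          "inactive"))
    out <- data.frame(well = sprintf("w%03d", seq_len(nrow(x))),
                      role = role, compound_id = compound_id,
                      is_active = c(rep(NA, n_ac + n_nc), is_active),
                      phenotype = phenotype,
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(x))
    attr(out, "params") <- pop[c("mu_nc", "mu_ac", "mu_dim", "sigma",
                                 "feature_names")]
    attr(out, "truth") <- data.frame(
      compound_id = compound_id[role == "compound"],
      is_active = is_active, phenotype = phenotype[role == "compound"],
      seed = rep(seed, length(is_active)), stringsAsFactors = FALSE)
    out
  })
}

#' Simulate a duplicate-run screen in feature space
#'
#' Generates one truth assignment (which compound wells are planted actives)
#' and then draws each replicate's feature table independently around that
#' shared truth, matching the duplicate-run design: a planted active is
#' active in every replicate, measurement noise is not shared.
#'
#' @inheritParams simulate_feature_table
#' @param n_replicates Number of replicate runs (>= 2 for hit calling).
#' @return List with `tables` (one feature data.frame per replicate) and
#'   `truth` (one row per compound well).
#' @export
simulate_screen_tables <- function(config, n_ac = 16L, n_nc = 16L,
                                   n_compound = 352L, n_replicates = 2L,
                                   seed = config$seed) {
  stopifnot(n_replicates >= 1L)
  pop <- sim_population(config)
  truth <- with_seed(child_seed(seed, 0L), {
    is_active <- stats::runif(n_compound) < config$active_fraction
    dimmer <- is_active & (stats::runif(n_compound) <
                             config$dimmer_active_fraction)
    data.frame(compound_id = sprintf("cmp%03d", seq_len(n_compound)),
               is_active = is_active,
               phenotype = ifelse(is_active,
                                  ifelse(dimmer, "active_dim", "active"),
                                  "inactive"),
               seed = rep(seed, length(is_active)), stringsAsFactors = FALSE)
  })
  e <- config$active_effect
  mu_act <- pop$mu_nc + e * (pop$mu_ac - pop$mu_nc)
  mu_act_dim <- pop$mu_nc + e * (pop$mu_dim - pop$mu_nc)
  mu_cmp <- rbind(inactive = pop$mu_nc, active = mu_act,
                  active_dim = mu_act_dim)
  tables <- lapply(seq_len(n_replicates), function(r) {
    with_seed(child_seed(seed, r), {
      xc <- rmvn_chol(n_compound, numeric(config$feature_dim), pop$chol) +
        mu_cmp[truth$phenotype, , drop = FALSE]
      x <- rbind(rmvn_chol(n_ac, pop$mu_ac, pop$chol),
                 rmvn_chol(n_nc, pop$mu_nc, pop$chol),
                 xc)
      colnames(x) <- pop$feature_names
      out <- data.frame(
        well = sprintf("w%03d", seq_len(nrow(x))),
        role = c(rep("active_control", n_ac),
                 rep("negative_control", n_nc),
                 rep("compound", n_compound)),
        compound_id = c(rep(NA_character_, n_ac + n_nc), truth$compound_id),
        replicate = r, stringsAsFactors = FALSE)
      cbind(out, as.data.frame(x))
    })
  })
  list(tables = tables, truth = truth)
}

# --- image rendering ---------------------------------------------------

# Render additive elliptical blobs onto a canvas. profile "gaussian" gives a
# smooth dome (sigma = semi-axis / 2); "disk" a hard-edged constant-intensity
# ellipse (used for geometry fixtures). Returns the canvas.
render_objects <- function(canvas, objects, profile = "gaussian") {
  n <- nrow(canvas)
  m <- ncol(canvas)
  for (i in seq_len(nrow(objects))) {
    o <- objects[i, ]
    e2 <- 1 - o$eccentricity^2
    a <- o$radius / e2^0.25        # semi-major
    b <- o$radius * e2^0.25        # semi-minor; area preserved at pi r^2
    ext <- ceiling(if (profile == "gaussian") 3 * a else a + 2)
    x0 <- max(1L, floor(o$x - ext)); x1 <- min(n, ceiling(o$x + ext))
    y0 <- max(1L, floor(o$y - ext)); y1 <- min(m, ceiling(o$y + ext))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1
    ys <- y0:y1
    dx <- outer(xs - o$x, rep(1, length(ys)))
    dy <- outer(rep(1, length(xs)), ys - o$y)
    ct <- cos(o$theta); st <- sin(o$theta)
    u <- dx * ct + dy * st
    v <- -dx * st + dy * ct
    r2 <- (u / a)^2 + (v / b)^2
    add <- if (profile == "gaussian") {
      o$intensity * exp(-2 * r2)   # sigma = semi-axis / 2
    } else {
      o$intensity * (r2 <= 1)
    }
    canvas[xs, ys] <- canvas[xs, ys] + add
  }
  canvas
}

# Rejection-sample object centres so centre distances exceed 1.4x the sum
# of effective radii (gaussian tails reach past the nominal radius); best
# effort with bounded retries, so overcrowded requests degrade to overlaps
# rather than failing.
place_objects <- function(k, image_size, radii, margin) {
  x <- numeric(k); y <- numeric(k)
  for (i in seq_len(k)) {
    for (try in 1:300) {
      xi <- stats::runif(1, margin, image_size - margin)
      yi <- stats::runif(1, margin, image_size - margin)
      if (i == 1L) break
      dd <- sqrt((x[seq_len(i - 1)] - xi)^2 + (y[seq_len(i - 1)] - yi)^2)
      if (all(dd > 1.4 * (radii[i] + radii[seq_len(i - 1)]) + 4)) break
    }
    x[i] <- xi; y[i] <- yi
  }
  cbind(x = x, y = y)
}

#' Simulate one grayscale well image
#'
#' Renders a 16-bit field image of one well: Poisson-many elliptical objects
#' with log-normal radii, normal fluorescence amplitudes and random
#' orientations, added onto Gaussian background noise and clipped to the
#' 16-bit dynamic range. Object placement avoids overlaps (bounded rejection
#' sampling), so rendered object counts are recoverable by segmentation.
#'
#' @param phenotype A [phenotype_params()].
#' @param image_size Side of the square image in pixels (> 0).
#' @param seed Integer seed; output is bit-identical for identical inputs.
#' @param profile `"gaussian"` (smooth domes, default) or `"disk"`
#'   (hard-edged, constant-intensity; geometry fixtures).
#' @return Integer matrix in \[0, 65535\] with attribute `truth`: a
#'   data.frame of the rendered objects (`x`, `y`, `radius`, `intensity`,
#'   `eccentricity`, `theta`).
#' @export
simulate_well_image <- function(phenotype, image_size = 256L, seed = 1L,
                                profile = c("gaussian", "disk")) {
  stopifnot(inherits(phenotype, "phenotype_params"))
  profile <- match.arg(profile)
  image_size <- as.integer(image_size)
  if (image_size <= 0L) stop("image size must be positive", call. = FALSE)
  with_seed(seed, {
    p <- phenotype
    k <- stats::rpois(1L, p$objects_per_well)
    canvas <- matrix(stats::rnorm(image_size^2, p$background_mean,
                                  p$background_sd),
                     image_size, image_size)
    truth <- data.frame(x = numeric(0), y = numeric(0), radius = numeric(0),
                        intensity = numeric(0), eccentricity = numeric(0),
                        theta = numeric(0))
    if (k > 0L) {
      radius <- stats::rlnorm(k, p$radius_log_mean, p$radius_log_sd)
      radius <- pmin(radius, image_size / 4)
      intensity <- pmax(stats::rnorm(k, p$intensity_mean, p$intensity_sd),
                        p$intensity_mean * 0.2)
      ecc <- pmin(pmax(stats::rnorm(k, p$eccentricity_mean, 0.1), 0), 0.9)
      theta <- stats::runif(k, 0, pi)
      margin <- min(max(radius) + 2, image_size / 3)
      xy <- place_objects(k, image_size, radius, margin)
      truth <- data.frame(x = xy[, "x"], y = xy[, "y"], radius = radius,
                          intensity = intensity, eccentricity = ecc,
                          theta = theta)
      canvas <- render_objects(canvas, truth, profile = profile)
    }
    img <- matrix(as.integer(pmin(pmax(round(canvas), 0), 65535)),
                  image_size, image_size)
    attr(img, "truth") <- truth
    img
  })
}

#' Simulate a full image-based screen to disk
#'
#' Writes 16-bit TIFF field images named `<plate>_<well>_f<field>.tif` for
#' every non-empty well of every layout, plus the plate maps and a truth
#' table. Duplicate plates share one truth assignment (a planted active is
#' active in both replicates) while their images carry independent noise.
#' The Poisson object budget of a well is split evenly over its fields.
#'
#' @param run A [screen_run()] (or list of layouts) describing the plates.
#' @param config A [screen_sim_config()].
#' @param out_dir Output directory, created if needed. When `NULL`, images
#'   are returned in memory instead of written (keep sizes small).
#' @param seed Integer seed.
#' @return Invisibly, a list with `truth` (data.frame, one row per compound
#'   well) and `files` (written image paths) or `images` (named list of
#'   per-well field image lists when `out_dir` is `NULL`).
#' @export
simulate_screen <- function(run, config = screen_sim_config(),
                            out_dir = NULL, seed = config$seed) {
  layouts <- if (inherits(run, "screen_run")) run$layouts else run
  stopifnot(all(vapply(layouts, inherits, TRUE, "plate_layout")))
  base <- layouts[[1L]]$wells
  cmp <- base[base$role == "compound", ]
  truth <- with_seed(child_seed(seed, 0L), {
    is_active <- stats::runif(nrow(cmp)) < config$active_fraction
    dimmer <- is_active & (stats::runif(nrow(cmp)) <
                             config$dimmer_active_fraction)
    data.frame(compound_id = cmp$compound_id, well = cmp$well,
               is_active = is_active,
               phenotype = ifelse(is_active,
                                  ifelse(dimmer, "active_dim", "active"),
                                  "inactive"),
               seed = rep(seed, length(is_active)), stringsAsFactors = FALSE)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  files <- character()
  images <- list()
  for (li in seq_along(layouts)) {
    lay <- layouts[[li]]
    w <- lay$wells
    for (wi in which(w$role != "empty")) {
      role <- w$role[wi]
      pheno <- well_phenotype(role, w$compound_id[wi], truth, config)
      # Poisson budget split evenly over the fields of the well
      pheno$objects_per_well <- pheno$objects_per_well / config$fields_per_well
      fields <- lapply(seq_len(config$fields_per_well), function(f) {
        simulate_well_image(pheno, config$image_size,
                            seed = child_seed(seed,
                                              li * 1000000L + wi * 16L + f))
      })
      if (is.null(out_dir)) {
        images[[paste0(lay$plate_id, "_", w$well[wi])]] <- fields
      } else {
        for (f in seq_along(fields)) {
          fn <- file.path(out_dir, sprintf("%s_%s_f%d.tif", lay$plate_id,
                                           w$well[wi], f))
          write_well_image(fields[[f]], fn)
          files <- c(files, fn)
        }
      }
    }
    if (!is.null(out_dir)) {
      write_plate_map(lay, file.path(out_dir,
                                     paste0(lay$plate_id, "_map.csv")))
    }
  }
  if (!is.null(out_dir)) {
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
  }
  invisible(list(truth = truth, files = files,
                 images = if (is.null(out_dir)) images))
}

# Phenotype of one well given its role and the shared truth table. Planted
# actives interpolate from the NC toward the AC phenotype by active_effect;
# the dimmer variant enlarges radius and attenuates intensity.
well_phenotype <- function(role, compound_id, truth, config) {
  ac <- config$ac_params
  nc <- config$nc_params
  if (role == "active_control") return(ac)
  if (role == "negative_control") return(nc)
  row <- truth[match(compound_id, truth$compound_id), ]
  if (!isTRUE(row$is_active)) return(nc)
  e <- config$active_effect
  mix <- function(field) nc[[field]] + e * (ac[[field]] - nc[[field]])
  p <- phenotype_params(
    objects_per_well = mix("objects_per_well"),
    radius_log_mean = mix("radius_log_mean"),
    radius_log_sd = mix("radius_log_sd"),
    intensity_mean = mix("intensity_mean"),
    intensity_sd = mix("intensity_sd"),
    eccentricity_mean = mix("eccentricity_mean"),
    background_mean = nc$background_mean,
    background_sd = nc$background_sd)
  if (identical(row$phenotype, "active_dim")) {
    p$radius_log_mean <- p$radius_log_mean + log(1.25)
    p$intensity_mean <- p$intensity_mean * 0.75
  }
  p
}

#' Read and write well images
#'
#' Grayscale well images with pixel values as 16-bit counts in
#' \[0, 65535\]. TIFF (via the tiff package) is the native format and
#' round-trips 16-bit data exactly; PNG (via the png package) is an 8-bit
#' interchange option, quantised on write.
#'
#' @param path Image file; format chosen by extension.
#' @param img Integer/numeric matrix of counts.
#' @return `read_well_image()` returns a numeric matrix of counts;
#'   `write_well_image()` returns `path` invisibly.
#' @export
read_well_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
              tif = , tiff = tiff::readTIFF(path),
              png = png::readPNG(path),
              stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  round(t(x) * 65535)   # readers return [0,1] row-major; internal is x,y
}

#' @rdname read_well_image
#' @export
write_well_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  m <- t(pmin(pmax(img / 65535, 0), 1))
  switch(ext,
         tif = , tiff = tiff::writeTIFF(m, path, bits.per.sample = 16L),
         png = png::writePNG(m, path),
         stop("unsupported image format: ", ext, call. = FALSE))
  invisible(path)
}
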