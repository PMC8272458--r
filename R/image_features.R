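#' The default 112-feature well catalog
#'
#' Eleven per-object measurements -- six shape parameters (area,
#' circumference, diameter, circularity, anisometry, compactness) and five
#' intensity values (mean, median, total, maximum, minimum) -- are
#' aggregated across the objects of a well with nine statistics (mean,
#' median, sum, SD, coefficient of variation, min, max, 10th and 90th
#' percentile), giving 99 features. Six covariance features (covariance of
#' each shape parameter with per-object mean intensity) and seven
#' well-level scalars (object count, foreground area fraction, total
#' foreground intensity, background mean and SD, mean nearest-neighbour
#' centroid distance, fraction of objects brighter than background mean +
#' 3 background SD) complete the catalog: 99 + 6 + 7 = 112 named features
#' in a fixed order.
#'
#' The instrument software's own feature list is not published; this
#' catalog is a documented reconstruction that uses every named measurement
#' and statistic family and totals exactly 112. It can be replaced by any
#' custom ordered name vector accepted by [aggregate_well_features()].
#'
#' @return Character vector of 112 feature names.
#' @export
feature_catalog <- function() {
  measures <- object_measures()
  stats <- c("mean", "median", "sum", "sd", "cv", "min", "max", "p10", "p90")
  c(as.vector(t(outer(measures, stats, paste, sep = "_"))),
    paste0("cov_", shape_measures(), "_intensity_mean"),
    c("n_objects", "fg_area_fraction", "fg_intensity_total",
      "background_mean", "background_sd", "nn_dist_mean",
      "bright_object_fraction"))
}

shape_measures <- function() {
  c("area", "circumference", "diameter", "circularity", "anisometry",
    "compactness")
}

object_measures <- function() {
  c(shape_measures(),
    "intensity_mean", "intensity_median", "intensity_total",
    "intensity_max", "intensity_min")
}

#' Segment fluorescent objects in a well image
#'
#' Foreground is found by Otsu's threshold on the field, floored at a
#' robust background estimate (median + 3 * 1.4826 MAD) so that blank
#' wells, where Otsu would split the noise in half, yield no objects.
#' Connected foreground components are labelled and components smaller
#' than `min_object_area` pixels are discarded as specks.
#'
#' @param img Numeric matrix of pixel counts (one field).
#' @param threshold_method Currently `"otsu"`.
#' @param min_object_area Minimum component area in pixels (default 10).
#' @return Integer label matrix: background 0, objects 1..K.
#' @export
segment_objects <- function(img, threshold_method = "otsu",
                            min_object_area = 10L) {
  if (length(img) == 0L || is.null(dim(img))) {
    stop("empty image", call. = FALSE)
  }
  threshold_method <- match.arg(threshold_method, "otsu")
  v <- as.numeric(img)
  rng <- range(v)
  bg_med <- stats::median(v)
  bg_mad <- stats::mad(v)
  floor_t <- bg_med + 3 * max(bg_mad, 1e-8)
  if (rng[2] > rng[1]) {
    scaled <- (img - rng[1]) / (rng[2] - rng[1])
    t_otsu <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1)) *
      (rng[2] - rng[1]) + rng[1]
  } else {
    t_otsu <- rng[2]
  }
  thr <- max(t_otsu, floor_t)
  mask <- EBImage::bwlabel(img > thr)
  labels <- EBImage::imageData(mask)
  if (max(labels) > 0L) {
    sizes <- tabulate(labels[labels > 0L])
    keep <- which(sizes >= min_object_area)
    relabel <- integer(length(sizes))
    relabel[keep] <- seq_along(keep)
    labels[labels > 0L] <- relabel[labels[labels > 0L]]
  }
  storage.mode(labels) <- "integer"
  labels
}

# Kulpa-corrected chain-code perimeter from an ordered 8-connected contour:
# straight steps weighted 0.948, diagonal steps 1.340. Near-unbiased for
# smooth shapes; a raw chain length would overestimate a disk's perimeter
# by ~5% and push circularity out of its tolerance.
contour_perimeter <- function(xy) {
  n <- nrow(xy)
  if (n < 2L) return(4)   # single-pixel fallback: pixel boundary
  d <- xy - xy[c(2:n, 1L), ]
  diag_step <- abs(d[, 1L]) == 1L & abs(d[, 2L]) == 1L
  sum(ifelse(diag_step, 1.340, 0.948) * (abs(d[, 1L]) | abs(d[, 2L])))
}

# Convex hull area over the pixel *corner* points so hull area >= pixel
# count; keeps compactness <= 1 by construction.
hull_area <- function(px, py) {
  cx <- c(px - 0.5, px - 0.5, px + 0.5, px + 0.5)
  cy <- c(py - 0.5, py + 0.5, py - 0.5, py + 0.5)
  h <- grDevices::chull(cx, cy)
  hx <- cx[h]; hy <- cy[h]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Per-object shape and intensity measurements
#'
#' For each labelled object: area (pixel count), circumference (corrected
#' boundary chain length), equivalent-circle diameter `2*sqrt(area/pi)`,
#' circularity `4*pi*area/perimeter^2`, anisometry (major/minor axis ratio
#' of the second-moment ellipse, >= 1), compactness (area / convex-hull
#' area, in (0, 1]), and the mean, median, total, maximum and minimum of
#' the object's pixel intensities. Centroids are carried along for
#' neighbour-distance features.
#'
#' @param labels Integer label matrix from [segment_objects()].
#' @param img Intensity image of the same shape.
#' @param well Optional well address attached to the result.
#' @param n_fields Number of fields pooled in this table.
#' @return Object of class `well_object_table`: list with `objects`
#'   (data.frame, one row per object), `well`, `n_fields`,
#'   `background_mean`, `background_sd` (over background pixels) and
#'   `image_area`.
#' @export
compute_object_features <- function(labels, img, well = NA_character_,
                                    n_fields = 1L) {
  if (!all(dim(labels) == dim(img))) {
    stop("mask and image shapes differ", call. = FALSE)
  }
  k <- max(labels)
  bg <- img[labels == 0L]
  contours <- if (k > 0L) EBImage::ocontour(labels) else list()
  rows <- vector("list", k)
  for (lab in seq_len(k)) {
    idx <- which(labels == lab, arr.ind = TRUE)
    px <- idx[, 1L]; py <- idx[, 2L]
    area <- nrow(idx)
    perim <- contour_perimeter(contours[[lab]])
    # second-moment ellipse; 1/12 is the variance of a unit pixel, keeps
    # the minor axis of 1-px-thin objects positive
    vx <- stats::var(px) + 1 / 12
    vy <- stats::var(py) + 1 / 12
    vxy <- if (area > 1L) stats::cov(px, py) else 0
    tr2 <- (vx + vy) / 2
    det_rt <- sqrt(max(((vx - vy) / 2)^2 + vxy^2, 0))
    l1 <- tr2 + det_rt
    l2 <- max(tr2 - det_rt, 1e-12)
    vals <- img[cbind(px, py)]
    rows[[lab]] <- data.frame(
      label = lab,
      area = area,
      circumference = perim,
      diameter = 2 * sqrt(area / pi),
      # chain-code discretization can push tiny objects past 1; cap at the
      # documented rasterization tolerance 1 + 0.1
      circularity = min(4 * pi * area / perim^2, 1.1),
      anisometry = sqrt(l1 / l2),
      compactness = min(area / hull_area(px, py), 1),
      intensity_mean = mean(vals),
      intensity_median = stats::median(vals),
      intensity_total = sum(vals),
      intensity_max = max(vals),
      intensity_min = min(vals),
      centroid_x = mean(px),
      centroid_y = mean(py))
  }
  objects <- if (k > 0L) do.call(rbind, rows) else
    data.frame(label = integer(0), area = numeric(0),
               circumference = numeric(0), diameter = numeric(0),
               circularity = numeric(0), anisometry = numeric(0),
               compactness = numeric(0), intensity_mean = numeric(0),
               intensity_median = numeric(0), intensity_total = numeric(0),
               intensity_max = numeric(0), intensity_min = numeric(0),
               centroid_x = numeric(0), centroid_y = numeric(0))
  structure(list(objects = objects, well = well,
                 n_fields = as.integer(n_fields),
                 background_mean = if (length(bg)) mean(bg) else NA_real_,
                 background_sd = if (length(bg) > 1L) stats::sd(bg) else 0,
                 image_area = length(img)),
            class = "well_object_table")
}

#' Pool the object tables of a well's fields
#'
#' Objects from all fields of a well are pooled into one table (relabelled
#' to stay unique); background statistics and image area are averaged /
#' summed across fields.
#'
#' @param tables List of `well_object_table`s, one per field.
#' @param well Well address of the pooled table.
#' @return A `well_object_table` covering all fields.
#' @export
pool_field_tables <- function(tables, well = NA_character_) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, TRUE, "well_object_table")))
  objs <- lapply(tables, `[[`, "objects")
  offset <- 0L
  for (i in seq_along(objs)) {
    if (nrow(objs[[i]])) objs[[i]]$label <- objs[[i]]$label + offset
    offset <- offset + nrow(objs[[i]])
  }
  structure(list(objects = do.call(rbind, objs), well = well,
                 n_fields = length(tables),
                 background_mean =
                   mean(vapply(tables, `[[`, 1, "background_mean"),
                        na.rm = TRUE),
                 background_sd =
                   mean(vapply(tables, `[[`, 1, "background_sd"),
                        na.rm = TRUE),
                 image_area = sum(vapply(tables, `[[`, 1, "image_area"))),
            class = "well_object_table")
}

agg_stats <- function(v) {
  n <- length(v)
  m <- mean(v)
  s <- if (n > 1L) stats::sd(v) else 0
  q <- stats::quantile(v, c(0.1, 0.9), names = FALSE, type = 7)
  c(mean = m, median = stats::median(v), sum = sum(v), sd = s,
    cv = if (abs(m) > 1e-12) s / m else 0,
    min = min(v), max = max(v), p10 = q[1L], p90 = q[2L])
}

#' Aggregate a well's object table into the per-well feature vector
#'
#' Applies the feature catalog (see [feature_catalog()]) to a
#' [compute_object_features()] table. Across-object SD is the sample
#' (n-1) SD, defined as 0 for single-object wells, as are the coefficient
#' of variation and covariances; the nearest-neighbour distance of a
#' single object is 0. Wells with no objects -- e.g. -DOX-like wells where
#' the colony phenotype has collapsed entirely -- are not dropped: every
#' feature is imputed to 0 and `no_object_flag` is set, so the well stays
#' scoreable as maximally NC-like.
#'
#' @param table A `well_object_table`.
#' @param catalog Ordered feature-name vector (default [feature_catalog()]).
#' @return Object of class `well_feature_vector`: list with `well`,
#'   `values` (named numeric vector, `length(catalog)`), `no_object_flag`,
#'   `n_objects`.
#' @export
aggregate_well_features <- function(table, catalog = feature_catalog()) {
  stopifnot(inherits(table, "well_object_table"))
  known <- feature_catalog()
  bad <- setdiff(catalog, known)
  if (length(bad)) {
    stop("unknown feature name in catalog: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  obj <- table$objects
  n <- nrow(obj)
  vals <- stats::setNames(numeric(length(known)), known)
  if (n > 0L) {
    for (m in object_measures()) {
      st <- agg_stats(obj[[m]])
      vals[paste(m, names(st), sep = "_")] <- st
    }
    for (m in shape_measures()) {
      vals[paste0("cov_", m, "_intensity_mean")] <-
        if (n > 1L) stats::cov(obj[[m]], obj$intensity_mean) else 0
    }
    bg_m <- if (is.na(table$background_mean)) 0 else table$background_mean
    bg_s <- table$background_sd
    nn <- if (n > 1L) {
      dd <- as.matrix(stats::dist(obj[, c("centroid_x", "centroid_y")]))
      diag(dd) <- Inf
      mean(apply(dd, 1L, min))
    } else 0
    vals["n_objects"] <- n
    vals["fg_area_fraction"] <- sum(obj$area) / table$image_area
    vals["fg_intensity_total"] <- sum(obj$intensity_total)
    vals["background_mean"] <- bg_m
    vals["background_sd"] <- bg_s
    vals["nn_dist_mean"] <- nn
    vals["bright_object_fraction"] <-
      mean(obj$intensity_mean > bg_m + 3 * bg_s)
  }
  structure(list(well = table$well,
                 values = vals[catalog],
                 no_object_flag = n == 0L,
                 n_objects = n),
            class = "well_feature_vector")
}

#' Extract the well x feature matrix from field images
#'
#' Convenience wrapper running [segment_objects()],
#' [compute_object_features()], [pool_field_tables()] and
#' [aggregate_well_features()] over a named list of wells.
#'
#' @param well_images Named list: one entry per well, each a list of field
#'   image matrices.
#' @param min_object_area Passed to [segment_objects()].
#' @param catalog Feature catalog.
#' @return List with `features` (matrix wells x features, rownames = well
#'   names) and `n_objects` (named integer vector).
#' @export
extract_well_features <- function(well_images,
                                  min_object_area = 10L,
                                  catalog = feature_catalog()) {
  stopifnot(is.list(well_images), !is.null(names(well_images)))
  res <- lapply(names(well_images), function(w) {
    fields <- well_images[[w]]
    if (is.matrix(fields)) fields <- list(fields)
    tabs <- lapply(fields, function(img) {
      compute_object_features(segment_objects(img,
                                              min_object_area =
                                                min_object_area),
                              img)
    })
    aggregate_well_features(pool_field_tables(tabs, well = w), catalog)
  })
  features <- do.call(rbind, lapply(res, `[[`, "values"))
  rownames(features) <- names(well_images)
  list(features = features,
       n_objects = stats::setNames(vapply(res, `[[`, 0L, "n_objects"),
                                   names(well_images)))
}
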