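#' Z'-factor of a screening assay window
#'
#' The Z'-factor is a screening effect-size statistic computed from the means
#' and standard deviations of the positive (+DOX, active) and negative
#' (-DOX) control readouts:
#' \deqn{Z' = 1 - \frac{3(\sigma_+ + \sigma_-)}{|\mu_+ - \mu_-|}}
#' It is bounded above by 1, reaches 1 only in the noiseless limit, and
#' values above about 0.5 indicate an excellent assay window. The formula is
#' symmetric in the two control populations.
#'
#' @param plus_values Numeric readouts of the positive-control wells (>= 2).
#' @param minus_values Numeric readouts of the negative-control wells (>= 2).
#' @return An object of class `zprime_result`: list with `zprime`, `n_plus`,
#'   `n_minus`.
#' @examples
#' # mu+ = 100, sd+ = 6, mu- = 10, sd- = 6  ->  1 - 3*12/90 = 0.6
#' zprime(c(94, 100, 106), c(4, 10, 16))
#' @export
zprime <- function(plus_values, minus_values) {
  plus_values <- as.numeric(plus_values)
  minus_values <- as.numeric(minus_values)
  if (length(plus_values) < 2L || length(minus_values) < 2L) {
    stop("zprime needs >= 2 values on each side", call. = FALSE)
  }
  if (anyNA(plus_values) || anyNA(minus_values)) {
    stop("zprime values must be finite", call. = FALSE)
  }
  mu_p <- mean(plus_values)
  mu_m <- mean(minus_values)
  sep <- abs(mu_p - mu_m)
  if (sep <= .Machine$double.eps * max(1, abs(mu_p), abs(mu_m))) {
    stop("degenerate separation: control means are equal", call. = FALSE)
  }
  z <- 1 - 3 * (stats::sd(plus_values) + stats::sd(minus_values)) / sep
  structure(list(zprime = z,
                 n_plus = length(plus_values),
                 n_minus = length(minus_values)),
            class = "zprime_result")
}

#' @export
print.zprime_result <- function(x, ...) {
  cat(sprintf("Z' = %.4f  (n+ = %d, n- = %d)\n",
              x$zprime, x$n_plus, x$n_minus))
  invisible(x)
}

# Per-feature Z' between AC and NC wells; NA for degenerate features
# (zero separation or both-side zero variance).
per_feature_zprime <- function(x, roles) {
  ac <- x[roles == "active_control", , drop = FALSE]
  nc <- x[roles == "negative_control", , drop = FALSE]
  vapply(seq_len(ncol(x)), function(j) {
    a <- ac[, j]
    n <- nc[, j]
    sep <- abs(mean(a) - mean(n))
    if (!is.finite(sep) ||
        sep <= .Machine$double.eps * max(1, abs(mean(a)), abs(mean(n)))) {
      return(NA_real_)
    }
    1 - 3 * (stats::sd(a) + stats::sd(n)) / sep
  }, numeric(1))
}

#' Select features by per-feature Z'-factor
#'
#' Implements the feature-selection step of the multi-parametric data
#' analysis: for every feature, the Z'-factor between the plate's active-
#' and negative-control wells is computed; features whose Z' clears
#' `zprime_floor` are kept, ranked by decreasing Z', and truncated to
#' `max_features` (ties broken by the input column order, i.e. catalog
#' order). Degenerate features (constant, or equal control means) are
#' excluded. Keeping the subset small keeps the control covariance estimable
#' from a handful of control wells; in practice a small combination of shape
#' and intensity features carries the assay window.
#'
#' @param x Numeric feature matrix (wells x features) with column names.
#' @param roles Character vector of well roles aligned to rows of `x`.
#' @param zprime_floor Minimum per-feature Z' to retain (default 0).
#' @param max_features Cap on subset size (default 10).
#' @return Object of class `feature_subset`: list with `names` (ordered
#'   selected features) and `per_feature_zprime` (named, all non-degenerate
#'   features).
#' @export
select_features <- function(x, roles, zprime_floor = 0, max_features = 10L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(roles), !is.null(colnames(x)))
  if (!any(roles == "active_control") || !any(roles == "negative_control")) {
    stop("need active_control and negative_control wells", call. = FALSE)
  }
  z <- per_feature_zprime(x, roles)
  names(z) <- colnames(x)
  usable <- !is.na(z)
  keep <- usable & z >= zprime_floor
  if (!any(keep)) {
    stop("no feature clears the Z' floor of ", zprime_floor, call. = FALSE)
  }
  idx <- which(keep)
  # stable sort: descending Z', catalog order breaks ties
  idx <- idx[order(-z[idx], idx)]
  idx <- idx[seq_len(min(length(idx), max_features))]
  structure(list(names = colnames(x)[idx],
                 per_feature_zprime = z[usable]),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat("feature_subset:", length(x$names), "features\n")
  z <- x$per_feature_zprime[x$names]
  for (i in seq_along(z)) {
    cat(sprintf("  %-28s Z' = %.3f\n", names(z)[i], z[i]))
  }
  invisible(x)
}

#' Fit a control-population model
#'
#' Models one control population (active or negative) as a multivariate
#' normal with mean `mu` and a shrunk covariance
#' \deqn{\Sigma = (1-\lambda) S + \lambda \frac{tr(S)}{d} I}
#' where `S` is the sample covariance of the control wells. Shrinkage toward
#' the scaled identity guarantees a positive-definite `Sigma` whenever the
#' data are not entirely constant, which matters because the number of
#' control wells on a plate is often close to (or below) the number of
#' selected features.
#'
#' @param x Numeric matrix of control wells (rows) x selected features.
#' @param lambda Shrinkage intensity in \[0, 1\] (default 0.1).
#' @return Object of class `control_model`: `mu`, `sigma`, `lambda`, `n`,
#'   `feature_names`, and the upper Cholesky factor `chol` used for scoring.
#' @export
fit_control_model <- function(x, lambda = 0.1) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need >= 2 control wells", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("control features must be finite", call. = FALSE)
  }
  stopifnot(lambda >= 0, lambda <= 1)
  d <- ncol(x)
  mu <- colMeans(x)
  s <- stats::cov(x)
  target <- sum(diag(s)) / d
  sigma <- (1 - lambda) * s + lambda * target * diag(d)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    stop("control covariance is singular after shrinkage; ",
         "increase lambda or reduce the feature subset", call. = FALSE)
  }
  structure(list(mu = mu, sigma = sigma, lambda = lambda, n = nrow(x),
                 feature_names = colnames(x), chol = ch),
            class = "control_model")
}

#' @export
print.control_model <- function(x, ...) {
  cat(sprintf("control_model: %d wells, %d features, lambda = %.3g\n",
              x$n, length(x$mu), x$lambda))
  invisible(x)
}

#' Mahalanobis distance of wells to a control model
#'
#' Computes \eqn{\sqrt{(x-\mu)^\top \Sigma^{-1} (x-\mu)}} against the shrunk
#' control covariance, solving the triangular system from the stored
#' Cholesky factor rather than forming an explicit inverse. The distance is
#' zero exactly at the control mean and, at `lambda = 0` with a
#' non-singular sample covariance, is invariant under invertible affine maps
#' of the feature space.
#'
#' @param x Numeric vector (one well) or matrix (wells x features) matching
#'   the model's feature dimension.
#' @param model A [fit_control_model()] result.
#' @return Non-negative numeric vector of distances, one per well.
#' @export
mahalanobis_score <- function(x, model) {
  stopifnot(inherits(model, "control_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != length(model$mu)) {
    stop("feature dimension mismatch: got ", ncol(x), ", model has ",
         length(model$mu), call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("non-finite feature values", call. = FALSE)
  }
  xc <- t(sweep(x, 2L, model$mu))            # d x n deviations
  u <- forwardsolve(t(model$chol), xc)       # solve R' u = xc
  sqrt(colSums(u * u))
}

#' Score every well of a plate against its control models
#'
#' The per-plate scoring step of the pipeline: features are z-scaled using
#' the pooled control wells' mean and SD, the feature subset is selected on
#' this plate's controls (unless supplied), active- and negative-control
#' models are fit on the scaled controls, and every well -- controls
#' included -- receives a Mahalanobis distance to each model (`mhd_ac`,
#' `mhd_nc`). Plate quality control is the Z'-factor between the AC and NC
#' wells' `mhd_ac` distributions.
#'
#' Control models are fit per plate rather than pooled across the screen so
#' that plate-to-plate intensity drift cannot leak into the scores.
#'
#' @param x Feature matrix (wells x features), rownames = well addresses.
#' @param roles Character roles aligned to rows of `x`.
#' @param subset Optional [select_features()] result; selected on this
#'   plate's controls when `NULL`.
#' @param lambda Covariance shrinkage passed to [fit_control_model()].
#' @param zprime_floor,max_features Passed to [select_features()].
#' @return Object of class `plate_scores`: `scores` (data.frame `well`,
#'   `role`, `mhd_ac`, `mhd_nc`), `zprime` ([zprime()] result on the AC-vs-NC
#'   `mhd_ac` distributions), `subset`, `lambda`.
#' @export
score_plate <- function(x, roles, subset = NULL, lambda = 0.1,
                        zprime_floor = 0, max_features = 10L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(roles))
  is_ac <- roles == "active_control"
  is_nc <- roles == "negative_control"
  if (sum(is_ac) < 2L || sum(is_nc) < 2L) {
    stop("need >= 2 wells per control role", call. = FALSE)
  }
  ctrl <- x[is_ac | is_nc, , drop = FALSE]
  mu0 <- colMeans(ctrl)
  sd0 <- apply(ctrl, 2L, stats::sd)
  sd0[sd0 == 0 | !is.finite(sd0)] <- 1
  xs <- sweep(sweep(x, 2L, mu0), 2L, sd0, `/`)
  if (is.null(subset)) {
    subset <- select_features(xs[is_ac | is_nc, , drop = FALSE],
                              roles[is_ac | is_nc],
                              zprime_floor = zprime_floor,
                              max_features = max_features)
  }
  stopifnot(inherits(subset, "feature_subset"))
  xs <- xs[, subset$names, drop = FALSE]
  ac_model <- fit_control_model(xs[is_ac, , drop = FALSE], lambda = lambda)
  nc_model <- fit_control_model(xs[is_nc, , drop = FALSE], lambda = lambda)
  mhd_ac <- mahalanobis_score(xs, ac_model)
  mhd_nc <- mahalanobis_score(xs, nc_model)
  scores <- data.frame(
    well = rownames(x) %||% sprintf("w%03d", seq_len(nrow(x))),
    role = roles,
    mhd_ac = mhd_ac,
    mhd_nc = mhd_nc,
    stringsAsFactors = FALSE
  )
  qc <- zprime(mhd_ac[is_ac], mhd_ac[is_nc])
  structure(list(scores = scores, zprime = qc, subset = subset,
                 lambda = lambda,
                 ac_model = ac_model, nc_model = nc_model),
            class = "plate_scores")
}

#' @export
print.plate_scores <- function(x, ...) {
  cat(sprintf("plate_scores: %d wells, %d features, plate Z' = %.3f\n",
              nrow(x$scores), length(x$subset$names), x$zprime$zprime))
  invisible(x)
}
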