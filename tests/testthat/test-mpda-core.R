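test_that("zprime matches direct arithmetic on random parameter draws", {
  # independent oracle: plain arithmetic on the sample moments
  set.seed(42)
  for (i in 1:100) {
    p <- stats::rnorm(sample(3:30, 1), stats::runif(1, -50, 50),
                      stats::runif(1, 0.1, 10))
    m <- stats::rnorm(sample(3:30, 1), stats::runif(1, -50, 50),
                      stats::runif(1, 0.1, 10))
    if (abs(mean(p) - mean(m)) < 1e-6) next
    expected <- 1 - 3 * (stats::sd(p) + stats::sd(m)) / abs(mean(p) - mean(m))
    expect_equal(zprime(p, m)$zprime, expected, tolerance = 1e-12)
  }
})

test_that("zprime hits 0.6 on the canonical worked example", {
  # mu+ = 100 sd+ = 6, mu- = 10 sd- = 6: 1 - 3*12/90 = 0.6
  plus <- c(94, 100, 106)
  minus <- c(4, 10, 16)
  expect_equal(zprime(plus, minus)$zprime, 0.6, tolerance = 1e-12)
  # symmetric in the two populations
  expect_equal(zprime(minus, plus)$zprime, 0.6, tolerance = 1e-12)
})

test_that("zprime boundary behaviour: noiseless limit and degenerate cases", {
  expect_equal(zprime(c(5, 5), c(1, 1))$zprime, 1.0)
  expect_error(zprime(c(3, 3), c(3, 3)), "degenerate")
  expect_error(zprime(c(1, 2, 3), c(2, 2, 2, 2)), "degenerate")
  expect_error(zprime(5, c(1, 2)), ">= 2 values")
  expect_error(zprime(c(1, 2), c(NA, 2)), "finite")
  expect_lte(zprime(stats::rnorm(50), stats::rnorm(50, 100))$zprime, 1)
})

test_that("select_features ranks by Z', excludes degenerates, caps and tie-breaks", {
  roles <- rep(c("active_control", "negative_control"), each = 12L)
  # one perfectly separating feature among pure-noise features
  set.seed(1)
  x <- cbind(good = c(rep(100, 12), rep(0, 12)) + stats::rnorm(24, 0, 0.5),
             matrix(stats::rnorm(24 * 10), 24,
                    dimnames = list(NULL, paste0("noise", 1:10))))
  fs <- select_features(x, roles, zprime_floor = 0)
  expect_equal(fs$names, "good")

  # constant feature is excluded as degenerate
  x2 <- cbind(x, flat = rep(7, 24))
  fs2 <- select_features(x2, roles, zprime_floor = 0)
  expect_false("flat" %in% names(fs2$per_feature_zprime))

  # exact ties are broken by catalog (column) order, capped at max_features
  base <- c(rep(100, 12), rep(0, 12)) + rep(c(-1, 1), 12)
  x3 <- matrix(base, 24, 5, dimnames = list(NULL, paste0("f", 1:5)))
  fs3 <- select_features(x3, roles, max_features = 3L)
  expect_equal(fs3$names, c("f1", "f2", "f3"))

  expect_error(select_features(matrix(stats::rnorm(24), 24, 1,
                                      dimnames = list(NULL, "a")),
                               roles, zprime_floor = 0.99),
               "no feature clears")
})

test_that("per-feature Z' increases with simulated control separation", {
  set.seed(7)
  noise_a <- stats::rnorm(40)
  noise_n <- stats::rnorm(40)
  z_at <- function(sep) {
    x <- matrix(c(noise_a + sep, noise_n), 80, 1,
                dimnames = list(NULL, "f"))
    roles <- rep(c("active_control", "negative_control"), each = 40L)
    mpdascreen:::per_feature_zprime(x, roles)
  }
  zs <- vapply(c(6, 12, 24), z_at, numeric(1))
  expect_true(all(diff(zs) > 0))
})

test_that("control-model shrinkage endpoints behave as documented", {
  set.seed(3)
  x <- matrix(stats::rnorm(200 * 4), 200, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  # lambda = 0 with n >> d: exactly the sample covariance
  m0 <- fit_control_model(x, lambda = 0)
  expect_equal(m0$sigma, stats::cov(x), tolerance = 1e-12)
  # lambda = 1: scaled identity, so MHD is scaled Euclidean distance
  m1 <- fit_control_model(x, lambda = 1)
  s <- sum(diag(stats::cov(x))) / 4
  expect_equal(m1$sigma, s * diag(4), tolerance = 1e-12,
               ignore_attr = TRUE)
  v <- stats::rnorm(4)
  expect_equal(mahalanobis_score(m1$mu + v, m1),
               sqrt(sum(v^2) / s), tolerance = 1e-10)
})

test_that("shrinkage keeps few-well models positive definite", {
  # n = 3 wells, d = 10 features: sample covariance is rank deficient
  set.seed(11)
  x <- matrix(stats::rnorm(30), 3, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  expect_error(fit_control_model(x, lambda = 0), "singular")
  m <- fit_control_model(x, lambda = 0.1)
  ev <- eigen(m$sigma, symmetric = TRUE, only.values = TRUE)$values
  s <- stats::cov(x)
  expect_gte(min(ev), 0.1 * sum(diag(s)) / 10 - 1e-10)
  expect_true(all(is.finite(mahalanobis_score(x, m))))
})

test_that("mahalanobis_score matches the explicit-inverse oracle", {
  set.seed(19)
  for (i in 1:100) {
    d <- sample(1:5, 1)
    a <- matrix(stats::rnorm(d * d), d)
    sigma <- crossprod(a) + diag(d) * 0.5
    mu <- stats::rnorm(d)
    model <- structure(list(mu = mu, sigma = sigma, lambda = 0, n = 99L,
                            feature_names = paste0("f", 1:d),
                            chol = chol(sigma)),
                       class = "control_model")
    x <- matrix(stats::rnorm(20 * d), 20, d)
    got <- mahalanobis_score(x, model)
    oracle <- sqrt(stats::mahalanobis(x, mu, sigma))
    expect_equal(got, unname(oracle), tolerance = 1e-8)
  }
})

test_that("MHD is zero at the mean, positive elsewhere, 1-D sanity", {
  set.seed(5)
  x <- matrix(stats::rnorm(50 * 3), 50, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  m <- fit_control_model(x, lambda = 0)
  expect_equal(mahalanobis_score(m$mu, m), 0)
  expect_true(all(mahalanobis_score(x, m) >= 0))
  # 1-D model with variance 4: |x - mu| / 2
  m1 <- structure(list(mu = 0, sigma = matrix(4), lambda = 0, n = 10L,
                       feature_names = "f", chol = chol(matrix(4))),
                  class = "control_model")
  expect_equal(mahalanobis_score(4, m1), 2.0)
  expect_error(mahalanobis_score(c(1, 2), m1), "dimension mismatch")
  expect_error(mahalanobis_score(NA_real_, m1), "finite")
})

test_that("MHD is invariant under invertible affine maps at lambda 0", {
  set.seed(29)
  d <- 4
  x <- matrix(stats::rnorm(60 * d), 60, d)
  q <- matrix(stats::rnorm(200 * d), 200, d)
  m <- fit_control_model(`colnames<-`(x, paste0("f", 1:d)), lambda = 0)
  base <- mahalanobis_score(q, m)
  for (i in 1:20) {
    repeat {
      a <- matrix(stats::rnorm(d * d), d)
      if (abs(det(a)) > 0.1) break
    }
    b <- stats::rnorm(d)
    xt <- sweep(x %*% a, 2, b, `+`)
    qt <- sweep(q %*% a, 2, b, `+`)
    mt <- fit_control_model(`colnames<-`(xt, paste0("f", 1:d)), lambda = 0)
    expect_equal(mahalanobis_score(qt, mt), base, tolerance = 1e-8)
  }
})

test_that("score_plate scores every well and computes plate QC", {
  cfg <- screen_sim_config()
  tb <- simulate_feature_table(cfg, seed = 31)
  sc <- score_replicate_table(tb)
  expect_equal(nrow(sc), 384L)
  expect_true(all(is.finite(sc$mhd_ac)) && all(sc$mhd_ac >= 0))
  expect_true(all(is.finite(sc$mhd_nc)) && all(sc$mhd_nc >= 0))
  is_ac <- sc$role == "active_control"
  is_nc <- sc$role == "negative_control"
  expect_lt(stats::median(sc$mhd_ac[is_ac]),
            stats::median(sc$mhd_ac[is_nc]))
  expect_true(is.finite(attr(sc, "plate_zprime")))
})

test_that("a controls-only plate is scoreable with defined QC", {
  cfg <- screen_sim_config()
  tb <- simulate_feature_table(cfg, n_compound = 0L, seed = 33)
  tb <- tb[tb$role != "compound", ]
  x <- as.matrix(tb[, attr(tb, "params")$feature_names])
  rownames(x) <- tb$well
  ps <- score_plate(x, tb$role)
  expect_equal(nrow(ps$scores), 32L)
  expect_true(is.finite(ps$zprime$zprime))
})

test_that("per-column affine maps leave well scores unchanged at lambda 0", {
  cfg <- screen_sim_config(feature_dim = 6L, n_informative = 6L)
  tb <- simulate_feature_table(cfg, n_ac = 20L, n_nc = 20L,
                               n_compound = 40L, seed = 37)
  feat <- attr(tb, "params")$feature_names
  x <- as.matrix(tb[, feat])
  rownames(x) <- tb$well
  ps1 <- score_plate(x, tb$role, lambda = 0, max_features = 6L,
                     zprime_floor = -Inf)
  set.seed(1)
  scale <- stats::runif(ncol(x), 0.2, 5)
  shift <- stats::rnorm(ncol(x), 0, 50)
  x2 <- sweep(sweep(x, 2, scale, `*`), 2, shift, `+`)
  ps2 <- score_plate(x2, tb$role, lambda = 0, max_features = 6L,
                     zprime_floor = -Inf)
  expect_equal(ps2$scores$mhd_ac, ps1$scores$mhd_ac, tolerance = 1e-8)
  expect_equal(ps2$scores$mhd_nc, ps1$scores$mhd_nc, tolerance = 1e-8)
})
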