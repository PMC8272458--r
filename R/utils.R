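#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic entry points route
# through this so outputs are pure functions of (arguments, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from (seed, k) that stays inside 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Draw n rows from N(mu, Sigma) given the upper Cholesky factor of Sigma.
rmvn_chol <- function(n, mu, chol_upper) {
  d <- length(mu)
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(z %*% chol_upper, 2L, mu, `+`)
}

# Longest run of TRUE in a logical vector (NA treated as FALSE).
max_true_run <- function(x) {
  x <- !is.na(x) & x
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}
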