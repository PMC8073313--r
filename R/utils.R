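#' @keywords internal
"_PACKAGE"

# Run code with a local RNG seed, restoring the caller's RNG state afterwards.
# All generators funnel randomness through here so that same seed => identical
# output regardless of surrounding code.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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

# Derive a child seed from a base seed; keeps results < 2^31 - 1.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 9973) %% (2^31 - 1))
}

# Lognormal meanlog/sdlog matching a target arithmetic mean and sd.
# Used throughout the synthetic generators for positive-valued parameters so
# that draws are positive while preserving the stated mean and sd exactly.
lnorm_pars <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) return(c(meanlog = log(mean), sdlog = 0))
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

rlnorm_ms <- function(n, mean, sd) {
  p <- lnorm_pars(mean, sd)
  if (p[["sdlog"]] == 0) rep(mean, n) else stats::rlnorm(n, p[["meanlog"]], p[["sdlog"]])
}

# Savitzky-Golay coefficients for a symmetric window (polynomial least squares).
# deriv = 0 returns the smoother, deriv = 1 the first-derivative filter
# (per sample; divide by the sampling interval for physical units).
sg_coefficients <- function(window, order = 2L, deriv = 0L) {
  if (window %% 2L != 1L || window < 3L) {
    stop("smoothing window must be odd and >= 3", call. = FALSE)
  }
  if (order >= window) stop("polynomial order must be < window", call. = FALSE)
  h <- (window - 1L) / 2L
  x <- (-h):h
  A <- outer(x, 0:order, `^`)
  cf <- solve(crossprod(A), t(A))[deriv + 1L, ]
  cf * factorial(deriv)
}

# Apply an SG filter; returns a vector the same length as y with NA at the
# edges (half-window on each side), like stats::filter().
sg_apply <- function(y, window, order = 2L, deriv = 0L) {
  cf <- sg_coefficients(window, order, deriv)
  h <- (window - 1L) / 2L
  n <- length(y)
  if (n < window) stop("series shorter than the smoothing window", call. = FALSE)
  out <- rep(NA_real_, n)
  for (j in seq_along(cf)) {
    idx <- (h + 1L):(n - h)
    out[idx] <- if (j == 1L) cf[j] * y[idx - h] else out[idx] + cf[j] * y[idx + (j - 1L) - h]
  }
  out
}

# Mean/SEM/n summary used by condition tables. SEM is NA for n < 2.
mean_sem <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  c(
    mean = if (n > 0) mean(x) else NA_real_,
    sem = if (n >= 2) stats::sd(x) / sqrt(n) else NA_real_,
    n = n
  )
}
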