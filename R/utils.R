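# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @keywords internal
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Weighted median of `x` with positive integer-ish weights is never needed;
# the category statistic throughout is the plain sample median, with the
# mean-of-central-pair convention for even n (stats::median default).
category_median <- function(x) stats::median(x)

# Check a correlation matrix: symmetric, unit diagonal, positive
# semi-definite (smallest eigenvalue >= -tol).
check_correlation_matrix <- function(R, label = "correlation matrix",
                                     tol = 1e-8) {
  assert_that(is.matrix(R) && nrow(R) == ncol(R),
              sprintf("%s must be a square matrix", label))
  assert_that(max(abs(R - t(R))) < 1e-8, sprintf("%s is not symmetric", label))
  assert_that(max(abs(diag(R) - 1)) < 1e-8,
              sprintf("%s does not have a unit diagonal", label))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    stop(sprintf("%s is not positive semi-definite (min eigenvalue %.3g); fix the input values rather than relying on automatic repair",
                 label, min(ev)), call. = FALSE)
  }
  invisible(TRUE)
}

# Covariance from SD vector and correlation matrix: D R D.
make_covariance <- function(sd, R) {
  D <- diag(sd, nrow = length(sd))
  D %*% R %*% D
}

# Multivariate Gaussian log-density via the Cholesky factor. `x` is an
# n x m matrix of points. Errors name the offending group when the
# covariance is singular.
ldmvnorm <- function(x, mean, sigma, label = "covariance") {
  m <- length(mean)
  ch <- tryCatch(chol(sigma),
                 error = function(e) stop(sprintf(
                   "singular or non-positive-definite %s matrix", label),
                   call. = FALSE))
  centred <- sweep(x, 2L, mean, "-")
  z <- centred %*% backsolve(ch, diag(m))
  -0.5 * (m * log(2 * pi) + rowSums(z^2)) - sum(log(diag(ch)))
}

# Draw n multivariate Gaussian deviates (n x m matrix) using the current
# RNG stream. Zero-variance coordinates are allowed (degenerate,
# noise-free); they are held at their mean.
rmvnorm_chol <- function(n, mean, sigma) {
  m <- length(mean)
  out <- matrix(mean, nrow = n, ncol = m, byrow = TRUE)
  live <- which(diag(sigma) > 0)
  if (length(live) == 0L) return(out)
  ch <- chol(sigma[live, live, drop = FALSE])
  z <- matrix(stats::rnorm(n * length(live)), nrow = n)
  out[, live] <- out[, live, drop = FALSE] + z %*% ch
  out
}

# Deterministic sub-seed derived from a root seed and a stage label, kept
# within the 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}
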