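#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

SEGMENTS <- paste0("A", 1:8)

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Multivariate normal log-density via Cholesky
#'
#' Log density of `x` (a vector, or a matrix with one observation per row)
#' under N(mean, sigma). Used throughout the Brownian-motion likelihood.
#'
#' @param x numeric vector or matrix.
#' @param mean numeric vector (recycled across rows of `x`).
#' @param sigma positive-definite covariance matrix.
#' @return numeric vector of log densities.
#' @keywords internal
ldmvnorm <- function(x, mean = 0, sigma) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  p <- ncol(x)
  ch <- chol(sigma)
  z <- backsolve(ch, t(x) - mean, transpose = TRUE)
  -0.5 * p * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

# draw n MVN deviates; thin wrapper so callers carry an explicit seed
rmvn <- function(n, mu, sigma) {
  if (length(mu) == 1L) {
    matrix(stats::rnorm(n, mu, sqrt(as.numeric(sigma))), ncol = 1L)
  } else {
    MASS::mvrnorm(n, mu = mu, Sigma = sigma)
  }
}

#' Effective sample size of an MCMC trace
#'
#' Initial positive sequence estimator (sums of adjacent autocorrelation
#' pairs, truncated when a pair sum goes non-positive).
#'
#' @param x numeric vector, one scalar parameter's trace.
#' @return effective sample size (numeric scalar, at most `length(x)`).
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4L || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 2L, 2000L), plot = FALSE)$acf[-1]
  m <- floor(length(ac) / 2)
  tau <- 1
  for (k in seq_len(m)) {
    pair <- ac[2 * k - 1] + ac[2 * k]
    if (pair <= 0) break
    tau <- tau + 2 * pair
  }
  min(n, n / tau)
}

check_psd <- function(m, name = "sigma2") {
  m <- as.matrix(m)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    abort(sprintf("`%s` must be symmetric", name), class = "segmorph_invalid_argument")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    abort(sprintf("`%s` must be positive semi-definite", name), class = "segmorph_invalid_argument")
  invisible(m)
}

assert_measurements <- function(measurements) {
  need <- c("species", "larva_id", "segment", "x_anterior_um", "x_posterior_um", "body_length_um")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    abort(paste0("measurement table lacks columns: ", paste(miss, collapse = ", ")),
          class = "segmorph_invalid_argument")
  invisible(measurements)
}

seg_index <- function(segment) match(segment, SEGMENTS)
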