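#' Precompute per-column prefix sums of the sufficient statistics
#'
#' Builds cumulative column totals of the family's sufficient statistics so
#' that any block total over columns `r:s` is recoverable in O(1) as
#' `prefix[s + 1] - prefix[r]`. Bernoulli needs the count of ones and of
#' observed entries; Gaussian needs the sum, the sum of squares and the count
#' of observed entries. The whole build costs O(n * m).
#'
#' @param data a [cpd_data()] object.
#' @return an object of class `cpd_prefix` with numeric prefix vectors of
#'   length `m + 1` (index 1 is zero) and fields `family`, `n`, `m`.
#' @examples
#' x <- cpd_data(matrix(c(1, 0, 1, 1, 1, 0), nrow = 2, byrow = TRUE), "bernoulli")
#' build_prefix(x)$ones  # 0 2 3 4
#' @export
build_prefix <- function(data) {
  stopifnot(inherits(data, "cpd_data"))
  v <- data$values
  v[!data$mask] <- 0
  cnt <- c(0, cumsum(unname(colSums(data$mask))))
  out <- list(family = data$family, n = data$n, m = data$m, cnt = cnt)
  if (data$family == "bernoulli") {
    out$ones <- c(0, cumsum(unname(colSums(v))))
  } else {
    out$sum <- c(0, cumsum(unname(colSums(v))))
    out$sumsq <- c(0, cumsum(unname(colSums(v * v))))
  }
  structure(out, class = "cpd_prefix")
}

#' @export
print.cpd_prefix <- function(x, ...) {
  cat(sprintf("cpd_prefix: family = %s, n = %d, m = %d\n", x$family, x$n, x$m))
  invisible(x)
}

.check_interval <- function(prefix, r, s) {
  if (length(r) != 1L || length(s) != 1L || is.na(r) || is.na(s))
    stop_validation("interval endpoints must be scalar integers")
  if (r > s) stop_validation(sprintf("invalid interval %d:%d (r > s)", r, s))
  if (r < 1L || s > prefix$m)
    stop_validation(sprintf("interval %d:%d outside 1:%d", r, s, prefix$m))
}

#' Maximum-likelihood fit of one block
#'
#' Estimates the family parameter on the block of columns `r:s` (1-based,
#' inclusive) from prefix sums, and evaluates the block's negative
#' log-likelihood at that estimate, summed over all observed entries.
#' Bernoulli uses the 0 * log 0 = 0 convention, so degenerate frequencies
#' give a finite (zero) contribution; the Gaussian variance MLE is clamped
#' below at `variance_floor` so constant blocks keep a finite likelihood.
#'
#' @param prefix a [build_prefix()] object.
#' @param r,s first and last column of the block (1-based, inclusive).
#' @param variance_floor lower clamp for the Gaussian variance MLE.
#' @return a list of class `block_estimate`: `theta` (`p_hat`, or
#'   `c(mu, sigma2)`), `nll`, and `n_obs`, the number of observed entries.
#' @examples
#' x <- cpd_data(matrix(c(1, 0, 1, 1, 1, 0), nrow = 2, byrow = TRUE), "bernoulli")
#' block_fit(build_prefix(x), 1, 3)
#' @export
block_fit <- function(prefix, r, s, variance_floor = 1e-8) {
  stopifnot(inherits(prefix, "cpd_prefix"))
  .check_interval(prefix, r, s)
  N <- prefix$cnt[s + 1] - prefix$cnt[r]
  if (N <= 0)
    stop_validation(sprintf("block %d:%d contains no observed entries", r, s))
  if (prefix$family == "bernoulli") {
    S <- prefix$ones[s + 1] - prefix$ones[r]
    p <- S / N
    nll <- 0
    if (S > 0) nll <- nll - S * log(p)
    if (N - S > 0) nll <- nll - (N - S) * log(1 - p)
    est <- list(theta = c(p_hat = p), nll = nll, n_obs = N)
  } else {
    sm <- prefix$sum[s + 1] - prefix$sum[r]
    ss <- prefix$sumsq[s + 1] - prefix$sumsq[r]
    mu <- sm / N
    v <- ss / N - mu * mu
    if (v < variance_floor) v <- variance_floor
    nll <- 0.5 * N * (log(2 * pi * v) + 1)
    est <- list(theta = c(mu = mu, sigma2 = v), nll = nll, n_obs = N)
  }
  structure(est, class = "block_estimate")
}

# like block_fit but returns an NA-parameter zero-likelihood estimate for a
# block with no observed entries (solvers may legitimately produce one when
# whole columns are missing)
.block_fit_safe <- function(prefix, r, s, variance_floor = 1e-8) {
  N <- prefix$cnt[s + 1] - prefix$cnt[r]
  if (N <= 0) {
    theta <- if (prefix$family == "bernoulli") c(p_hat = NA_real_)
             else c(mu = NA_real_, sigma2 = NA_real_)
    return(structure(list(theta = theta, nll = 0, n_obs = 0),
                     class = "block_estimate"))
  }
  block_fit(prefix, r, s, variance_floor)
}

#' @export
print.block_estimate <- function(x, ...) {
  cat("block_estimate:", paste(names(x$theta), signif(x$theta, 6),
                               sep = " = ", collapse = ", "),
      sprintf("| nll = %g over %d entries\n", x$nll, x$n_obs))
  invisible(x)
}
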