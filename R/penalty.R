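#' Regularization: constant cost per block
#'
#' Every block contributes rho = 1, so the penalty term counts blocks:
#' R(C) = k_C + 1 over the blocks of C.
#' @return a regularization descriptor of class `cpd_reg`.
#' @export
reg_constant <- function() {
  structure(list(type = "constant"), class = "cpd_reg")
}

#' Regularization: physical block span with a minimal-size threshold
#'
#' For a block of columns `r:s` with physical positions `B` (base pairs),
#' rho(r, s) is the span `|B(s) - B(r)| / beta` (megabases when
#' `beta = 1e6`), and +Inf when that span is at most `T`. Infinite-cost
#' blocks can never appear in a finite-cost segmentation, so `T` acts as a
#' hard minimum on the physical size of any estimated block — in the ROH
#' application, the minimal physical distance allowed for an island.
#'
#' @param positions numeric vector of per-column physical positions (bp),
#'   strictly increasing; one per data column.
#' @param T minimal admissible span, in units of `beta` (megabases by
#'   default); blocks spanning `<= T` get infinite cost.
#' @param beta scaling from base pairs to the unit of `T` (default 1e6).
#' @return a regularization descriptor of class `cpd_reg`.
#' @export
reg_roh <- function(positions, T, beta = 1e6) {
  if (is.null(positions) || length(positions) < 1L)
    stop_validation("roh regularization requires per-column physical positions")
  if (any(diff(positions) <= 0))
    stop_validation("physical positions must be strictly increasing within a chromosome")
  if (T < 0) stop_validation("T must be non-negative")
  if (beta <= 0) stop_validation("beta must be positive")
  structure(list(type = "roh", positions = as.double(positions),
                 T = as.double(T), beta = as.double(beta)),
            class = "cpd_reg")
}

#' Evaluate the per-block regularization rho(r, s)
#'
#' @param reg a [reg_constant()] or [reg_roh()] descriptor.
#' @param r,s block endpoints (1-based column indices, inclusive).
#' @return 1 for the constant regularization; for the physical-distance
#'   regularization, the block span in megabases, or `Inf` when the span is
#'   at most `T`.
#' @export
rho <- function(reg, r, s) {
  stopifnot(inherits(reg, "cpd_reg"))
  if (r > s) stop_validation(sprintf("invalid interval %d:%d (r > s)", r, s))
  if (reg$type == "constant") return(1)
  if (s > length(reg$positions))
    stop_validation("interval endpoint beyond the marker map")
  span <- abs(reg$positions[s] - reg$positions[r]) / reg$beta
  if (span <= reg$T) Inf else span
}

#' Penalty specification
#'
#' Bundles the penalization constant lambda, the sample-size scaling J(n)
#' and the per-block regularization into the penalty term
#' lambda * J(n) * R(C) added to the negative log-likelihood.
#'
#' @param lambda non-negative penalization constant.
#' @param sample_penalty `"sqrt_n"` (default), `"log_n"`, or `"custom"` with
#'   `J` a function of n. Consistency of the estimator requires J(n) to grow,
#'   but slower than n.
#' @param J custom J(n) function, used when `sample_penalty = "custom"`.
#' @param reg regularization descriptor from [reg_constant()] or [reg_roh()].
#' @return an object of class `penalty_spec`.
#' @examples
#' penalty_spec(1)                      # lambda = 1, sqrt(n), one per block
#' penalty_spec(2, sample_penalty = "log_n")
#' @export
penalty_spec <- function(lambda, sample_penalty = c("sqrt_n", "log_n", "custom"),
                         J = NULL, reg = reg_constant()) {
  sample_penalty <- match.arg(sample_penalty)
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda < 0)
    stop_validation("lambda must be a single non-negative number")
  if (sample_penalty == "custom" && !is.function(J))
    stop_validation("sample_penalty = \"custom\" requires J to be a function of n")
  stopifnot(inherits(reg, "cpd_reg"))
  structure(list(lambda = as.double(lambda), sample_penalty = sample_penalty,
                 J = J, reg = reg),
            class = "penalty_spec")
}

#' Evaluate the sample-size penalty J(n)
#' @param pen a [penalty_spec()].
#' @param n sample count.
#' @return J(n).
#' @export
sample_penalty_value <- function(pen, n) {
  stopifnot(inherits(pen, "penalty_spec"))
  switch(pen$sample_penalty,
         sqrt_n = sqrt(n),
         log_n = log(n),
         custom = pen$J(n))
}

#' Penalized cost of one block
#'
#' Q(r:s) = nll(r:s) + lambda * J(n) * rho(r, s); `Inf` exactly when rho is
#' infinite. This is the additive cell the solvers minimize over.
#'
#' @param prefix a [build_prefix()] object.
#' @param pen a [penalty_spec()].
#' @param n sample count used in J(n).
#' @param r,s block endpoints (1-based, inclusive).
#' @param variance_floor Gaussian variance clamp, as in [block_fit()].
#' @return the penalized block cost (possibly `Inf`).
#' @export
block_cost <- function(prefix, pen, n, r, s, variance_floor = 1e-8) {
  fit <- block_fit(prefix, r, s, variance_floor)
  p <- rho(pen$reg, r, s)
  if (is.infinite(p)) return(Inf)
  fit$nll + (pen$lambda * sample_penalty_value(pen, n)) * p
}

# internal: block cost from a precomputed penalty weight pw = lambda * J(n),
# tolerant of empty blocks; used by pl_of so its arithmetic matches the solvers
.block_cost_pw <- function(prefix, reg, pw, r, s, variance_floor = 1e-8) {
  p <- rho(reg, r, s)
  if (is.infinite(p)) return(Inf)
  fit <- .block_fit_safe(prefix, r, s, variance_floor)
  fit$nll + pw * p
}
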