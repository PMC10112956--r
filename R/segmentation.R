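#' Validate a change-point set
#'
#' A change-point set over m columns is a strictly increasing integer vector
#' starting at 0 and ending at m; consecutive elements delimit the blocks
#' (block j spans columns (c_{j-1} + 1):c_j).
#'
#' @param points integer vector.
#' @param m number of columns.
#' @return the points, as integers, invisibly on success; errors otherwise.
#' @export
validate_change_points <- function(points, m) {
  points <- as.integer(round(points))
  if (length(points) < 2L || points[1] != 0L || points[length(points)] != m)
    stop_validation("change-point set must start at 0 and end at m = ", m)
  if (any(diff(points) <= 0L))
    stop_validation("change-point set must be strictly increasing")
  invisible(points)
}

# shared solver plumbing: marshal prefix sums + penalty into the C++ call
.solver_args <- function(prefix, pen, variance_floor) {
  pw <- pen$lambda * sample_penalty_value(pen, prefix$n)
  if (pen$reg$type == "roh") {
    if (length(pen$reg$positions) != prefix$m)
      stop_validation("physical positions must have one entry per data column")
    regtype <- 1L
    pos <- pen$reg$positions
    T <- pen$reg$T
    beta <- pen$reg$beta
  } else {
    regtype <- 0L
    pos <- double(prefix$m)
    T <- 0
    beta <- 1
  }
  if (prefix$family == "bernoulli") {
    pa <- prefix$ones
    pb <- double(prefix$m + 1)
    fam <- 0L
  } else {
    pa <- prefix$sum
    pb <- prefix$sumsq
    fam <- 1L
  }
  list(fam = fam, pa = pa, pb = pb, pcnt = prefix$cnt, pw = pw,
       vfloor = variance_floor, regtype = regtype, pos = pos, T = T, beta = beta)
}

# assemble a SegmentationResult from a change-point vector; pl_value is the
# left-to-right sum of the per-block penalized costs, the same accumulation
# order the dynamic program uses
.make_result <- function(prefix, pen, points, variance_floor, solver) {
  points <- validate_change_points(points, prefix$m)
  pw <- pen$lambda * sample_penalty_value(pen, prefix$n)
  nb <- length(points) - 1L
  fits <- vector("list", nb)
  rhos <- numeric(nb)
  pl <- 0
  for (j in seq_len(nb)) {
    r <- points[j] + 1L
    s <- points[j + 1L]
    fits[[j]] <- .block_fit_safe(prefix, r, s, variance_floor)
    rhos[j] <- rho(pen$reg, r, s)
    pl <- pl + (fits[[j]]$nll + pw * rhos[j])
  }
  total_nll <- sum(vapply(fits, `[[`, numeric(1), "nll"))
  structure(list(change_points = points,
                 k_hat = nb - 1L,
                 n_blocks = nb,
                 block_params = fits,
                 block_rho = rhos,
                 total_nll = total_nll,
                 total_penalty = pw * sum(rhos),
                 pl_value = pl,
                 lambda = pen$lambda,
                 sample_penalty = pen$sample_penalty,
                 Jn = sample_penalty_value(pen, prefix$n),
                 family = prefix$family,
                 n = prefix$n, m = prefix$m,
                 reg = pen$reg,
                 variance_floor = variance_floor,
                 solver = solver),
            class = "cpd_fit")
}

#' Exact penalized-likelihood segmentation by dynamic programming
#'
#' Minimizes PL(C) = -l(C) + lambda * J(n) * R(C) over all change-point sets
#' C by the optimal-partitioning recursion F(i) = min_c F(c) + Q((c+1):i),
#' where Q is the penalized block cost. The optimum is global and the run
#' costs O(n m + m^2): block costs come from prefix sums in O(1) each. Ties
#' in the recursion go to the leftmost admissible previous change-point, so
#' the output is deterministic.
#'
#' @param data a [cpd_data()] object.
#' @param pen a [penalty_spec()].
#' @param variance_floor Gaussian variance clamp (see [block_fit()]).
#' @return an object of class `cpd_fit`: `change_points` (including 0 and m),
#'   `k_hat` (internal change-point count), `block_params`, `total_nll`,
#'   `total_penalty`, `pl_value`, and the fit configuration.
#' @examples
#' x <- cpd_data(cbind(matrix(0, 50, 5), matrix(1, 50, 5)), "bernoulli")
#' fit_dp(x, penalty_spec(1))$change_points
#' @export
fit_dp <- function(data, pen, variance_floor = 1e-8) {
  stopifnot(inherits(data, "cpd_data"), inherits(pen, "penalty_spec"))
  prefix <- build_prefix(data)
  .fit_with_prefix(prefix, pen, "dp", variance_floor)
}

#' Greedy hierarchical (binary) segmentation
#'
#' Approximates the penalized-likelihood optimum by recursive splitting:
#' starting from the single interval 1:m, each interval I = r:s is split at
#' the leftmost minimizer of h_I(c) = PL(r:c) + PL((c+1):s) provided that
#' strictly improves on PL(I) (h_I(s) = PL(I) by the PL(empty) = 0
#' convention); recursion continues on both sides until no interval admits an
#' improving split. Typically much faster than [fit_dp()] when the number of
#' change-points is small; the result is not guaranteed optimal but is
#' consistent under the same conditions.
#'
#' @inheritParams fit_dp
#' @return a `cpd_fit` object, as in [fit_dp()].
#' @export
fit_hierarchical <- function(data, pen, variance_floor = 1e-8) {
  stopifnot(inherits(data, "cpd_data"), inherits(pen, "penalty_spec"))
  prefix <- build_prefix(data)
  .fit_with_prefix(prefix, pen, "hierarchical", variance_floor)
}

# run a solver against prebuilt prefix statistics (FRV reuses the prefix)
.fit_with_prefix <- function(prefix, pen, solver, variance_floor = 1e-8) {
  a <- .solver_args(prefix, pen, variance_floor)
  pts <- if (solver == "dp") {
    dp_solve_cpp(a$fam, a$pa, a$pb, a$pcnt, a$pw, a$vfloor,
                 a$regtype, a$pos, a$T, a$beta)
  } else {
    hs_solve_cpp(a$fam, a$pa, a$pb, a$pcnt, a$pw, a$vfloor,
                 a$regtype, a$pos, a$T, a$beta)
  }
  .make_result(prefix, pen, pts, variance_floor, solver)
}

#' Penalized likelihood of a given change-point set
#'
#' Evaluates PL(C) and the per-block maximum-likelihood fits for an arbitrary
#' user-supplied change-point set, without optimizing anything. Useful for
#' comparing candidate segmentations and for auditing solver output.
#'
#' @inheritParams fit_dp
#' @param C change-point vector (must start at 0 and end at m).
#' @return a `cpd_fit` object for the supplied set.
#' @export
pl_of <- function(data, pen, C, variance_floor = 1e-8) {
  stopifnot(inherits(data, "cpd_data"), inherits(pen, "penalty_spec"))
  prefix <- build_prefix(data)
  .make_result(prefix, pen, C, variance_floor, solver = "fixed")
}

#' @export
print.cpd_fit <- function(x, ...) {
  cat(sprintf("cpd_fit (%s, %s): n = %d, m = %d, lambda = %g, J(n) = %g\n",
              x$family, x$solver, x$n, x$m, x$lambda, x$Jn))
  cat(sprintf("  %d change-points: {%s}\n", x$k_hat,
              paste(x$change_points, collapse = ", ")))
  cat(sprintf("  -loglik = %.4f, penalty = %.4f, PL = %.4f\n",
              x$total_nll, x$total_penalty, x$pl_value))
  invisible(x)
}

#' Serialize a segmentation result to JSON
#'
#' Writes a structured document with the change-points, per-block parameter
#' estimates, block spans in column indices (and base pairs when a marker map
#' is supplied), and the penalty configuration.
#'
#' @param fit a `cpd_fit` object.
#' @param path output path.
#' @param map optional [marker_map()] covering the fitted columns.
#' @return `path`, invisibly.
#' @export
write_result <- function(fit, path, map = NULL) {
  stopifnot(inherits(fit, "cpd_fit"))
  pts <- fit$change_points
  nb <- fit$n_blocks
  blocks <- lapply(seq_len(nb), function(j) {
    r <- pts[j] + 1L
    s <- pts[j + 1L]
    b <- list(start_col = r, end_col = s,
              theta = as.list(fit$block_params[[j]]$theta),
              nll = fit$block_params[[j]]$nll,
              n_obs = fit$block_params[[j]]$n_obs)
    if (!is.null(map)) {
      b$start_bp <- map$pos[r]
      b$end_bp <- map$pos[s]
      b$chrom <- map$chrom[r]
    }
    b
  })
  doc <- list(format = "rohcpt_segmentation", version = 1L,
              family = fit$family, solver = fit$solver,
              n = fit$n, m = fit$m,
              lambda = fit$lambda, sample_penalty = fit$sample_penalty,
              Jn = fit$Jn,
              reg = fit$reg[setdiff(names(fit$reg), "positions")],
              change_points = as.integer(fit$change_points),
              k_hat = fit$k_hat,
              total_nll = fit$total_nll, total_penalty = fit$total_penalty,
              pl_value = fit$pl_value,
              blocks = blocks)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a segmentation result written by [write_result()]
#'
#' @param path path to the JSON document.
#' @return a `cpd_fit`-like object (class `cpd_fit`); block parameter
#'   estimates and the penalty configuration are restored, the raw data are
#'   not.
#' @export
read_result <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "rohcpt_segmentation"))
    stop_validation("not a rohcpt segmentation document: ", path)
  fits <- lapply(doc$blocks, function(b) {
    structure(list(theta = unlist(b$theta), nll = b$nll, n_obs = b$n_obs),
              class = "block_estimate")
  })
  pts <- as.integer(unlist(doc$change_points))
  reg <- doc$reg
  structure(list(change_points = pts,
                 k_hat = as.integer(doc$k_hat),
                 n_blocks = length(pts) - 1L,
                 block_params = fits,
                 total_nll = doc$total_nll,
                 total_penalty = doc$total_penalty,
                 pl_value = doc$pl_value,
                 lambda = doc$lambda,
                 sample_penalty = doc$sample_penalty,
                 Jn = doc$Jn,
                 family = doc$family,
                 n = as.integer(doc$n), m = as.integer(doc$m),
                 reg = reg,
                 solver = doc$solver),
            class = "cpd_fit")
}
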