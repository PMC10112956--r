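#' Configuration for the First Repeated Value (FRV) scan
#'
#' @param lambda_max upper end of the penalization-constant grid (default 10).
#' @param gamma grid step, or `"auto"` for 1/log(n) (falling back to
#'   `lambda_max / 20` when n <= 2, where log(n) is not a usable step).
#' @param solver `"hierarchical"` (default) or `"dp"`.
#' @param max_halvings safety cap on how many times the step may be halved
#'   when no repeated value is found on the current grid (default 20).
#' @return an object of class `frv_config`.
#' @export
frv_config <- function(lambda_max = 10, gamma = "auto",
                       solver = c("hierarchical", "dp"), max_halvings = 20L) {
  solver <- match.arg(solver)
  if (!is.numeric(lambda_max) || lambda_max <= 0)
    stop_validation("lambda_max must be positive")
  if (!identical(gamma, "auto")) {
    if (!is.numeric(gamma) || gamma <= 0)
      stop_validation("gamma must be positive or \"auto\"")
    if (gamma > lambda_max)
      stop_validation("gamma must not exceed lambda_max")
  }
  if (max_halvings < 1L) stop_validation("max_halvings must be at least 1")
  structure(list(lambda_max = lambda_max, gamma = gamma, solver = solver,
                 max_halvings = as.integer(max_halvings)),
            class = "frv_config")
}

#' Automatic penalization-constant selection by First Repeated Value
#'
#' Scans the grid lambda = gamma, 2 gamma, ..., b gamma (b = floor(lambda_max
#' / gamma)), fitting the model at each value and tracking the proportion of
#' change-points, k_C / m, where k_C counts the blocks of the fitted set (the
#' proportion is 1 for the saturated fit, which is also the reference value
#' the scan starts from, since an unpenalized fit splits everywhere). The
#' scan returns at the first grid point whose proportion equals the previous
#' one. If the whole grid is exhausted without a repeat, gamma is halved and
#' the scan restarts, up to `max_halvings` times.
#'
#' The rationale: the set of lambda values selecting exactly k change-points
#' is an interval whose length shrinks with n for k above the true count and
#' grows for k equal to it, so with a suitable step the first repeat happens
#' at the true count.
#'
#' @param data a [cpd_data()] object.
#' @param pen_template a [penalty_spec()] supplying J(n) and the
#'   regularization; its lambda is ignored.
#' @param cfg an [frv_config()].
#' @param variance_floor Gaussian variance clamp (see [block_fit()]).
#' @return an object of class `frv_result`: `selected_lambda`,
#'   `selected_model` (a `cpd_fit`), `trace` (data frame of lambda, k_hat,
#'   proportion per visited grid point), `halvings_used`, `gamma_final`.
#' @export
frv_select <- function(data, pen_template = penalty_spec(1), cfg = frv_config(),
                       variance_floor = 1e-8) {
  stopifnot(inherits(data, "cpd_data"), inherits(pen_template, "penalty_spec"),
            inherits(cfg, "frv_config"))
  prefix <- build_prefix(data)
  m <- prefix$m
  gamma <- if (identical(cfg$gamma, "auto")) {
    if (data$n > 2) 1 / log(data$n) else cfg$lambda_max / 20
  } else cfg$gamma
  if (gamma > cfg$lambda_max) gamma <- cfg$lambda_max

  trace <- list()
  halvings <- 0L
  repeat {
    last_prop <- 1  # the unpenalized fit splits everywhere: proportion 1
    b <- floor(cfg$lambda_max / gamma)
    for (i in seq_len(b)) {
      lam <- i * gamma
      pen <- penalty_spec(lam, sample_penalty = pen_template$sample_penalty,
                          J = pen_template$J, reg = pen_template$reg)
      fit <- .fit_with_prefix(prefix, pen, cfg$solver, variance_floor)
      prop <- fit$n_blocks / m
      trace[[length(trace) + 1L]] <-
        data.frame(lambda = lam, k_hat = fit$k_hat, proportion = prop,
                   gamma = gamma, halving = halvings)
      if (prop == last_prop) {
        if (prop == 1)
          warning("FRV selected a saturated model (proportion 1); ",
                  "the data may carry no block structure at this resolution")
        if (i == 1L)
          warning("FRV returned at the first grid point (lambda = gamma); ",
                  "consider a smaller gamma")
        return(structure(list(selected_lambda = lam,
                              selected_model = fit,
                              trace = do.call(rbind, trace),
                              halvings_used = halvings,
                              gamma_final = gamma),
                         class = "frv_result"))
      }
      last_prop <- prop
    }
    halvings <- halvings + 1L
    if (halvings > cfg$max_halvings) {
      cond <- structure(class = c("rohcpt_frv_error", "error", "condition"),
                        list(message = paste0(
                          "FRV found no repeated change-point count after ",
                          cfg$max_halvings, " step halvings"),
                          call = sys.call(-1),
                          trace = do.call(rbind, trace)))
      stop(cond)
    }
    gamma <- gamma / 2
  }
}

#' @export
print.frv_result <- function(x, ...) {
  cat(sprintf("frv_result: lambda = %g (gamma = %g, %d halvings), k_hat = %d\n",
              x$selected_lambda, x$gamma_final, x$halvings_used,
              x$selected_model$k_hat))
  invisible(x)
}
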