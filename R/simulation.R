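#' Draw a blockwise-constant simulation scenario
#'
#' Fixes the ground truth of a simulation study: k_star internal
#' change-points sampled without replacement, uniformly from 1:(m-1), and one
#' parameter per block. Bernoulli block frequencies are drawn Uniform(0, 1);
#' Gaussian block means are Normal(0, sd = `mean_sd`) and block variances
#' Exponential(rate = `var_rate`). The scenario is drawn once and then shared
#' by every dataset simulated from it, whatever the sample size, so
#' consistency can be studied as n grows against a fixed truth.
#'
#' @param family `"bernoulli"` or `"gaussian"`.
#' @param m number of variables (columns); default 200.
#' @param k_star number of internal change-points; must be < m.
#' @param seed integer seed for the scenario draw (independent of the seeds
#'   used to simulate datasets).
#' @param mean_sd standard deviation of the Gaussian block-mean draw
#'   (default 5).
#' @param var_rate rate of the Exponential block-variance draw (default 1).
#' @param change_points optional fixed change-point vector (0, ..., m),
#'   bypassing the draw.
#' @param params optional fixed per-block parameters: a numeric vector of
#'   frequencies (bernoulli) or a list with `mean` and `var` vectors
#'   (gaussian).
#' @return an object of class `cpd_scenario`.
#' @examples
#' sc <- draw_scenario("bernoulli", m = 50, k_star = 3, seed = 1)
#' sc$change_points
#' @export
draw_scenario <- function(family = c("bernoulli", "gaussian"), m = 200L,
                          k_star = 10L, seed = 1L, mean_sd = 5, var_rate = 1,
                          change_points = NULL, params = NULL) {
  family <- match.arg(family)
  m <- as.integer(m)
  k_star <- as.integer(k_star)
  if (k_star >= m) stop_validation("k_star must be smaller than m")
  if (k_star < 0L) stop_validation("k_star must be non-negative")
  sc <- with_seed(seed, {
    pts <- if (is.null(change_points)) {
      internal <- if (k_star > 0L) sort(sample.int(m - 1L, k_star)) else integer(0)
      c(0L, internal, m)
    } else validate_change_points(change_points, m)
    nb <- length(pts) - 1L
    par <- if (is.null(params)) {
      if (family == "bernoulli") list(p = runif(nb))
      else list(mean = rnorm(nb, 0, mean_sd), var = rexp(nb, var_rate))
    } else {
      if (family == "bernoulli") {
        stopifnot(is.numeric(params), length(params) == nb)
        list(p = as.double(params))
      } else {
        stopifnot(is.list(params), length(params$mean) == nb,
                  length(params$var) == nb)
        list(mean = as.double(params$mean), var = as.double(params$var))
      }
    }
    list(pts = pts, par = par)
  })
  flat <- if (family == "bernoulli") sc$par$p else sc$par$mean
  if (any(diff(flat) == 0))
    warning("adjacent blocks share identical parameters; ",
            "the boundary between them is not identifiable")
  structure(list(family = family, m = m, k_star = length(sc$pts) - 2L,
                 change_points = sc$pts, params = sc$par,
                 mean_sd = mean_sd, var_rate = var_rate, seed = seed),
            class = "cpd_scenario")
}

#' @export
print.cpd_scenario <- function(x, ...) {
  cat(sprintf("cpd_scenario (%s): m = %d, k_star = %d, seed = %d\n",
              x$family, x$m, x$k_star, x$seed))
  invisible(x)
}

#' Simulate a dataset from a scenario
#'
#' Draws n i.i.d. sample rows; within a row, the entries of block j are
#' i.i.d. from the family with that block's parameter.
#'
#' @param scenario a [draw_scenario()] object.
#' @param n number of sample rows.
#' @param seed integer seed for the data draw (independent of the scenario
#'   seed, so changing n or the replication never changes the truth).
#' @return a [cpd_data()] object.
#' @export
simulate_data <- function(scenario, n, seed = 1L) {
  stopifnot(inherits(scenario, "cpd_scenario"))
  n <- as.integer(n)
  if (n < 1L) stop_validation("n must be at least 1")
  pts <- scenario$change_points
  nb <- length(pts) - 1L
  values <- with_seed(seed, {
    cols <- vector("list", nb)
    for (j in seq_len(nb)) {
      len <- pts[j + 1L] - pts[j]
      cols[[j]] <- if (scenario$family == "bernoulli") {
        matrix(rbinom(n * len, 1L, scenario$params$p[j]), nrow = n)
      } else {
        matrix(rnorm(n * len, scenario$params$mean[j],
                     sqrt(scenario$params$var[j])), nrow = n)
      }
    }
    do.call(cbind, cols)
  })
  cpd_data(values, family = scenario$family)
}

#' Jaccard index between two change-point sets
#'
#' |C1 intersect C2| / |C1 union C2| over the full point sets, including the
#' shared endpoints 0 and m (so the index is always positive). Equals 1 iff
#' the sets are identical.
#'
#' @param C1,C2 change-point vectors over the same m.
#' @return a number in (0, 1].
#' @examples
#' jaccard(c(0, 5, 10), c(0, 10))        # 2/3
#' jaccard(c(0, 3, 7, 10), c(0, 3, 8, 10))  # 3/5
#' @export
jaccard <- function(C1, C2) {
  C1 <- unique(as.integer(C1))
  C2 <- unique(as.integer(C2))
  m1 <- max(C1)
  if (m1 != max(C2))
    stop_validation("change-point sets are over different m: ",
                    m1, " vs ", max(C2))
  validate_change_points(sort(C1), m1)
  validate_change_points(sort(C2), m1)
  length(intersect(C1, C2)) / length(union(C1, C2))
}

#' Run a simulation study over sample sizes and solvers
#'
#' For each sample size in `n_grid` and each replication: simulate a dataset
#' from the scenario, select the penalization constant by FRV for each
#' solver, fit, and record the Jaccard index between the estimated and true
#' change-point sets plus the estimated change-point count.
#'
#' @param scenario a [draw_scenario()] object.
#' @param n_grid integer vector of sample sizes.
#' @param replications datasets per sample size.
#' @param solvers subset of `c("dp", "hierarchical")`.
#' @param frv_cfg an [frv_config()] (its `solver` field is overridden per
#'   run).
#' @param pen_template a [penalty_spec()] providing J(n) and the
#'   regularization for every fit.
#' @param seed base seed; each (n, replication) dataset gets a seed derived
#'   deterministically from it.
#' @return a data frame with columns `n`, `replication`, `solver`,
#'   `jaccard`, `k_hat`, `lambda`.
#' @export
run_study <- function(scenario, n_grid, replications,
                      solvers = c("dp", "hierarchical"),
                      frv_cfg = frv_config(), pen_template = penalty_spec(1),
                      seed = 1L) {
  stopifnot(inherits(scenario, "cpd_scenario"), replications >= 1)
  solvers <- match.arg(solvers, c("dp", "hierarchical"), several.ok = TRUE)
  rows <- vector("list", length(n_grid) * replications * length(solvers))
  idx <- 0L
  counter <- 0L
  for (n in n_grid) {
    for (rep in seq_len(replications)) {
      counter <- counter + 1L
      ds_seed <- (seed + 9973L * counter) %% 2147483647L
      data <- simulate_data(scenario, n, seed = ds_seed)
      for (sv in solvers) {
        cfg <- frv_config(lambda_max = frv_cfg$lambda_max, gamma = frv_cfg$gamma,
                          solver = sv, max_halvings = frv_cfg$max_halvings)
        res <- tryCatch(
          frv_select(data, pen_template, cfg),
          error = function(e) stop("solver ", sv, " failed at n = ", n,
                                   ", replication ", rep, ": ",
                                   conditionMessage(e)))
        idx <- idx + 1L
        rows[[idx]] <- data.frame(
          n = n, replication = rep, solver = sv,
          jaccard = jaccard(res$selected_model$change_points,
                            scenario$change_points),
          k_hat = res$selected_model$k_hat,
          lambda = res$selected_lambda)
      }
    }
  }
  do.call(rbind, rows)
}

#' Serialize a scenario for exact replay
#' @param scenario a [draw_scenario()] object.
#' @param path output path (JSON).
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "cpd_scenario"))
  doc <- unclass(scenario)
  doc$format <- "rohcpt_scenario"
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a scenario written by [write_scenario()]
#' @param path path to the JSON document.
#' @return a `cpd_scenario` object.
#' @export
read_scenario <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "rohcpt_scenario"))
    stop_validation("not a rohcpt scenario document: ", path)
  structure(list(family = doc$family, m = as.integer(doc$m),
                 k_star = as.integer(doc$k_star),
                 change_points = as.integer(doc$change_points),
                 params = lapply(doc$params, as.double),
                 mean_sd = doc$mean_sd, var_rate = doc$var_rate,
                 seed = as.integer(doc$seed)),
            class = "cpd_scenario")
}
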