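test_that("rho evaluates the constant and physical-distance regularizations", {
  expect_equal(rho(reg_constant(), 3, 17), 1)

  pos <- c(1e6, 1.2e6, 1.5e6, 3e6, 5e6)
  rg <- reg_roh(pos, T = 1.0)
  expect_equal(rho(rg, 1, 3), Inf)   # span 0.5 Mb <= T = 1
  expect_equal(rho(rg, 1, 5), 4)     # span 4 Mb
  rg2 <- reg_roh(c(0, 2.5e6, 5e6), T = 1.0)
  expect_equal(rho(rg2, 1, 3), 5)

  expect_error(reg_roh(NULL, T = 1), "positions")
  expect_error(reg_roh(c(3, 2, 1), T = 1), "increasing")
})

test_that("block_cost adds lambda * J(n) * rho to the block nll", {
  x <- strong_two_block()
  pre <- build_prefix(x)
  nll <- block_fit(pre, 1, 20)$nll

  expect_equal(block_cost(pre, penalty_spec(0), x$n, 1, 20), nll)
  expect_equal(block_cost(pre, penalty_spec(2), 100, 1, 20), nll + 2 * 10 * 1)
  expect_equal(block_cost(pre, penalty_spec(1, "log_n"), x$n, 1, 20),
               nll + log(200))

  pos <- seq(1e6, 20e6, length.out = 20)
  pen_roh <- penalty_spec(1, reg = reg_roh(pos, T = 50))
  expect_equal(block_cost(pre, pen_roh, x$n, 1, 20), Inf)
})

test_that("fit_dp returns the known optimum on stylized inputs", {
  # constant data: any split costs penalty and gains no likelihood
  z <- cpd_data(matrix(0, 100, 50), "bernoulli")
  f <- fit_dp(z, penalty_spec(1))
  expect_equal(f$change_points, c(0L, 50L))
  expect_equal(unname(f$block_params[[1]]$theta), 0)

  # two well-separated blocks
  sc <- draw_scenario("bernoulli", m = 10, k_star = 1, seed = 5,
                      change_points = c(0, 5, 10), params = c(0.05, 0.95))
  x <- simulate_data(sc, 200, seed = 6)
  pen <- penalty_spec(1)
  f2 <- fit_dp(x, pen)
  expect_equal(f2$change_points, c(0L, 5L, 10L))
  # agrees with exhaustive minimization over all 2^9 segmentations
  or <- oracle_exhaustive(x, pen)
  expect_identical(f2$pl_value, or$pl)
  expect_identical(f2$change_points, or$points)

  # a huge penalty forces the single block
  f3 <- fit_dp(x, penalty_spec(1e6))
  expect_equal(f3$change_points, c(0L, 10L))
})

test_that("hierarchical segmentation matches dp on strong signals and stops on flat data", {
  x <- strong_two_block(n = 200, p = c(0.1, 0.9))
  pen <- penalty_spec(1)
  expect_identical(fit_hierarchical(x, pen)$change_points,
                   fit_dp(x, pen)$change_points)

  z <- cpd_data(matrix(1, 50, 30), "bernoulli")
  expect_equal(fit_hierarchical(z, penalty_spec(0.5))$change_points,
               c(0L, 30L))
})

test_that("pl_of evaluates arbitrary sets and is dominated by fit_dp", {
  set.seed(21)
  sc <- draw_scenario("bernoulli", m = 15, k_star = 2, seed = 3)
  x <- simulate_data(sc, 40, seed = 4)
  pen <- penalty_spec(1)

  whole <- pl_of(x, pen, c(0, 15))
  pre <- build_prefix(x)
  expect_equal(whole$total_nll, block_fit(pre, 1, 15)$nll)
  expect_equal(whole$pl_value,
               block_fit(pre, 1, 15)$nll + sqrt(40) * 1, tolerance = 1e-12)

  best <- fit_dp(x, pen)$pl_value
  for (i in 1:200) {
    k <- sample(0:6, 1)
    C <- c(0, sort(sample(1:14, k)), 15)
    expect_lte(best, pl_of(x, pen, C)$pl_value + 1e-12)
  }

  expect_error(pl_of(x, pen, c(0, 7, 7, 15)), "strictly increasing")
  expect_error(pl_of(x, pen, c(1, 15)), "start at 0")
})

test_that("at lambda = 0 the penalized likelihood is non-increasing under refinement", {
  set.seed(22)
  x <- cpd_data(matrix(rnorm(20 * 12), 20, 12), "gaussian")
  pen0 <- penalty_spec(0)
  C <- c(0, 4, 9, 12)
  for (extra in setdiff(1:11, C)) {
    refined <- sort(unique(c(C, extra)))
    expect_lte(pl_of(x, pen0, refined)$pl_value,
               pl_of(x, pen0, C)$pl_value + 1e-9)
  }
})

test_that("dp never does worse than hierarchical segmentation", {
  set.seed(23)
  for (i in 1:40) {
    fam <- if (i %% 2) "bernoulli" else "gaussian"
    sc <- draw_scenario(fam, m = sample(8:25, 1), k_star = sample(0:4, 1),
                        seed = i)
    x <- simulate_data(sc, sample(10:60, 1), seed = 100 + i)
    pen <- penalty_spec(sample(c(0.2, 1, 3), 1))
    expect_lte(fit_dp(x, pen)$pl_value,
               fit_hierarchical(x, pen)$pl_value + 1e-9)
  }
})

test_that("the detected change-point count is non-increasing in lambda", {
  sc <- draw_scenario("bernoulli", m = 60, k_star = 6, seed = 31)
  x <- simulate_data(sc, 150, seed = 32)
  ks <- vapply(c(0.05, 0.2, 0.5, 1, 2, 5, 10),
               function(l) fit_dp(x, penalty_spec(l))$k_hat, integer(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("solvers are deterministic and report consistent components", {
  sc <- draw_scenario("gaussian", m = 30, k_star = 3, seed = 41)
  x <- simulate_data(sc, 50, seed = 42)
  pen <- penalty_spec(1)
  f1 <- fit_dp(x, pen)
  f2 <- fit_dp(x, pen)
  expect_identical(f1$change_points, f2$change_points)
  expect_identical(f1$pl_value, f2$pl_value)
  h1 <- fit_hierarchical(x, pen)
  h2 <- fit_hierarchical(x, pen)
  expect_identical(h1$change_points, h2$change_points)

  for (f in list(f1, h1)) {
    expect_equal(f$pl_value, f$total_nll + f$total_penalty, tolerance = 1e-9)
    expect_equal(f$n_blocks, length(f$block_params))
    expect_equal(f$k_hat, length(f$change_points) - 2L)
  }
})

test_that("the physical-distance threshold is a hard minimum block span", {
  set.seed(51)
  sc <- draw_scenario("bernoulli", m = 40, k_star = 5, seed = 52)
  x <- simulate_data(sc, 100, seed = 53)
  pos <- cumsum(runif(40, 5e4, 3e5))
  T <- 1.5
  pen <- penalty_spec(0.5, reg = reg_roh(pos, T = T))
  for (fit in list(fit_dp(x, pen), fit_hierarchical(x, pen))) {
    pts <- fit$change_points
    spans <- (pos[pts[-1]] - pos[pts[-length(pts)] + 1]) / 1e6
    expect_true(all(spans > T))
  }

  # infeasible threshold: the whole span is below T
  pen_bad <- penalty_spec(0.5, reg = reg_roh(pos, T = 1e9))
  expect_error(fit_dp(x, pen_bad), "finite penalized cost")
  expect_error(fit_hierarchical(x, pen_bad), "finite penalized cost")
})

test_that("segmentation results round-trip through JSON", {
  x <- strong_two_block()
  f <- fit_dp(x, penalty_spec(1))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_result(f, tmp)
  g <- read_result(tmp)
  expect_identical(g$change_points, f$change_points)
  expect_equal(g$pl_value, f$pl_value)
  expect_equal(g$block_params[[1]]$theta, f$block_params[[1]]$theta)
  expect_equal(g$family, f$family)
})
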