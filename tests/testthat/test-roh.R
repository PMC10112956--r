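# deterministic 0/1 matrix whose column means are exact block frequencies:
# each column of block j has round(10 * p_j) ones out of n = 10 rows
exact_freq_data <- function(block_len, p) {
  cols <- unlist(mapply(function(len, pj) rep(pj, len), block_len, p,
                        SIMPLIFY = FALSE))
  v <- vapply(cols, function(pj) {
    ones <- round(10 * pj)
    c(rep(1, ones), rep(0, 10 - ones))
  }, numeric(10))
  cpd_data(v, "bernoulli")
}

test_that("marker maps validate coordinates", {
  mm <- marker_map(paste0("s", 1:4), c("1", "1", "2", "2"),
                   c(100, 200, 50, 400))
  expect_s3_class(mm, "marker_map")
  expect_error(marker_map("a", "1", -5), "non-negative")
  expect_error(marker_map(c("a", "b"), c("1", "1"), c(200, 100)),
               "strictly increasing")

  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write.table(mm, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  mm2 <- read_marker_map(tmp)
  expect_equal(mm2$pos, mm$pos)
})

test_that("the default minimal island span is 1% of the chromosome span", {
  mm <- marker_map(paste0("s", 1:3), rep("7", 3), c(1e6, 50e6, 101e6))
  expect_equal(unname(default_roh_threshold(mm)), 0.01 * 100e6 / 1e6)
})

test_that("island calling flags blocks at the length-weighted quantile cutoff", {
  x <- exact_freq_data(c(100, 50, 50), c(0.1, 0.2, 0.9))
  fit <- pl_of(x, penalty_spec(1), c(0, 100, 150, 200))
  mm <- marker_map(paste0("s", 1:200), rep("1", 200),
                   seq(1e5, by = 1e5, length.out = 200))
  calls <- call_islands(fit, mm, quantile = 0.95)
  expect_equal(attr(calls, "cutoff"), 0.9)
  expect_equal(sum(calls$island), 1)
  isl <- calls[calls$island, ]
  expect_equal(isl$start_col, 151)
  expect_equal(isl$end_col, 200)
  expect_equal(isl$p_hat, 0.9)
  # 0-based half-open physical coordinates
  expect_equal(isl$start, mm$pos[151] - 1)
  expect_equal(isl$end, mm$pos[200])

  # unweighted: one value per block; the 95th percentile of (0.1, 0.2, 0.9)
  # still isolates the top block
  calls_u <- call_islands(fit, mm, quantile = 0.95, weighted = FALSE)
  expect_equal(sum(calls_u$island), 1)

  # all blocks at the same frequency reach the cutoff: one whole-span island
  x2 <- exact_freq_data(c(100, 100), c(0.8, 0.8))
  fit2 <- pl_of(x2, penalty_spec(1), c(0, 100, 200))
  calls2 <- call_islands(fit2, mm, quantile = 0.95)
  expect_equal(nrow(calls2), 1)
  expect_true(calls2$island)
  expect_equal(calls2$start_col, 1)
  expect_equal(calls2$end_col, 200)
})

test_that("adjacent flagged blocks merge: no two contiguous islands remain", {
  x <- exact_freq_data(c(50, 50, 50, 50), c(0.1, 0.9, 0.8, 0.1))
  fit <- pl_of(x, penalty_spec(1), c(0, 50, 100, 150, 200))
  mm <- marker_map(paste0("s", 1:200), rep("1", 200),
                   seq(1e5, by = 1e5, length.out = 200))
  calls <- call_islands(fit, mm, quantile = 0.7)
  isl <- calls[calls$island, ]
  expect_equal(nrow(isl), 1)  # 0.9 and 0.8 blocks merged
  expect_equal(isl$start_col, 51)
  expect_equal(isl$end_col, 150)
  expect_equal(isl$p_hat, (0.9 * 50 + 0.8 * 50) / 100)
  # non-island rows are untouched
  expect_equal(sum(!calls$island), 2)
})

test_that("island calling requires a bernoulli fit", {
  g <- cpd_data(matrix(rnorm(200), 10, 20), "gaussian")
  fit <- pl_of(g, penalty_spec(1), c(0, 20))
  mm <- marker_map(paste0("s", 1:20), rep("1", 20), seq_len(20) * 1e5)
  expect_error(call_islands(fit, mm), "bernoulli")
})

test_that("island calls round-trip through BED", {
  x <- exact_freq_data(c(100, 50, 50), c(0.1, 0.2, 0.9))
  fit <- pl_of(x, penalty_spec(1), c(0, 100, 150, 200))
  mm <- marker_map(paste0("s", 1:200), rep("chr2", 200),
                   seq(1e5, by = 1e5, length.out = 200))
  calls <- call_islands(fit, mm, quantile = 0.95)
  tmp <- tempfile(fileext = ".bed")
  on.exit(unlink(tmp))
  write_islands_bed(calls, tmp)
  back <- read_islands_bed(tmp)
  isl <- calls[calls$island, ]
  expect_equal(back$chrom, isl$chrom)
  expect_equal(back$start, isl$start)
  expect_equal(back$end, isl$end)
  expect_equal(back$p_hat, isl$p_hat, tolerance = 1e-12)
})

test_that("base-pair overlap follows interval Jaccard arithmetic", {
  a <- data.frame(chrom = "1", start = 100, end = 200, island = TRUE)
  b <- data.frame(chrom = "1", start = 150, end = 250, island = TRUE)
  ov <- intersect_islands(a, b)
  expect_equal(ov$overall$bp_intersection, 50)
  expect_equal(ov$overall$bp_union, 150)
  expect_equal(ov$overall$intersection_pct, 100 * 50 / 150, tolerance = 1e-9)

  expect_equal(intersect_islands(a, a)$overall$intersection_pct, 100)

  c2 <- data.frame(chrom = "1", start = 500, end = 600, island = TRUE)
  expect_equal(intersect_islands(a, c2)$overall$intersection_pct, 0)
})

test_that("roh_segment fits chromosomes independently and respects T", {
  set.seed(71)
  sc1 <- draw_scenario("bernoulli", m = 60, k_star = 3, seed = 72)
  sc2 <- draw_scenario("bernoulli", m = 40, k_star = 2, seed = 73)
  x <- cpd_data(cbind(simulate_data(sc1, 120, seed = 74)$values,
                      simulate_data(sc2, 120, seed = 75)$values), "bernoulli")
  mm <- marker_map(paste0("s", 1:100),
                   rep(c("1", "2"), c(60, 40)),
                   c(cumsum(runif(60, 1e5, 5e5)), cumsum(runif(40, 1e5, 5e5))))
  gfit <- roh_segment(x, mm, lambda = 0.5, solver = "hierarchical")
  expect_named(gfit$fits, c("1", "2"))
  expect_equal(gfit$fits[["1"]]$m, 60)
  expect_equal(gfit$fits[["2"]]$m, 40)
  # per-chromosome fit equals the fit of the column slice alone
  sub <- cpd_data(x$values[, 1:60], "bernoulli")
  pos1 <- mm$pos[1:60]
  pen1 <- penalty_spec(0.5, reg = reg_roh(pos1, T = unname(gfit$T["1"])))
  expect_identical(gfit$fits[["1"]]$change_points,
                   fit_hierarchical(sub, pen1)$change_points)
  # islands inherit the minimal physical span
  calls <- call_islands(gfit)
  isl <- calls[calls$island, ]
  expect_true(all((isl$end - isl$start) / 1e6 > gfit$T[isl$chrom] - 1e-9))
})

test_that("a stricter quantile flags a subset of islands", {
  sc <- draw_scenario("bernoulli", m = 120, k_star = 8, seed = 76)
  x <- simulate_data(sc, 150, seed = 77)
  mm <- marker_map(paste0("s", 1:120), rep("1", 120),
                   cumsum(runif(120, 1e5, 4e5)))
  gfit <- roh_segment(x, mm, lambda = 0.5)
  c95 <- call_islands(gfit, quantile = 0.95)
  c99 <- call_islands(gfit, quantile = 0.99)
  m95 <- rep(FALSE, 120)
  for (i in which(c95$island)) m95[c95$start_col[i]:c95$end_col[i]] <- TRUE
  m99 <- rep(FALSE, 120)
  for (i in which(c99$island)) m99[c99$start_col[i]:c99$end_col[i]] <- TRUE
  expect_true(all(!m99 | m95))  # markers flagged at 0.99 are flagged at 0.95
})
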