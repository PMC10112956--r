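# Independent oracles used across the suite.

# brute-force negative log-likelihood of a block at the block MLE, computed
# entry by entry from the raw data (never through prefix sums)
oracle_block_nll <- function(values, mask, family, r, s, variance_floor = 1e-8) {
  v <- values[, r:s, drop = FALSE]
  ok <- mask[, r:s, drop = FALSE]
  x <- v[ok]
  if (length(x) == 0L) return(0)
  if (family == "bernoulli") {
    p <- mean(x)
    ll <- sum(ifelse(x == 1, log(p), log(1 - p)))
    if (p == 0) ll <- 0
    if (p == 1) ll <- 0
    -ll
  } else {
    mu <- mean(x)
    v2 <- mean((x - mu)^2)
    if (v2 < variance_floor) v2 <- variance_floor
    -sum(dnorm(x, mu, sqrt(v2), log = TRUE))
  }
}

# all change-point sets over m columns (2^(m-1) of them), cached per m
.seg_cache <- new.env(parent = emptyenv())
all_segmentations <- function(m) {
  key <- as.character(m)
  if (!is.null(.seg_cache[[key]])) return(.seg_cache[[key]])
  segs <- lapply(0:(2^(m - 1) - 1), function(mask) {
    internal <- which(bitwAnd(mask, bitwShiftL(1L, 0:(m - 2))) != 0L)
    c(0L, internal, m)
  })
  .seg_cache[[key]] <- segs
  segs
}

# exhaustive penalized-likelihood minimization: block costs from the public
# cost oracle, totals accumulated left to right (plain double adds, the same
# accumulation the dynamic program performs), minimum taken over every
# possible segmentation. Ties resolved the way leftmost backtracking does:
# among optimal sets, smallest last internal point, then smallest
# next-to-last, and so on (absent points count as 0).
oracle_exhaustive <- function(data, pen, variance_floor = 1e-8) {
  m <- data$m
  pre <- build_prefix(data)
  Q <- matrix(NA_real_, m, m)
  for (r in 1:m) for (s in r:m)
    Q[r, s] <- block_cost(pre, pen, data$n, r, s, variance_floor)
  segs <- all_segmentations(m)
  pls <- vapply(segs, function(pts) {
    tot <- 0
    for (j in seq_len(length(pts) - 1L)) tot <- tot + Q[pts[j] + 1L, pts[j + 1L]]
    tot
  }, numeric(1))
  best <- min(pls)
  cands <- segs[pls == best]
  key <- function(pts) {
    k <- rev(pts[-c(1, length(pts))])
    c(k, rep(0L, m - length(k)))
  }
  keys <- t(vapply(cands, key, integer(m)))
  ord <- do.call(order, as.data.frame(keys))
  list(pl = best, points = as.integer(cands[[ord[1]]]))
}

# a small strong-signal two-block bernoulli dataset used by several tests
strong_two_block <- function(n = 200, m1 = 10, m2 = 10, p = c(0.1, 0.9),
                             seed = 42) {
  sc <- draw_scenario("bernoulli", m = m1 + m2, k_star = 1, seed = seed,
                      change_points = c(0, m1, m1 + m2), params = p)
  simulate_data(sc, n, seed = seed + 1)
}
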