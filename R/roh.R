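#' Marker map: chromosome and physical position per data column
#'
#' @param marker character vector of marker names.
#' @param chrom chromosome label per marker.
#' @param pos 1-based physical position in base pairs, strictly increasing
#'   within each chromosome.
#' @return a data frame of class `marker_map` with columns `marker`,
#'   `chrom`, `pos`.
#' @export
marker_map <- function(marker, chrom, pos) {
  if (length(marker) != length(chrom) || length(marker) != length(pos))
    stop_validation("marker, chrom and pos must have equal length")
  pos <- as.numeric(pos)
  if (any(is.na(pos)) || any(pos < 0))
    stop_validation("positions must be non-negative numbers")
  mm <- data.frame(marker = as.character(marker), chrom = as.character(chrom),
                   pos = pos, stringsAsFactors = FALSE)
  for (ch in unique(mm$chrom)) {
    p <- mm$pos[mm$chrom == ch]
    if (any(diff(p) <= 0))
      stop_validation("positions must be strictly increasing within chromosome ", ch)
  }
  class(mm) <- c("marker_map", "data.frame")
  mm
}

#' Read a marker map from TSV (columns: marker, chrom, pos)
#' @param path file path; must have a header row naming the three columns.
#' @return a [marker_map()].
#' @export
read_marker_map <- function(path) {
  if (!file.exists(path)) stop_validation("marker map not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(dt)))
    stop_validation("marker map needs columns: ", paste(need, collapse = ", "))
  marker_map(dt$marker, dt$chrom, dt$pos)
}

#' Default minimal island span: 1% of the chromosome's physical length
#'
#' @param map a [marker_map()].
#' @param beta base pairs per unit (1e6 for megabases).
#' @return named numeric vector: per chromosome, 0.01 times the span of the
#'   mapped markers, in units of `beta`.
#' @export
default_roh_threshold <- function(map, beta = 1e6) {
  stopifnot(inherits(map, "marker_map"))
  vapply(split(map$pos, map$chrom),
         function(p) 0.01 * (max(p) - min(p)) / beta, numeric(1))
}

#' Segment a codified SNP matrix per chromosome with the ROH regularization
#'
#' Splits the columns by chromosome (change-points never cross chromosome
#' boundaries), builds the physical-distance regularization for each
#' chromosome with minimal span `T`, and fits each chromosome independently,
#' either at a fixed lambda or with FRV selection per chromosome.
#'
#' @param data a bernoulli [cpd_data()]; columns must match `map` rows.
#' @param map a [marker_map()].
#' @param lambda fixed penalization constant; ignored when `frv_cfg` given.
#' @param frv_cfg optional [frv_config()]; when supplied, lambda is selected
#'   per chromosome by FRV (and `frv_cfg$solver` is used).
#' @param solver solver for fixed-lambda fits: `"hierarchical"` (default)
#'   or `"dp"`.
#' @param sample_penalty J(n) choice, as in [penalty_spec()].
#' @param T minimal island span in units of `beta`: a single number, a named
#'   per-chromosome vector, or `NULL` for the default 1% of each
#'   chromosome's span.
#' @param beta base pairs per unit (default 1e6, megabases).
#' @param variance_floor unused for bernoulli; kept for interface symmetry.
#' @return an object of class `cpd_genome_fit`: a list with `fits` (named
#'   per-chromosome `cpd_fit` list), `map`, `T`, `beta`, and `lambda` (per
#'   chromosome).
#' @export
roh_segment <- function(data, map, lambda = NULL, frv_cfg = NULL,
                        solver = c("hierarchical", "dp"),
                        sample_penalty = "sqrt_n", T = NULL, beta = 1e6,
                        variance_floor = 1e-8) {
  stopifnot(inherits(data, "cpd_data"), inherits(map, "marker_map"))
  solver <- match.arg(solver)
  if (nrow(map) != data$m)
    stop_validation("marker map must have one row per data column (",
                    nrow(map), " vs ", data$m, ")")
  if (is.null(lambda) && is.null(frv_cfg))
    stop_validation("supply either a fixed lambda or an frv_config")
  chroms <- unique(map$chrom)
  Tdef <- default_roh_threshold(map, beta)
  fits <- list()
  lambdas <- numeric(0)
  for (ch in chroms) {
    idx <- which(map$chrom == ch)
    Tch <- if (is.null(T)) Tdef[[ch]]
           else if (length(T) == 1L && is.null(names(T))) as.numeric(T)
           else as.numeric(T[[ch]])
    sub <- cpd_data(data$values[, idx, drop = FALSE], family = data$family,
                    mask = data$mask[, idx, drop = FALSE])
    reg <- reg_roh(map$pos[idx], T = Tch, beta = beta)
    if (is.null(frv_cfg)) {
      pen <- penalty_spec(lambda, sample_penalty = sample_penalty, reg = reg)
      fit <- if (solver == "dp") fit_dp(sub, pen, variance_floor)
             else fit_hierarchical(sub, pen, variance_floor)
      lambdas[ch] <- lambda
    } else {
      tmpl <- penalty_spec(1, sample_penalty = sample_penalty, reg = reg)
      res <- frv_select(sub, tmpl, frv_cfg, variance_floor)
      fit <- res$selected_model
      lambdas[ch] <- res$selected_lambda
    }
    fits[[ch]] <- fit
  }
  structure(list(fits = fits, map = map, T = Tdef, beta = beta,
                 lambda = lambdas),
            class = "cpd_genome_fit")
}

#' @export
print.cpd_genome_fit <- function(x, ...) {
  cat(sprintf("cpd_genome_fit: %d chromosome(s), %d markers\n",
              length(x$fits), nrow(x$map)))
  for (ch in names(x$fits))
    cat(sprintf("  %s: %d change-points, lambda = %g\n",
                ch, x$fits[[ch]]$k_hat, x$lambda[[ch]]))
  invisible(x)
}

# per-marker block frequency: every marker inherits the p_hat of its block
.marker_phat <- function(fit) {
  pts <- fit$change_points
  p <- vapply(fit$block_params, function(b) unname(b$theta[["p_hat"]]),
              numeric(1))
  rep(p, times = diff(pts))
}

#' Call ROH islands from a Bernoulli segmentation
#'
#' Islands are the blocks whose estimated frequency reaches the empirical
#' quantile cutoff of the fitted frequencies. By default the quantile is
#' taken over the per-marker values (each marker inherits its block's
#' estimate, so blocks are weighted by their length, comparable to a per-SNP
#' frequency distribution); set `weighted = FALSE` for one value per block.
#' Adjacent flagged blocks on the same chromosome are merged into a single
#' island interval.
#'
#' @param fit a `cpd_fit` from a bernoulli fit (one chromosome) or a
#'   `cpd_genome_fit`; the cutoff is computed over all supplied markers.
#' @param map a [marker_map()] covering the fitted columns (optional for a
#'   `cpd_genome_fit`, which carries its own).
#' @param quantile cutoff quantile in (0, 1); default 0.95.
#' @param weighted weight blocks by length when computing the cutoff.
#' @return a data frame of class `island_calls`, one row per (merged) block:
#'   `chrom`, `start`, `end` (base pairs, 0-based half-open), `start_col`,
#'   `end_col` (1-based columns, per chromosome), `p_hat`, `island`.
#' @export
call_islands <- function(fit, map = NULL, quantile = 0.95, weighted = TRUE) {
  if (inherits(fit, "cpd_genome_fit")) {
    fits <- fit$fits
    map <- fit$map
  } else {
    stopifnot(inherits(fit, "cpd_fit"))
    if (is.null(map)) stop_validation("a marker map is required")
    if (nrow(map) != fit$m)
      stop_validation("marker map must have one row per fitted column")
    if (length(unique(map$chrom)) != 1L)
      stop_validation("a single cpd_fit covers one chromosome; ",
                      "use roh_segment() for multi-chromosome data")
    fits <- setNames(list(fit), unique(map$chrom))
  }
  if (!(quantile > 0 && quantile < 1))
    stop_validation("quantile must be in (0, 1)")
  for (f in fits)
    if (f$family != "bernoulli")
      stop_validation("island calling requires a bernoulli family fit")

  pool <- if (weighted) {
    unlist(lapply(fits, .marker_phat), use.names = FALSE)
  } else {
    unlist(lapply(fits, function(f)
      vapply(f$block_params, function(b) unname(b$theta[["p_hat"]]),
             numeric(1))), use.names = FALSE)
  }
  cutoff <- as.numeric(stats::quantile(pool, probs = quantile, na.rm = TRUE,
                                       names = FALSE))

  out <- list()
  for (ch in names(fits)) {
    f <- fits[[ch]]
    pos <- map$pos[map$chrom == ch]
    pts <- f$change_points
    p <- vapply(f$block_params, function(b) unname(b$theta[["p_hat"]]),
                numeric(1))
    flag <- !is.na(p) & p >= cutoff
    nb <- length(p)
    j <- 1L
    while (j <= nb) {
      if (flag[j]) {
        j2 <- j
        while (j2 < nb && flag[j2 + 1L]) j2 <- j2 + 1L
        r <- pts[j] + 1L
        s <- pts[j2 + 1L]
        w <- diff(pts)[j:j2]
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch,
          start = pos[r] - 1, end = pos[s],  # 0-based half-open
          start_col = r, end_col = s,
          p_hat = sum(p[j:j2] * w) / sum(w),
          island = TRUE, stringsAsFactors = FALSE)
        j <- j2 + 1L
      } else {
        r <- pts[j] + 1L
        s <- pts[j + 1L]
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = pos[r] - 1, end = pos[s],
          start_col = r, end_col = s, p_hat = p[j],
          island = FALSE, stringsAsFactors = FALSE)
        j <- j + 1L
      }
    }
  }
  calls <- do.call(rbind, out)
  attr(calls, "cutoff") <- cutoff
  attr(calls, "quantile") <- quantile
  class(calls) <- c("island_calls", "data.frame")
  calls
}

#' Write island calls as BED3+ (chrom, 0-based half-open start/end, p_hat,
#' island flag)
#' @param calls an [call_islands()] data frame.
#' @param path output path.
#' @param islands_only write only the rows flagged as islands (default TRUE).
#' @return `path`, invisibly.
#' @export
write_islands_bed <- function(calls, path, islands_only = TRUE) {
  stopifnot(is.data.frame(calls))
  df <- as.data.frame(calls)
  if (islands_only && "island" %in% names(df)) df <- df[df$island, , drop = FALSE]
  bed <- data.frame(chrom = df$chrom,
                    start = format(df$start, scientific = FALSE, trim = TRUE),
                    end = format(df$end, scientific = FALSE, trim = TRUE),
                    p_hat = df$p_hat,
                    island = as.integer(if ("island" %in% names(df)) df$island
                                        else TRUE))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3(+) interval file of island calls
#' @param path BED path: chrom, start, end, optionally p_hat and island flag.
#' @return a data frame with columns `chrom`, `start`, `end` (plus `p_hat`,
#'   `island` when present), class `island_calls`.
#' @export
read_islands_bed <- function(path) {
  if (!file.exists(path)) stop_validation("BED file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "p_hat", "island")[
                     seq_len(max(count.fields(path, sep = "\t")))],
                   stringsAsFactors = FALSE)
  if (any(df$end <= df$start))
    stop_validation("malformed BED: end must exceed start")
  if ("island" %in% names(df)) df$island <- as.logical(df$island)
  else df$island <- TRUE
  class(df) <- c("island_calls", "data.frame")
  df
}

.island_granges <- function(x) {
  df <- as.data.frame(x)
  if ("island" %in% names(df)) df <- df[df$island, , drop = FALSE]
  if (nrow(df) == 0L)
    return(GenomicRanges::GRanges())
  GenomicRanges::reduce(GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)))
}

#' Base-pair overlap between two sets of island calls
#'
#' Compares two interval lists (half-open base-pair coordinates) per
#' chromosome and overall. The headline number is the Jaccard-style
#' intersection percentage 100 * |a intersect b| / |a union b| in base pairs.
#'
#' @param a,b island call data frames ([call_islands()] output or
#'   [read_islands_bed()]); rows with an `island` column are filtered to
#'   flagged ones.
#' @return a list with `per_chromosome` (data frame: chrom, bp_a, bp_b,
#'   bp_intersection, bp_union, intersection_pct) and `overall` (the same
#'   fields genome-wide).
#' @export
intersect_islands <- function(a, b) {
  ga <- .island_granges(a)
  gb <- .island_granges(b)
  chroms <- union(as.character(GenomicRanges::seqnames(ga)),
                  as.character(GenomicRanges::seqnames(gb)))
  per <- lapply(sort(chroms), function(ch) {
    sa <- ga[GenomicRanges::seqnames(ga) == ch]
    sb <- gb[GenomicRanges::seqnames(gb) == ch]
    bi <- sum(IRanges::width(GenomicRanges::intersect(sa, sb,
                                                      ignore.strand = TRUE)))
    bu <- sum(IRanges::width(GenomicRanges::union(sa, sb,
                                                  ignore.strand = TRUE)))
    data.frame(chrom = ch,
               bp_a = sum(IRanges::width(sa)), bp_b = sum(IRanges::width(sb)),
               bp_intersection = bi, bp_union = bu,
               intersection_pct = if (bu > 0) 100 * bi / bu else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  bi <- sum(per$bp_intersection)
  bu <- sum(per$bp_union)
  overall <- data.frame(bp_a = sum(per$bp_a), bp_b = sum(per$bp_b),
                        bp_intersection = bi, bp_union = bu,
                        intersection_pct = if (bu > 0) 100 * bi / bu
                                           else NA_real_)
  list(per_chromosome = per, overall = overall)
}
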