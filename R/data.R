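#' Construct a data matrix of aligned samples
#'
#' Wraps an n x m numeric matrix of n independent samples (rows) over m
#' aligned variables (columns), together with the model family and an
#' observation mask. For the ROH application the matrix is the codified SNP
#' matrix: entry (i, j) is 1 when marker j lies inside a run of homozygosity
#' of individual i, 0 otherwise.
#'
#' @param values numeric matrix, n rows (samples) by m columns (variables).
#'   `NA` entries are treated as missing and excluded from all likelihoods.
#' @param family `"bernoulli"` (0/1 entries) or `"gaussian"`.
#' @param mask optional logical matrix, `TRUE` where the entry is observed;
#'   defaults to `!is.na(values)`.
#' @return an object of class `cpd_data` with elements `values`, `mask`,
#'   `family`, `n`, `m`.
#' @examples
#' x <- cpd_data(matrix(c(1, 0, 1, 1, 1, 0), nrow = 2, byrow = TRUE), "bernoulli")
#' x$m
#' @export
cpd_data <- function(values, family = c("bernoulli", "gaussian"), mask = NULL) {
  family <- match.arg(family)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop_validation("data matrix must have at least one row and one column")
  if (is.null(mask)) mask <- !is.na(values)
  if (!is.logical(mask) || !identical(dim(mask), dim(values)))
    stop_validation("mask must be a logical matrix with the same shape as values")
  mask <- mask & !is.na(values)
  if (family == "bernoulli") {
    bad <- which(mask & !(values %in% c(0, 1)), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop_validation(sprintf(
        "bernoulli family requires 0/1 entries; first offending entry at row %d, column %d (value %g)",
        bad[1, 1], bad[1, 2], values[bad[1, 1], bad[1, 2]]))
  }
  structure(list(values = values, mask = mask, family = family,
                 n = nrow(values), m = ncol(values)),
            class = "cpd_data")
}

#' @export
print.cpd_data <- function(x, ...) {
  cat(sprintf("cpd_data: %d samples x %d variables, family = %s, %d missing entries\n",
              x$n, x$m, x$family, sum(!x$mask)))
  invisible(x)
}

#' Read a sample matrix from delimited text
#'
#' Reads a comma- or tab-delimited text file with one row per individual and
#' one column per variable (marker). An optional header row carries marker
#' names. Empty fields and `NA` are treated as missing.
#'
#' @param path file path.
#' @param family model family, as in [cpd_data()].
#' @param header `TRUE`, `FALSE` or `"auto"` (detect).
#' @return a `cpd_data` object; marker names, when present, are kept as
#'   column names of `$values`.
#' @export
read_matrix <- function(path, family = c("bernoulli", "gaussian"), header = "auto") {
  family <- match.arg(family)
  if (!file.exists(path)) stop_validation("input file not found: ", path)
  hdr <- if (identical(header, "auto")) "auto" else isTRUE(header)
  dt <- data.table::fread(path, header = hdr, na.strings = c("", "NA"),
                          data.table = FALSE, showProgress = FALSE)
  cpd_data(as.matrix(dt), family = family)
}

#' Write a sample matrix as tab-delimited text
#'
#' @param data a `cpd_data` object.
#' @param path output file path.
#' @param col_names write a header row of column names.
#' @export
write_matrix <- function(data, path, col_names = !is.null(colnames(data$values))) {
  stopifnot(inherits(data, "cpd_data"))
  out <- data$values
  out[!data$mask] <- NA
  data.table::fwrite(as.data.frame(out), path, sep = "\t",
                     col.names = col_names, na = "NA", quote = FALSE)
  invisible(path)
}
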