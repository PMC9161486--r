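#' Reads-per-million normalization
#'
#' Scales each sample's counts by its library size: rpm = count /
#' library_size * 1e6. A fully assigned library therefore has columns
#' summing to exactly one million.
#'
#' @param counts numeric matrix, features x samples, non-negative.
#' @param library_sizes per-sample totals (defaults to the column sums,
#'   i.e. treating the matrix itself as the whole library).
#' @return numeric matrix of RPM values, same dimnames.
#' @export
rpm_normalize <- function(counts, library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == length(library_sizes))
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  sweep(counts, 2L, library_sizes, "/") * 1e6
}

#' Keep features expressed above an RPM threshold
#'
#' Retains features whose per-feature summary (median by default)
#' across all samples is strictly greater than the threshold; the
#' conventional cut of 15 RPM defines the expressed-isomiR universe of
#' a cohort analysis.
#'
#' @param rpm numeric matrix of RPM values, features x samples.
#' @param threshold expression cut, default 15 RPM; strict `>`.
#' @param summary `"median"` (default) or `"mean"`.
#' @return the row-subset matrix (possibly 0 rows), dimnames kept.
#' @export
filter_expressed <- function(rpm, threshold = 15, summary = c("median", "mean")) {
  rpm <- as.matrix(rpm)
  summary <- match.arg(summary)
  f <- if (summary == "median") stats::median else mean
  keep <- apply(rpm, 1L, f) > threshold
  rpm[keep, , drop = FALSE]
}
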