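#' One-sided Fisher enrichment of a gene set among regulated features
#'
#' Builds the 2x2 table (regulated-in-set, regulated-not-in-set,
#' set-not-regulated, neither) over an explicit universe -- in a
#' proteome analysis the universe is every protein detected in at least
#' one sample -- and tests for over-representation with the
#' hypergeometric upper tail. The odds ratio is the sample odds ratio
#' (a*d)/(b*c), infinite when b*c = 0 with a*d > 0.
#'
#' @param regulated character vector of regulated feature ids.
#' @param gene_set character vector of set members.
#' @param universe character vector of all measured features.
#' @return list: `table` (a, b, c, d), `odds_ratio`, `p` (one-sided,
#'   enrichment).
#' @export
fisher_enrichment <- function(regulated, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  regulated <- unique(intersect(regulated, universe))
  gene_set <- unique(intersect(gene_set, universe))
  a <- length(intersect(regulated, gene_set))
  b <- length(regulated) - a
  c_ <- length(gene_set) - a
  d <- length(universe) - a - b - c_
  # upper-tail hypergeometric: P(X >= a) drawing |regulated| from the urn
  p <- stats::phyper(a - 1L, length(gene_set),
                     length(universe) - length(gene_set),
                     length(regulated), lower.tail = FALSE)
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c_)
  list(table = c(a = a, b = b, c = c_, d = d), odds_ratio = or, p = p)
}

#' Downshifted-Gaussian imputation of missing log-intensities
#'
#' Models detection-limit censoring in label-free proteomics: each
#' missing value in a sample is drawn from a normal distribution
#' narrowed to `width * sd` and shifted down by `shift * sd`, where
#' mean/sd are the sample's observed statistics (the Perseus-default
#' constants are width 0.3, shift 1.8). Observed values are returned
#' untouched; the draw is deterministic under `seed`.
#'
#' @param mat numeric matrix of log-intensities, features x samples,
#'   `NA` = missing.
#' @param width relative width of the imputation distribution.
#' @param shift downshift in observed-sd units.
#' @param seed integer RNG seed (optional; uses the session RNG stream
#'   when `NULL`).
#' @return matrix with all `NA` cells filled.
#' @export
impute_downshift <- function(mat, width = 0.3, shift = 1.8, seed = NULL) {
  mat <- as.matrix(mat)
  if (!anyNA(mat)) return(mat)
  if (!is.null(seed)) set.seed(seed)
  for (j in seq_len(ncol(mat))) {
    miss <- is.na(mat[, j])
    if (!any(miss)) next
    obs <- mat[!miss, j]
    if (length(obs) < 2L)
      stop("sample ", j, " has fewer than 2 observed values; cannot impute")
    s <- stats::sd(obs)
    if (s == 0) stop("sample ", j, " has zero observed sd; cannot impute")
    mat[miss, j] <- stats::rnorm(sum(miss),
                                 mean = mean(obs) - shift * s,
                                 sd = width * s)
  }
  mat
}

#' Ranked list of features by group fold change
#'
#' The preranked-GSEA input of a proteome comparison: per-feature log2
#' fold change of the treatment group versus the reference group,
#' sorted descending. On log-scale data the fold change is the
#' difference of group means; on linear-scale data the log2 ratio of
#' means. Ties are broken lexicographically by feature id so the
#' ordering is deterministic.
#'
#' @param mat numeric matrix, features x samples (no missing values;
#'   impute first).
#' @param group factor/character of length ncol(mat).
#' @param treatment,reference the two group levels to compare.
#' @param log_scale TRUE (default) when `mat` holds log2 intensities.
#' @param pseudocount used only when `log_scale = FALSE`.
#' @return data.frame (feature, score) ordered descending by score.
#' @export
ranked_list_from_groups <- function(mat, group, treatment, reference,
                                    log_scale = TRUE, pseudocount = 0.5) {
  mat <- as.matrix(mat)
  group <- as.character(group)
  stopifnot(length(group) == ncol(mat),
            treatment %in% group, reference %in% group)
  mt <- rowMeans(mat[, group == treatment, drop = FALSE])
  mr <- rowMeans(mat[, group == reference, drop = FALSE])
  score <- if (log_scale) mt - mr else
    log2((mt + pseudocount) / (mr + pseudocount))
  feature <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  o <- order(-score, feature)
  data.frame(feature = feature[o], score = unname(score[o]),
             stringsAsFactors = FALSE)
}
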