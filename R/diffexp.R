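#' Analysis thresholds
#'
#' The cohort-analysis constants in one place: |log2 fold change| > 2
#' and BH-adjusted p < 0.05 define significance in the volcano
#' classification; 15 RPM defines expression; p < 0.05 defines
#' regulated proteins.
#'
#' @param log2fc_cut absolute log2 fold-change cut (default 2).
#' @param padj_cut adjusted-p cut (default 0.05).
#' @param protein_p_cut raw-p cut for protein regulation (default 0.05).
#' @param rpm_cut expression cut in RPM (default 15).
#' @return named list of thresholds.
#' @export
thresholds <- function(log2fc_cut = 2, padj_cut = 0.05,
                       protein_p_cut = 0.05, rpm_cut = 15) {
  th <- list(log2fc_cut = log2fc_cut, padj_cut = padj_cut,
             protein_p_cut = protein_p_cut, rpm_cut = rpm_cut)
  if (any(unlist(th) <= 0)) stop("thresholds must be positive")
  th
}

#' Log2 fold change between two groups
#'
#' log2((mean(g1) + ps) / (mean(g2) + ps)). The pseudocount (default
#' 0.5 RPM) keeps zero-expression groups finite; set it to 0 for data
#' that cannot vanish.
#'
#' @param values_g1,values_g2 non-negative expression values of the two
#'   groups (g1 = numerator, e.g. tumor).
#' @param pseudocount added to both group means before the ratio.
#' @return log2 fold change (scalar).
#' @export
log2_group_fc <- function(values_g1, values_g2, pseudocount = 0.5) {
  stopifnot(length(values_g1) > 0L, length(values_g2) > 0L)
  denom <- mean(values_g2) + pseudocount
  if (denom == 0) stop("denominator group mean + pseudocount is zero")
  log2((mean(values_g1) + pseudocount) / denom)
}

#' Two-sided unpaired t-test
#'
#' Thin wrapper over [stats::t.test()] (Welch by default) with defined
#' behavior on degenerate variances: identical constant groups give
#' t = 0, p = 1; constant groups with different means give the smallest
#' representable p.
#'
#' @param x,y numeric vectors, length >= 2, finite.
#' @param variant `"welch"` (default) or `"student"` (pooled variance).
#' @return list with `t` and `p`.
#' @export
unpaired_t <- function(x, y, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  stopifnot(length(x) >= 2L, length(y) >= 2L,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = .Machine$double.xmin))
  }
  tt <- stats::t.test(x, y, var.equal = (variant == "student"))
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment via [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Volcano classification of a differential-expression result
#'
#' `sig_up` iff log2fc > +cut and p_adj < padj_cut; `sig_down` iff
#' log2fc < -cut and p_adj < padj_cut; otherwise `ns`. All inequalities
#' strict, so features sitting exactly on a cut are not significant.
#'
#' @param log2fc,p_adj numeric vectors (recycled to common length).
#' @param th a [thresholds()] list.
#' @return character vector in {"sig_up", "sig_down", "ns"}.
#' @export
volcano_classify <- function(log2fc, p_adj, th = thresholds()) {
  stopifnot(all(is.finite(log2fc)), all(is.finite(p_adj)))
  out <- rep("ns", length(log2fc))
  sig <- p_adj < th$padj_cut
  out[sig & log2fc >  th$log2fc_cut] <- "sig_up"
  out[sig & log2fc < -th$log2fc_cut] <- "sig_down"
  out
}

#' Protein regulation call
#'
#' A protein is `up` when its log2 fold change versus control is > 0
#' with p < cut, `down` when < 0 with p < cut, otherwise `unchanged`.
#' A fold change of exactly 0 is never regulated.
#'
#' @param log2fc_vs_control,p numeric vectors.
#' @param p_cut raw-p cut, default 0.05.
#' @return character vector in {"up", "down", "unchanged"}.
#' @export
protein_regulation <- function(log2fc_vs_control, p, p_cut = 0.05) {
  stopifnot(all(is.finite(log2fc_vs_control)), all(is.finite(p)))
  out <- rep("unchanged", length(log2fc_vs_control))
  out[p < p_cut & log2fc_vs_control > 0] <- "up"
  out[p < p_cut & log2fc_vs_control < 0] <- "down"
  out
}

#' Two-group differential expression table
#'
#' Per-feature log2 fold change (ratio of group means with
#' pseudocount), unpaired t-test (vectorized Welch or pooled), BH
#' adjustment, and volcano class. The fold change is the ratio of
#' group means, matching an unpaired design; a paired mean-of-ratios
#' variant is available when a sample pairing exists.
#'
#' @param mat numeric matrix, features x samples (expression scale,
#'   e.g. RPM).
#' @param group factor/character of length ncol(mat) with exactly two
#'   levels; the **first** level is the numerator (e.g. tumor).
#' @param th a [thresholds()] list.
#' @param pseudocount see [log2_group_fc()].
#' @param variant t-test variant, `"welch"` (default) or `"student"`.
#' @param paired_ratio if TRUE, log2fc is the mean over pairs of
#'   log2((x_i + ps)/(y_i + ps)), pairing columns by order within group.
#' @return data.frame: feature, log2fc, t, p, p_adj, class.
#' @export
de_table <- function(mat, group, th = thresholds(), pseudocount = 0.5,
                     variant = c("welch", "student"), paired_ratio = FALSE) {
  variant <- match.arg(variant)
  mat <- as.matrix(mat)
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2L, length(group) == ncol(mat))
  g1 <- mat[, group == levels(group)[1], drop = FALSE]
  g2 <- mat[, group == levels(group)[2], drop = FALSE]
  n1 <- ncol(g1); n2 <- ncol(g2)
  stopifnot(n1 >= 2L, n2 >= 2L)

  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  if (paired_ratio) {
    stopifnot(n1 == n2)
    lfc <- rowMeans(log2((g1 + pseudocount) / (g2 + pseudocount)))
  } else {
    lfc <- log2((m1 + pseudocount) / (m2 + pseudocount))
  }

  v1 <- apply(g1, 1L, stats::var); v2 <- apply(g2, 1L, stats::var)
  if (variant == "welch") {
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(tstat))
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate variances: identical constants -> p = 1; separated -> min p
  zero <- is.na(tstat) | !is.finite(tstat)
  eq <- zero & (m1 == m2)
  p[eq] <- 1; tstat[eq] <- 0
  p[zero & !eq] <- .Machine$double.xmin
  tstat[zero & !eq] <- sign(m1 - m2)[zero & !eq] * Inf

  p_adj <- bh_adjust(p)
  data.frame(feature = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             log2fc = lfc, t = tstat, p = p, p_adj = p_adj,
             class = volcano_classify(lfc, p_adj, th),
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
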