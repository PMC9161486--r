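#' Z-scale each gene over patients
#'
#' Centers and scales every gene row to mean 0, sd 1 (sample sd, n-1)
#' over its non-missing values. Zero-variance genes cannot be scaled
#' and are emitted as all-missing with a warning.
#'
#' @param mat numeric matrix, genes x patients (>= 2 patients).
#' @return matrix of z-scores, same dimnames.
#' @export
zscale_genes <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("z-scaling needs at least 2 patients")
  mu <- rowMeans(mat, na.rm = TRUE)
  nobs <- rowSums(!is.na(mat))
  sd_ <- sqrt(rowSums((mat - mu)^2, na.rm = TRUE) / pmax(nobs - 1L, 1L))
  sd_[nobs < 2L] <- NA_real_
  flat <- !is.na(sd_) & sd_ == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance gene(s) emitted as all-missing")
    sd_[flat] <- NA_real_
  }
  (mat - mu) / sd_
}

#' Single-sample gene-set activity score
#'
#' Per-patient median of z-scaled expression over the genes of a set
#' (e.g. the Hallmark E2F targets), a robust one-number summary of the
#' set's transcriptional activity in that patient. Genes missing for a
#' patient are skipped in that patient's median.
#'
#' @param zmat z-scaled matrix from [zscale_genes()], genes x patients.
#' @param gene_set character vector of gene ids; members absent from
#'   the matrix are ignored (at least one must be present).
#' @return named numeric vector, one score per patient.
#' @export
activity_score <- function(zmat, gene_set) {
  zmat <- as.matrix(zmat)
  rows <- intersect(gene_set, rownames(zmat))
  if (length(rows) == 0L) stop("no gene of the set is in the matrix")
  apply(zmat[rows, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranked values via [stats::cor()]. When
#' either vector has zero rank variance the coefficient is undefined
#' and `NA` is returned.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\], or `NA` when undefined.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Correlation ranking metric for phenotype GSEA
#'
#' Ranks every gene by its Spearman correlation with a per-patient
#' phenotype (e.g. the expression of one 5'isomiR), descending. Genes
#' whose correlation is undefined (zero rank variance) are excluded.
#' Ties are broken lexicographically by gene id for determinism.
#'
#' @param mat numeric matrix, genes x patients.
#' @param phenotype numeric vector, one value per patient.
#' @return data.frame (feature, score) ordered descending by score.
#' @export
correlation_rank_metric <- function(mat, phenotype) {
  mat <- as.matrix(mat)
  stopifnot(length(phenotype) == ncol(mat))
  r <- spearman_cor_rows(mat, phenotype)
  keep <- !is.na(r)
  if (!all(keep))
    message(sum(!keep), " gene(s) with undefined correlation excluded")
  feature <- (rownames(mat) %||% as.character(seq_len(nrow(mat))))[keep]
  r <- r[keep]
  o <- order(-r, feature)
  data.frame(feature = feature[o], score = unname(r[o]),
             stringsAsFactors = FALSE)
}

# vectorized per-row Spearman against one phenotype vector
spearman_cor_rows <- function(mat, phenotype) {
  rp <- rank(phenotype)
  if (stats::sd(rp) == 0) return(rep(NA_real_, nrow(mat)))
  rm_ <- t(apply(mat, 1L, rank))
  rsd <- apply(rm_, 1L, stats::sd)
  out <- rep(NA_real_, nrow(mat))
  ok <- rsd > 0
  if (any(ok)) {
    rc <- rm_[ok, , drop = FALSE] - rowMeans(rm_[ok, , drop = FALSE])
    pc <- rp - mean(rp)
    out[ok] <- as.numeric(rc %*% pc) /
      (sqrt(rowSums(rc^2)) * sqrt(sum(pc^2)))
  }
  out
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The classic GSEA running-sum statistic: walking down the ranked
#' list, set members ("hits") increment the sum by |score|^p
#' normalized over all hits, non-members decrement by 1/(N - Nh); the
#' enrichment score is the signed extremum of the walk. `weight_p = 1`
#' is the standard weighted statistic; `weight_p = 0` recovers the
#' unweighted KS statistic.
#'
#' @param ranked data.frame (feature, score), descending by score.
#' @param gene_set character vector of member ids.
#' @param weight_p weighting exponent on |score| (default 1).
#' @return list: `es`, and `running` (the full running sum).
#' @export
gsea_es <- function(ranked, gene_set, weight_p = 1) {
  feature <- ranked$feature
  score <- ranked$score
  n <- length(feature)
  hit <- feature %in% gene_set
  nh <- sum(hit)
  if (nh == 0L || nh == n)
    stop("gene set must overlap the ranked list without covering it")
  w <- abs(score)^weight_p
  denom <- sum(w[hit])
  inc <- numeric(n)
  if (denom == 0) inc[hit] <- 1 / nh else inc[hit] <- w[hit] / denom
  inc[!hit] <- -1 / (n - nh)
  running <- cumsum(inc)
  list(es = es_extreme(running), running = running)
}

# signed extreme of the running sum; when the positive and negative
# deviations tie in magnitude (within numerical noise) the positive
# one is reported, a documented deterministic convention
es_extreme <- function(running) {
  pos <- max(running)
  neg <- min(running)
  if (pos >= -neg - 1e-9) pos else neg
}

# ES values for many gene sets / permutations given a fixed ranking;
# hit_idx is a list of integer index vectors into the ranking
gsea_es_many <- function(score, hit_idx_list, weight_p = 1) {
  n <- length(score)
  w <- abs(score)^weight_p
  vapply(hit_idx_list, function(idx) {
    nh <- length(idx)
    inc <- rep.int(-1 / (n - nh), n)
    denom <- sum(w[idx])
    inc[idx] <- if (denom == 0) 1 / nh else w[idx] / denom
    es_extreme(cumsum(inc))
  }, numeric(1))
}

#' GSEA with permutation significance
#'
#' Computes ES, NES, permutation p and FDR q for every gene set, in
#' either of two modes. `preranked_setperm`: the null distribution is
#' built by drawing random gene sets of matching size from the ranked
#' universe. `phenotype_perm`: the phenotype vector is permuted and
#' the Spearman correlation ranking recomputed for each permutation,
#' preserving gene-gene correlation (requires `mat`/`phenotype`
#' instead of a precomputed ranking). Normalization is
#' sign-stratified: NES = ES / mean(|null ES| of the same sign);
#' p = (1 + #{same-sign null at least as extreme}) / (1 + #{same-sign
#' null}); q follows the standard pooled-NES FDR estimate.
#'
#' @param ranked data.frame (feature, score) for preranked mode.
#' @param sets named list of character vectors (the collection).
#' @param mode `"preranked_setperm"` or `"phenotype_perm"`.
#' @param mat,phenotype genes x patients matrix and phenotype vector,
#'   required for `phenotype_perm` (the ranking is computed internally
#'   via [correlation_rank_metric()]).
#' @param n_perm number of permutations (default 1000, >= 100).
#' @param weight_p weighting exponent, default 1.
#' @param min_size sets reduced below this size after intersection
#'   with the universe are skipped with a warning (default 5).
#' @param seed integer RNG seed for the permutations.
#' @return data.frame: set, size, es, nes, p_perm, fdr_q.
#' @export
gsea_significance <- function(ranked = NULL, sets,
                              mode = c("preranked_setperm", "phenotype_perm"),
                              mat = NULL, phenotype = NULL,
                              n_perm = 1000L, weight_p = 1,
                              min_size = 5L, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.list(sets), !is.null(names(sets)), n_perm >= 100L)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "phenotype_perm") {
    stopifnot(!is.null(mat), !is.null(phenotype))
    ranked <- correlation_rank_metric(mat, phenotype)
  }
  stopifnot(is.data.frame(ranked), nrow(ranked) >= 2L)
  n <- nrow(ranked)

  sets <- lapply(sets, intersect, y = ranked$feature)
  sizes <- lengths(sets)
  drop <- sizes < min_size | sizes >= n
  if (any(drop)) {
    warning(sum(drop), " set(s) skipped (size < ", min_size,
            " or covering the universe)")
    sets <- sets[!drop]; sizes <- sizes[!drop]
  }
  if (length(sets) == 0L) stop("no usable gene set")

  hit_idx <- lapply(sets, function(s) which(ranked$feature %in% s))
  es_obs <- gsea_es_many(ranked$score, hit_idx, weight_p)

  # null ES matrix: n_perm x n_sets
  if (mode == "preranked_setperm") {
    null_es <- vapply(sizes, function(k) {
      gsea_es_many(ranked$score,
                   lapply(seq_len(n_perm), function(i) sample.int(n, k)),
                   weight_p)
    }, numeric(n_perm))
  } else {
    null_es <- matrix(NA_real_, n_perm, length(sets))
    for (b in seq_len(n_perm)) {
      rb <- correlation_rank_metric(mat, sample(phenotype))
      hb <- lapply(sets, function(s) which(rb$feature %in% s))
      null_es[b, ] <- gsea_es_many(rb$score, hb, weight_p)
    }
  }
  if (is.null(dim(null_es))) null_es <- matrix(null_es, nrow = n_perm)

  nes <- p_perm <- rep(NA_real_, length(sets))
  null_nes <- matrix(NA_real_, n_perm, length(sets))
  for (k in seq_along(sets)) {
    nk <- null_es[, k]
    mpos <- mean(nk[nk >= 0]); mneg <- mean(abs(nk[nk < 0]))
    # normalize the observed and the null by the matching sign-mean
    null_nes[, k] <- ifelse(nk >= 0,
                            if (is.nan(mpos)) NA_real_ else nk / mpos,
                            if (is.nan(mneg)) NA_real_ else nk / mneg)
    same <- if (es_obs[k] >= 0) nk[nk >= 0] else nk[nk < 0]
    if (length(same) == 0L) {
      warning("set '", names(sets)[k],
              "' has no same-sign permutation ES; p/q undefined")
      next
    }
    nes[k] <- es_obs[k] / mean(abs(same))
    p_perm[k] <- (1 + sum(abs(same) >= abs(es_obs[k]))) / (1 + length(same))
  }

  fdr_q <- gsea_fdr(nes, null_nes)
  data.frame(set = names(sets), size = as.integer(sizes),
             es = es_obs, nes = nes, p_perm = p_perm, fdr_q = fdr_q,
             row.names = NULL, stringsAsFactors = FALSE)
}

# standard pooled-NES FDR: for NES* >= 0,
#   q = [%(pooled null NES >= NES*) / %(pooled null NES >= 0)] /
#       [%(observed NES >= NES*) / %(observed NES >= 0)], capped at 1
gsea_fdr <- function(nes, null_nes) {
  pool <- as.numeric(null_nes)
  pool <- pool[!is.na(pool)]
  q <- rep(NA_real_, length(nes))
  for (k in seq_along(nes)) {
    s <- nes[k]
    if (is.na(s)) next
    if (s >= 0) {
      denom_null <- sum(pool >= 0); denom_obs <- sum(nes >= 0, na.rm = TRUE)
      if (denom_null == 0L || denom_obs == 0L) next
      num <- sum(pool >= s) / denom_null
      den <- sum(nes >= s, na.rm = TRUE) / denom_obs
    } else {
      denom_null <- sum(pool < 0); denom_obs <- sum(nes < 0, na.rm = TRUE)
      if (denom_null == 0L || denom_obs == 0L) next
      num <- sum(pool <= s) / denom_null
      den <- sum(nes <= s, na.rm = TRUE) / denom_obs
    }
    q[k] <- min(1, num / den)
  }
  q
}

#' Long-format summary of enrichment results across conditions
#'
#' Stacks per-condition GSEA results into the (condition, set, NES, q)
#' long table behind a bubble heatmap, completing the condition x set
#' grid with `NA` rows for combinations a condition did not test.
#'
#' @param results named list of [gsea_significance()] data.frames, one
#'   per condition.
#' @return data.frame: condition, set, nes, fdr_q (complete grid).
#' @export
bubble_summary <- function(results) {
  stopifnot(is.list(results), length(results) >= 1L,
            !is.null(names(results)))
  all_sets <- sort(unique(unlist(lapply(results, `[[`, "set"))))
  grid <- expand.grid(condition = names(results), set = all_sets,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$nes <- grid$fdr_q <- NA_real_
  for (cond in names(results)) {
    r <- results[[cond]]
    i <- match(paste(cond, r$set), paste(grid$condition, grid$set))
    grid$nes[i] <- r$nes
    grid$fdr_q[i] <- r$fdr_q
  }
  grid[order(grid$condition, grid$set), c("condition", "set", "nes", "fdr_q")]
}
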