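#' Expressed 3'UTR regions from read coverage
#'
#' Intersects read-alignment intervals with annotated 3'UTRs and merges
#' overlapping or book-ended pieces, so each maximal covered run within
#' a UTR becomes one expressed region. Restricting target prediction to
#' these regions keeps predictions to UTR sequence that is actually
#' transcribed in the cell lines at hand.
#'
#' @param reads a [GenomicRanges::GRanges] of read alignments.
#' @param utrs a [GenomicRanges::GRanges] of 3'UTR annotations; a
#'   `utr_id` metadata column (or names) labels the output.
#' @return a `GRanges` of expressed regions with a `utr_id` metadata
#'   column, sorted, disjoint within each UTR.
#' @export
expressed_utr_regions <- function(reads, utrs) {
  stopifnot(methods::is(reads, "GRanges"), methods::is(utrs, "GRanges"))
  ids <- if (!is.null(utrs$utr_id)) as.character(utrs$utr_id)
         else if (!is.null(names(utrs)) && all(nzchar(names(utrs)))) names(utrs)
         else as.character(seq_along(utrs))
  pieces <- lapply(seq_along(utrs), function(i) {
    hit <- GenomicRanges::reduce(
      GenomicRanges::intersect(reads, utrs[i], ignore.strand = FALSE),
      min.gapwidth = 1L)  # merge book-ended runs
    if (length(hit)) hit$utr_id <- ids[i]
    hit
  })
  out <- do.call(c, pieces)
  GenomicRanges::sort(out)
}

#' Scan a 3'UTR for canonical seed-match sites of a (shifted) miRNA
#'
#' Finds every occurrence, on the mRNA 5'->3' strand, of the four
#' canonical site types for the seed of the offset-applied miRNA:
#' 8mer (Watson-Crick pairing to miRNA positions 2-8 plus an A opposite
#' position 1), 7mer-m8 (pairing 2-8), 7mer-A1 (pairing 2-7 plus the
#' A), and 6mer (pairing 2-7). Because a 5' shift moves the seed, the
#' same UTR yields different site sets for different 5'isomiRs of one
#' miRNA. Each seed-match position is reported once with its
#' highest-priority type (8mer > 7mer-m8 > 7mer-A1 > 6mer).
#'
#' @param utr_seq UTR sequence, mRNA 5'->3' (DNA or RNA alphabet).
#' @param mirna_seq canonical mature miRNA sequence.
#' @param offset5 5' offset of the isomiR being scanned (>= 0).
#' @param policy a [seed_policy()].
#' @return data.frame: start, end (0-based half-open on the UTR),
#'   site_type, seed_pairs (7 for 8mer/7mer-m8, 6 otherwise), site
#'   (the matched UTR substring). Zero rows when no site exists.
#' @examples
#' seed_site_scan("AAACAGUGCCAAA", "UAUGGCACUGGUAGAAUUCACU", offset5 = 2)
#' @export
seed_site_scan <- function(utr_seq, mirna_seq, offset5 = 0L,
                           policy = seed_policy()) {
  utr <- as_rna(utr_seq)
  seed <- seed_sequence(mirna_seq, offset5, policy)      # m2..m8 (7 nt)
  core <- substr(seed, 1L, 6L)                           # m2..m7
  m8 <- substr(seed, 7L, 7L)
  rc_core <- rna_revcomp(core)                           # 6-nt site core
  m8_comp <- chartr("ACGU", "UGCA", m8)                  # base pairing m8

  empty <- data.frame(start = integer(0), end = integer(0),
                      site_type = character(0), seed_pairs = integer(0),
                      site = character(0), stringsAsFactors = FALSE)
  n <- nchar(utr)
  if (n < 6L) return(empty)
  starts0 <- find_all_occurrences(utr, rc_core)          # 0-based core starts
  if (length(starts0) == 0L) return(empty)

  rows <- lapply(starts0, function(t) {
    has_m8 <- t >= 1L && substr(utr, t, t) == m8_comp    # base before core
    has_a <- t + 7L <= n && substr(utr, t + 7L, t + 7L) == "A"
    if (has_m8 && has_a) {
      c(t - 1L, t + 7L, "8mer", 7L)
    } else if (has_m8) {
      c(t - 1L, t + 6L, "7mer_m8", 7L)
    } else if (has_a) {
      c(t, t + 7L, "7mer_A1", 6L)
    } else {
      c(t, t + 6L, "6mer", 6L)
    }
  })
  m <- do.call(rbind, rows)
  out <- data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
                    site_type = m[, 3], seed_pairs = as.integer(m[, 4]),
                    stringsAsFactors = FALSE)
  out$site <- substr(rep(utr, nrow(out)), out$start + 1L, out$end)
  out[order(out$start), , drop = FALSE]
}

#' Duplex complementarity scoring parameters
#'
#' A deliberately simple miRanda-style scheme: Watson-Crick pair +5,
#' G:U wobble +1, mismatch -3, gap open -8, gap extend -2 (a gap of
#' length L costs open + (L-1)*extend), with pair scores at miRNA seed
#' positions 2-8 multiplied by `seed_scale`. Pairs predicted by both
#' the seed scanner and this scorer (score >= `score_threshold`) form
#' the consensus target set.
#'
#' @param match,gu_wobble,mismatch,gap_open,gap_extend alignment scores.
#' @param seed_scale multiplier on pair scores at miRNA positions 2-8.
#' @param score_threshold consensus cut on the best duplex score.
#' @return named list of parameters.
#' @export
duplex_params <- function(match = 5, gu_wobble = 1, mismatch = -3,
                          gap_open = -8, gap_extend = -2, seed_scale = 2,
                          score_threshold = 80) {
  stopifnot(match > gu_wobble, gu_wobble > 0, 0 > mismatch,
            mismatch > gap_open, seed_scale > 0)
  list(match = match, gu_wobble = gu_wobble, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend,
       seed_scale = seed_scale, score_threshold = score_threshold)
}

pair_score <- function(a, b, params) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
        (a == "G" & b == "C") | (a == "C" & b == "G")
  gu <- (a == "G" & b == "U") | (a == "U" & b == "G")
  ifelse(wc, params$match, ifelse(gu, params$gu_wobble, params$mismatch))
}

#' Best local duplex score of a miRNA against a UTR window
#'
#' Smith-Waterman local alignment of the miRNA (5'->3') against the
#' reversed UTR window (so position i of the miRNA faces the
#' antiparallel mRNA strand), scored by base-pairing quality under
#' [duplex_params()], with affine gaps and the floor at zero. Seed
#' positions (miRNA 2-8) carry scaled pair scores, encoding the seed's
#' dominant contribution to target recognition.
#'
#' @param mirna_seq mature (offset-applied) miRNA sequence, 5'->3'.
#' @param utr_window UTR subsequence, mRNA 5'->3', 15-40 nt.
#' @param params a [duplex_params()] list.
#' @return best local alignment score (>= 0).
#' @export
duplex_score <- function(mirna_seq, utr_window, params = duplex_params()) {
  mir <- strsplit(as_rna(mirna_seq), "")[[1]]
  win <- nchar(utr_window)
  if (win < 15L || win > 40L)
    stop("utr_window must be 15-40 nt (got ", win, ")")
  # antiparallel: align miRNA 5'->3' to the window read 3'->5'
  utr <- rev(strsplit(as_rna(utr_window), "")[[1]])
  sw_local_affine(mir, utr, params)
}

# Gotoh local alignment over a pairing score; rows = miRNA positions
# (seed scaling applies per row), columns = target bases.
sw_local_affine <- function(mir, utr, params) {
  n <- length(mir); m <- length(utr)
  scale_row <- ifelse(seq_len(n) >= 2L & seq_len(n) <= 8L,
                      params$seed_scale, 1)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)  # gap in miRNA (move along target)
  F_ <- matrix(-Inf, n + 1L, m + 1L) # gap in target (move along miRNA)
  best <- 0
  for (i in seq_len(n)) {
    ps <- pair_score(mir[i], utr, params) * scale_row[i]
    for (j in seq_len(m)) {
      E[i + 1L, j + 1L] <- max(H[i + 1L, j] + params$gap_open,
                               E[i + 1L, j] + params$gap_extend)
      F_[i + 1L, j + 1L] <- max(H[i, j + 1L] + params$gap_open,
                                F_[i, j + 1L] + params$gap_extend)
      h <- max(0, H[i, j] + ps[j], E[i + 1L, j + 1L], F_[i + 1L, j + 1L])
      H[i + 1L, j + 1L] <- h
      if (h > best) best <- h
    }
  }
  best
}

#' Consensus target prediction for one 5'isomiR
#'
#' A UTR is a predicted target only when two independent predictors
#' agree: the seed scanner finds at least one site of the minimum type
#' (default 7mer, i.e. 7mer-A1 or better), and the best duplex score
#' over windows centred on any seed site reaches the threshold. The
#' intersection logic trades sensitivity for precision, the standard
#' remedy for the high false-positive rate of single predictors.
#'
#' @param utrs named character vector (or list) of UTR sequences,
#'   mRNA 5'->3'.
#' @param mirna_seq canonical mature miRNA sequence.
#' @param offset5 5' offset of the isomiR.
#' @param params a [duplex_params()] list.
#' @param policy a [seed_policy()].
#' @param min_site_type minimum qualifying seed-site type:
#'   `"8mer"`, `"7mer_m8"`, `"7mer_A1"` (default: any 7mer or better)
#'   or `"6mer"`.
#' @param window_flank nt of UTR context taken on each side of a site
#'   centre when scoring the duplex (default 15).
#' @return data.frame: utr_id, n_sites, best_site_type,
#'   best_duplex_score -- one row per consensus target, ordered by
#'   utr_id.
#' @export
consensus_targets <- function(utrs, mirna_seq, offset5 = 0L,
                              params = duplex_params(),
                              policy = seed_policy(),
                              min_site_type = "7mer_A1",
                              window_flank = 15L) {
  utrs <- unlist(utrs)
  if (length(utrs) == 0L)
    return(data.frame(utr_id = character(0), n_sites = integer(0),
                      best_site_type = character(0),
                      best_duplex_score = numeric(0)))
  if (is.null(names(utrs))) names(utrs) <- as.character(seq_along(utrs))
  rank_of <- c("6mer" = 1L, "7mer_A1" = 2L, "7mer_m8" = 3L, "8mer" = 4L)
  stopifnot(min_site_type %in% names(rank_of))
  mir_shift <- substr(as_rna(mirna_seq), offset5 + 1L, nchar(mirna_seq))

  rows <- lapply(sort(names(utrs)), function(id) {
    sites <- seed_site_scan(utrs[[id]], mirna_seq, offset5, policy)
    sites <- sites[rank_of[sites$site_type] >= rank_of[min_site_type], ,
                   drop = FALSE]
    if (nrow(sites) == 0L) return(NULL)
    utr <- as_rna(utrs[[id]])
    n <- nchar(utr)
    best <- max(vapply(seq_len(nrow(sites)), function(k) {
      centre <- (sites$start[k] + sites$end[k]) %/% 2L
      lo <- max(0L, centre - as.integer(window_flank))
      hi <- min(n, centre + as.integer(window_flank))
      if (hi - lo < 15L) { lo <- max(0L, hi - 15L); hi <- min(n, lo + 15L) }
      if (hi - lo < 15L) return(0)
      duplex_score(mir_shift, substr(utr, lo + 1L, hi), params)
    }, numeric(1)))
    if (best < params$score_threshold) return(NULL)
    data.frame(utr_id = id, n_sites = nrow(sites),
               best_site_type = sites$site_type[
                 which.max(rank_of[sites$site_type])],
               best_duplex_score = best, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(utr_id = character(0), n_sites = integer(0),
                      best_site_type = character(0),
                      best_duplex_score = numeric(0)))
  do.call(rbind, rows)
}

#' Venn partition of per-isomiR target sets
#'
#' Counts every region of the Venn partition of two or more target
#' sets (e.g. targets unique to the +2 variant versus those shared
#' with the canonical miRNA). Region labels join member set names with
#' `&`; counts over all regions sum to the union size.
#'
#' @param sets named list of character vectors (e.g. utr ids per
#'   isomiR label); >= 2 sets.
#' @return named integer vector over the 2^k - 1 membership regions.
#' @export
target_overlap <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  k <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  counts <- apply(combos, 1L, function(inc) {
    if (length(universe) == 0L) return(0L)
    sum(apply(member, 1L, function(r) all(r == inc)))
  })
  names(counts) <- apply(combos, 1L, function(inc)
    paste(names(sets)[as.logical(inc)], collapse = "&"))
  counts
}
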