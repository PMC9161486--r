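#' Classify a small-RNA read as a 5'isomiR
#'
#' A read is assigned when it is an exact substring of the precursor
#' whose start lies on the queried arm and whose 3' end is within
#' `policy$tol3` of the canonical arm end. The signed difference of the
#' start from the canonical arm start is the 5' offset (the isomiR
#' identity); the 3' difference is bookkept but collapsed away later.
#' If the read occurs at several positions in the hairpin, the
#' occurrence minimizing `|offset5|` wins (tie: smaller signed offset),
#' favoring the canonical annotation.
#'
#' @param read_seq read sequence (DNA or RNA alphabet), length >= 15.
#' @param ref a [premirna_reference()].
#' @param arm_id mature arm to classify against.
#' @param policy a [seed_policy()]; `tol3` bounds the 3' heterogeneity.
#' @param trim_nontemplated if > 0, up to that many 3'-terminal bases
#'   (max 2) are trimmed and classification retried, to admit short
#'   non-templated 3' additions. Default 0: non-templated tails are
#'   UNASSIGNED.
#' @return list with `assigned` (logical), and when assigned `key`
#'   (an [isomir_key()]), `offset5`, `offset3`, `implausible` (TRUE for
#'   |offset5| > 5, which Drosha/Dicer heterogeneity rarely produces).
#' @examples
#' ref <- premirna_reference("syn-mir", paste0("GGGACG",
#'   "UAUGGCACUGGUAGAAUUCACUGUG", "ACGUACG"),
#'   data.frame(arm_id = "miR-x-5p", start = 6, end = 28))
#' classify_read("UAUGGCACUGGUAGAAUUCACU", ref, "miR-x-5p")$offset5  # 0
#' @export
classify_read <- function(read_seq, ref, arm_id, policy = seed_policy(),
                          trim_nontemplated = 0L) {
  stopifnot(inherits(ref, "premirna_reference"))
  read_seq <- as_rna(read_seq)
  if (nchar(read_seq) < 15L) stop("read shorter than 15 nt")
  a <- arm_coords(ref, arm_id)
  trim_nontemplated <- min(as.integer(trim_nontemplated), 2L)

  for (trim in 0:trim_nontemplated) {
    seq_try <- if (trim == 0L) read_seq else
      substr(read_seq, 1L, nchar(read_seq) - trim)
    if (nchar(seq_try) < 15L) break
    hit <- classify_exact(seq_try, ref$sequence, a, policy)
    if (!is.null(hit)) {
      return(list(assigned = TRUE,
                  key = isomir_key(arm_id, hit$offset5),
                  offset5 = hit$offset5, offset3 = hit$offset3,
                  trimmed = trim,
                  implausible = abs(hit$offset5) > 5L))
    }
  }
  list(assigned = FALSE, key = NULL, offset5 = NA_integer_,
       offset3 = NA_integer_, trimmed = NA_integer_, implausible = NA)
}

# exact-substring search with the |offset5|-minimizing tie rule
classify_exact <- function(read_seq, hairpin, arm, policy) {
  starts <- find_all_occurrences(hairpin, read_seq)
  if (length(starts) == 0L) return(NULL)
  off5 <- starts - arm$start
  off3 <- (starts + nchar(read_seq)) - arm$end
  ok <- abs(off3) <= policy$tol3 &
    (arm$end - (arm$start + off5)) >= 8L   # a seed must remain
  if (!any(ok)) return(NULL)
  off5 <- off5[ok]; off3 <- off3[ok]
  pick <- order(abs(off5), off5)[1]
  list(offset5 = off5[pick], offset3 = off3[pick])
}

# all (possibly overlapping) 0-based start positions of pattern in subject
find_all_occurrences <- function(subject, pattern) {
  np <- nchar(pattern); ns <- nchar(subject)
  if (np > ns) return(integer(0))
  starts <- integer(0)
  from <- 1L
  repeat {
    i <- regexpr(pattern, substr(subject, from, ns), fixed = TRUE)
    if (i == -1L) break
    pos <- from + as.integer(i) - 1L
    starts <- c(starts, pos - 1L)
    from <- pos + 1L
    if (from + np - 1L > ns) break
  }
  starts
}

#' Classify many reads and tally 5'isomiR counts
#'
#' Applies [classify_read()] to a read vector and aggregates counts
#' over the 3' offset, so each count is per (arm, 5'-offset) key --
#' reads sharing a 5' end are summed regardless of their 3' ends.
#'
#' @param reads character vector of read sequences (a whole library).
#' @param ref a [premirna_reference()].
#' @param arm_id mature arm to classify against.
#' @inheritParams classify_read
#' @return list: `counts` named integer vector keyed by isomiR label,
#'   `assignments` data.frame (read index, offset5, offset3, assigned),
#'   `n_unassigned`, `n_total`.
#' @export
classify_reads <- function(reads, ref, arm_id, policy = seed_policy(),
                           trim_nontemplated = 0L) {
  reads <- as_rna(reads)
  # classify unique sequences once; libraries are highly redundant
  uniq <- unique(reads)
  res <- lapply(uniq, classify_read, ref = ref, arm_id = arm_id,
                policy = policy, trim_nontemplated = trim_nontemplated)
  idx <- match(reads, uniq)
  assigned <- vapply(res, `[[`, logical(1), "assigned")[idx]
  off5 <- vapply(res, `[[`, integer(1), "offset5")[idx]
  off3 <- vapply(res, `[[`, integer(1), "offset3")[idx]
  asg <- data.frame(read = seq_along(reads), assigned = assigned,
                    offset5 = off5, offset3 = off3)
  counts <- collapse_5p(asg, arm_id)
  list(counts = counts, assignments = asg,
       n_unassigned = sum(!assigned), n_total = length(reads))
}

#' Aggregate read assignments over the 3' end
#'
#' Sums read counts across all 3' offsets so that the result is keyed
#' purely by the 5' end -- the defining aggregation of a 5'isomiR
#' analysis. Unassigned reads are excluded (their number is reported by
#' [classify_reads()]).
#'
#' @param assignments data.frame with columns `assigned` (logical),
#'   `offset5`, and optionally `count` (default 1 per row).
#' @param mirna_id label stem for the output keys.
#' @return named integer vector of counts, names are isomiR labels,
#'   sorted by offset.
#' @export
collapse_5p <- function(assignments, mirna_id) {
  stopifnot(is.data.frame(assignments))
  if (is.null(assignments$count)) assignments$count <- 1L
  keep <- assignments$assigned %in% TRUE
  if (!any(keep)) return(stats::setNames(integer(0), character(0)))
  tab <- tapply(assignments$count[keep], assignments$offset5[keep], sum)
  off <- sort(as.integer(names(tab)))
  counts <- as.integer(tab[as.character(off)])
  names(counts) <- vapply(off, function(o)
    format_label(isomir_key(mirna_id, o)), "")
  counts
}
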