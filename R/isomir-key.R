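#' Normalize a nucleotide string to RNA alphabet
#'
#' Uppercases and maps T to U. Sequencers and FASTQ files report DNA
#' alphabet; all internal sequence logic runs on {A,C,G,U}.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector over {A,C,G,U}.
#' @export
as_rna <- function(x) {
  x <- chartr("acgut", "ACGUU", x)
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop("non-nucleotide characters in sequence(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  x
}

#' Reverse complement of an RNA string
#'
#' @param x character vector of RNA sequences (A/C/G/U).
#' @return character vector, reverse complements.
#' @export
rna_revcomp <- function(x) {
  comp <- chartr("ACGU", "UGCA", as_rna(x))
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

#' Construct a 5'isomiR key
#'
#' The unit of all quantification: a mature miRNA identity plus the
#' signed 5'-end offset relative to the canonical start. Positive
#' offsets are downstream shifts (5' trimming), negative offsets are
#' upstream extensions. 3'-end variation is deliberately not part of
#' the key.
#'
#' @param mirna_id miRNA name, e.g. `"miR-183-5p"`.
#' @param offset5 integer 5' offset in nucleotides.
#' @return an `isomir_key` object (named list).
#' @examples
#' isomir_key("miR-183-5p", 2L)
#' @export
isomir_key <- function(mirna_id, offset5) {
  stopifnot(is.character(mirna_id), length(mirna_id) == 1L, nzchar(mirna_id))
  offset5 <- as.integer(offset5)
  stopifnot(length(offset5) == 1L, !is.na(offset5))
  structure(list(mirna_id = mirna_id, offset5 = offset5),
            class = "isomir_key")
}

#' @export
print.isomir_key <- function(x, ...) {
  cat("<isomir_key>", format_label(x), "\n")
  invisible(x)
}

#' Format a 5'isomiR label
#'
#' Labels follow the `name|offset` convention used for 5' variants:
#' `"miR-183-5p|0"` is the canonical miRNA, `"miR-183-5p|+2"` the
#' variant whose 5' end starts two bases downstream.
#'
#' @param key an [isomir_key()].
#' @return single character label.
#' @export
format_label <- function(key) {
  stopifnot(inherits(key, "isomir_key"))
  off <- key$offset5
  sprintf("%s|%s", key$mirna_id,
          if (off > 0) paste0("+", off) else as.character(off))
}

#' Parse a 5'isomiR label
#'
#' Inverse of [format_label()]: `parse_label(format_label(k))` is `k`.
#'
#' @param s single character label such as `"miR-183-5p|+2"`.
#' @return an [isomir_key()].
#' @export
parse_label <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  m <- regmatches(s, regexec("^(.+)\\|([+-]?[0-9]+)$", s))[[1]]
  if (length(m) != 3L) stop("malformed isomiR label: ", s)
  isomir_key(m[2], as.integer(m[3]))
}

#' Construct a pre-miRNA reference
#'
#' A precursor hairpin sequence plus the coordinates of its annotated
#' mature arms, the frame in which every read is classified.
#'
#' @param premirna_id precursor name.
#' @param sequence precursor sequence (DNA or RNA alphabet; stored as RNA).
#' @param mature_arms data.frame with columns `arm_id`, `start`, `end`
#'   (0-based half-open into `sequence`).
#' @return a `premirna_reference` object.
#' @export
premirna_reference <- function(premirna_id, sequence, mature_arms) {
  sequence <- as_rna(sequence)
  stopifnot(is.data.frame(mature_arms),
            all(c("arm_id", "start", "end") %in% names(mature_arms)))
  arms <- data.frame(arm_id = as.character(mature_arms$arm_id),
                     start  = as.integer(mature_arms$start),
                     end    = as.integer(mature_arms$end),
                     stringsAsFactors = FALSE)
  n <- nchar(sequence)
  if (any(arms$start < 0 | arms$start >= arms$end | arms$end > n))
    stop("arm interval outside precursor sequence")
  if (any(arms$end - arms$start < 16L))
    stop("mature arm shorter than 16 nt")
  o <- order(arms$start)
  if (nrow(arms) > 1L &&
      any(arms$start[o][-1] < arms$end[o][-nrow(arms)]))
    stop("mature arm intervals overlap")
  if (anyDuplicated(arms$arm_id)) stop("duplicate arm_id")
  structure(list(premirna_id = premirna_id, sequence = sequence,
                 mature_arms = arms),
            class = "premirna_reference")
}

#' @export
print.premirna_reference <- function(x, ...) {
  cat("<premirna_reference>", x$premirna_id,
      sprintf("(%d nt, %d arm(s))\n", nchar(x$sequence),
              nrow(x$mature_arms)))
  invisible(x)
}

arm_coords <- function(ref, arm_id) {
  i <- match(arm_id, ref$mature_arms$arm_id)
  if (is.na(i)) stop("unknown arm_id: ", arm_id)
  ref$mature_arms[i, ]
}

#' Mature sequence of a 5'isomiR
#'
#' Extracts the (offset-applied) mature sequence of an arm from the
#' precursor, keeping the canonical 3' end.
#'
#' @param ref a [premirna_reference()].
#' @param arm_id which mature arm.
#' @param offset5 signed 5' offset (0 = canonical).
#' @return RNA string.
#' @export
mature_sequence <- function(ref, arm_id, offset5 = 0L) {
  a <- arm_coords(ref, arm_id)
  s <- a$start + as.integer(offset5)
  if (s < 0L || s >= a$end)
    stop("offset5 places the 5' end outside the precursor/arm")
  substr(ref$sequence, s + 1L, a$end)
}

#' Seed policy
#'
#' Which miRNA positions constitute the seed (canonically nucleotides
#' 2-8 from the 5' end) and how much 3'-end heterogeneity is tolerated
#' during read classification.
#'
#' @param seed_start,seed_end 1-based positions on the mature miRNA.
#' @param tol3 maximum |3' offset| a read may carry and still be
#'   assigned (default 3 nt).
#' @return a `seed_policy` list.
#' @export
seed_policy <- function(seed_start = 2L, seed_end = 8L, tol3 = 3L) {
  seed_start <- as.integer(seed_start); seed_end <- as.integer(seed_end)
  tol3 <- as.integer(tol3)
  stopifnot(seed_start >= 1L, seed_start < seed_end, tol3 >= 0L)
  structure(list(seed_start = seed_start, seed_end = seed_end, tol3 = tol3),
            class = "seed_policy")
}

#' Seed sequence of a (shifted) mature miRNA
#'
#' The seed of a 5'isomiR is read off the offset-applied sequence, so a
#' +2 variant has a seed shifted two bases downstream of the canonical
#' one -- the molecular basis of isomiR-specific targeting.
#'
#' @param mature_seq canonical mature sequence (RNA or DNA alphabet).
#'   For negative offsets it must already include the upstream template.
#' @param offset5 signed 5' offset; positive trims the 5' end.
#' @param policy a [seed_policy()].
#' @return 7-nt (under defaults) RNA seed string.
#' @examples
#' seed_sequence("UAUGGCACUGGUAGAAUUCACU", 0)  # "AUGGCAC"
#' seed_sequence("UAUGGCACUGGUAGAAUUCACU", 2)  # "GGCACUG"
#' @export
seed_sequence <- function(mature_seq, offset5 = 0L, policy = seed_policy()) {
  mature_seq <- as_rna(mature_seq)
  offset5 <- as.integer(offset5)
  if (offset5 < 0L)
    stop("negative offset5 requires the upstream template; extend mature_seq ",
         "and call with the corresponding non-negative offset")
  shifted <- substr(mature_seq, offset5 + 1L, nchar(mature_seq))
  if (nchar(shifted) < 8L)
    stop("shifted mature sequence shorter than 8 nt; no seed exists")
  if (nchar(shifted) < policy$seed_end)
    stop("shifted mature sequence shorter than seed_end")
  substr(shifted, policy$seed_start, policy$seed_end)
}
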