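#' Read / write an expression matrix as TSV
#'
#' Matrices travel as TSV with a header row of sample ids and feature
#' ids in the first column, the interchange format of every stage.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  as.matrix(df)
}

#' @rdname read_matrix_tsv
#' @param mat numeric matrix, features x samples.
#' @param feature_col name of the first (feature id) column.
#' @export
write_matrix_tsv <- function(mat, path, feature_col = "feature") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- feature_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene set collection from GMT
#'
#' Tab-separated: set name, description, then members. Parsing is
#' delegated to [fgsea::gmtPathways()]; empty sets are rejected.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (any(lengths(sets) == 0L)) stop("GMT contains an empty set")
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param description description field, recycled over sets.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)), all(lengths(sets) > 0L))
  lines <- mapply(function(nm, members)
    paste(c(nm, description, members), collapse = "\t"),
    names(sets), sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read small-RNA reads from FASTA/FASTQ
#'
#' Gzip-transparent via [Biostrings::readDNAStringSet()]; sequences
#' are returned in RNA alphabet for classification.
#'
#' @param path FASTA or FASTQ file (optionally .gz).
#' @param format `"fastq"` or `"fasta"`; guessed from the extension
#'   by default.
#' @return character vector of RNA-alphabet reads.
#' @export
read_reads <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  as_rna(as.character(x))
}

#' Write simulated reads as FASTQ
#'
#' DNA-alphabet FASTQ (U mapped back to T, constant quality) through
#' [Biostrings::writeXStringSet()], so the file round-trips through
#' any standard small-RNA tool.
#'
#' @param reads character vector of reads (RNA or DNA alphabet).
#' @param path output path (.fastq or .fastq.gz).
#' @param ids read names; default `read_1..n`.
#' @export
write_reads_fastq <- function(reads, path, ids = NULL) {
  dna <- Biostrings::DNAStringSet(chartr("Uu", "Tt", reads))
  names(dna) <- ids %||% sprintf("read_%d", seq_along(reads))
  qual <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep("I", n), ""))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read UTR (or any) sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of RNA-alphabet sequences.
#' @export
read_fasta_rna <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as_rna(as.character(x)), names(x))
}

#' @rdname read_fasta_rna
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Default analysis parameters
#'
#' The constants every stage defaults to: 15 RPM expression cut,
#' |log2FC| > 2 with BH q < 0.05 for volcano significance, p < 0.05
#' for protein regulation, seed positions 2-8 with 3 nt of tolerated
#' 3' heterogeneity, 1000 GSEA permutations with weight 1 and minimum
#' set size 5, and the duplex scoring scheme of [duplex_params()].
#'
#' @return nested named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(thresholds = thresholds(),
       seed_policy = seed_policy(),
       duplex = duplex_params(),
       gsea = list(n_perm = 1000L, weight_p = 1, min_size = 5L),
       imputation = list(width = 0.3, shift = 1.8),
       pseudocount = 0.5)
}
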