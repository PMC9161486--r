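#' Packaged synthetic miR-183-like precursor reference
#'
#' A constructed hairpin (not the miRBase stem-loop, which is external
#' data) that embeds the canonical mature miR-183-5p sequence
#' 5'-UAUGGCACUGGUAGAAUUCACU-3' with templated flanks on both sides,
#' so every 5' offset in \[-3, +5\] and 3' offset in \[-3, +3\] is a
#' valid, unique substring. Sufficient for every classification
#' property; swap in a real precursor FASTA + arm table for real data.
#'
#' @return a [premirna_reference()] with one arm `"miR-183-5p"`.
#' @export
synthetic_mir183_reference <- function() {
  mature <- "UAUGGCACUGGUAGAAUUCACU"
  up <- "CCGCAGAG"            # upstream template for 5' extensions
  down <- "GUGAACCA"          # downstream template for 3' extensions
  loop <- "CUUAGG"
  arm3 <- rna_revcomp(paste0(up, mature, down))  # fold-back 3p arm
  hairpin <- paste0(up, mature, down, loop, arm3)
  ref <- premirna_reference(
    "syn-mir-183", hairpin,
    data.frame(arm_id = "miR-183-5p",
               start = nchar(up), end = nchar(up) + nchar(mature)))
  ref
}

#' Simulate an error-free 5'isomiR read library
#'
#' Draws (5' offset, 3' offset) pairs i.i.d. from the given
#' distributions and emits the corresponding exact precursor
#' substrings -- the read structure of a small-RNA library over one
#' hairpin, without sequencing error. Every read carries a truth label
#' for classifier validation.
#'
#' @param ref a [premirna_reference()].
#' @param arm_id mature arm the reads derive from.
#' @param offset5_probs named numeric vector, probability per 5'
#'   offset (names are signed integers); must sum to 1.
#' @param offset3_probs named numeric vector over offsets in
#'   \[-3, 3\]; must sum to 1.
#' @param n_reads number of reads.
#' @param seed integer RNG seed.
#' @return list: `reads` (character vector), `truth` (data.frame read,
#'   offset5, offset3).
#' @export
simulate_reads <- function(ref, arm_id, offset5_probs, offset3_probs,
                           n_reads, seed = 1L) {
  stopifnot(inherits(ref, "premirna_reference"), n_reads > 0)
  p5 <- offset5_probs / sum(offset5_probs)
  p3 <- offset3_probs / sum(offset3_probs)
  o3v <- as.integer(names(p3))
  stopifnot(all(abs(o3v) <= 3L),
            abs(sum(offset5_probs) - 1) < 1e-8,
            abs(sum(offset3_probs) - 1) < 1e-8)
  a <- arm_coords(ref, arm_id)
  n_hp <- nchar(ref$sequence)
  o5v <- as.integer(names(p5))
  # precompute every variant sequence; invalid combinations are spec errors
  variants <- outer(o5v, o3v, Vectorize(function(o5, o3) {
    s <- a$start + o5; e <- a$end + o3
    if (s < 0L || e > n_hp || e - s < 15L || (a$end - s) < 8L)
      stop("offset combination (", o5, ",", o3,
           ") does not yield a valid read")
    substr(ref$sequence, s + 1L, e)
  }))
  set.seed(seed)
  i5 <- sample.int(length(o5v), n_reads, replace = TRUE, prob = p5)
  i3 <- sample.int(length(o3v), n_reads, replace = TRUE, prob = p3)
  list(reads = variants[cbind(i5, i3)],
       truth = data.frame(read = seq_len(n_reads),
                          offset5 = o5v[i5], offset3 = o3v[i3]))
}

#' Simulate a matched tumor/normal isomiR count cohort
#'
#' Negative-binomial counts around log-normal per-feature baselines,
#' the standard over-dispersion model for sequencing counts. Planted
#' features have their tumor-group mean scaled by 2^log2fc; everything
#' else is null. Dispersion 0 degrades to Poisson.
#'
#' @param n_tumor,n_normal samples per group.
#' @param n_features number of isomiR features.
#' @param planted data.frame (feature index or id, log2fc) of true
#'   effects; NULL for a fully null cohort.
#' @param dispersion NB dispersion (1/size); 0 = Poisson.
#' @param library_size expected reads per sample (default 1e6, so
#'   baseline means are on the RPM scale).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline of
#'   per-feature mean expression (defaults give a median around
#'   55 RPM with a long right tail, as in small-RNA libraries).
#' @param seed integer RNG seed.
#' @return list: `counts` (features x samples), `group` (factor,
#'   levels tumor/normal), `truth` (planted table),
#'   `library_sizes`.
#' @export
simulate_cohort <- function(n_tumor = 20L, n_normal = 20L,
                            n_features = 500L, planted = NULL,
                            dispersion = 0.2, library_size = 1e6,
                            baseline_meanlog = 4, baseline_sdlog = 1.5,
                            seed = 1L) {
  set.seed(seed)
  feat <- sprintf("isomiR_%03d", seq_len(n_features))
  base_rpm <- stats::rlnorm(n_features, baseline_meanlog, baseline_sdlog)
  lfc <- stats::setNames(rep(0, n_features), feat)
  if (!is.null(planted)) {
    idx <- if (is.numeric(planted$feature)) as.integer(planted$feature)
           else match(as.character(planted$feature), feat)
    stopifnot(!anyNA(idx), all(idx >= 1L & idx <= n_features))
    lfc[idx] <- planted$log2fc
  }
  mu_t <- base_rpm * 2^lfc          # tumor mean, RPM scale
  mu_n <- base_rpm
  scale <- library_size / 1e6
  draw <- function(mu, n) {
    m <- matrix(rep(mu * scale, n), ncol = n)
    if (dispersion > 0)
      matrix(stats::rnbinom(length(m), mu = m, size = 1 / dispersion),
             ncol = n)
    else matrix(stats::rpois(length(m), m), ncol = n)
  }
  counts <- cbind(draw(mu_t, n_tumor), draw(mu_n, n_normal))
  dimnames(counts) <- list(feat, c(sprintf("tumor_%02d", seq_len(n_tumor)),
                                   sprintf("normal_%02d", seq_len(n_normal))))
  list(counts = counts,
       group = factor(rep(c("tumor", "normal"), c(n_tumor, n_normal)),
                      levels = c("tumor", "normal")),
       truth = data.frame(feature = feat, log2fc = unname(lfc)),
       library_sizes = rep(library_size, n_tumor + n_normal))
}

#' Simulate a patient cohort with a latent gene-set activity
#'
#' A latent activity A ~ N(0,1) per patient drives the genes of one
#' designated set (expression = loading * A + noise) while background
#' genes are pure noise; a miRNA is coupled to A through a Gaussian
#' copula calibrated so the population Spearman correlation equals
#' `mir_rho` exactly (rank correlation of a bivariate normal:
#' rho_S = (6/pi) * asin(rho_P / 2)). This is the structure behind a
#' transcription factor whose activity both shapes its target-gene
#' signature and drives a miRNA's expression.
#'
#' @param n_patients,n_genes cohort dimensions.
#' @param set_size genes in the driven set (ids `setgene_*`).
#' @param loading effect of A on set genes.
#' @param mir_rho target Spearman correlation between miRNA and A.
#' @param noise_sd residual sd of every gene.
#' @param seed integer RNG seed.
#' @return list: `mat` (genes x patients), `mirna` (vector),
#'   `gene_set` (character), `activity` (the latent truth A).
#' @export
simulate_activity_cohort <- function(n_patients = 300L, n_genes = 1000L,
                                     set_size = 100L, loading = 1,
                                     mir_rho = 0.4, noise_sd = 1,
                                     seed = 1L) {
  stopifnot(abs(mir_rho) <= 1, set_size < n_genes)
  set.seed(seed)
  A <- stats::rnorm(n_patients)
  genes <- c(sprintf("setgene_%03d", seq_len(set_size)),
             sprintf("bg_%04d", seq_len(n_genes - set_size)))
  mat <- matrix(stats::rnorm(n_genes * n_patients, sd = noise_sd),
                nrow = n_genes, dimnames = list(genes, NULL))
  mat[seq_len(set_size), ] <- mat[seq_len(set_size), ] +
    matrix(loading * A, set_size, n_patients, byrow = TRUE)
  colnames(mat) <- sprintf("patient_%03d", seq_len(n_patients))
  # Gaussian copula: Pearson rho_P on the normal scale that yields the
  # requested Spearman rho_S
  rho_p <- 2 * sin(pi * mir_rho / 6)
  mirna <- rho_p * A + sqrt(1 - rho_p^2) * stats::rnorm(n_patients)
  list(mat = mat, mirna = mirna,
       gene_set = genes[seq_len(set_size)], activity = A)
}

#' Simulate a label-free proteome with left-censored missingness
#'
#' Gaussian log2 intensities around protein-specific baselines; the
#' treatment group's members of one designated set are shifted down by
#' `shift`; each cell goes missing with a probability that decreases
#' logistically with its intensity, emulating detection-limit
#' censoring.
#'
#' @param n_control,n_treatment replicates per group.
#' @param n_proteins number of proteins.
#' @param set_size proteins in the shifted set (ids `setprot_*`).
#' @param shift downshift (log2 units) applied to set proteins in the
#'   treatment group; 0 = null.
#' @param replicate_sd within-group sd of each protein (log2 units).
#' @param baseline_mean,baseline_sd distribution of per-protein
#'   baseline intensity (log2 LFQ scale).
#' @param missing_mid intensity at which the missingness probability
#'   is 50%; defaults 3 sd below the baseline mean so overall
#'   missingness is realistic (roughly 5-10%).
#' @param missing_scale steepness of the logistic censoring curve.
#' @param seed integer RNG seed.
#' @return list: `mat` (proteins x samples with NA), `group` (factor
#'   control/treatment), `gene_set` (character), `full` (the
#'   uncensored matrix).
#' @export
simulate_proteome <- function(n_control = 4L, n_treatment = 4L,
                              n_proteins = 1000L, set_size = 50L,
                              shift = 1, replicate_sd = 0.25,
                              baseline_mean = 25, baseline_sd = 2,
                              missing_mid = baseline_mean - 3 * baseline_sd,
                              missing_scale = 0.8, seed = 1L) {
  stopifnot(set_size < n_proteins)
  set.seed(seed)
  prot <- c(sprintf("setprot_%03d", seq_len(set_size)),
            sprintf("prot_%04d", seq_len(n_proteins - set_size)))
  base <- stats::rnorm(n_proteins, baseline_mean, baseline_sd)
  n <- n_control + n_treatment
  mu <- matrix(base, n_proteins, n)
  mu[seq_len(set_size), n_control + seq_len(n_treatment)] <-
    mu[seq_len(set_size), n_control + seq_len(n_treatment)] - shift
  full <- mu + matrix(stats::rnorm(n_proteins * n, sd = replicate_sd),
                      n_proteins, n)
  dimnames(full) <- list(prot, c(sprintf("control_%d", seq_len(n_control)),
                                 sprintf("treat_%d", seq_len(n_treatment))))
  p_miss <- stats::plogis((missing_mid - full) / missing_scale)
  mat <- full
  mat[stats::runif(length(mat)) < p_miss] <- NA_real_
  list(mat = mat,
       group = factor(rep(c("control", "treatment"),
                          c(n_control, n_treatment)),
                      levels = c("control", "treatment")),
       gene_set = prot[seq_len(set_size)], full = full)
}

#' Simulate 3'UTR sequences with planted seed sites
#'
#' Random-background UTRs into which exact site strings (8mer,
#' 7mer-m8, 7mer-A1 or 6mer for a given isomiR seed) are planted at
#' recorded positions. Backgrounds are rejection-sampled so they
#' contain no accidental site of the queried isomiRs at or above
#' `min_site_type`, making the returned truth table exhaustive.
#'
#' @param n_utrs number of UTRs.
#' @param length_range integer range (lo, hi) of UTR lengths.
#' @param planted_sites data.frame (utr, mirna_seq, offset5,
#'   site_type) of sites to plant; `utr` is a 1-based UTR index.
#' @param scan_isomirs data.frame (mirna_seq, offset5) of every isomiR
#'   whose accidental sites must be excluded from backgrounds;
#'   defaults to the isomiRs appearing in `planted_sites`.
#' @param min_site_type site types at or above this rank are rejected
#'   in backgrounds (default `"6mer"`: no seed match at all).
#' @param max_attempts rejection-sampling bound per UTR.
#' @param seed integer RNG seed.
#' @return list: `utrs` (named character vector), `truth` (data.frame
#'   utr_id, start, end, site_type, mirna_seq, offset5).
#' @export
simulate_utrs <- function(n_utrs = 10L, length_range = c(200L, 400L),
                          planted_sites = NULL, scan_isomirs = NULL,
                          min_site_type = "6mer",
                          max_attempts = 10000L, seed = 1L) {
  set.seed(seed)
  rank_of <- c("6mer" = 1L, "7mer_A1" = 2L, "7mer_m8" = 3L, "8mer" = 4L)
  if (is.null(scan_isomirs) && !is.null(planted_sites))
    scan_isomirs <- unique(planted_sites[c("mirna_seq", "offset5")])
  has_site <- function(seq_) {
    if (is.null(scan_isomirs)) return(FALSE)
    for (i in seq_len(nrow(scan_isomirs))) {
      s <- seed_site_scan(seq_, scan_isomirs$mirna_seq[i],
                          scan_isomirs$offset5[i])
      if (any(rank_of[s$site_type] >= rank_of[min_site_type])) return(TRUE)
    }
    FALSE
  }
  site_string <- function(mirna_seq, offset5, site_type) {
    seed7 <- seed_sequence(mirna_seq, offset5)
    core6 <- substr(seed7, 1L, 6L)
    switch(site_type,
           "8mer"    = paste0(rna_revcomp(seed7), "A"),
           "7mer_m8" = rna_revcomp(seed7),
           "7mer_A1" = paste0(rna_revcomp(core6), "A"),
           "6mer"    = rna_revcomp(core6),
           stop("unknown site_type: ", site_type))
  }
  utrs <- character(n_utrs)
  names(utrs) <- sprintf("UTR_%03d", seq_len(n_utrs))
  truth <- NULL
  for (u in seq_len(n_utrs)) {
    want <- if (is.null(planted_sites)) NULL
            else planted_sites[planted_sites$utr == u, , drop = FALSE]
    len <- sample(length_range[1]:length_range[2], 1L)
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      bg <- paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
                  collapse = "")
      if (has_site(bg)) next
      seq_ <- bg
      rows <- NULL
      good <- TRUE
      if (!is.null(want) && nrow(want)) {
        for (k in seq_len(nrow(want))) {
          pat <- site_string(want$mirna_seq[k], want$offset5[k],
                             want$site_type[k])
          pos <- sample.int(nchar(seq_) - nchar(pat) + 1L, 1L)  # 1-based
          substr(seq_, pos, pos + nchar(pat) - 1L) <- pat
          rows <- rbind(rows, data.frame(
            utr_id = names(utrs)[u], start = pos - 1L,
            end = pos - 1L + nchar(pat), site_type = want$site_type[k],
            mirna_seq = want$mirna_seq[k], offset5 = want$offset5[k],
            stringsAsFactors = FALSE))
        }
        # planting may create junction sites or overwrite earlier plants:
        # accept only when the scan result equals the intended truth
        for (i in seq_len(nrow(scan_isomirs))) {
          found <- seed_site_scan(seq_, scan_isomirs$mirna_seq[i],
                                  scan_isomirs$offset5[i])
          found <- found[rank_of[found$site_type] >= rank_of[min_site_type], ]
          exp_ <- rows[rows$mirna_seq == scan_isomirs$mirna_seq[i] &
                       rows$offset5 == scan_isomirs$offset5[i], , drop = FALSE]
          expected_keys <- site_keys_expected(exp_)
          if (!setequal(paste(found$start, found$end, found$site_type),
                        expected_keys)) { good <- FALSE; break }
        }
      }
      if (good) { utrs[u] <- seq_; truth <- rbind(truth, rows); ok <- TRUE }
      if (ok) break
    }
    if (!ok) stop("rejection sampling failed for UTR ", u,
                  "; try longer UTRs or fewer planted sites")
  }
  if (is.null(truth))
    truth <- data.frame(utr_id = character(0), start = integer(0),
                        end = integer(0), site_type = character(0),
                        mirna_seq = character(0), offset5 = integer(0))
  list(utrs = utrs, truth = truth)
}

# the (start, end, type) keys seed_site_scan should report for planted
# sites: the scanner anchors on the 6mer core, so a planted 7mer_A1 /
# 6mer string is reported with its own coordinates
site_keys_expected <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0L) return(character(0))
  paste(rows$start, rows$end, rows$site_type)
}
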