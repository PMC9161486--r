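# Independent brute-force oracles. Each is written from the definition
# of the quantity it checks, not from the package implementation.

# step-up Benjamini-Hochberg, literal definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  ranked <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest rank down
  for (i in m:1) {
    adj[i] <- if (i == m) ranked[i] else min(ranked[i], adj[i + 1])
  }
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# upper-tail hypergeometric P(X >= a) by explicit summation
oracle_hyper_tail <- function(a, n_set, n_universe, n_drawn) {
  ks <- a:min(n_set, n_drawn)
  sum(choose(n_set, ks) * choose(n_universe - n_set, n_drawn - ks)) /
    choose(n_universe, n_drawn)
}

# weighted KS running-sum walk, literal loop
oracle_es <- function(scores, is_hit, p = 1) {
  n <- length(scores)
  nh <- sum(is_hit)
  denom <- sum(abs(scores[is_hit])^p)
  run <- 0
  pos <- -Inf
  neg <- Inf
  for (i in seq_len(n)) {
    if (is_hit[i]) {
      run <- run + (if (denom == 0) 1 / nh else abs(scores[i])^p / denom)
    } else {
      run <- run - 1 / (n - nh)
    }
    if (run > pos) pos <- run
    if (run < neg) neg <- run
  }
  # same tie convention as the statistic under test: positive wins
  if (pos >= -neg - 1e-9) pos else neg
}

# exhaustive sliding-window seed-site check. For every UTR position,
# tests the four site-type patterns directly; candidate matches are
# grouped by the coordinate of their 6-nt seed core and only the
# highest-priority type per core survives.
oracle_seed_scan <- function(utr, seed7) {
  rc <- function(s) {
    comp <- chartr("ACGU", "UGCA", s)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }
  core6 <- substr(seed7, 1, 6)
  pats <- list(
    `8mer`    = list(pat = paste0(rc(seed7), "A"), core_off = 1L),
    `7mer_m8` = list(pat = rc(seed7),              core_off = 1L),
    `7mer_A1` = list(pat = paste0(rc(core6), "A"), core_off = 0L),
    `6mer`    = list(pat = rc(core6),              core_off = 0L))
  n <- nchar(utr)
  found <- list()
  for (ty in names(pats)) {
    pat <- pats[[ty]]$pat
    L <- nchar(pat)
    for (s in 0:(n - L)) {
      if (n - L < 0) break
      if (substr(utr, s + 1, s + L) == pat) {
        core <- s + pats[[ty]]$core_off
        key <- as.character(core)
        if (is.null(found[[key]]))   # types iterated in priority order
          found[[key]] <- data.frame(start = s, end = s + L,
                                     site_type = ty,
                                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(found) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      site_type = character(0)))
  out <- do.call(rbind, found)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# top-down memoized local-alignment oracle (independent formulation of
# the affine-gap duplex score; mir/utr are character vectors, utr
# already reversed to the antiparallel orientation)
oracle_duplex <- function(mir, utr, params) {
  n <- length(mir); m <- length(utr)
  scale_of <- function(i) if (i >= 2 && i <= 8) params$seed_scale else 1
  psc <- function(a, b) {
    if ((a == "A" && b == "U") || (a == "U" && b == "A") ||
        (a == "G" && b == "C") || (a == "C" && b == "G")) return(params$match)
    if ((a == "G" && b == "U") || (a == "U" && b == "G"))
      return(params$gu_wobble)
    params$mismatch
  }
  memo <- new.env()
  # best score of an alignment ending in state st at (i, j)
  f <- function(i, j, st) {
    if (i < 1 || j < 1) return(-Inf)
    key <- paste(i, j, st)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (st == "M") {
      s <- psc(mir[i], utr[j]) * scale_of(i)
      s + max(0, f(i - 1, j - 1, "M"), f(i - 1, j - 1, "E"),
              f(i - 1, j - 1, "F"))
    } else if (st == "E") {  # gap consuming utr
      max(max(0, f(i, j - 1, "M"), f(i, j - 1, "F")) + params$gap_open,
          f(i, j - 1, "E") + params$gap_extend)
    } else {                 # gap consuming mir
      max(max(0, f(i - 1, j, "M"), f(i - 1, j, "E")) + params$gap_open,
          f(i - 1, j, "F") + params$gap_extend)
    }
    memo[[key]] <- val
    val
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m))
    best <- max(best, f(i, j, "M"))
  best
}

random_rna <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
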