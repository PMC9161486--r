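test_that("group fold changes follow the ratio-of-means definition", {
  expect_equal(log2_group_fc(c(8, 8), c(2, 2), pseudocount = 0), 2)
  expect_equal(log2_group_fc(c(3, 5, 7), c(3, 5, 7), pseudocount = 0), 0)
  expect_equal(log2_group_fc(c(4, 4), c(0, 0), pseudocount = 0.5), log2(9))
  expect_error(log2_group_fc(c(1, 2), c(0, 0), pseudocount = 0), "zero")
})

test_that("unpaired t-test matches the closed-form Welch computation", {
  expect_equal(unpaired_t(c(1, 2, 3), c(1, 2, 3)), list(t = 0, p = 1))
  deg <- unpaired_t(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_equal(deg$p, .Machine$double.xmin)
  expect_equal(deg$t, -Inf)
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(10); y <- rnorm(10, 0.5)
    got <- unpaired_t(x, y)
    # textbook Welch: t, Welch-Satterthwaite df, two-sided p
    se2 <- var(x) / 10 + var(y) / 10
    tt <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((var(x) / 10)^2 / 9 + (var(y) / 10)^2 / 9)
    expect_equal(got$t, tt, tolerance = 1e-10)
    expect_equal(got$p, 2 * pt(-abs(tt), df), tolerance = 1e-10)
    student <- unpaired_t(x, y, "student")
    expect_equal(student$p, t.test(x, y, var.equal = TRUE)$p.value)
  }
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.5, 100)), rep(0.5, 100))
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    # monotone in the p-values
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})

test_that("volcano classes use strict cuts and mirror under sign flip", {
  th <- thresholds()
  expect_equal(volcano_classify(3.0, 0.01, th), "sig_up")
  expect_equal(volcano_classify(-2.5, 0.049, th), "sig_down")
  expect_equal(volcano_classify(2.0, 0.01, th), "ns")   # boundary strict
  expect_equal(volcano_classify(3.0, 0.05, th), "ns")   # padj boundary
  set.seed(41)
  x <- rnorm(200, sd = 3); p <- runif(200)
  flipped <- volcano_classify(-x, p, th)
  orig <- volcano_classify(x, p, th)
  expect_equal(orig == "sig_up", flipped == "sig_down")
  expect_equal(orig == "ns", flipped == "ns")
})

test_that("protein regulation requires p < 0.05 and a signed fold change", {
  expect_equal(protein_regulation(0.4, 0.01), "up")
  expect_equal(protein_regulation(-0.4, 0.2), "unchanged")
  expect_equal(protein_regulation(0.0, 0.001), "unchanged")
  expect_equal(protein_regulation(-0.1, 0.049), "down")
})

test_that("Fisher enrichment equals the hypergeometric summation oracle", {
  universe <- sprintf("g%02d", 1:100)
  gene_set <- universe[1:10]
  regulated <- universe[c(1:5, 11:15)]     # a=5, b=5, c=5, d=85
  got <- fisher_enrichment(regulated, gene_set, universe)
  expect_equal(unname(got$table), c(5, 5, 5, 85))
  expect_equal(got$p, oracle_hyper_tail(5, 10, 100, 10), tolerance = 1e-12)
  expect_equal(got$odds_ratio, (5 * 85) / (5 * 5))
  # dual route: stats::fisher.test one-sided p
  expect_equal(got$p,
               fisher.test(matrix(c(5, 5, 5, 85), 2), alternative = "greater")$p.value,
               tolerance = 1e-12)

  expect_equal(fisher_enrichment(universe[11:20], gene_set, universe)$p, 1,
               tolerance = 1e-12)
  expect_equal(fisher_enrichment(universe[1:7], universe, universe)$p, 1)
  expect_error(fisher_enrichment("a", "a", character(0)), "empty universe")
})

test_that("Fisher enrichment is exact on exhaustive small universes", {
  set.seed(51)
  for (i in 1:30) {
    n_u <- sample(5:50, 1)
    universe <- sprintf("u%02d", seq_len(n_u))
    gene_set <- sample(universe, sample(n_u, 1))
    regulated <- sample(universe, sample(n_u, 1))
    got <- fisher_enrichment(regulated, gene_set, universe)
    a <- length(intersect(regulated, gene_set))
    expect_equal(got$p,
                 oracle_hyper_tail(a, length(gene_set), n_u,
                                   length(regulated)),
                 tolerance = 1e-12)
  }
})

test_that("downshift imputation draws from the narrowed shifted normal", {
  set.seed(61)
  full <- matrix(rnorm(30, 20), 10, 3)
  expect_identical(impute_downshift(full), full)

  m <- matrix(rnorm(2e4, mean = 20, sd = 1), ncol = 2)
  m[sample(length(m), 5e3)] <- NA
  m[1:2, ] <- matrix(rnorm(4, 20), 2)    # keep >= 2 observed per column
  imp <- impute_downshift(m, seed = 9)
  obs <- !is.na(m)
  expect_identical(imp[obs], m[obs])     # observed cells bit-identical
  for (j in 1:2) {
    mu <- mean(m[, j], na.rm = TRUE); s <- sd(m[, j], na.rm = TRUE)
    vals <- imp[!obs[, j], j]
    se <- 0.3 * s / sqrt(length(vals))
    expect_lt(abs(mean(vals) - (mu - 1.8 * s)), 3 * se)
    expect_equal(sd(vals), 0.3 * s, tolerance = 0.05)
  }
  expect_identical(impute_downshift(m, seed = 9), imp)
  expect_error(impute_downshift(matrix(NA_real_, 3, 1)), "observed")
})

test_that("ranked lists sort by fold change with lexicographic ties", {
  mat <- rbind(f1 = c(8, 8, 2, 2), f2 = c(2, 2, 2, 2))
  grp <- c("t", "t", "c", "c")
  r <- ranked_list_from_groups(mat, grp, "t", "c",
                               log_scale = FALSE, pseudocount = 0)
  expect_equal(r$feature, c("f1", "f2"))
  expect_equal(r$score, c(2, 0))

  flat <- matrix(5, 4, 4, dimnames = list(c("b", "d", "a", "c"), NULL))
  rf <- ranked_list_from_groups(flat, grp, "t", "c")
  expect_equal(rf$feature, c("a", "b", "c", "d"))
  expect_equal(rf$score, rep(0, 4))

  set.seed(71)
  m <- matrix(2^rnorm(50 * 6, 5), 50, 6,
              dimnames = list(sprintf("p%02d", 1:50), NULL))
  g <- rep(c("t", "c"), each = 3)
  r2 <- ranked_list_from_groups(m, g, "t", "c", log_scale = FALSE,
                                pseudocount = 0)
  byhand <- sort(vapply(seq_len(50), function(i)
    log2(mean(m[i, 1:3]) / mean(m[i, 4:6])), numeric(1)),
    decreasing = TRUE)
  expect_equal(r2$score, unname(byhand), tolerance = 1e-12)
})

test_that("de_table agrees with per-feature scalar statistics", {
  set.seed(81)
  mat <- matrix(rexp(30 * 12, 1 / 50), 30, 12,
                dimnames = list(sprintf("f%02d", 1:30), NULL))
  grp <- factor(rep(c("tumor", "normal"), each = 6),
                levels = c("tumor", "normal"))
  de <- de_table(mat, grp)
  for (i in c(1, 7, 30)) {
    x <- mat[i, 1:6]; y <- mat[i, 7:12]
    expect_equal(de$log2fc[i], log2_group_fc(x, y), tolerance = 1e-12)
    st <- unpaired_t(x, y)
    expect_equal(de$t[i], st$t, tolerance = 1e-10)
    expect_equal(de$p[i], st$p, tolerance = 1e-10)
  }
  expect_equal(de$p_adj, bh_adjust(de$p))
  expect_equal(de$class, volcano_classify(de$log2fc, de$p_adj))
  # degenerate rows: identical constants vs separated constants
  mat2 <- rbind(same = rep(5, 12), apart = rep(c(1, 9), each = 6))
  de2 <- de_table(mat2, grp)
  expect_equal(de2$p[de2$feature == "same"], 1)
  expect_lt(de2$p[de2$feature == "apart"], 1e-300)
})
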