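test_that("z-scaling standardizes each gene over patients", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(10, 20, 60))
  z <- zscale_genes(m)
  expect_equal(unname(z["g1", ]), c(-1, 0, 1))
  expect_equal(mean(z["g2", ]), 0, tolerance = 1e-12)
  expect_equal(sd(z["g2", ]), 1, tolerance = 1e-12)
  expect_warning(zf <- zscale_genes(rbind(flat = c(5, 5, 5), m)),
                 "zero-variance")
  expect_true(all(is.na(zf["flat", ])))
  expect_equal(suppressWarnings(zscale_genes(z)), z, tolerance = 1e-12)
  expect_error(zscale_genes(matrix(1)), "2 patients")
})

test_that("activity score is the per-patient median over set genes", {
  z <- rbind(g1 = c(-1, 0), g2 = c(0, 1), g3 = c(2, -3),
             other = c(50, 50))
  sc <- activity_score(z, c("g1", "g2", "g3"))
  expect_equal(unname(sc), c(0, 0))
  # locality: rescaling a non-set gene cannot move the score
  z2 <- z; z2["other", ] <- z2["other", ] * 1000
  expect_equal(activity_score(z2, c("g1", "g2", "g3")), sc)
  expect_error(activity_score(z, "absent"), "no gene")
})

test_that("activity score is exactly invariant under per-gene affine maps", {
  set.seed(141)
  m <- matrix(rnorm(50 * 30), 50, 30,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  gene_set <- sample(rownames(m), 12)
  a <- runif(50, 0.1, 5); b <- rnorm(50, sd = 10)
  m2 <- m * a + b
  s1 <- activity_score(zscale_genes(m), gene_set)
  s2 <- activity_score(zscale_genes(m2), gene_set)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("Spearman correlation matches the midrank-Pearson oracle", {
  expect_equal(spearman_cor(1:10, (1:10)^3), 1)
  expect_equal(spearman_cor(1:10, -(1:10)), -1)
  x <- c(1, 2, 2, 3); y <- c(1, 3, 2, 4)
  # manual midranks: x -> 1, 2.5, 2.5, 4
  expect_equal(spearman_cor(x, y),
               cor(c(1, 2.5, 2.5, 4), c(1, 3, 2, 4)), tolerance = 1e-12)
  expect_true(is.na(spearman_cor(c(1, 1, 1), c(1, 2, 3))))
})

test_that("correlation ranking orders genes by Spearman with the phenotype", {
  set.seed(151)
  pheno <- rnorm(30)
  m <- rbind(self = pheno, anti = -pheno,
             matrix(rnorm(20 * 30), 20, 30,
                    dimnames = list(sprintf("g%02d", 1:20), NULL)))
  r <- correlation_rank_metric(m, pheno)
  expect_equal(r$feature[1], "self")
  expect_equal(r$score[1], 1)
  expect_equal(r$feature[nrow(r)], "anti")
  expect_equal(r$score[nrow(r)], -1)
  want <- sort(vapply(rownames(m), function(g)
    cor(m[g, ], pheno, method = "spearman"), numeric(1)),
    decreasing = TRUE)
  expect_equal(r$score, unname(want), tolerance = 1e-12)
  # a flat gene has undefined correlation and is excluded
  m2 <- rbind(m, flat = rep(1, 30))
  expect_message(r2 <- correlation_rank_metric(m2, pheno), "excluded")
  expect_false("flat" %in% r2$feature)
})

test_that("enrichment score equals the running-sum walk on worked examples", {
  ranked <- data.frame(feature = paste0("g", 1:10),
                       score = seq(10, 1))
  expect_equal(gsea_es(ranked, "g1")$es, 1)           # single top hit
  expect_lt(gsea_es(ranked, "g10")$es, 0)             # single bottom hit

  r5 <- data.frame(feature = paste0("g", 1:5), score = c(5, 4, 3, 2, 1))
  walk <- gsea_es(r5, c("g1", "g3"))
  # hand walk: hits weigh 5/8 and 3/8, misses -1/3
  run <- cumsum(c(5 / 8, -1 / 3, 3 / 8, -1 / 3, -1 / 3))
  expect_equal(walk$running, run, tolerance = 1e-12)
  expect_equal(walk$es, run[which.max(abs(run))], tolerance = 1e-12)
  expect_error(gsea_es(r5, "absent"), "overlap")
  expect_error(gsea_es(r5, paste0("g", 1:5)), "overlap")
})

test_that("enrichment score equals the oracle on exhaustive small instances", {
  set.seed(161)
  for (n in 2:8) {
    score <- sort(rnorm(n, sd = 2), decreasing = TRUE)
    ranked <- data.frame(feature = paste0("f", seq_len(n)), score = score)
    for (mask in 1:(2^n - 2)) {
      hit <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
      got <- gsea_es(ranked, ranked$feature[hit])$es
      expect_equal(got, oracle_es(score, hit), tolerance = 1e-12)
      if (n <= 6)  # unweighted limit agreement
        expect_equal(gsea_es(ranked, ranked$feature[hit], weight_p = 0)$es,
                     oracle_es(score, hit, p = 0), tolerance = 1e-12)
    }
  }
})

test_that("enrichment score agrees with fgsea's statistic", {
  set.seed(171)
  score <- sort(rnorm(50), decreasing = TRUE)
  ranked <- data.frame(feature = paste0("g", 1:50), score = score)
  for (i in 1:10) {
    hit <- sort(sample(50, 8))
    expect_equal(gsea_es(ranked, ranked$feature[hit])$es,
                 fgsea::calcGseaStat(setNames(score, ranked$feature),
                                     hit, gseaParam = 1),
                 tolerance = 1e-10)
  }
})

test_that("permutation GSEA flags a planted leading-edge set", {
  set.seed(181)
  n <- 300
  score <- sort(rnorm(n, sd = 0.5) + c(rep(2, 30), rep(0, n - 30)),
                decreasing = TRUE)
  ranked <- data.frame(feature = paste0("g", seq_len(n)), score = score)
  sets <- c(list(planted = paste0("g", 1:30)),
            lapply(setNames(1:9, paste0("null", 1:9)), function(i)
              paste0("g", sample(n, 30))))
  res <- gsea_significance(ranked, sets, n_perm = 1000, seed = 4)
  top <- res[res$set == "planted", ]
  expect_lte(top$p_perm, 0.01)
  expect_gt(top$nes, 1)
  expect_lt(top$fdr_q, 0.05)
  expect_equal(sign(res$nes), sign(res$es))
  expect_true(all(res$p_perm >= 1 / 1001))
  # determinism under the seed
  res2 <- gsea_significance(ranked, sets, n_perm = 1000, seed = 4)
  expect_identical(res, res2)
})

test_that("phenotype-permutation mode recovers a driven gene set", {
  set.seed(191)
  sim <- simulate_activity_cohort(n_patients = 80, n_genes = 120,
                                  set_size = 25, loading = 1,
                                  mir_rho = 0.8, noise_sd = 0.5, seed = 6)
  sets <- list(driven = sim$gene_set,
               random = sample(rownames(sim$mat), 25))
  res <- gsea_significance(sets = sets, mode = "phenotype_perm",
                           mat = sim$mat, phenotype = sim$mirna,
                           n_perm = 200, seed = 8)
  expect_gt(res$nes[res$set == "driven"], 1)
  expect_lte(res$p_perm[res$set == "driven"], 0.05)
})

test_that("small sets are skipped and degenerate collections error", {
  ranked <- data.frame(feature = paste0("g", 1:50),
                       score = seq(5, -5, length.out = 50))
  expect_warning(
    res <- gsea_significance(ranked,
                             list(tiny = c("g1", "g2"),
                                  ok = paste0("g", 1:10)),
                             n_perm = 100, seed = 1),
    "skipped")
  expect_equal(res$set, "ok")
  expect_error(suppressWarnings(
    gsea_significance(ranked, list(tiny = "g1"), n_perm = 100, seed = 1)),
    "no usable")
})

test_that("bubble summary completes the condition-by-set grid", {
  r1 <- data.frame(set = c("A", "B"), size = c(5L, 6L), es = c(0.5, -0.4),
                   nes = c(1.5, -1.2), p_perm = c(0.01, 0.2),
                   fdr_q = c(0.02, 0.5))
  r2 <- data.frame(set = "A", size = 5L, es = 0.1, nes = 0.3,
                   p_perm = 0.9, fdr_q = 1)
  tab <- bubble_summary(list(cond1 = r1, cond2 = r2))
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$nes[tab$condition == "cond1" & tab$set == "A"], 1.5)
  expect_true(is.na(tab$nes[tab$condition == "cond2" & tab$set == "B"]))
  one <- bubble_summary(list(only = r2))
  expect_equal(nrow(one), 1L)
  expect_equal(one$fdr_q, 1)
})
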