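# Differential-expression module: Poisson LRT against the closed form,
# Bonferroni, stratified runs, sex-pattern classification, DEG comparison.

test_that("poisson_glm_test matches the closed-form two-group LRT", {
  # identical groups: stat 0, p 1
  y <- c(3, 1, 4, 3, 1, 4); grp <- rep(c("TG", "WT"), each = 3)
  t0 <- poisson_glm_test(y, grp, rep(10, 6))
  expect_equal(t0$stat, 0, tolerance = 1e-10)
  expect_equal(t0$p, 1)
  # worked two-group example: 10 counts / exposure 100 vs 20 / 100
  y <- c(rep(2, 5), rep(4, 5)); grp <- rep(c("WT", "TG"), each = 5)
  t1 <- poisson_glm_test(y, grp, rep(20, 10))
  expect_equal(t1$stat, 2 * (10 * log(10 / 15) + 20 * log(20 / 15)),
               tolerance = 1e-8)
  expect_equal(t1$stat, 3.398, tolerance = 1e-3)
  expect_equal(t1$p, 0.0653, tolerance = 1e-3)
  expect_equal(t1$logFC, log(2), tolerance = 1e-8)
  # scale equivariance: doubling counts and exposures keeps logFC
  t2 <- poisson_glm_test(2 * y, grp, rep(40, 10))
  expect_equal(t2$logFC, t1$logFC, tolerance = 1e-8)
  grp6 <- rep(c("TG", "WT"), each = 3)
  # zero gene
  expect_identical(poisson_glm_test(rep(0, 6), grp6, rep(5, 6)),
                   list(logFC = 0, p = 1, stat = 0))
  # separation: one group all zero stays finite
  t3 <- poisson_glm_test(c(0, 0, 0, 5, 6, 7), grp6, rep(10, 6))
  expect_true(is.finite(t3$p) && t3$p < 0.01)
  expect_error(poisson_glm_test(c(-1, 1), c("TG", "WT"), c(1, 1)),
               "negative")
})

test_that("LRT equals the closed form on random instances", {
  withr::with_seed(2024, {
    for (i in 1:200) {
      nA <- sample(2:8, 1); nB <- sample(2:8, 1)
      yA <- rpois(nA, 3); yB <- rpois(nB, 5)
      eA <- runif(nA, 5, 15); eB <- runif(nB, 5, 15)
      if (sum(yA) + sum(yB) == 0) next
      t0 <- poisson_glm_test(c(yA, yB), rep(c("TG", "WT"), c(nA, nB)),
                             c(eA, eB))
      expect_equal(t0$stat, lrt_oracle(yB, eB, yA, eA), tolerance = 1e-8)
    }
  })
})

test_that("bonferroni_adjust caps and scales", {
  expect_equal(bonferroni_adjust(0.001, 100), 0.1)
  expect_equal(bonferroni_adjust(0.5, 10), 1)
  expect_equal(bonferroni_adjust(0.123, 1), 0.123)
  p <- c(0.2, 0.01, 1)
  expect_true(all(bonferroni_adjust(p) >= p))
})

test_that("compute_pct_expressing counts positive cells per genotype", {
  grp <- rep(c("TG", "WT"), c(12, 4))
  y <- c(rep(1, 3), rep(0, 9), rep(2, 4))
  expect_equal(compute_pct_expressing(y, grp),
               c(pct_tg = 0.25, pct_wt = 1))
  expect_equal(compute_pct_expressing(rep(0, 16), grp),
               c(pct_tg = 0, pct_wt = 0))
})

test_that("run_stratified_de recovers planted male-specific genes", {
  hits_m <- hits_f <- logical(0)
  for (s in 1:10) {
    w <- small_de_world(500 + s, n_cells_arm = 300L, lfc = 1.2)
    de <- run_stratified_de(w$sim$counts, w$sim$metadata,
                            include_all = FALSE)
    for (g in w$effects$gene) {
      qm <- de$q[de$gene == g & de$gender == "M"]
      qf <- de$q[de$gene == g & de$gender == "F"]
      hits_m <- c(hits_m, length(qm) == 1 && qm < 0.05)
      hits_f <- c(hits_f, length(qf) == 1 && qf > 0.5)
    }
  }
  expect_gte(mean(hits_m & hits_f), 0.9)
})

test_that("run_stratified_de bookkeeping: rows, skipped strata", {
  w <- small_de_world(77, n_cells_arm = 40L)
  de <- run_stratified_de(w$sim$counts, w$sim$metadata, include_all = TRUE)
  expect_s3_class(de, "de_results")
  expect_setequal(unique(de$cell_type), c("ct", "ALL"))
  # row count: expressed genes per stratum
  for (gd in c("M", "F")) {
    md <- w$sim$metadata
    sel <- md$gender == gd
    expressed <- sum(Matrix::rowSums(w$sim$counts[, md$barcode[sel]] > 0) >= 3)
    expect_identical(sum(de$cell_type == "ct" & de$gender == gd),
                     as.integer(expressed))
  }
  expect_true(all(de$q >= de$p))
  # stratum missing a genotype is skipped with a warning
  md2 <- w$sim$metadata
  md2 <- md2[!(md2$gender == "F" & md2$genotype == "TG"), ]
  expect_warning(
    run_stratified_de(w$sim$counts, md2, include_all = FALSE),
    "lacks a genotype")
})

test_that("classify_gender_pattern reproduces the published worked
           examples and rule boundaries", {
  cls <- function(lm, qm, lf, qf)
    classify_gender_pattern(list(logFC = lm, q = qm),
                            list(logFC = lf, q = qf))
  # B2m, endothelial
  expect_identical(cls(-0.43, 8.1e-16, 0.68, 4.4e-17), "dimorphic")
  # mt-Rnr2, neurons
  expect_identical(cls(-1.08, 9.98e-13, 0.83, 1.15e-13), "dimorphic")
  # Egr1, astrocytes
  expect_identical(cls(-0.31, 2.82e-07, 0.53, 0.00016), "dimorphic")
  # Egr1, endothelial: male-specific decrease
  expect_identical(cls(-0.26, 0.0012, 0.1, 0.7), "male_specific")
  # buffer zone: q_f between 0.05 and 0.5 is unclassified
  expect_identical(cls(-0.26, 0.01, 0.2, 0.3), "unclassified")
  expect_identical(cls(0.5, 0.001, 0.4, 0.002), "neutral")
  expect_identical(cls(0.2, 0.7, -0.5, 0.01), "female_specific")
  # zero logFC with significance in both: sign undefined
  expect_warning(out <- cls(0, 0.001, 0.5, 0.001), "sign undefined")
  expect_identical(out, "unclassified")
})

test_that("classification is a partition over simulated strata", {
  w <- small_de_world(88, n_cells_arm = 60L,
                      classes = c("male_specific", "neutral", "dimorphic"))
  de <- run_stratified_de(w$sim$counts, w$sim$metadata, include_all = FALSE)
  cl <- classify_gender_patterns(de)
  expect_identical(anyDuplicated(paste(cl$gene, cl$cell_type)), 0L)
  expect_true(all(cl$label %in% c("neutral", "male_specific",
                                  "female_specific", "dimorphic",
                                  "unclassified")))
})

test_that("type-I error on a fully null simulation stays below 0.05", {
  cfg <- sim_config(n_genes = 2000L, cells_per_arm = c(a = 100L),
                    marker_genes_per_type = 0L, seed = 314L)
  sim <- generate_counts(cfg)
  md <- sim$metadata[sim$metadata$gender == "M", ]  # 200 cells/arm total
  # the female stratum is empty by design and warns
  de <- suppressWarnings(run_stratified_de(sim$counts[, md$barcode], md,
                                           include_all = FALSE))
  expect_lte(mean(de$q < 0.05), 0.05)
})

test_that("compare_deg_sets flags concordance by class and sign", {
  a <- data.frame(gene = c("Mbp", "Hsp90ab1", "Xyz"),
                  cell_type = "oligodendrocytes",
                  label = "male_specific",
                  logFC_m = c(-0.5, -0.4, 0.2), logFC_f = 0,
                  q_m = 1e-4, q_f = 0.9)
  b <- data.frame(gene = c("MBP", "HSP90AB1"),
                  cell_type = "oligodendrocytes",
                  label = "male_specific",
                  logFC_m = c(-0.3, 0.6), logFC_f = 0,
                  q_m = 1e-3, q_f = 0.8)
  out <- compare_deg_sets(a, b)
  expect_identical(nrow(out), 2L)
  expect_true(out$concordant[out$gene == "MBP"])
  expect_false(out$concordant[out$gene == "HSP90AB1"])
  # disjoint sets -> empty table
  empty <- compare_deg_sets(a, transform(b, gene = c("AAA", "BBB")))
  expect_identical(nrow(empty), 0L)
  # case-sensitive matching finds nothing without the uppercase map
  expect_identical(nrow(compare_deg_sets(a, b, map_uppercase = FALSE)), 0L)
})
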