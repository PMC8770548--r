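test_that("MAF files parse with comments skipped and columns validated", {
  path <- withr::local_tempfile(fileext = ".maf")
  write_toy_maf(path)
  maf <- read_maf(path)
  expect_equal(nrow(maf), 5)
  expect_true(all(c("Hugo_Symbol", "Tumor_Sample_Barcode",
                    "Variant_Classification") %in% names(maf)))

  # header only
  writeLines("Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification",
             path)
  expect_equal(nrow(read_maf(path)), 0)

  # missing required column
  writeLines(c("Hugo_Symbol\tTumor_Sample_Barcode", "TTN\tS1"), path)
  expect_error(read_maf(path), "Variant_Classification")

  # unknown classification is kept with a warning
  writeLines(c("Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification",
               "TTN\tS1\tWeird_Class"), path)
  expect_warning(maf2 <- read_maf(path), "Weird_Class")
  expect_equal(nrow(maf2), 1)
})

test_that("TMB counts non-silent variants and divides by capture size", {
  maf <- data.frame(
    Hugo_Symbol = c("A", "B", "C", "D", "E"),
    Tumor_Sample_Barcode = rep("S1", 5),
    Variant_Classification = c("Missense_Mutation", "Missense_Mutation",
                               "Missense_Mutation", "Silent", "Silent"),
    stringsAsFactors = FALSE
  )
  tmb <- compute_tmb(maf)
  expect_equal(tmb$n_nonsilent, 3L)
  expect_equal(tmb$tmb_per_mb, 3 / 38)
  expect_equal(compute_tmb(maf, include_silent = TRUE)$n_nonsilent, 5L)
  # sample missing from MAF but in the cohort gets zero
  tmb2 <- compute_tmb(maf, samples = c("S1", "S2"))
  expect_equal(tmb2$n_nonsilent[tmb2$sample_id == "S2"], 0L)
  expect_error(compute_tmb(maf, capture_mb = 0), "positive")
})

test_that("Spearman correlation handles hand examples, ties, and errors", {
  expect_equal(spearman_corr(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_corr(c(1, 2, 3, 4), c(3, 1, 2, 4))$rho,
               cor(c(1, 2, 3, 4), c(3, 1, 2, 4), method = "spearman"))
  # hand rank computation: ranks (1,2,3) vs (3,1,2)
  expect_equal(spearman_corr(c(1, 2, 3), c(3, 1, 2))$rho, -0.5)
  # tied data: equals Pearson on mid-ranks
  set.seed(3)
  xt <- sample(1:5, 30, replace = TRUE)
  yt <- xt + sample(0:2, 30, replace = TRUE)
  oracle <- cor(rank(xt), rank(yt))
  expect_equal(spearman_corr(xt, yt)$rho, oracle, tolerance = 1e-12)
  # p via the t approximation matches cor.test
  ct <- suppressWarnings(cor.test(xt, yt, method = "spearman", exact = FALSE))
  expect_equal(spearman_corr(xt, yt)$p, ct$p.value, tolerance = 1e-9)
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
  expect_error(spearman_corr(1:2, 2:1), "at least 3")
})

test_that("the planted score-TMB correlation is recovered at cohort scale", {
  co <- simulate_cohort(simulation_config(
    n_genes = 300, n_celltypes = 5, n_samples = 400, tmb_score_rho = -0.5,
    n_signature_genes = 20, batch_sizes = 400, seed = 7
  ))
  tmb <- compute_tmb(co$maf, samples = co$survival$sample_id)
  est <- spearman_corr(co$truth$risk_score[tmb$sample_id], tmb$n_nonsilent)
  expect_lt(abs(est$rho - (-0.5)), 0.1)
})

test_that("mutation-frequency contrasts match the printed cohort table and an exact oracle", {
  # published 2x2: 58/171 vs 111/191 mutated
  make_maf <- function(k1, n1, k2, n2, gene = "TTN") {
    ids <- c(sprintf("H%03d", seq_len(n1)), sprintf("L%03d", seq_len(n2)))
    groups <- stats::setNames(rep(c("high", "low"), c(n1, n2)), ids)
    carriers <- c(sprintf("H%03d", seq_len(k1)), sprintf("L%03d", seq_len(k2)))
    maf <- data.frame(
      Hugo_Symbol = gene, Tumor_Sample_Barcode = carriers,
      Variant_Classification = "Missense_Mutation", stringsAsFactors = FALSE
    )
    list(maf = maf, groups = groups)
  }
  x <- make_maf(58, 171, 111, 191)
  tab <- gene_freq_contrast(x$maf, x$groups)
  expect_equal(tab$mutated_high, 58)
  expect_equal(tab$pct_high, 100 * 58 / 171, tolerance = 1e-9)
  # Yates chi-square on this table is in the published 7e-6 range
  expect_lt(tab$p, 2e-5)
  expect_gt(tab$p, 2e-6)
  expect_equal(
    tab$p,
    chisq.test(matrix(c(58, 171 - 58, 111, 191 - 111), 2))$p.value,
    tolerance = 1e-12
  )
  # the exact test agrees on the order of magnitude
  fisher_p <- fisher.test(matrix(c(58, 171 - 58, 111, 191 - 111), 2))$p.value
  expect_lt(abs(log10(tab$p) - log10(fisher_p)), 1)

  # doubling all counts strengthens the evidence
  x2 <- make_maf(116, 342, 222, 382)
  expect_lt(gene_freq_contrast(x2$maf, x2$groups)$p, tab$p)

  # identical patterns: chi-square statistic 0, p in the 1 region
  x3 <- make_maf(30, 100, 30, 100)
  expect_gt(gene_freq_contrast(x3$maf, x3$groups)$p, 0.99)
})

test_that("sparse tables fall back to the Fisher exact test", {
  maf <- data.frame(
    Hugo_Symbol = "RARE",
    Tumor_Sample_Barcode = "A01",
    Variant_Classification = "Missense_Mutation", stringsAsFactors = FALSE
  )
  groups <- stats::setNames(rep(c("a", "b"), c(5, 5)),
                            c(sprintf("A%02d", 1:5), sprintf("B%02d", 1:5)))
  tab <- gene_freq_contrast(maf, groups)
  expect_equal(tab$test, "fisher")
})
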