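pure_sig <- make_signature_matrix(150, 5, seed = 2)

test_that("a pure cell-type profile deconvolves to a unit fraction", {
  mix <- pure_sig[, 3, drop = FALSE]
  colnames(mix) <- "pure"
  fr <- deconvolve(mix, pure_sig, n_perm = 0)
  expect_equal(unname(fr$fractions["pure", ]), c(0, 0, 1, 0, 0),
               tolerance = 1e-6)
})

test_that("a noiseless 50/50 mix matches the non-negative least-squares oracle", {
  skip_if_not_installed("pracma")
  mix <- matrix(0.5 * pure_sig[, 1] + 0.5 * pure_sig[, 4],
                dimnames = list(rownames(pure_sig), "mix"))
  fr <- deconvolve(mix, pure_sig, n_perm = 0)
  expect_equal(unname(fr$fractions["mix", c(1, 4)]), c(0.5, 0.5),
               tolerance = 1e-6)
  # NNLS on the raw linear system is an independent route to the fractions
  nn <- pracma::lsqnonneg(pure_sig, mix[, 1])$x
  expect_equal(unname(fr$fractions["mix", ]), nn / sum(nn), tolerance = 1e-6)
})

test_that("noisy synthetic mixtures are recovered with high per-type correlation", {
  co <- simulate_cohort(simulation_config(
    n_genes = 300, n_celltypes = 5, n_samples = 100, noise_sd = 0.5,
    n_signature_genes = 20, batch_sizes = 100, seed = 5
  ))
  fr <- deconvolve(co$expression, co$signature_matrix, n_perm = 0)
  r <- vapply(1:5, function(k) {
    cor(co$true_fractions[, k], fr$fractions[, k])
  }, numeric(1))
  expect_true(all(r >= 0.9))
  expect_true(all(abs(rowSums(fr$fractions) - 1) < 1e-9))
})

test_that("deconvolution is invariant to sample order and positive scaling", {
  co <- simulate_cohort(simulation_config(
    n_genes = 300, n_celltypes = 5, n_samples = 8, noise_sd = 0.3,
    n_signature_genes = 20, batch_sizes = 8, seed = 6
  ))
  m <- co$expression$values
  fr1 <- deconvolve(expression_matrix(m, "TPM"), co$signature_matrix,
                    n_perm = 0)
  perm <- c(5, 1, 8, 2, 7, 3, 6, 4)
  fr2 <- deconvolve(expression_matrix(m[, perm], "TPM"), co$signature_matrix,
                    n_perm = 0)
  expect_equal(fr2$fractions[colnames(m), ], fr1$fractions, tolerance = 1e-8)
  fr3 <- deconvolve(expression_matrix(m * 7, "TPM"), co$signature_matrix,
                    n_perm = 0)
  expect_equal(fr3$fractions, fr1$fractions, tolerance = 1e-8)
})

test_that("insufficient signature-gene overlap is an error listing missing genes", {
  set.seed(2)
  mix <- matrix(rexp(150), 150, 1,
                dimnames = list(c(rownames(pure_sig)[1:40],
                                  sprintf("OTHER%03d", 1:110)), "s"))
  expect_error(deconvolve(mix, pure_sig, n_perm = 0), "missing")
})

test_that("permutation p-values are roughly uniform for structureless mixtures", {
  sig <- make_signature_matrix(60, 4, seed = 3)
  pool <- as.vector(sig)
  set.seed(17)
  n_draw <- 200
  # one deconvolution per draw, each with its own permutation null, so the
  # 200 p-values are independent; for a single-sample mixture the null is a
  # pure permutation of the observed values, hence exchangeable
  p <- vapply(seq_len(n_draw), function(j) {
    mix <- matrix(sample(pool, 60, replace = TRUE), 60, 1,
                  dimnames = list(rownames(sig), "draw"))
    deconvolve(mix, sig, n_perm = 99, seed = 1000 + j)$p_value
  }, numeric(1))
  # smear each p over its own permutation-grid cell: the smoothed p-values
  # are continuous-uniform under the null, so KS applies despite ties
  p_smooth <- p - runif(n_draw, 0, 1 / 100)
  ks <- ks.test(p_smooth, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("ssGSEA depends on ranks only and is maximal for a top-loaded set", {
  m <- random_log_matrix(40, 3, seed = 4)
  set <- rownames(m)[c(3, 10, 22)]
  s1 <- ssgsea_score(m, set)
  s2 <- ssgsea_score(2^m + 5, set) # monotone transform
  expect_equal(s1, s2, tolerance = 1e-12)

  # raising the in-set genes above everything maximizes the score among
  # random placements
  top <- m
  top[set, 1] <- max(m[, 1]) + 1:3
  s_top <- ssgsea_score(top, set)[1]
  others <- replicate(30, {
    sh <- sample(rownames(m), 3)
    ssgsea_score(m, sh)[1]
  })
  expect_gte(s_top, max(others))
})

test_that("ssGSEA matches the exhaustive summation oracle on a toy sample", {
  set.seed(11)
  v <- matrix(rnorm(10), 10, 1,
              dimnames = list(paste0("g", 1:10), "s1"))
  set <- c("g2", "g5", "g9")
  expect_equal(
    unname(ssgsea_score(v, set, alpha = 0.25)[1]),
    ssgsea_oracle(setNames(v[, 1], rownames(v)), set, alpha = 0.25),
    tolerance = 1e-12
  )
  expect_error(ssgsea_score(v, c("absent1", "absent2")), "no gene")
})

test_that("microenvironment scores add exactly and respond to enrichment", {
  m <- random_log_matrix(60, 4, seed = 9)
  stromal <- rownames(m)[1:10]
  immune <- rownames(m)[11:20]
  m[immune, 1] <- m[immune, 1] + 5 # sample 1 immune-enriched
  m[immune, 2] <- m[immune, 2] - 5
  tb <- estimate_scores(m, stromal, immune)
  expect_equal(tb$estimate_score, tb$stromal_score + tb$immune_score)
  expect_gt(tb$immune_score[1], tb$immune_score[2])
  m2 <- cbind(m, dup = m[, 3])
  colnames(m2)[3] <- "orig"
  tb2 <- estimate_scores(m2, stromal, immune)
  expect_equal(tb2$immune_score[tb2$sample_id == "dup"],
               tb2$immune_score[tb2$sample_id == "orig"])
})
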