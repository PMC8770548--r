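make_ref <- function(n_genes = 50, n_samples = 200, seed = 1,
                     noise_sd = 0, n_causal = 10) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * n_samples, 5, 1), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("c%03d", seq_len(n_samples))))
  beta <- numeric(n_genes)
  beta[seq_len(n_causal)] <- rnorm(n_causal, 0, 0.8)
  y <- drop(t(x) %*% beta) + rnorm(n_samples, 0, noise_sd)
  list(x = x, y = y, beta = beta)
}

test_that("a noiseless linear response is learned almost perfectly", {
  ref <- make_ref(noise_sd = 0, seed = 3)
  train <- 1:150
  test <- 151:200
  model <- fit_drug_model(ref$x[, train], ref$y[train], seed = 5)
  pred <- predict_ic50(model, ref$x[, test])
  expect_gte(cor(pred, ref$y[test]), 0.99)
})

test_that("pure-noise responses show no held-out association", {
  ref <- make_ref(seed = 7, n_samples = 400, n_causal = 0, noise_sd = 1)
  train <- 1:200
  test <- 201:400
  model <- fit_drug_model(ref$x[, train], ref$y[train], seed = 5)
  pred <- predict_ic50(model, ref$x[, test])
  expect_lt(abs(cor(pred, ref$y[test])), 0.2)
})

test_that("an overwhelming penalty collapses predictions to the training mean", {
  ref <- make_ref(seed = 9, noise_sd = 0.5)
  model <- fit_drug_model(ref$x, ref$y, lambda_grid = c(1e9, 0.9e9), seed = 2)
  pred <- predict_ic50(model, ref$x)
  expect_lt(max(abs(pred - mean(ref$y))), 0.05 * sd(ref$y))
})

test_that("prediction mechanics: training reproduction, missing and extra genes", {
  ref <- make_ref(seed = 11, noise_sd = 0.3)
  model <- fit_drug_model(ref$x, ref$y, seed = 4)
  pred <- predict_ic50(model, ref$x)
  # refitting on the training matrix reproduces the fitted values
  expect_equal(
    pred,
    setNames(
      drop(model$intercept +
             t((ref$x - model$gene_mean) / model$gene_sd) %*%
               model$coefficients),
      colnames(ref$x)
    ),
    tolerance = 1e-12
  )
  # an extra all-zero gene changes nothing
  x2 <- rbind(ref$x, extra = 0)
  expect_equal(predict_ic50(model, x2), pred)
  # dropping genes imputes at the training mean; below 50% overlap errors
  x3 <- ref$x[1:30, ]
  expect_length(predict_ic50(model, x3), 200)
  expect_error(predict_ic50(model, ref$x[1:20, ]), "half")
})

test_that("fold housekeeping: seeds reproduce, tiny cohorts reduce folds", {
  ref <- make_ref(seed = 13, noise_sd = 0.5)
  m1 <- fit_drug_model(ref$x, ref$y, seed = 21)
  m2 <- fit_drug_model(ref$x, ref$y, seed = 21)
  expect_equal(m1$lambda, m2$lambda)
  expect_equal(m1$coefficients, m2$coefficients)
  w <- capture_warnings(
    fit_drug_model(ref$x[, 1:25], ref$y[1:25], n_folds = 30, seed = 1)
  )
  expect_true(any(grepl("reducing folds", w)))
  expect_error(fit_drug_model(ref$x[, 1:10], ref$y[1:10]), "20 reference")
})

test_that("ridge predictions ignore gene ordering", {
  ref <- make_ref(seed = 15, noise_sd = 0.3)
  model <- fit_drug_model(ref$x, ref$y, seed = 6)
  perm <- sample(nrow(ref$x))
  expect_equal(predict_ic50(model, ref$x[perm, ]),
               predict_ic50(model, ref$x))
})

test_that("a planted sensitivity difference separates the groups", {
  ref <- make_ref(seed = 17, noise_sd = 0.5)
  model <- fit_drug_model(ref$x, ref$y, seed = 8)
  set.seed(18)
  n <- 200
  causal <- names(which(model$coefficients > 0.1))
  skip_if(length(causal) < 2)
  x_new <- matrix(rnorm(50 * n, 5, 1), 50, n,
                  dimnames = list(rownames(ref$x), sprintf("p%03d", 1:n)))
  group <- rep(c("HIGH", "LOW"), each = n / 2)
  x_new[causal, group == "LOW"] <- x_new[causal, group == "LOW"] - 1.5
  pred <- predict_ic50(model, x_new)
  wt <- wilcoxon_rank_sum(pred, group)
  expect_lt(wt$p, 0.01)
  expect_gt(median(pred[group == "HIGH"]), median(pred[group == "LOW"]))
})

test_that("Wilcoxon branches: exact enumeration, ties, and approximations", {
  # complete separation of (1,2,3) vs (4,5,6): exact two-sided p = 0.1
  res <- wilcoxon_rank_sum(c(1, 2, 3, 4, 5, 6),
                           rep(c("a", "b"), each = 3))
  expect_equal(res$p, 0.1)
  # identical groups: p in the 1 region
  res_same <- wilcoxon_rank_sum(c(1, 2, 3, 1, 2, 3) + rep(c(0, 1e-9), 3),
                                rep(c("a", "b"), 3))
  expect_gt(res_same$p, 0.5)
  # exact vs normal approximation agree at n = 8 per group
  set.seed(19)
  x <- rnorm(16)
  g <- rep(c("a", "b"), each = 8)
  p_exact <- wilcoxon_rank_sum(x, g)$p
  p_approx <- suppressWarnings(
    wilcox.test(x[g == "a"], x[g == "b"], exact = FALSE, correct = TRUE)
  )$p.value
  expect_lt(abs(p_exact - p_approx), 0.02)
  expect_error(wilcoxon_rank_sum(1:4, c("a", "a", "a", "b")), ">= 2")
  expect_error(wilcoxon_rank_sum(1:4, rep("a", 4)), "2 groups")
})
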