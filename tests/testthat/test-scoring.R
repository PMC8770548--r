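make_survival <- function(time, event, ids = NULL) {
  data.frame(
    sample_id = ids %||% sprintf("s%03d", seq_along(time)),
    time = time, event = event, stringsAsFactors = FALSE
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("informative features are confirmed and noise rejected", {
  set.seed(3)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  info <- sapply(1:10, function(i) rnorm(n) + 2 * y) # 2-sigma class shift
  noise <- matrix(rnorm(n * 50), n, 50)
  x <- cbind(info, noise)
  colnames(x) <- c(sprintf("info%02d", 1:10), sprintf("noise%02d", 1:50))
  confirmed <- boruta_select(x, y, max_iter = 40, seed = 3)
  expect_true(all(sprintf("info%02d", 1:10) %in% confirmed))
  expect_gte(sum(grepl("^noise", attr(confirmed, "rejected"))), 45)
})

test_that("all-noise input confirms at most one feature", {
  set.seed(5)
  x <- matrix(rnorm(150 * 30), 150, 30)
  y <- rep(c(0, 1), each = 75)
  confirmed <- boruta_select(x, y, max_iter = 40, alpha = 0.01, seed = 5)
  expect_lte(length(confirmed), 1)
})

test_that("degenerate feature input is handled", {
  x <- cbind(matrix(rnorm(40 * 6), 40, 6), const = 1)
  y <- rep(c(0, 1), each = 20)
  expect_warning(boruta_select(x, y, max_iter = 5, seed = 1), "constant")
  expect_error(boruta_select(x[, 1:3], y), "at least 5")
  expect_error(boruta_select(x[, 1:6], rep(1, 40)), "2 classes")
})

test_that("the ICI score is antisymmetric, centered, and sign-oriented", {
  m <- random_log_matrix(60, 40, seed = 11)
  part <- list(signature_a = rownames(m)[1:20],
               signature_b = rownames(m)[21:40])
  sc <- ici_score(m, part)
  swapped <- ici_score(m, list(signature_a = part$signature_b,
                               signature_b = part$signature_a))
  expect_equal(sc$ici_score, -swapped$ici_score, tolerance = 1e-12)
  expect_lt(abs(mean(sc$pc1_a)), 1e-9)
  expect_lt(abs(mean(sc$ici_score)), 1e-9)

  # a sample with uniformly elevated signature-A genes scores high
  m2 <- m
  m2[part$signature_a, 1] <- m2[part$signature_a, 1] + 3
  sc2 <- ici_score(m2, part)
  expect_gt(sc2$ici_score[1], median(sc2$ici_score))

  expect_error(
    ici_score(m, list(signature_a = "g001", signature_b = part$signature_b)),
    "fewer than 2"
  )
})

test_that("the score ignores sample-wide additive offsets", {
  m <- random_log_matrix(60, 30, seed = 13)
  part <- list(signature_a = rownames(m)[1:20],
               signature_b = rownames(m)[21:40])
  sc1 <- ici_score(m, part)
  m2 <- m
  m2[, 5] <- m2[, 5] + 0 # identical
  expect_equal(ici_score(m2, part)$ici_score, sc1$ici_score)
})

test_that("the selected cutpoint matches the brute-force log-rank scan", {
  set.seed(29)
  for (rep_i in 1:50) {
    n <- 40
    score <- rnorm(n)
    time <- rexp(n, exp(0.5 * score - 1))
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    surv <- make_survival(time, event)
    dc <- dichotomize(
      data.frame(sample_id = surv$sample_id, ici_score = score), surv
    )
    oracle <- cutpoint_oracle(score, time, event)
    expect_equal(attr(dc, "cutpoint"), oracle$cut, tolerance = 1e-12)
    expect_equal(abs(attr(dc, "statistic")), oracle$z, tolerance = 1e-8)
  }
})

test_that("minprop 0.5 with even n admits only the median split", {
  score <- c(1, 2, 3, 4, 5, 6)
  surv <- make_survival(c(5, 4, 6, 1, 2, 3), rep(1, 6))
  dc <- dichotomize(
    data.frame(sample_id = surv$sample_id, ici_score = score),
    surv, minprop = 0.5
  )
  expect_equal(attr(dc, "cutpoint"), 3.5)
  expect_equal(sum(dc$group == "HIGH"), 3)
})

test_that("the maximally selected statistic is not significant under the null", {
  # survival independent of score: permutation-corrected p rarely < 0.05
  set.seed(41)
  n_sig <- 0
  n_cohorts <- 10
  for (i in seq_len(n_cohorts)) {
    n <- 60
    score <- rnorm(n)
    surv <- make_survival(rexp(n, 0.3), rbinom(n, 1, 0.7))
    dc <- dichotomize(
      data.frame(sample_id = surv$sample_id, ici_score = score),
      surv, n_perm = 200, seed = 100 + i
    )
    if (attr(dc, "p_perm") < 0.05) n_sig <- n_sig + 1
  }
  expect_lte(n_sig, 1) # >= 90% of null cohorts non-significant
})

test_that("scores separate the planted subtypes end-to-end", {
  co <- uniform_composition_cohort(
    n_samples = 80, n_subtypes = 2, subtype_effect = 2, noise_sd = 0.5,
    n_genes = 600, n_signature_genes = 40, seed = 17
  )
  lg <- log2_transform(co$expression)
  part <- list(signature_a = co$truth$de_gene_sets[[1]],
               signature_b = co$truth$de_gene_sets[[2]])
  sc <- ici_score(lg, part)
  is_s1 <- co$subtype_labels == 1
  # rank-sum AUC of score vs planted subtype
  r <- rank(sc$ici_score)
  auc <- (sum(r[is_s1]) - sum(is_s1) * (sum(is_s1) + 1) / 2) /
    (sum(is_s1) * sum(!is_s1))
  expect_gte(max(auc, 1 - auc), 0.8)
})
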