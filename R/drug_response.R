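#' Fit a ridge expression-to-IC50 model
#'
#' Ridge regression of log IC50 on gene-standardized reference expression,
#' with the penalty chosen by cross-validated mean squared error over a
#' lambda grid. The fold split is deterministic given the seed.
#'
#' @param ref_expr Reference expression, genes x samples (`expr_matrix` or
#'   matrix), sample-matched to `ref_log_ic50`.
#' @param ref_log_ic50 Numeric response (natural-log IC50, log uM).
#' @param lambda_grid Decreasing-sorted penalty grid; `NULL` lets glmnet
#'   build one.
#' @param n_folds Cross-validation folds (reduced with a warning when n <
#'   folds).
#' @param seed Integer seed for the fold split.
#' @param drug_name Label stored on the model.
#' @return A `drug_model` list: `drug_name`, `coefficients` (per training
#'   gene, on the standardized scale), `intercept`, `lambda`,
#'   `training_genes`, `gene_mean`, `gene_sd`, `cv_mse`.
#' @export
fit_drug_model <- function(ref_expr, ref_log_ic50, lambda_grid = NULL,
                           n_folds = 10, seed = 1, drug_name = "drug") {
  m <- as_expr_values(ref_expr)
  n <- ncol(m)
  if (n < 20) stop_arg("need at least 20 reference samples")
  if (length(ref_log_ic50) != n) {
    stop_arg("response must be sample-matched to the expression")
  }
  if (n < n_folds) {
    warning("reducing folds from ", n_folds, " to ", n, call. = FALSE)
    n_folds <- n
  }
  gene_mean <- rowMeans(m)
  gene_sd <- apply(m, 1, stats::sd)
  usable <- gene_sd > 0
  x <- t((m[usable, , drop = FALSE] - gene_mean[usable]) / gene_sd[usable])
  foldid <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  cv <- glmnet::cv.glmnet(x, ref_log_ic50, alpha = 0, lambda = lambda_grid,
                          foldid = foldid, standardize = FALSE)
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))
  structure(
    list(
      drug_name = drug_name,
      coefficients = stats::setNames(beta[-1], colnames(x)),
      intercept = beta[1],
      lambda = cv$lambda.min,
      training_genes = colnames(x),
      gene_mean = gene_mean[usable],
      gene_sd = gene_sd[usable],
      cv_mse = min(cv$cvm)
    ),
    class = "drug_model"
  )
}

#' @export
print.drug_model <- function(x, ...) {
  cat(sprintf("drug_model '%s': %d genes, lambda = %.4g\n",
              x$drug_name, length(x$training_genes), x$lambda))
  invisible(x)
}

#' Predict log IC50 from expression
#'
#' Linear prediction on the model's training genes after applying the
#' training standardization. At least half of the training genes must be
#' present; missing genes are imputed at the training mean (standardized
#' zero), and extra genes in the input are ignored.
#'
#' @param model A [fit_drug_model()] result.
#' @param expr Expression, genes x samples.
#' @return Named numeric vector of predicted log IC50 per sample.
#' @export
predict_ic50 <- function(model, expr) {
  m <- as_expr_values(expr)
  present <- intersect(model$training_genes, rownames(m))
  if (length(present) < 0.5 * length(model$training_genes)) {
    stop_arg("fewer than half of the training genes present (",
             length(present), "/", length(model$training_genes), ")")
  }
  x <- matrix(0, ncol(m), length(model$training_genes),
              dimnames = list(colnames(m), model$training_genes))
  x[, present] <- t((m[present, , drop = FALSE] - model$gene_mean[present]) /
                      model$gene_sd[present])
  drop(model$intercept + x %*% model$coefficients)
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration when both groups have at most 8 observations and there
#' are no ties; otherwise the tie-corrected normal approximation with
#' continuity correction. Two-sided.
#'
#' @param values Numeric vector.
#' @param group_labels Two-level grouping, one per value; both groups need
#'   >= 2 observations.
#' @return List with `w` (rank-sum statistic of the first group) and `p`.
#' @export
wilcoxon_rank_sum <- function(values, group_labels) {
  g <- factor(group_labels)
  if (nlevels(g) != 2) stop_arg("need exactly 2 groups")
  x <- values[g == levels(g)[1]]
  y <- values[g == levels(g)[2]]
  if (length(x) < 2 || length(y) < 2) stop_arg("both groups need >= 2 values")
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- length(x) <= 8 && length(y) <= 8 && !has_ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE,
                       alternative = "two.sided")
  )
  list(w = unname(res$statistic), p = res$p.value)
}
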