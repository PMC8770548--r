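#' Convert FPKM to TPM
#'
#' Rescales each sample so transcript abundances sum to one million:
#' \eqn{TPM_{gj} = FPKM_{gj} / \sum_g FPKM_{gj} \times 10^6}. The
#' transformation is idempotent: applying it to columns that already sum to
#' 1e6 leaves them unchanged.
#'
#' @param expr An `expr_matrix` on FPKM scale.
#' @return An `expr_matrix` on TPM scale; every column sums to 1e6.
#' @export
fpkm_to_tpm <- function(expr) {
  m <- as_expr_values(expr, scale = "FPKM")
  cs <- colSums(m)
  if (any(cs <= 0)) {
    bad <- colnames(m)[cs <= 0]
    stop_arg(
      "all-zero expression for sample(s): ", paste(bad, collapse = ", ")
    )
  }
  out <- sweep(m, 2, cs, "/") * 1e6
  expression_matrix(out, "TPM")
}

#' Log2-transform expression values
#'
#' @param expr An `expr_matrix` on a linear scale (or non-negative matrix).
#' @param pseudocount Added before taking logs; default 1 maps 0 to 0.
#' @return An `expr_matrix` on LOG2 scale.
#' @export
log2_transform <- function(expr, pseudocount = 1) {
  m <- as_expr_values(expr)
  if (any(m < 0)) stop_arg("log2_transform requires non-negative input")
  expression_matrix(log2(m + pseudocount), "LOG2")
}

#' Invert a log2 transform
#'
#' @param expr An `expr_matrix` on LOG2 scale.
#' @param pseudocount The pseudocount used in the forward transform.
#' @param scale Scale to assign to the recovered linear values.
#' @return An `expr_matrix` on the requested linear scale.
#' @export
unlog2_transform <- function(expr, pseudocount = 1, scale = "TPM") {
  m <- as_expr_values(expr, scale = "LOG2")
  expression_matrix(pmax(2^m - pseudocount, 0), scale)
}

#' Empirical-Bayes batch adjustment (ComBat)
#'
#' Removes additive and multiplicative batch effects from log-scale
#' expression by parametric empirical-Bayes shrinkage of per-gene, per-batch
#' location and scale parameters. A single batch is returned unchanged;
#' genes with zero variance cannot be standardized and are passed through
#' unchanged with a warning.
#'
#' @param expr An `expr_matrix` on LOG2 scale.
#' @param batch_labels Factor-like vector of batch ids, one per sample.
#' @param covariates Optional model matrix (or data.frame of factors) of
#'   biological covariates to preserve; default none.
#' @return A batch-adjusted `expr_matrix` on LOG2 scale, same dimensions.
#' @export
combat_adjust <- function(expr, batch_labels, covariates = NULL) {
  m <- as_expr_values(expr, scale = "LOG2")
  if (length(batch_labels) != ncol(m)) {
    stop_arg("batch_labels must have one entry per sample")
  }
  batch <- factor(batch_labels)
  if (nlevels(batch) == 1L) {
    return(expression_matrix(m, "LOG2"))
  }
  sizes <- table(batch)
  if (any(sizes < 2)) {
    stop_arg(
      "batch(es) with a single sample: ",
      paste(names(sizes)[sizes < 2], collapse = ", ")
    )
  }
  v <- apply(m, 1, stats::var)
  flat <- v <= .Machine$double.eps
  if (any(flat)) {
    warning(
      sum(flat), " zero-variance gene(s) passed through unadjusted",
      call. = FALSE
    )
  }
  mod <- NULL
  if (!is.null(covariates)) {
    mod <- stats::model.matrix(~., data = as.data.frame(covariates))
  }
  adj <- m
  keep <- !flat
  if (sum(keep) > 0) {
    fit <- suppressMessages(
      sva::ComBat(dat = m[keep, , drop = FALSE], batch = batch, mod = mod,
                  par.prior = TRUE, prior.plots = FALSE)
    )
    adj[keep, ] <- fit
  }
  expression_matrix(adj, "LOG2")
}

#' Merge two cohorts on shared gene symbols
#'
#' Exact-symbol intersection; duplicate symbols within a cohort are collapsed
#' to the row with the highest mean expression before intersecting.
#'
#' @param a,b Expression matrices (`expr_matrix` or matrix) on the same scale.
#' @return A list with the merged `values` matrix, a `batch` factor, and the
#'   shared `genes`.
#' @export
merge_cohorts <- function(a, b) {
  ma <- collapse_duplicates(as_expr_values(a))
  mb <- collapse_duplicates(as_expr_values(b))
  genes <- intersect(rownames(ma), rownames(mb))
  if (length(genes) == 0) stop_arg("no shared gene symbols between cohorts")
  values <- cbind(ma[genes, , drop = FALSE], mb[genes, , drop = FALSE])
  batch <- factor(rep(c("batch1", "batch2"), c(ncol(ma), ncol(mb))))
  list(values = values, batch = batch, genes = genes)
}

collapse_duplicates <- function(m) {
  if (!anyDuplicated(rownames(m))) return(m)
  means <- rowMeans(m)
  ord <- order(rownames(m), -means)
  m <- m[ord, , drop = FALSE]
  m[!duplicated(rownames(m)), , drop = FALSE]
}
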