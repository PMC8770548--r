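#' Moderated-t differential expression, one-vs-rest per cluster
#'
#' For each cluster, compares its samples against all others with a
#' two-sample t-statistic whose per-gene variance is shrunk by empirical
#' Bayes toward a common prior:
#' \eqn{\tilde s^2_g = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}, with the
#' prior degrees of freedom \eqn{d_0} and prior variance \eqn{s_0^2}
#' estimated by the method of moments on the log pooled variances. P-values
#' use a t distribution on \eqn{d_0 + d_g} df and are BH-adjusted within
#' each contrast. A gene is called differential when `p_adj < alpha` and
#' `|log2 FC| > fc_thresh` ("fold-change > 1" is read on the log2 scale: on
#' the linear scale every gene would pass).
#'
#' @param log_expr LOG2-scale expression, genes x samples.
#' @param cluster_labels Vector of cluster ids, one per sample; every
#'   cluster needs >= 3 samples.
#' @param fc_thresh Absolute log2 fold-change cutoff.
#' @param alpha Adjusted-p cutoff.
#' @param d0 Optional fixed prior degrees of freedom; `NULL` (default)
#'   estimates it. `d0 = 0` gives the ordinary two-sample t.
#' @return data.frame with `gene_id`, `contrast` (cluster id), `log2_fc`,
#'   `t_moderated`, `df`, `p`, `p_adj`, `is_deg`.
#' @export
moderated_t_degs <- function(log_expr, cluster_labels, fc_thresh = 1,
                             alpha = 0.05, d0 = NULL) {
  m <- as_expr_values(log_expr)
  if (length(cluster_labels) != ncol(m)) {
    stop_arg("cluster_labels must have one entry per sample")
  }
  cl <- factor(cluster_labels)
  sizes <- table(cl)
  if (any(sizes < 3)) {
    stop_arg(
      "cluster(s) with fewer than 3 samples: ",
      paste(names(sizes)[sizes < 3], collapse = ", ")
    )
  }
  out <- lapply(levels(cl), function(g) {
    in_g <- cl == g
    n1 <- sum(in_g)
    n2 <- sum(!in_g)
    row_var <- function(x, mu) {
      rowSums((x - mu)^2) / (ncol(x) - 1)
    }
    m1 <- rowMeans(m[, in_g, drop = FALSE])
    m2 <- rowMeans(m[, !in_g, drop = FALSE])
    v1 <- row_var(m[, in_g, drop = FALSE], m1)
    v2 <- row_var(m[, !in_g, drop = FALSE], m2)
    dg <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dg
    prior <- if (is.null(d0)) {
      fit_f_dist(s2, dg)
    } else {
      list(d0 = d0, s0_sq = if (d0 > 0) mean(s2) else NA_real_)
    }
    d0g <- prior$d0
    s2_tilde <- if (is.finite(d0g)) {
      if (d0g > 0) (d0g * prior$s0_sq + dg * s2) / (d0g + dg) else s2
    } else {
      rep(prior$s0_sq, length(s2))
    }
    se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
    tstat <- (m1 - m2) / se
    df_total <- if (is.finite(d0g)) d0g + dg else Inf
    p <- 2 * stats::pt(abs(tstat), df = df_total, lower.tail = FALSE)
    p_adj <- stats::p.adjust(p, method = "BH")
    data.frame(
      gene_id = rownames(m), contrast = g, log2_fc = m1 - m2,
      t_moderated = tstat, df = df_total, p = p, p_adj = p_adj,
      is_deg = p_adj < alpha & abs(m1 - m2) > fc_thresh,
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  do.call(rbind, out)
}

# Method-of-moments fit of the scaled-F prior for gene variances:
# s2_g ~ s0^2 * F(d_g, d0), moments taken on log(s2) (finite at all d0 > 0).
fit_f_dist <- function(s2, dg) {
  ok <- s2 > 0
  if (sum(ok) < 2) return(list(d0 = Inf, s0_sq = mean(s2)))
  e <- log(s2[ok])
  e_mean <- mean(e)
  e_var <- stats::var(e)
  resid_var <- e_var - trigamma(dg / 2)
  if (resid_var <= 0) {
    # no excess dispersion beyond sampling noise: complete shrinkage to the
    # pooled mean variance
    d0 <- Inf
    s0_sq <- mean(s2[ok])
  } else {
    d0 <- 2 * trigamma_inverse(resid_var)
    s0_sq <- exp(e_mean - digamma(dg / 2) + log(dg / 2) +
                   digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton solve of trigamma(y) = x for y > 0 (decreasing convex function).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Union of differential genes over contrasts
#'
#' @param deg_table Output of [moderated_t_degs()].
#' @return Character vector of gene ids flagged in any contrast.
#' @export
deg_union <- function(deg_table) {
  unique(deg_table$gene_id[deg_table$is_deg])
}

#' Consensus clustering of genes
#'
#' Clusters genes (rows) by their expression profiles across samples using
#' the same resampled consensus machinery as the sample clustering, with k
#' defaulting to 2 for the two-signature split.
#'
#' @param log_expr LOG2-scale expression restricted to the genes of
#'   interest (e.g. the DEG union), genes x samples.
#' @param k Number of gene clusters (>= 2).
#' @param n_reps,p_item,seed Passed to [consensus_cluster()].
#' @return Named integer vector of per-gene cluster labels.
#' @export
gene_cluster <- function(log_expr, k = 2, n_reps = 1000, p_item = 0.8,
                         seed = 1) {
  if (k < 2) stop_arg("k must be at least 2")
  m <- as_expr_values(log_expr)
  if (nrow(m) < 2) stop_arg("need at least 2 genes to cluster")
  res <- consensus_cluster(m, k_range = k, n_reps = n_reps, p_item = p_item,
                           seed = seed)
  consensus_labels(res, k)
}

#' Partition differential genes into signatures A and B
#'
#' Given exactly two gene clusters and a two-group sample partition, the
#' gene cluster whose mean expression is higher in the first sample group
#' becomes signature A; the other becomes signature B. Swapping the sample
#' groups swaps the signatures.
#'
#' @param deg_expr LOG2-scale expression of the differential genes, genes x
#'   samples.
#' @param gene_cluster_labels Two-level labels, one per gene.
#' @param sample_cluster_labels Two-level labels, one per sample; the first
#'   factor level anchors signature A.
#' @return A `signature_partition` list: `signature_a`, `signature_b`
#'   (disjoint gene sets) and `gene_cluster_labels`.
#' @export
partition_signatures <- function(deg_expr, gene_cluster_labels,
                                 sample_cluster_labels) {
  m <- as_expr_values(deg_expr)
  gcl <- factor(gene_cluster_labels)
  scl <- factor(sample_cluster_labels)
  if (nlevels(gcl) != 2) stop_arg("need exactly 2 gene clusters")
  if (nlevels(scl) != 2) stop_arg("need exactly 2 sample groups")
  if (length(gcl) != nrow(m)) stop_arg("one gene-cluster label per gene required")
  if (length(scl) != ncol(m)) stop_arg("one sample label per sample required")
  in_a <- scl == levels(scl)[1]
  sig <- list()
  for (g in levels(gcl)) {
    rows <- gcl == g
    delta <- mean(m[rows, in_a, drop = FALSE]) -
      mean(m[rows, !in_a, drop = FALSE])
    key <- if (delta > 0) "signature_a" else "signature_b"
    sig[[key]] <- c(sig[[key]], rownames(m)[rows])
  }
  if (is.null(sig$signature_a) || is.null(sig$signature_b)) {
    stop_arg("both gene clusters track the same sample group; a signature is empty")
  }
  structure(
    list(
      signature_a = sig$signature_a,
      signature_b = sig$signature_b,
      gene_cluster_labels = stats::setNames(as.integer(gcl), rownames(m))
    ),
    class = "signature_partition"
  )
}

#' @export
print.signature_partition <- function(x, ...) {
  cat(sprintf("signature_partition: A = %d genes, B = %d genes\n",
              length(x$signature_a), length(x$signature_b)))
  invisible(x)
}
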