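#' Resampled consensus clustering
#'
#' Repeatedly subsamples items, clusters each subsample by hierarchical
#' clustering (Euclidean distance, Ward linkage), and records for every item
#' pair how often they co-cluster among the runs where both were drawn. The
#' consensus matrix is re-clustered (Ward on `1 - consensus`) for the final
#' labels at each k, and the proportion of ambiguous clustering (PAC) is
#' computed per k for model selection.
#'
#' @param features Numeric matrix, items (samples) in rows, features in
#'   columns.
#' @param k_range Candidate cluster numbers.
#' @param n_reps Number of subsampling repetitions.
#' @param p_item Fraction of items drawn per repetition.
#' @param seed Integer seed; results are deterministic given it.
#' @param pac_lower,pac_upper Consensus-value band counted as ambiguous.
#' @return A `consensus_result` list: `consensus` (per k, item x item in
#'   [0,1]), `labels_by_k`, `chosen_k`, `pac_by_k`, `cdf_by_k`, and the run
#'   parameters.
#' @export
consensus_cluster <- function(features, k_range = 2:6, n_reps = 1000,
                              p_item = 0.8, seed = 1,
                              pac_lower = 0.1, pac_upper = 0.9) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (anyNA(features)) stop_arg("features contain NA")
  if (max(k_range) >= n) stop_arg("max(k_range) must be smaller than the number of items")
  if (n < 2 * max(k_range)) stop_arg("need at least 2 x max(k_range) items")
  ids <- rownames(features) %||% sprintf("item%04d", seq_len(n))
  rownames(features) <- ids

  m_draw <- ceiling(p_item * n)
  co_count <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_count) <- as.character(k_range)
  pair_count <- matrix(0, n, n)

  with_seed(seed, {
    for (rep_i in seq_len(n_reps)) {
      idx <- sort(sample.int(n, m_draw))
      hc <- stats::hclust(stats::dist(features[idx, , drop = FALSE]),
                          method = "ward.D2")
      pair_count[idx, idx] <- pair_count[idx, idx] + 1
      for (k in k_range) {
        lab <- stats::cutree(hc, k = k)
        same <- outer(lab, lab, "==")
        ck <- as.character(k)
        co_count[[ck]][idx, idx] <- co_count[[ck]][idx, idx] + same
      }
    }
  })

  consensus <- lapply(co_count, function(cc) {
    cons <- ifelse(pair_count > 0, cc / pmax(pair_count, 1), 0)
    diag(cons) <- 1
    dimnames(cons) <- list(ids, ids)
    cons
  })

  labels_by_k <- list()
  pac_by_k <- stats::setNames(numeric(length(k_range)), as.character(k_range))
  cdf_by_k <- list()
  for (k in k_range) {
    ck <- as.character(k)
    cons <- consensus[[ck]]
    hc <- stats::hclust(stats::as.dist(1 - cons), method = "ward.D2")
    labels_by_k[[ck]] <- stats::setNames(stats::cutree(hc, k = k), ids)
    off <- cons[upper.tri(cons)]
    pac_by_k[ck] <- mean(off > pac_lower & off < pac_upper)
    cdf_by_k[[ck]] <- stats::ecdf(off)
  }

  res <- structure(
    list(
      consensus = consensus, labels_by_k = labels_by_k,
      pac_by_k = pac_by_k, cdf_by_k = cdf_by_k,
      chosen_k = NA_integer_, k_range = k_range,
      n_reps = n_reps, p_item = p_item, seed = seed
    ),
    class = "consensus_result"
  )
  res$chosen_k <- select_k(res)
  res
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(
    "consensus_result: %d items, k in {%s}, chosen k = %d (PAC %.3f)\n",
    length(x$labels_by_k[[1]]), paste(x$k_range, collapse = ","),
    x$chosen_k, x$pac_by_k[as.character(x$chosen_k)]
  ))
  invisible(x)
}

#' Choose the number of clusters by minimum PAC
#'
#' Returns the k with the smallest proportion of ambiguous clustering;
#' ties break toward the smaller k.
#'
#' @param result A [consensus_cluster()] result.
#' @return Integer k.
#' @export
select_k <- function(result) {
  stopifnot(inherits(result, "consensus_result"))
  pac <- result$pac_by_k
  ks <- as.integer(names(pac))
  ks[which.min(pac)] # which.min returns the first (smallest k) on ties
}

#' Cluster labels at a given k
#'
#' @param result A [consensus_cluster()] result.
#' @param k Cluster number; defaults to the chosen k.
#' @return Named integer vector of labels in `1..k`.
#' @export
consensus_labels <- function(result, k = result$chosen_k) {
  stopifnot(inherits(result, "consensus_result"))
  lab <- result$labels_by_k[[as.character(k)]]
  if (is.null(lab)) stop_arg("k = ", k, " was not in the evaluated range")
  lab
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in [-1, 1]; 1 means identical partitions up to renaming.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_arg("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
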