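#' Boruta-style all-relevant feature selection
#'
#' Iteratively appends "shadow" features (column-wise permuted copies of the
#' remaining candidates), fits a random forest, and scores a hit for every
#' candidate whose permutation importance exceeds the best shadow
#' importance. Features whose hit count is binomially significantly above
#' (below) chance at `alpha` are confirmed (rejected); candidates still
#' undecided after `max_iter` iterations are tentative and excluded from
#' the confirmed set.
#'
#' @param feature_matrix Numeric matrix, observations x features.
#' @param target_labels Class label per observation (>= 2 classes).
#' @param max_iter Maximum Boruta iterations.
#' @param alpha Two-sided binomial significance level.
#' @param seed Integer seed (shadows and forests are seeded).
#' @param num_trees Trees per forest.
#' @return Character vector of confirmed feature names, with attributes
#'   `tentative` and `rejected`.
#' @export
boruta_select <- function(feature_matrix, target_labels, max_iter = 100,
                          alpha = 0.01, seed = 1, num_trees = 300) {
  x <- as.matrix(feature_matrix)
  if (ncol(x) < 5) stop_arg("need at least 5 features")
  if (is.null(colnames(x))) colnames(x) <- rep("", ncol(x))
  blank <- which(!nzchar(colnames(x)))
  colnames(x)[blank] <- sprintf("feat%04d", blank)
  y <- factor(target_labels)
  if (nlevels(y) < 2) stop_arg("target needs at least 2 classes")
  if (length(y) != nrow(x)) stop_arg("one target label per observation required")

  sds <- apply(x, 2, stats::sd)
  constant <- sds <= .Machine$double.eps
  if (any(constant)) {
    warning(sum(constant), " constant feature(s) auto-rejected", call. = FALSE)
  }
  status <- stats::setNames(
    ifelse(constant, "rejected", "undecided"), colnames(x)
  )
  hits <- trials <- stats::setNames(integer(ncol(x)), colnames(x))

  with_seed(seed, {
    for (iter in seq_len(max_iter)) {
      active <- names(status)[status %in% c("undecided", "confirmed")]
      testing <- names(status)[status == "undecided"]
      if (length(testing) == 0) break
      xa <- x[, active, drop = FALSE]
      shadows <- apply(xa, 2, sample)
      colnames(shadows) <- paste0("shadow_", colnames(xa))
      rf <- randomForest::randomForest(
        cbind(xa, shadows), y, ntree = num_trees, importance = TRUE
      )
      imp <- randomForest::importance(rf, type = 1)[, 1]
      shadow_max <- max(imp[paste0("shadow_", colnames(xa))])
      hits[testing] <- hits[testing] +
        as.integer(imp[testing] > shadow_max)
      trials[testing] <- trials[testing] + 1L
      p_hi <- stats::pbinom(hits[testing] - 1L, trials[testing], 0.5,
                            lower.tail = FALSE)
      p_lo <- stats::pbinom(hits[testing], trials[testing], 0.5)
      status[testing[p_hi < alpha]] <- "confirmed"
      status[testing[p_lo < alpha]] <- "rejected"
    }
  })
  confirmed <- names(status)[status == "confirmed"]
  attr(confirmed, "tentative") <- names(status)[status == "undecided"]
  attr(confirmed, "rejected") <- names(status)[status == "rejected"]
  confirmed
}

#' Per-sample immune-infiltration (ICI) score
#'
#' First principal component of the gene-standardized signature-A expression
#' minus that of signature B: `ici_score = pc1_a - pc1_b` per sample. Each
#' component's sign is fixed so it correlates positively with the mean
#' expression of its own signature, making the score orientation
#' reproducible.
#'
#' @param log_expr LOG2-scale expression, genes x samples.
#' @param partition A [partition_signatures()] result (or a list with
#'   `signature_a` / `signature_b` gene sets).
#' @return data.frame with `sample_id`, `pc1_a`, `pc1_b`, `ici_score`.
#' @export
ici_score <- function(log_expr, partition) {
  m <- as_expr_values(log_expr)
  pc1_of <- function(genes, label) {
    genes <- intersect(genes, rownames(m))
    sub <- m[genes, , drop = FALSE]
    sub <- sub[apply(sub, 1, stats::sd) > 0, , drop = FALSE]
    if (nrow(sub) < 2) {
      stop_arg("signature ", label, " has fewer than 2 usable genes")
    }
    pc <- stats::prcomp(t(sub), center = TRUE, scale. = TRUE)
    s <- pc$x[, 1]
    if (stats::cor(s, colMeans(sub)) < 0) s <- -s
    s
  }
  a <- pc1_of(partition$signature_a, "A")
  b <- pc1_of(partition$signature_b, "B")
  data.frame(
    sample_id = colnames(m), pc1_a = unname(a), pc1_b = unname(b),
    ici_score = unname(a - b), stringsAsFactors = FALSE
  )
}

#' Dichotomize a score at the maximally selected log-rank cutpoint
#'
#' Scans every admissible threshold (both sides keep at least `minprop` of
#' the samples) and keeps the one maximizing the absolute standardized
#' log-rank statistic between the resulting groups; ties break toward the
#' lower cutpoint. Optionally estimates a permutation-corrected p-value for
#' the selected statistic by re-maximizing over label permutations.
#'
#' @param scores data.frame with `sample_id` and `ici_score` (e.g. from
#'   [ici_score()]), or a named numeric vector.
#' @param survival data.frame with `sample_id`, `time`, `event`.
#' @param minprop Minimum fraction of samples on each side.
#' @param n_perm Number of permutations for the corrected p-value (0 skips).
#' @param seed Seed for the permutations.
#' @return The scores data.frame with added `group` ("HIGH" iff score >
#'   cutpoint, else "LOW") and attributes `cutpoint`, `statistic` (the
#'   standardized log-rank z at the cutpoint) and, if requested, `p_perm`.
#' @export
dichotomize <- function(scores, survival, minprop = 0.1, n_perm = 0,
                        seed = 1) {
  if (is.numeric(scores)) {
    scores <- data.frame(
      sample_id = names(scores), ici_score = unname(scores),
      stringsAsFactors = FALSE
    )
  }
  idx <- match(scores$sample_id, survival$sample_id)
  if (anyNA(idx)) stop_arg("samples missing from the survival table")
  time <- survival$time[idx]
  event <- survival$event[idx]
  if (sum(event) < 1) stop_arg("need at least one event")
  s <- scores$ici_score

  best <- max_logrank_cutpoint(s, time, event, minprop)
  if (is.null(best)) stop_arg("no admissible cutpoint at minprop = ", minprop)

  out <- scores
  out$group <- ifelse(s > best$cutpoint, "HIGH", "LOW")
  attr(out, "cutpoint") <- best$cutpoint
  attr(out, "statistic") <- best$statistic
  if (n_perm > 0) {
    obs <- abs(best$statistic)
    null_stat <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        b <- max_logrank_cutpoint(sample(s), time, event, minprop)
        if (is.null(b)) 0 else abs(b$statistic)
      }, numeric(1))
    })
    attr(out, "p_perm") <- (1 + sum(null_stat >= obs)) / (1 + n_perm)
  }
  out
}

# Scan admissible midpoints for the standardized log-rank maximum.
max_logrank_cutpoint <- function(s, time, event, minprop) {
  n <- length(s)
  vals <- sort(unique(s))
  if (length(vals) < 2) return(NULL)
  mids <- (vals[-1] + vals[-length(vals)]) / 2
  lo <- ceiling(minprop * n)
  admissible <- vapply(mids, function(ct) {
    k <- sum(s <= ct)
    k >= lo && (n - k) >= lo
  }, logical(1))
  mids <- mids[admissible]
  if (length(mids) == 0) return(NULL)
  best_z <- NA_real_
  best_ct <- NA_real_
  for (ct in mids) {
    z <- logrank_z(s > ct, time, event)
    if (is.finite(z) && (is.na(best_z) || abs(z) > abs(best_z) + 1e-12)) {
      best_z <- z
      best_ct <- ct
    }
  }
  if (is.na(best_z)) return(NULL)
  list(cutpoint = best_ct, statistic = best_z)
}

# Standardized two-group log-rank statistic (O - E) / sqrt(V) for group 1.
logrank_z <- function(in_g1, time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; g1 <- in_g1[ord]
  ev_times <- unique(time[event == 1])
  o_minus_e <- 0
  v <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n_t)
    if (n_t > 1) {
      v <- v + d * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d) / (n_t - 1)
    }
  }
  if (v <= 0) return(NA_real_)
  o_minus_e / sqrt(v)
}
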