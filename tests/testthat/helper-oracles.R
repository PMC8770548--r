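# Independent oracles used to freeze expected values. Each deliberately
# takes a different computational route from the implementation it checks.

# Direct double-loop ssGSEA running statistic.
ssgsea_oracle <- function(values, gene_set, alpha = 0.25) {
  r <- rank(values, ties.method = "average")
  ord <- order(r, decreasing = TRUE)
  in_set <- names(values)[ord] %in% gene_set
  w <- r[ord]^alpha
  denom_in <- sum(w[in_set])
  total <- 0
  for (i in seq_along(ord)) {
    p_in <- sum(w[seq_len(i)][in_set[seq_len(i)]]) / denom_in
    p_out <- sum(!in_set[seq_len(i)]) / sum(!in_set)
    total <- total + (p_in - p_out)
  }
  total
}

# Exhaustive running-sum GSEA enrichment score.
gsea_es_oracle <- function(scores, set, weight = 0) {
  ord <- order(scores, decreasing = TRUE)
  genes <- names(scores)[ord]
  s <- abs(scores[ord])^weight
  in_set <- genes %in% set
  n <- length(genes)
  m <- sum(in_set)
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    run <- run + if (in_set[i]) s[i] / sum(s[in_set]) else -1 / (n - m)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Brute-force maximally selected log-rank cutpoint via survival::survdiff:
# a different log-rank implementation from the package's internal scan.
cutpoint_oracle <- function(score, time, event, minprop = 0.1) {
  n <- length(score)
  vals <- sort(unique(score))
  mids <- (vals[-1] + vals[-length(vals)]) / 2
  lo <- ceiling(minprop * n)
  best <- NULL
  for (ct in mids) {
    k <- sum(score <= ct)
    if (k < lo || (n - k) < lo) next
    g <- factor(score > ct)
    if (nlevels(g) < 2) next
    sd <- try(survival::survdiff(survival::Surv(time, event) ~ g),
              silent = TRUE)
    if (inherits(sd, "try-error")) next
    z <- sqrt(sd$chisq)
    if (!is.finite(z)) next
    if (is.null(best) || z > best$z + 1e-12) best <- list(cut = ct, z = z)
  }
  best
}

# Permutation-null log-rank p for two groups.
logrank_perm_oracle <- function(time, event, group, n_perm = 10000,
                                seed = 99) {
  obs <- survival::survdiff(survival::Surv(time, event) ~ group)$chisq
  set.seed(seed)
  null <- replicate(n_perm, {
    survival::survdiff(
      survival::Surv(time, event) ~ sample(group)
    )$chisq
  })
  mean(null >= obs - 1e-12)
}

# Resampling estimate of the hypergeometric upper-tail probability.
ora_resampling_oracle <- function(universe, set, query_size, observed,
                                  n_draw = 10000, seed = 7) {
  set.seed(seed)
  mean(replicate(n_draw, {
    draw <- sample(universe, query_size)
    sum(draw %in% set) >= observed
  }))
}
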