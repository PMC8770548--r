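#' Build an LM22-like cell-type signature matrix
#'
#' Constructs a non-negative reference profile matrix in which each cell type
#' owns a disjoint block of marker genes with strongly elevated mean
#' expression over a common background, mimicking the structure of purified
#' leukocyte signature matrices used for deconvolution.
#'
#' @param n_genes Number of signature genes (rows); must be at least
#'   `10 * n_celltypes` so every type gets >= 10 markers.
#' @param n_celltypes Number of cell types (columns).
#' @param seed Integer seed; the matrix is deterministic given the seed.
#' @param marker_fold Mean elevation of marker genes over background.
#' @return Numeric matrix `n_genes x n_celltypes` with rownames
#'   `SIG0001...` and colnames `CellType01...`.
#' @export
make_signature_matrix <- function(n_genes, n_celltypes, seed = 1,
                                  marker_fold = 8) {
  if (n_genes <= 0 || n_celltypes <= 0) {
    stop_arg("n_genes and n_celltypes must be positive")
  }
  if (n_genes < 10 * n_celltypes) {
    stop_arg("need n_genes >= 10 * n_celltypes for >=10 markers per type")
  }
  with_seed(seed, {
    background <- 20
    m <- matrix(
      stats::runif(n_genes * n_celltypes, 0.5 * background, 1.5 * background),
      nrow = n_genes, ncol = n_celltypes
    )
    block <- n_genes %/% n_celltypes
    for (k in seq_len(n_celltypes)) {
      rows <- ((k - 1) * block + 1):(k * block)
      m[rows, k] <- stats::runif(
        length(rows), marker_fold * background, 1.5 * marker_fold * background
      )
    }
    dimnames(m) <- list(
      sprintf("SIG%04d", seq_len(n_genes)),
      sprintf("CellType%02d", seq_len(n_celltypes))
    )
    m
  })
}

#' Simulation configuration
#'
#' Collects the planted parameters of a synthetic cohort. The defaults
#' emulate a two-cohort gastric-cancer meta-analysis: 854 samples in two
#' batches (407 + 447), three expression subtypes with distinct immune-cell
#' mixing priors and survival hazards, 252 subtype-signature genes, and
#' mutation counts negatively rank-correlated (rho = -0.52) with the planted
#' risk score.
#'
#' @param n_genes Total genes simulated (signature genes first).
#' @param n_celltypes Cell types in the mixing model.
#' @param n_samples Cohort size.
#' @param n_subtypes Number of planted expression subtypes.
#' @param subtype_effect Log2-scale mean shift of subtype-specific genes.
#' @param n_signature_genes Subtype-specific differential genes per subtype.
#' @param noise_sd Gaussian noise SD on the log2 scale (log-normal noise on
#'   the linear scale).
#' @param dirichlet_alpha Matrix (`n_subtypes x n_celltypes`) of Dirichlet
#'   mixing priors, or `NULL` for an automatic subtype-skewed default.
#' @param baseline_hazard Baseline event hazard (events per year).
#' @param subtype_log_hazard Per-subtype log-hazard offsets.
#' @param censor_rate Expected fraction of censored samples in `[0, 1]`.
#' @param tmb_score_rho Target Spearman correlation between the planted risk
#'   score and the non-silent mutation count.
#' @param mean_mutations Mean non-silent mutation count per sample.
#' @param batch_sizes Integer vector of per-batch sample counts (must sum to
#'   `n_samples`); `NULL` for a single batch split 407/447-style.
#' @param batch_additive,batch_multiplicative Per-batch location/scale batch
#'   effects applied on the log2 scale.
#' @param seed Global seed; all sub-generators draw from it via
#'   [spawn_seed()].
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_genes = 500,
                              n_celltypes = 22,
                              n_samples = 854,
                              n_subtypes = 3,
                              subtype_effect = 2,
                              n_signature_genes = 84,
                              noise_sd = 0.5,
                              dirichlet_alpha = NULL,
                              baseline_hazard = 0.154,
                              subtype_log_hazard = c(0.2, 0.1, -0.3),
                              censor_rate = 0.6,
                              tmb_score_rho = -0.52,
                              mean_mutations = 80,
                              batch_sizes = NULL,
                              batch_additive = c(0, 0),
                              batch_multiplicative = c(1, 1),
                              seed = 1) {
  if (n_genes <= 0 || n_celltypes <= 0 || n_samples <= 0 || n_subtypes <= 0) {
    stop_arg("all counts must be positive")
  }
  if (censor_rate < 0 || censor_rate > 1) stop_arg("censor_rate must be in [0, 1]")
  if (abs(tmb_score_rho) > 1) stop_arg("tmb_score_rho must be in [-1, 1]")
  if (length(subtype_log_hazard) != n_subtypes) {
    stop_arg("subtype_log_hazard needs one entry per subtype")
  }
  if (is.null(dirichlet_alpha)) {
    dirichlet_alpha <- matrix(1, n_subtypes, n_celltypes)
    # each subtype favors a disjoint band of cell types
    band <- max(1L, n_celltypes %/% n_subtypes)
    for (s in seq_len(n_subtypes)) {
      cols <- ((s - 1) * band + 1):min(s * band, n_celltypes)
      dirichlet_alpha[s, cols] <- 4
    }
  }
  dirichlet_alpha <- as.matrix(dirichlet_alpha)
  if (any(dirichlet_alpha <= 0)) stop_arg("dirichlet_alpha must be strictly positive")
  if (!all(dim(dirichlet_alpha) == c(n_subtypes, n_celltypes))) {
    stop_arg("dirichlet_alpha must be n_subtypes x n_celltypes")
  }
  if (is.null(batch_sizes)) {
    batch_sizes <- if (n_samples >= 20) {
      first <- round(n_samples * 407 / 854)
      c(first, n_samples - first)
    } else {
      n_samples
    }
  }
  if (sum(batch_sizes) != n_samples) stop_arg("batch_sizes must sum to n_samples")
  n_batches <- length(batch_sizes)
  batch_additive <- rep_len(batch_additive, n_batches)
  batch_multiplicative <- rep_len(batch_multiplicative, n_batches)
  structure(
    list(
      n_genes = n_genes, n_celltypes = n_celltypes, n_samples = n_samples,
      n_subtypes = n_subtypes, subtype_effect = subtype_effect,
      n_signature_genes = n_signature_genes, noise_sd = noise_sd,
      dirichlet_alpha = dirichlet_alpha, baseline_hazard = baseline_hazard,
      subtype_log_hazard = subtype_log_hazard, censor_rate = censor_rate,
      tmb_score_rho = tmb_score_rho, mean_mutations = mean_mutations,
      batch_sizes = batch_sizes, batch_additive = batch_additive,
      batch_multiplicative = batch_multiplicative, seed = seed
    ),
    class = "sim_config"
  )
}

rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a synthetic tumor cohort
#'
#' Generates a cohort with the statistical structure the downstream analysis
#' assumes: bulk expression as linear mixtures of cell-type signature
#' profiles plus subtype-specific log2 shifts, batch effects and log-normal
#' noise; Dirichlet cell fractions per planted subtype; exponential survival
#' with subtype-dependent hazard and exponential censoring; and per-sample
#' non-silent mutation counts coupled to the planted risk score through a
#' Gaussian copula so their Spearman correlation approximates
#' `tmb_score_rho`.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_cohort` list: `expression` (linear-scale
#'   `expr_matrix`), `true_fractions` (samples x cell types), the
#'   `signature_matrix`, `subtype_labels`, `survival` (sample_id, time,
#'   event), `maf` (long-format mutation records), `batch_labels`, and
#'   `truth` (all planted parameters, per-subtype signature gene sets,
#'   per-sample risk score and mutation counts).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  sig <- make_signature_matrix(
    min(cfg$n_genes, 10 * cfg$n_celltypes * 2),
    cfg$n_celltypes,
    seed = spawn_seed(cfg$seed, 1)
  )
  n_sig_genes <- nrow(sig)
  n_extra <- cfg$n_genes - n_sig_genes
  if (n_extra < cfg$n_subtypes * cfg$n_signature_genes) {
    stop_arg(
      "n_genes too small: need >= ", n_sig_genes + cfg$n_subtypes *
        cfg$n_signature_genes, " genes for the requested signature structure"
    )
  }
  samples <- sprintf("S%04d", seq_len(cfg$n_samples))
  gene_names <- c(rownames(sig), sprintf("GENE%04d", seq_len(n_extra)))

  subtype <- with_seed(
    spawn_seed(cfg$seed, 2),
    sample(rep_len(seq_len(cfg$n_subtypes), cfg$n_samples))
  )
  fractions <- with_seed(spawn_seed(cfg$seed, 3), {
    t(vapply(
      subtype,
      function(s) rdirichlet_one(cfg$dirichlet_alpha[s, ]),
      numeric(cfg$n_celltypes)
    ))
  })
  dimnames(fractions) <- list(samples, colnames(sig))

  # mixture part: signature genes are pure linear mixtures
  mixed <- sig %*% t(fractions)

  # subtype-specific genes ride on a lognormal baseline
  de_sets <- list()
  log2_expr <- with_seed(spawn_seed(cfg$seed, 4), {
    base_mean <- stats::runif(n_extra, 3, 8)
    extra <- matrix(
      rep(base_mean, cfg$n_samples),
      nrow = n_extra, ncol = cfg$n_samples
    )
    for (s in seq_len(cfg$n_subtypes)) {
      rows <- ((s - 1) * cfg$n_signature_genes + 1):(s * cfg$n_signature_genes)
      de_sets[[s]] <- gene_names[n_sig_genes + rows]
      extra[rows, subtype == s] <- extra[rows, subtype == s] + cfg$subtype_effect
    }
    rbind(log2(mixed + 1), extra)
  })
  names(de_sets) <- sprintf("SUBTYPE%d_UP", seq_len(cfg$n_subtypes))

  batch <- rep(seq_along(cfg$batch_sizes), cfg$batch_sizes)
  log2_expr <- sweep(log2_expr, 2, cfg$batch_multiplicative[batch], "*")
  log2_expr <- sweep(log2_expr, 2, cfg$batch_additive[batch], "+")

  if (cfg$noise_sd > 0) {
    log2_expr <- log2_expr + with_seed(
      spawn_seed(cfg$seed, 5),
      matrix(stats::rnorm(length(log2_expr), 0, cfg$noise_sd),
             nrow = nrow(log2_expr))
    )
  }
  expr <- pmax(2^log2_expr - 1, 0)
  dimnames(expr) <- list(gene_names, samples)

  # survival: exponential event times, exponential censoring tuned so that
  # P(censored) = censor_rate for every sample
  risk <- with_seed(
    spawn_seed(cfg$seed, 6),
    cfg$subtype_log_hazard[subtype] + stats::rnorm(cfg$n_samples, 0, 0.05)
  )
  hazard <- cfg$baseline_hazard * exp(risk)
  surv <- with_seed(spawn_seed(cfg$seed, 7), {
    event_time <- stats::rexp(cfg$n_samples, rate = hazard)
    if (cfg$censor_rate > 0) {
      crate <- hazard * cfg$censor_rate / (1 - cfg$censor_rate)
      cens_time <- stats::rexp(cfg$n_samples, rate = crate)
    } else {
      cens_time <- rep(Inf, cfg$n_samples)
    }
    data.frame(
      sample_id = samples,
      time = pmax(pmin(event_time, cens_time), 1e-6),
      event = as.integer(event_time <= cens_time),
      stringsAsFactors = FALSE
    )
  })

  # mutation counts: Gaussian copula against the planted risk score
  rho <- cfg$tmb_score_rho
  if (abs(rho) > 0.95 && cfg$n_samples < 30) {
    warning("extreme tmb_score_rho with tiny n: best-effort coupling",
            call. = FALSE)
  }
  counts <- with_seed(spawn_seed(cfg$seed, 8), {
    # Gaussian-copula latent correlation giving Spearman rho between two
    # Gaussians: rho_s = (6/pi) asin(rho_g / 2), inverted here
    rho_g <- 2 * sin(pi * rho / 6)
    z1 <- as.numeric(scale(risk + stats::rnorm(cfg$n_samples, 0, 1e-6)))
    z2 <- rho_g * z1 + sqrt(max(0, 1 - rho_g^2)) * stats::rnorm(cfg$n_samples)
    stats::qpois(stats::pnorm(z2), lambda = cfg$mean_mutations)
  })
  maf <- with_seed(spawn_seed(cfg$seed, 9), {
    pool <- sprintf("MUT%03d", seq_len(60))
    weight <- 1 / seq_along(pool) # head-heavy gene frequencies
    recs <- lapply(seq_len(cfg$n_samples), function(i) {
      n_mut <- counts[i]
      n_sil <- stats::rpois(1, 0.1 * cfg$mean_mutations)
      if (n_mut + n_sil == 0) return(NULL)
      data.frame(
        Hugo_Symbol = sample(pool, n_mut + n_sil, replace = TRUE, prob = weight),
        Tumor_Sample_Barcode = samples[i],
        Variant_Classification = c(
          sample(c("Missense_Mutation", "Nonsense_Mutation",
                   "Frame_Shift_Del", "In_Frame_Del"),
                 n_mut, replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1)),
          rep("Silent", n_sil)
        ),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, recs)
  })

  structure(
    list(
      expression = expression_matrix(expr, "TPM"),
      true_fractions = fractions,
      signature_matrix = sig,
      subtype_labels = stats::setNames(subtype, samples),
      survival = surv,
      maf = maf,
      batch_labels = stats::setNames(batch, samples),
      truth = list(
        config = cfg,
        risk_score = stats::setNames(risk, samples),
        hazard = stats::setNames(hazard, samples),
        mutation_counts = stats::setNames(counts, samples),
        de_gene_sets = de_sets
      )
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d genes x %d samples, %d subtypes, %d batches\n",
    nrow(x$expression$values), ncol(x$expression$values),
    x$truth$config$n_subtypes, length(unique(x$batch_labels))
  ))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits `expression.tsv`, `fractions.tsv`, `survival.tsv`, `cohort.maf`
#' (minimal MAF v2.4 columns), `sets.gmt` (the planted subtype gene sets),
#' and `truth.json`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  frac <- data.frame(sample_id = rownames(cohort$true_fractions),
                     cohort$true_fractions, check.names = FALSE)
  utils::write.table(frac, file.path(dir, "fractions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$survival, file.path(dir, "survival.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$maf, file.path(dir, "cohort.maf"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(cohort$truth$de_gene_sets, file.path(dir, "sets.gmt"))
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  truth$config$dirichlet_alpha <- as.vector(truth$config$dirichlet_alpha)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
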