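#' Default pipeline parameters
#'
#' Returns the per-stage parameter defaults of [run_pipeline()]: deconvolution
#' permutations (1000), consensus-clustering repetitions (1000) and item
#' fraction (0.8), the ICI-cluster count (3) and gene-cluster count (2),
#' moderated-t cutoffs (|log2 FC| > 1, adjusted p < 0.05), Boruta iterations,
#' cutpoint minprop (0.1), TMB capture size (38 Mb), ROC evaluation times
#' (1/3/5 years), and GSEA permutations. Any element can be overridden via
#' the config's `params` block.
#'
#' @return Named list of parameter defaults.
#' @export
pipeline_defaults <- function() {
  list(
    deconvolve = list(n_perm = 1000),
    cluster = list(k_range = 2:6, n_reps = 1000, p_item = 0.8, k_ici = 3),
    degs = list(fc_thresh = 1, alpha = 0.05),
    gene_cluster = list(k = 2, n_reps = 1000, p_item = 0.8),
    boruta = list(enabled = TRUE, max_iter = 50, alpha = 0.01,
                  num_trees = 200),
    cutpoint = list(minprop = 0.1),
    tmb = list(capture_mb = 38),
    roc = list(eval_times = c(1, 3, 5)),
    gsea = list(n_perm = 1000, weight = 1, min_size = 5)
  )
}

merge_params <- function(defaults, override) {
  for (stage in names(override)) {
    for (key in names(override[[stage]])) {
      defaults[[stage]][[key]] <- override[[stage]][[key]]
    }
  }
  defaults
}

#' Run the full ICI landscape pipeline
#'
#' Executes the workflow end to end on a simulated or user-supplied cohort:
#' preprocessing (log2 + batch adjustment), immune deconvolution and
#' microenvironment scores, consensus clustering into ICI subtypes,
#' differential expression and signature partitioning, Boruta reduction and
#' ICI scoring with a survival-optimal cutpoint, survival analyses
#' (Kaplan-Meier, log-rank, time-dependent AUC), TMB association and
#' mutation contrasts, preranked GSEA/ORA, and drug-sensitivity prediction.
#' Every stage writes plain-text artifacts under `output_dir` and is
#' recorded with an md5 checksum in `manifest.json`; reruns with the same
#' config and seed are bit-identical.
#'
#' @param config A named list or path to a YAML file. Required: `seed` and
#'   either a `simulate` block (arguments to [simulation_config()]) or an
#'   `inputs` block with file paths (`expression`, `signature_matrix`,
#'   `survival`, `maf`, `sets_gmt`, `batch`). Optional: `params` overriding
#'   [pipeline_defaults()], and `stages` (subset to run, in pipeline order).
#' @param output_dir Artifact directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, output_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) stop_arg("config validation: `seed` is required")
  seed <- as.integer(config$seed)
  all_stages <- c("simulate", "preprocess", "infiltration", "clustering",
                  "diffexp", "scoring", "survival", "mutation", "enrichment",
                  "drug_response")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) stop_arg("config validation: unknown stage(s): ",
                                paste(bad, collapse = ", "))
  simulate_mode <- !is.null(config$simulate) || is.null(config$inputs)
  if (!simulate_mode) {
    need <- c("expression", "signature_matrix", "survival")
    if ("mutation" %in% stages) need <- c(need, "maf")
    if ("enrichment" %in% stages) need <- c(need, "sets_gmt")
    for (key in need) {
      path <- config$inputs[[key]]
      if (is.null(path) || !file.exists(path)) {
        stop_arg("config validation: missing input file for `", key, "`")
      }
    }
  }
  params <- merge_params(pipeline_defaults(), config$params %||% list())
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    seed = seed, stages = list(), params = params,
    started = "run"
  )
  results <- list()
  emit <- function(stage, name, writer) {
    path <- file.path(output_dir, name)
    writer(path)
    manifest$stages[[stage]]$files[[name]] <<-
      unname(tools::md5sum(path))
    path
  }
  run_stage <- function(stage, fun) {
    if (!(stage %in% stages)) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e) {
      stop_arg("stage `", stage, "` failed: ", conditionMessage(e))
    })
    manifest$stages[[stage]]$complete <<- TRUE
    results[[stage]] <<- res
    res
  }

  # --- simulate / load ------------------------------------------------------
  cohort <- run_stage("simulate", function() {
    if (simulate_mode) {
      sim_args <- config$simulate %||% list()
      sim_args$seed <- sim_args$seed %||% spawn_seed(seed, 101)
      co <- simulate_cohort(do.call(simulation_config, sim_args))
      write_cohort(co, file.path(output_dir, "cohort"))
      for (f in list.files(file.path(output_dir, "cohort"))) {
        manifest$stages[["simulate"]]$files[[file.path("cohort", f)]] <<-
          unname(tools::md5sum(file.path(output_dir, "cohort", f)))
      }
      co
    } else {
      inp <- config$inputs
      sig_tab <- utils::read.delim(inp$signature_matrix, check.names = FALSE)
      sig <- as.matrix(sig_tab[, -1]); rownames(sig) <- sig_tab[[1]]
      list(
        expression = read_expression_tsv(inp$expression,
                                         scale = inp$scale %||% "TPM"),
        signature_matrix = sig,
        survival = read_survival_tsv(inp$survival),
        maf = if (!is.null(inp$maf)) read_maf(inp$maf) else NULL,
        sets = if (!is.null(inp$sets_gmt)) read_gmt(inp$sets_gmt) else NULL,
        batch_labels = if (!is.null(inp$batch)) {
          b <- utils::read.delim(inp$batch, stringsAsFactors = FALSE)
          stats::setNames(b[[2]], b[[1]])
        } else NULL
      )
    }
  })
  if (is.null(cohort)) stop_arg("the `simulate` stage cannot be skipped")
  sets <- if (inherits(cohort, "synthetic_cohort")) {
    cohort$truth$de_gene_sets
  } else {
    cohort$sets
  }

  # --- preprocess -----------------------------------------------------------
  log_expr <- run_stage("preprocess", function() {
    lg <- log2_transform(cohort$expression)
    if (!is.null(cohort$batch_labels) &&
        length(unique(cohort$batch_labels)) > 1) {
      lg <- combat_adjust(lg, cohort$batch_labels)
    }
    emit("preprocess", "log2_expression.tsv",
         function(p) write_expression_tsv(lg, p))
    lg
  })
  if (is.null(log_expr)) log_expr <- log2_transform(cohort$expression)

  # --- infiltration ---------------------------------------------------------
  infil <- run_stage("infiltration", function() {
    fr <- deconvolve(cohort$expression, cohort$signature_matrix,
                     n_perm = params$deconvolve$n_perm,
                     seed = spawn_seed(seed, 102))
    emit("infiltration", "fractions.tsv", function(p) {
      utils::write.table(
        data.frame(sample_id = rownames(fr$fractions), fr$fractions,
                   p_value = fr$p_value, rmse = fr$rmse, corr = fr$corr,
                   check.names = FALSE),
        p, sep = "\t", quote = FALSE, row.names = FALSE
      )
    })
    tme <- NULL
    if (length(sets) >= 2) {
      tme <- estimate_scores(log_expr, sets[[1]], sets[[2]])
      emit("infiltration", "tme_scores.tsv", function(p) {
        utils::write.table(tme, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      })
    }
    list(fractions = fr, tme = tme)
  })

  # --- clustering -----------------------------------------------------------
  clus <- run_stage("clustering", function() {
    if (is.null(infil)) stop("requires the infiltration stage")
    cc <- consensus_cluster(
      infil$fractions$fractions, k_range = params$cluster$k_range,
      n_reps = params$cluster$n_reps, p_item = params$cluster$p_item,
      seed = spawn_seed(seed, 103)
    )
    labels <- consensus_labels(cc, params$cluster$k_ici)
    emit("clustering", "ici_clusters.tsv", function(p) {
      utils::write.table(
        data.frame(sample_id = names(labels), ici_cluster = labels),
        p, sep = "\t", quote = FALSE, row.names = FALSE
      )
    })
    emit("clustering", "pac_by_k.tsv", function(p) {
      utils::write.table(
        data.frame(k = names(cc$pac_by_k), pac = cc$pac_by_k),
        p, sep = "\t", quote = FALSE, row.names = FALSE
      )
    })
    list(result = cc, labels = labels)
  })

  # --- diffexp --------------------------------------------------------------
  sigpart <- run_stage("diffexp", function() {
    if (is.null(clus)) stop("requires the clustering stage")
    degs <- moderated_t_degs(log_expr, clus$labels,
                             fc_thresh = params$degs$fc_thresh,
                             alpha = params$degs$alpha)
    emit("diffexp", "degs.tsv", function(p) {
      utils::write.table(degs, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
    deg_genes <- deg_union(degs)
    if (length(deg_genes) < 4) stop("fewer than 4 differential genes")
    deg_expr <- log_expr$values[deg_genes, , drop = FALSE]
    gcl <- gene_cluster(deg_expr, k = params$gene_cluster$k,
                        n_reps = params$gene_cluster$n_reps,
                        p_item = params$gene_cluster$p_item,
                        seed = spawn_seed(seed, 104))
    scc <- consensus_cluster(t(deg_expr), k_range = 2,
                             n_reps = params$gene_cluster$n_reps,
                             p_item = params$gene_cluster$p_item,
                             seed = spawn_seed(seed, 105))
    sample_gcl <- consensus_labels(scc, 2)
    part <- partition_signatures(deg_expr, gcl, sample_gcl)
    emit("diffexp", "signatures.gmt", function(p) {
      write_gmt(list(ICI_SIGNATURE_A = part$signature_a,
                     ICI_SIGNATURE_B = part$signature_b), p)
    })
    list(degs = degs, partition = part, sample_gene_clusters = sample_gcl)
  })

  # --- scoring --------------------------------------------------------------
  scoring <- run_stage("scoring", function() {
    if (is.null(sigpart)) stop("requires the diffexp stage")
    part <- sigpart$partition
    if (isTRUE(params$boruta$enabled)) {
      deg_genes <- c(part$signature_a, part$signature_b)
      confirmed <- boruta_select(
        t(log_expr$values[deg_genes, , drop = FALSE]),
        sigpart$sample_gene_clusters,
        max_iter = params$boruta$max_iter, alpha = params$boruta$alpha,
        num_trees = params$boruta$num_trees, seed = spawn_seed(seed, 106)
      )
      a <- intersect(part$signature_a, confirmed)
      b <- intersect(part$signature_b, confirmed)
      if (length(a) >= 2 && length(b) >= 2) {
        part <- list(signature_a = a, signature_b = b)
      }
    }
    sc <- ici_score(log_expr, part)
    sc <- dichotomize(sc, cohort$survival,
                      minprop = params$cutpoint$minprop)
    emit("scoring", "ici_scores.tsv", function(p) {
      utils::write.table(sc, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
    list(scores = sc, cutpoint = attr(sc, "cutpoint"),
         signatures_used = part)
  })

  # --- survival -------------------------------------------------------------
  surv_res <- run_stage("survival", function() {
    if (is.null(scoring)) stop("requires the scoring stage")
    sc <- scoring$scores
    idx <- match(sc$sample_id, cohort$survival$sample_id)
    surv <- cohort$survival[idx, , drop = FALSE]
    lr_score <- logrank_test(surv, sc$group)
    auc <- time_dependent_auc(sc$ici_score, surv,
                              eval_times = params$roc$eval_times)
    km_high <- km_estimate(surv[sc$group == "HIGH", , drop = FALSE])
    km_low <- km_estimate(surv[sc$group == "LOW", , drop = FALSE])
    emit("survival", "score_group_km.tsv", function(p) {
      utils::write.table(
        rbind(cbind(group = "HIGH", km_high), cbind(group = "LOW", km_low)),
        p, sep = "\t", quote = FALSE, row.names = FALSE
      )
    })
    emit("survival", "time_dependent_auc.tsv", function(p) {
      utils::write.table(
        data.frame(time = params$roc$eval_times, auc = unname(auc)),
        p, sep = "\t", quote = FALSE, row.names = FALSE
      )
    })
    list(logrank = lr_score, auc = auc)
  })

  # --- mutation -------------------------------------------------------------
  mut_res <- run_stage("mutation", function() {
    if (is.null(scoring)) stop("requires the scoring stage")
    if (is.null(cohort$maf)) stop("no MAF available")
    sc <- scoring$scores
    tmb <- compute_tmb(cohort$maf, samples = sc$sample_id,
                       capture_mb = params$tmb$capture_mb)
    rho <- spearman_corr(sc$ici_score, tmb$n_nonsilent)
    # tiny deterministic jitter so tied counts admit a cutpoint scan
    tmb_vals <- tmb$n_nonsilent + seq_along(tmb$sample_id) * 1e-9
    tmb_groups <- dichotomize(
      stats::setNames(tmb_vals, tmb$sample_id),
      cohort$survival, minprop = params$cutpoint$minprop
    )
    idx <- match(sc$sample_id, cohort$survival$sample_id)
    strat <- stratified_km(cohort$survival[idx, , drop = FALSE],
                           tmb_groups$group, sc$group)
    contrast <- gene_freq_contrast(
      cohort$maf, stats::setNames(sc$group, sc$sample_id)
    )
    emit("mutation", "tmb.tsv", function(p) {
      utils::write.table(tmb, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
    emit("mutation", "mutation_contrast.tsv", function(p) {
      utils::write.table(contrast, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
    list(tmb = tmb, spearman = rho, stratified = strat,
         contrast = contrast)
  })

  # --- enrichment -----------------------------------------------------------
  enr_res <- run_stage("enrichment", function() {
    if (is.null(scoring)) stop("requires the scoring stage")
    if (is.null(sets)) stop("no gene sets available")
    sc <- scoring$scores
    ranking <- apply(log_expr$values, 1, function(v) {
      if (stats::sd(v) == 0) return(0)
      stats::cor(rank(v), rank(sc$ici_score))
    })
    gsea <- gsea_preranked(ranking, sets, weight = params$gsea$weight,
                           n_perm = params$gsea$n_perm,
                           min_size = params$gsea$min_size,
                           seed = spawn_seed(seed, 107))
    ora <- ora_hypergeometric(deg_union(sigpart$degs),
                              rownames(log_expr$values), sets)
    emit("enrichment", "gsea.tsv", function(p) {
      utils::write.table(gsea, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
    emit("enrichment", "ora.tsv", function(p) {
      utils::write.table(ora, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
    list(gsea = gsea, ora = ora)
  })

  # --- drug response --------------------------------------------------------
  drug_res <- run_stage("drug_response", function() {
    if (is.null(scoring)) stop("requires the scoring stage")
    sc <- scoring$scores
    # synthetic reference cohort: linear response in a random gene subset
    ref <- with_seed(spawn_seed(seed, 108), {
      genes <- rownames(log_expr$values)
      n_ref <- 100
      x <- matrix(stats::rnorm(length(genes) * n_ref, 5, 1),
                  nrow = length(genes),
                  dimnames = list(genes, sprintf("REF%03d", seq_len(n_ref))))
      beta <- stats::setNames(numeric(length(genes)), genes)
      beta[sample(genes, 25)] <- stats::rnorm(25, 0, 0.5)
      y <- drop(t(x) %*% beta) + stats::rnorm(n_ref, 0, 0.5)
      list(x = x, y = y)
    })
    model <- fit_drug_model(ref$x, ref$y, n_folds = 5,
                            seed = spawn_seed(seed, 109))
    pred <- predict_ic50(model, log_expr)
    wt <- wilcoxon_rank_sum(pred, sc$group)
    emit("drug_response", "predicted_ic50.tsv", function(p) {
      utils::write.table(
        data.frame(sample_id = names(pred), log_ic50 = unname(pred),
                   group = sc$group),
        p, sep = "\t", quote = FALSE, row.names = FALSE
      )
    })
    list(model = model, predictions = pred, wilcoxon = wt)
  })

  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(list(results = results, manifest = manifest,
                 manifest_path = manifest_path))
}
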