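MAF_REQUIRED_COLS <- c("Hugo_Symbol", "Tumor_Sample_Barcode",
                       "Variant_Classification")

MAF_KNOWN_CLASSES <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation", "Silent",
  "Splice_Site", "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del",
  "In_Frame_Ins", "Translation_Start_Site", "Intron", "3'UTR", "5'UTR",
  "3'Flank", "5'Flank", "IGR", "RNA", "Targeted_Region"
)

MAF_SILENT_CLASSES <- c("Silent", "Intron", "3'UTR", "5'UTR", "IGR", "RNA")

#' Read a Mutation Annotation Format (MAF) file
#'
#' Tab-separated MAF with at least `Hugo_Symbol`, `Tumor_Sample_Barcode`,
#' `Variant_Classification`; lines starting with `#` are skipped; fully
#' duplicated records are dropped; unknown classification values produce a
#' warning but the records are kept.
#'
#' @param path File path.
#' @return data.frame of mutation records.
#' @export
read_maf <- function(path) {
  maf <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(MAF_REQUIRED_COLS, names(maf))
  if (length(missing) > 0) {
    stop_arg("MAF is missing required column(s): ",
             paste(missing, collapse = ", "))
  }
  if (nrow(maf) > 0) {
    unknown <- setdiff(unique(maf$Variant_Classification), MAF_KNOWN_CLASSES)
    if (length(unknown) > 0) {
      warning("unknown Variant_Classification value(s): ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    maf <- maf[!duplicated(maf), , drop = FALSE]
    rownames(maf) <- NULL
  }
  maf
}

#' Tumor mutational burden per sample
#'
#' Counts variants per sample, excluding silent classes (Silent, Intron,
#' 3'UTR, 5'UTR, IGR, RNA) unless `include_silent`, and divides by the
#' capture size in megabases.
#'
#' @param maf MAF data.frame (see [read_maf()]).
#' @param samples Optional full cohort sample ids; samples absent from the
#'   MAF get TMB 0.
#' @param capture_mb Capture region size in Mb.
#' @param include_silent Count silent classes too.
#' @return data.frame with `sample_id`, `n_nonsilent`, `tmb_per_mb`.
#' @export
compute_tmb <- function(maf, samples = NULL, capture_mb = 38,
                        include_silent = FALSE) {
  if (capture_mb <= 0) stop_arg("capture_mb must be positive")
  keep <- if (include_silent) {
    rep(TRUE, nrow(maf))
  } else {
    !(maf$Variant_Classification %in% MAF_SILENT_CLASSES)
  }
  counts <- table(maf$Tumor_Sample_Barcode[keep])
  ids <- samples %||% sort(unique(maf$Tumor_Sample_Barcode))
  n <- as.integer(counts[match(ids, names(counts))])
  n[is.na(n)] <- 0L
  data.frame(
    sample_id = ids, n_nonsilent = n, tmb_per_mb = n / capture_mb,
    stringsAsFactors = FALSE
  )
}

#' Spearman rank correlation with tie correction
#'
#' Pearson correlation of average (mid-) ranks; the p-value uses the t
#' approximation on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return List with `rho` and `p`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop_arg("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop_arg("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_arg("constant vector: Spearman correlation undefined")
  }
  rho <- stats::cor(rank(x, ties.method = "average"),
                    rank(y, ties.method = "average"))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p)
}

#' Per-gene mutation-frequency contrast between two groups
#'
#' For each gene, forms the 2x2 table (mutated / not mutated) x group and
#' tests it with the chi-square test (Yates continuity correction by
#' default). Where any expected cell count falls below 1 the Fisher exact
#' test is used instead and flagged. Genes are ranked by p; the `in_top_n`
#' column marks the `top_n` genes by overall mutation frequency.
#'
#' @param maf MAF data.frame.
#' @param group_labels Named vector mapping every cohort sample id (also the
#'   mutation-free ones) to one of two groups.
#' @param top_n Number of most-frequently-mutated genes to flag.
#' @param yates Apply the continuity correction.
#' @return data.frame with per-group mutated counts and percentages, `p`,
#'   `test` ("chisq" or "fisher"), ordered by `p`.
#' @export
gene_freq_contrast <- function(maf, group_labels, top_n = 20, yates = TRUE) {
  groups <- factor(group_labels)
  if (nlevels(groups) != 2) stop_arg("need exactly 2 groups")
  if (is.null(names(group_labels))) {
    stop_arg("group_labels must be named by sample id")
  }
  g1 <- levels(groups)[1]
  g2 <- levels(groups)[2]
  n1 <- sum(groups == g1)
  n2 <- sum(groups == g2)
  maf <- maf[maf$Tumor_Sample_Barcode %in% names(group_labels), , drop = FALSE]
  genes <- unique(maf$Hugo_Symbol)
  rows <- lapply(genes, function(gene) {
    carriers <- unique(maf$Tumor_Sample_Barcode[maf$Hugo_Symbol == gene])
    m1 <- sum(groups[match(carriers, names(group_labels))] == g1)
    m2 <- length(carriers) - m1
    tab <- matrix(c(m1, n1 - m1, m2, n2 - m2), nrow = 2)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 1)) {
      p <- stats::fisher.test(tab)$p.value
      test <- "fisher"
    } else {
      p <- suppressWarnings(stats::chisq.test(tab, correct = yates)$p.value)
      test <- "chisq"
    }
    data.frame(
      gene = gene, mutated_g1 = m1, pct_g1 = 100 * m1 / n1,
      mutated_g2 = m2, pct_g2 = 100 * m2 / n2,
      p = p, test = test, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  total <- out$mutated_g1 + out$mutated_g2
  out$in_top_n <- rank(-total, ties.method = "min") <= top_n
  out <- out[order(out$p), , drop = FALSE]
  names(out)[names(out) == "mutated_g1"] <- paste0("mutated_", g1)
  names(out)[names(out) == "pct_g1"] <- paste0("pct_", g1)
  names(out)[names(out) == "mutated_g2"] <- paste0("mutated_", g2)
  names(out)[names(out) == "pct_g2"] <- paste0("pct_", g2)
  rownames(out) <- NULL
  out
}
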