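# Shared fixture builders. Everything is generated in code; nothing binary.

# Small single-batch cohort with uniform cell composition across subtypes,
# so only the planted subtype genes are differential.
uniform_composition_cohort <- function(n_samples = 60, n_subtypes = 3,
                                       subtype_effect = 2, noise_sd = 0.5,
                                       n_genes = 500, n_celltypes = 5,
                                       n_signature_genes = 30, seed = 42,
                                       ...) {
  simulate_cohort(simulation_config(
    n_genes = n_genes, n_celltypes = n_celltypes, n_samples = n_samples,
    n_subtypes = n_subtypes, subtype_effect = subtype_effect,
    noise_sd = noise_sd, n_signature_genes = n_signature_genes,
    dirichlet_alpha = matrix(1, n_subtypes, n_celltypes),
    subtype_log_hazard = seq(0.3, -0.3, length.out = n_subtypes),
    batch_sizes = n_samples, seed = seed, ...
  ))
}

# Expression features that carry the planted subtype separation: the
# top-variance genes of the log2 matrix, samples in rows.
subtype_features <- function(cohort, n_top = 100) {
  lg <- log2_transform(cohort$expression)
  v <- apply(lg$values, 1, stats::var)
  t(lg$values[order(-v)[seq_len(n_top)], , drop = FALSE])
}

# A minimal MAF data.frame.
toy_maf <- function() {
  data.frame(
    Hugo_Symbol = c("TTN", "TTN", "TP53", "TP53", "MUC16"),
    Tumor_Sample_Barcode = c("S1", "S2", "S1", "S3", "S2"),
    Variant_Classification = c("Missense_Mutation", "Silent",
                               "Nonsense_Mutation", "Missense_Mutation",
                               "Frame_Shift_Del"),
    stringsAsFactors = FALSE
  )
}

write_toy_maf <- function(path, maf = toy_maf()) {
  writeLines("#version 2.4", path)
  suppressWarnings(utils::write.table(
    maf, path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE
  ))
  path
}

random_log_matrix <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * n_samples, 6, 1), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  m
}
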