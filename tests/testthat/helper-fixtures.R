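# Shared fixtures, built in code at test time.

# A small two-group cohort with a detectable genotype effect; defaults keep
# every downstream routine fast.
small_cohort <- function(seed = 11, n_features = 120, effect = 2,
                         n_genotype = 15, n_per = 10) {
  generate_cohort(cohort_config(
    n_per_group = c(WT6 = n_per, KO6 = n_per, WT18 = 0, KO18 = 0),
    n_qc = 4, n_features = n_features, n_genotype_features = n_genotype,
    genotype_effect = effect, age_effect = 1,
    noise_feature_fraction = 0.1), seed = seed)
}

study_labels <- function(fm, column = "genotype") {
  fm$sample_meta[[column]][!fm$sample_meta$qc_flag]
}

study_matrix <- function(fm) {
  fm$intensities[!fm$sample_meta$qc_flag, , drop = FALSE]
}

# Plain feature_matrix from a bare numeric matrix.
fm_from_matrix <- function(x) {
  rownames(x) <- sprintf("S%02d", seq_len(nrow(x)))
  colnames(x) <- sprintf("F%03d", seq_len(ncol(x)))
  feature_matrix(x)
}

expect_2dp <- function(value, printed) {
  expect_equal(metabophen:::round_half_up(value, 2), printed)
}
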