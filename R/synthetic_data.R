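#' Cohort configuration for the synthetic LC-MS generator
#'
#' Describes the simulated study: a two-genotype (WT, KO) by two-age (6, 18
#' weeks) murine cohort profiled by untargeted LC-MS with pooled-QC
#' injections. Defaults emulate the structure the downstream analysis
#' assumes: 3129 aligned mass ions over four acquisition windows, group
#' sizes 18/18/17/12, a dominant age effect over a large feature subset, a
#' weaker genotype effect confined to a small subset, per-sample dilution
#' scaling, internal-standard ions and low-intensity noise ions near the
#' noise threshold.
#'
#' @param n_per_group named integer vector of non-QC sample counts; names
#'   must be exactly `WT6`, `KO6`, `WT18`, `KO18`.
#' @param n_qc number of pooled-QC injections.
#' @param n_features total number of mass-ion features.
#' @param n_genotype_features number of features carrying the genotype
#'   effect (ground truth recorded in `feature_meta$is_genotype_feature`).
#' @param genotype_effect multiplicative fold-change applied to genotype
#'   features in KO samples; 1 disables the effect.
#' @param age_effect multiplicative fold-change applied to age features in
#'   18-week samples; 1 disables the effect.
#' @param age_feature_fraction fraction of features carrying the age effect
#'   (a larger subset than the genotype features, so age dominates the
#'   variance structure).
#' @param dilution_cv coefficient of variation of the per-sample
#'   log-normal dilution scalar (urine concentration varies between
#'   animals; internal standards share the dilution, enabling ratio
#'   normalization).
#' @param noise_feature_fraction fraction of features that are pure noise
#'   ions near `noise_level`, intermittently detected in QC injections.
#' @param noise_level intensity scale of noise ions (instrument units).
#' @param n_internal_standards count of internal-standard ions (endogenous
#'   compounds, e.g. creatine/histidine analogues): unaffected by genotype
#'   and age, affected by dilution.
#' @param qc_technical_cv technical coefficient of variation of QC
#'   injections for reliable features.
#' @param rt_jitter_sd standard deviation (minutes) of per-injection
#'   retention-time jitter, used for the optional RT observation matrix.
#' @param colitis_score_range range of the uniform colitis score for KO
#'   18-week animals; WT and 6-week animals score 0.
#' @param couple_colitis if `TRUE`, KO 18-week scores are a monotone
#'   function of the first genotype feature instead of independent noise.
#' @param seed default RNG seed used by [generate_cohort()].
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(WT6 = 18L, KO6 = 18L, WT18 = 17L, KO18 = 12L),
                          n_qc = 8L,
                          n_features = 3129L,
                          n_genotype_features = 60L,
                          genotype_effect = 2,
                          age_effect = 2,
                          age_feature_fraction = 0.3,
                          dilution_cv = 0.3,
                          noise_feature_fraction = 0.1,
                          noise_level = 1e5,
                          n_internal_standards = 2L,
                          qc_technical_cv = 0.05,
                          rt_jitter_sd = 0.02,
                          colitis_score_range = c(2, 8),
                          couple_colitis = FALSE,
                          seed = 1L) {
  cfg <- list(n_per_group = n_per_group, n_qc = as.integer(n_qc),
              n_features = as.integer(n_features),
              n_genotype_features = as.integer(n_genotype_features),
              genotype_effect = genotype_effect, age_effect = age_effect,
              age_feature_fraction = age_feature_fraction,
              dilution_cv = dilution_cv,
              noise_feature_fraction = noise_feature_fraction,
              noise_level = noise_level,
              n_internal_standards = as.integer(n_internal_standards),
              qc_technical_cv = qc_technical_cv,
              rt_jitter_sd = rt_jitter_sd,
              colitis_score_range = colitis_score_range,
              couple_colitis = isTRUE(couple_colitis),
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  if (!identical(sort(names(cfg$n_per_group)), sort(c("WT6", "KO6", "WT18", "KO18"))))
    stop("n_per_group must be named exactly WT6, KO6, WT18, KO18", call. = FALSE)
  if (any(cfg$n_per_group < 0) || cfg$n_qc < 0 || cfg$n_features < 1)
    stop("counts must be non-negative (n_features >= 1)", call. = FALSE)
  if (cfg$genotype_effect <= 0 || cfg$age_effect <= 0)
    stop("effects must be strictly positive fold-changes", call. = FALSE)
  for (f in c("age_feature_fraction", "noise_feature_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(f, " must lie in [0, 1]", call. = FALSE)
  if (cfg$n_genotype_features > cfg$n_features)
    stop("n_genotype_features (", cfg$n_genotype_features,
         ") exceeds n_features (", cfg$n_features, ")", call. = FALSE)
  cfg
}

# Acquisition windows: positive/negative mode crossed with a low (m/z
# 60-200) and high (m/z 140-1250) mass range, mirroring a four-event
# acquisition scheme.
acq_windows <- data.frame(
  window = c("pos_60_200", "pos_140_1250", "neg_60_200", "neg_140_1250"),
  mode = c("pos", "pos", "neg", "neg"),
  mz_lo = c(60, 140, 60, 140),
  mz_hi = c(200, 1250, 200, 1250),
  stringsAsFactors = FALSE)

#' Generate a synthetic LC-MS cohort
#'
#' Simulates an aligned feature matrix. Per-feature log-intensities are
#' Gaussian around a feature-specific baseline spanning roughly three
#' orders of magnitude; genotype and age act as multiplicative fold-changes
#' on configured feature subsets; every study sample is scaled by a
#' log-normal dilution factor; pooled-QC rows are the feature-wise mean of
#' the study samples perturbed by low-variance technical noise (noise ions
#' are intermittently detected in QCs with high variability, so QC
#' reliability filtering removes them). Ground-truth feature roles are
#' recorded in `feature_meta`. Deterministic given the seed.
#'
#' A per-injection retention-time observation matrix (for the RT
#' repeatability criterion) is attached as `attr(, "rt_obs")`.
#'
#' @param config a [cohort_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return a [feature_matrix()] with `sum(n_per_group) + n_qc` rows.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  cfg <- validate_cohort_config(config)
  with_seed(seed, {
    groups <- c("WT6", "KO6", "WT18", "KO18")
    genotype <- rep(c("WT", "KO", "WT", "KO"), cfg$n_per_group[groups])
    age <- rep(c("6", "6", "18", "18"), cfg$n_per_group[groups])
    n_s <- length(genotype)
    n_f <- cfg$n_features

    # feature roles
    role_noise <- rep(FALSE, n_f)
    n_noise <- round(cfg$noise_feature_fraction * n_f)
    if (n_noise > 0) role_noise[sample.int(n_f, n_noise)] <- TRUE
    candidates <- which(!role_noise)
    role_is <- rep(FALSE, n_f)
    n_is <- min(cfg$n_internal_standards, length(candidates))
    if (n_is > 0) {
      is_idx <- sample(candidates, n_is)
      role_is[is_idx] <- TRUE
      candidates <- setdiff(candidates, is_idx)
    }
    role_geno <- rep(FALSE, n_f)
    if (cfg$n_genotype_features > 0) {
      if (cfg$n_genotype_features > length(candidates))
        stop("n_genotype_features exceeds the number of assignable features",
             call. = FALSE)
      role_geno[sample(candidates, cfg$n_genotype_features)] <- TRUE
    }
    role_age <- rep(FALSE, n_f)
    n_age <- round(cfg$age_feature_fraction * n_f)
    if (n_age > 0)
      role_age[sample(which(!role_noise & !role_is), min(n_age, sum(!role_noise & !role_is)))] <- TRUE

    # feature metadata: window, m/z, retention time
    win <- acq_windows[sample.int(4, n_f, replace = TRUE), ]
    mz <- stats::runif(n_f, win$mz_lo, win$mz_hi)
    rt <- stats::runif(n_f, 0.5, 23.0)
    fmeta <- data.frame(
      feature_id = sprintf("F%04d", seq_len(n_f)),
      mz = round(mz, 4), rt = round(rt, 3),
      mode = win$mode, window = win$window,
      is_internal_standard = role_is,
      is_genotype_feature = role_geno,
      is_age_feature = role_age,
      is_noise_feature = role_noise,
      stringsAsFactors = FALSE)

    # baselines: real features span ~3 orders of magnitude above the noise
    # level; internal standards sit high so they are detected everywhere.
    log_base <- stats::runif(n_f, log(10) * 5.5, log(10) * 8.5)
    log_base[role_is] <- log(10) * stats::runif(n_is, 7.5, 8.5)
    log_base[role_noise] <- log(cfg$noise_level) + stats::rnorm(n_noise, -0.5, 0.4)
    sd_log <- stats::runif(n_f, 0.2, 0.5)
    # internal standards are biologically stable: their between-sample
    # variation is essentially the dilution, which ratioing removes
    sd_log[role_is] <- 0.02

    # study-sample log intensities
    logx <- matrix(stats::rnorm(n_s * n_f), n_s, n_f)
    logx <- sweep(logx, 2, sd_log, `*`)
    logx <- sweep(logx, 2, log_base, `+`)
    ko <- genotype == "KO"
    old <- age == "18"
    if (cfg$genotype_effect != 1 && any(role_geno))
      logx[ko, role_geno] <- logx[ko, role_geno] + log(cfg$genotype_effect)
    if (cfg$age_effect != 1 && any(role_age))
      logx[old, role_age] <- logx[old, role_age] + log(cfg$age_effect)

    # per-sample dilution (log-normal with CV dilution_cv); noise ions are
    # instrument background and do not dilute, internal standards do.
    sdlog_d <- sqrt(log(1 + cfg$dilution_cv^2))
    dil <- stats::rlnorm(n_s, meanlog = -sdlog_d^2 / 2, sdlog = sdlog_d)
    x <- exp(logx)
    x[, !role_noise] <- x[, !role_noise] * dil

    # pooled QC rows: feature-wise mean of study samples with low technical
    # noise; noise ions show dropout and high variability across QCs.
    n_qc <- cfg$n_qc
    if (n_qc > 0) {
      qmean <- colMeans(x)
      sdlog_q <- sqrt(log(1 + cfg$qc_technical_cv^2))
      q <- matrix(stats::rlnorm(n_qc * n_f, -sdlog_q^2 / 2, sdlog_q),
                  n_qc, n_f)
      q <- sweep(q, 2, qmean, `*`)
      if (n_noise > 0) {
        noisy <- matrix(stats::rlnorm(n_qc * n_noise, -0.18, 0.6), n_qc, n_noise)
        drop <- matrix(stats::runif(n_qc * n_noise) < 0.5, n_qc, n_noise)
        q[, role_noise] <- sweep(noisy * !drop, 2, qmean[role_noise], `*`)
      }
      x <- rbind(x, q)
    }

    # sample metadata incl. colitis scores (0 except KO 18-week)
    score <- rep(0, n_s)
    ko18 <- ko & old
    if (any(ko18)) {
      if (cfg$couple_colitis && any(role_geno)) {
        drv <- logx[ko18, which(role_geno)[1]]
        u <- (drv - min(drv)) / max(diff(range(drv)), .Machine$double.eps)
        score[ko18] <- cfg$colitis_score_range[1] +
          u * diff(cfg$colitis_score_range)
      } else {
        score[ko18] <- stats::runif(sum(ko18), cfg$colitis_score_range[1],
                                    cfg$colitis_score_range[2])
      }
    }
    smeta <- data.frame(
      sample_id = c(sprintf("S%03d", seq_len(n_s)),
                    if (n_qc > 0) sprintf("QC%02d", seq_len(n_qc))),
      genotype = c(genotype, rep("QC", n_qc)),
      age_group = c(age, rep(NA_character_, n_qc)),
      qc_flag = c(rep(FALSE, n_s), rep(TRUE, n_qc)),
      colitis_score = c(score, rep(NA_real_, n_qc)),
      stringsAsFactors = FALSE)

    fm <- feature_matrix(x, smeta, fmeta)

    # per-injection RT observations (jitter around the aligned RT)
    rt_obs <- matrix(rep(fmeta$rt, each = nrow(x)), nrow(x), n_f) +
      stats::rnorm(nrow(x) * n_f, 0, cfg$rt_jitter_sd)
    dimnames(rt_obs) <- dimnames(fm$intensities)
    attr(fm, "rt_obs") <- rt_obs
    fm
  })
}

#' Generate a synthetic pathway-abundance count table
#'
#' Emulates an inferred functional-pathway count table: compositional
#' counts with log-normal pathway baselines and per-sample multinomial
#' sampling at comparable depths. Samples are split into two equal groups;
#' `group_shift` applies a multiplicative location effect `exp(group_shift)`
#' to the first 20% of pathways in the second group (0 = null).
#'
#' @param n_samples,n_pathways positive counts.
#' @param group_shift location effect on the log scale; 0 for no structure.
#' @param seed RNG seed.
#' @param depth approximate per-sample sequencing depth (multinomial total,
#'   jittered 20% between samples).
#' @return a [feature_matrix()] of non-negative integer counts whose
#'   `sample_meta` carries a `group` column (`"A"`/`"B"`).
#' @export
generate_pathway_table <- function(n_samples, n_pathways, group_shift = 0,
                                   seed = 1L, depth = 10000) {
  stopifnot(n_samples >= 2, n_pathways >= 1)
  with_seed(seed, {
    base <- stats::rnorm(n_pathways, 0, 1.5)
    grp <- rep(c("A", "B"), length.out = n_samples)
    shifted <- seq_len(max(1, floor(0.2 * n_pathways)))
    counts <- matrix(0L, n_samples, n_pathways)
    for (i in seq_len(n_samples)) {
      lam <- base + stats::rnorm(n_pathways, 0, 0.6)
      if (grp[i] == "B") lam[shifted] <- lam[shifted] + group_shift
      p <- exp(lam); p <- p / sum(p)
      d <- round(depth * stats::runif(1, 0.9, 1.1))
      counts[i, ] <- stats::rmultinom(1, d, p)[, 1]
    }
    smeta <- data.frame(sample_id = sprintf("P%03d", seq_len(n_samples)),
                        genotype = NA_character_, age_group = NA_character_,
                        qc_flag = FALSE, colitis_score = NA_real_,
                        group = grp, stringsAsFactors = FALSE)
    fmeta <- data.frame(feature_id = sprintf("path%04d", seq_len(n_pathways)),
                        mz = NA_real_, rt = NA_real_, mode = NA_character_,
                        window = NA_character_, is_internal_standard = FALSE,
                        stringsAsFactors = FALSE)
    feature_matrix(counts, smeta, fmeta)
  })
}
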