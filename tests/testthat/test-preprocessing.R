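test_that("noise threshold filter removes exactly the sub-threshold features", {
  x <- cbind(a = c(2e5, 3e5, 1e5), b = c(4e4, 5e4, 2e4), c = c(9e4, 9.9e4, 5e4))
  fm <- feature_matrix(x)
  r0 <- noise_threshold_filter(fm, 0)
  expect_identical(r0$matrix$intensities, fm$intensities)   # identity at 0
  r <- noise_threshold_filter(fm, 1e5)
  expect_equal(r$report$removed, c("b", "c"))
  expect_equal(colnames(r$matrix$intensities), "a")
  expect_equal(r$report$features_out, 1)
  # monotone: stricter threshold keeps no more features
  fm2 <- small_cohort(seed = 4, n_features = 300)
  n1 <- noise_threshold_filter(fm2, 1e5)$report$features_out
  n2 <- noise_threshold_filter(fm2, 1e6)$report$features_out
  expect_lte(n2, n1)
})

test_that("singleton features (detected once) are dropped", {
  x <- cbind(a = c(1e6, 2e6, 3e6), b = c(5e5, 0, 0), c = c(0, 0, 0))
  r <- singleton_filter(feature_matrix(x))
  expect_equal(r$report$removed, "b")
  expect_equal(colnames(r$matrix$intensities), c("a", "c"))
})

test_that("QC statistics follow their definitions", {
  x <- rbind(s1 = c(100, 50), s2 = c(120, 60),
             q1 = c(100, 100), q2 = c(100, 100), q3 = c(100, 0), q4 = c(100, 0))
  sm <- data.frame(sample_id = rownames(x),
                   genotype = c("WT", "KO", "QC", "QC", "QC", "QC"),
                   age_group = NA, qc_flag = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
                   colitis_score = NA_real_)
  fm <- feature_matrix(x, sm)
  st <- qc_stats(fm)
  expect_equal(st$qc_presence, c(1, 0.5))
  expect_equal(st$area_rsd[1], 0)                   # identical QC intensities
  expect_equal(st$area_rsd[2], sd(c(100, 100, 0, 0)) / 50)
  # presence 0.5 < 0.8 -> removed; constant feature retained
  qf <- qc_reliability_filter(fm)
  expect_equal(ncol(qf$matrix$intensities), 1)
  expect_match(qf$report$notes, "skipped")
  # fewer than 2 QC rows is an explicit error
  expect_error(qc_stats(fm[1:3, ]), "at least 2 QC rows")
})

test_that("QC reliability filtering separates noise from real features", {
  fm <- small_cohort(seed = 9, n_features = 400)
  qf <- qc_reliability_filter(fm)
  kept <- qf$matrix$feature_meta
  noise <- fm$feature_meta$is_noise_feature
  geno <- fm$feature_meta$is_genotype_feature
  noise_kept <- sum(kept$is_noise_feature)
  geno_kept <- sum(kept$is_genotype_feature)
  expect_lte(noise_kept, 0.10 * sum(noise))      # >= 90% of noise removed
  expect_gte(geno_kept, 0.90 * sum(geno))        # <= 10% of real signal lost
  # RT criterion engages when observations are present
  qf_rt <- qc_reliability_filter(fm, rt_obs = attr(fm, "rt_obs"))
  expect_length(qf_rt$report$notes, 0)
  expect_false(anyNA(qf_rt$stats$rt_rsd))
})

test_that("correlation filter leaves no retained pair at or above threshold", {
  set.seed(21)
  x <- matrix(rnorm(20 * 40), 20, 40)
  x[, 5] <- x[, 2]                       # exact duplicate
  x[, 9] <- x[, 3] + rnorm(20, 0, 1e-4)  # near-duplicate
  fm <- fm_from_matrix(x)
  r <- correlation_filter(fm, 0.98)
  expect_true(all(c("F005", "F009") %in% r$report$removed))
  kept <- r$matrix$intensities
  cm <- abs(cor(kept))                   # brute-force pairwise verification
  diag(cm) <- 0
  expect_lt(max(cm), 0.98)
  # threshold 1 with jittered columns is the identity
  xj <- x + rnorm(length(x), 0, 1e-6)
  expect_length(correlation_filter(fm_from_matrix(xj), 1.0)$report$removed, 0)
})

test_that("correlation filter keeps the earlier column and tolerates constants", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), k = c(5, 5, 5, 5))
  r <- correlation_filter(feature_matrix(x), 0.98)
  expect_equal(r$report$removed, "b")            # later duplicate removed
  expect_true("k" %in% colnames(r$matrix$intensities))
  expect_match(r$report$notes, "zero-variance")
  # appending a duplicate of a retained column does not change the survivors
  x2 <- cbind(x, a2 = x[, "a"])
  r2 <- correlation_filter(feature_matrix(x2), 0.98)
  expect_setequal(colnames(r2$matrix$intensities), colnames(r$matrix$intensities))
})

test_that("Z-scoring gives mean 0, population sd 1, and is idempotent", {
  fm <- small_cohort(seed = 3, n_features = 50)
  z <- zscore_normalize(fm)
  idx <- !z$sample_meta$qc_flag
  zz <- z$intensities[idx, ]
  n <- sum(idx)
  expect_lt(max(abs(colMeans(zz))), 1e-12)
  expect_lt(max(abs(sqrt(colMeans(sweep(zz, 2, colMeans(zz))^2)) - 1)), 1e-12)
  # QC rows share the same transform (not re-centered on themselves)
  j <- 1
  expect_equal(z$intensities[!idx, j],
               (fm$intensities[!idx, j] - attr(z, "center")[j]) / attr(z, "scale")[j])
  # idempotent up to floating tolerance
  z2 <- zscore_normalize(z)
  expect_lt(max(abs(z2$intensities[idx, ] - zz)), 1e-10)
  # constant column maps to zeros and is flagged
  x <- cbind(a = c(1, 2, 3), k = c(7, 7, 7))
  zc <- zscore_normalize(feature_matrix(x))
  expect_equal(unname(zc$intensities[, "k"]), c(0, 0, 0))
  expect_equal(attr(zc, "zero_variance"), "k")
})

test_that("internal-standard ratio cancels dilution", {
  fm <- small_cohort(seed = 6, n_features = 150)
  std_ids <- fm$feature_meta$feature_id[fm$feature_meta$is_internal_standard]
  r <- internal_standard_ratio(fm, std_ids[1])
  expect_true(all(abs(r$intensities[, std_ids[1]] - 1) < 1e-12))
  # the second standard varies only through dilution: ratioing collapses its CV
  v <- fm$intensities[!fm$sample_meta$qc_flag, std_ids[2]]
  v_ratio <- r$intensities[!r$sample_meta$qc_flag, std_ids[2]]
  expect_gt(sd(v) / mean(v), 0.15)
  expect_lt(sd(v_ratio) / mean(v_ratio), 0.05)
  # uniform dilution of 1: ratioing by a constant-1 standard is the identity
  x <- cbind(a = c(2, 4), s = c(1, 1))
  r2 <- internal_standard_ratio(feature_matrix(x), "s")
  expect_equal(r2$intensities[, "a"], c(S1 = 2, S2 = 4))
  # zero standard names the offending sample
  x3 <- cbind(a = c(2, 4), s = c(1, 0))
  expect_error(internal_standard_ratio(feature_matrix(x3), "s"), "S2")
})

test_that("the canonical filter chain only shrinks the feature set", {
  fm <- small_cohort(seed = 8, n_features = 300)
  n0 <- ncol(fm$intensities)
  a <- noise_threshold_filter(fm, 1e5)
  b <- qc_reliability_filter(a$matrix)
  d <- correlation_filter(b$matrix)
  ns <- c(n0, ncol(a$matrix$intensities), ncol(b$matrix$intensities),
          ncol(d$matrix$intensities))
  expect_true(all(diff(ns) <= 0))
  # sample rows never reordered or dropped
  expect_identical(d$matrix$sample_meta$sample_id, fm$sample_meta$sample_id)
})
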