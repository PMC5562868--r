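test_that("confusion metrics reproduce textbook values from raw counts", {
  m <- confusion_metrics(8, 1, 9, 4)
  expect_equal(m$recall, 8 / 12)
  expect_equal(m$precision, 8 / 9)
  expect_equal(m$specificity, 9 / 10)
  expect_equal(m$accuracy, 17 / 22)
  # kappa from first principles: observed vs marginal chance agreement
  p_o <- 17 / 22
  p_e <- (9 * 12 + 13 * 10) / 22^2
  expect_equal(m$kappa, (p_o - p_e) / (1 - p_e))
  # perfect prediction
  p <- confusion_metrics(10, 0, 10, 0)
  for (f in c("recall", "precision", "specificity", "accuracy", "kappa", "f_measure"))
    expect_equal(p[[f]], 1)
  # zero-denominator ratios come back flagged, not silently zero
  u <- confusion_metrics(0, 0, 10, 0)
  expect_true(is.na(u$recall))
  expect_equal(u$specificity, 1)
})

test_that("PLS-LDA separates well-separated clouds and is deterministic", {
  set.seed(1)
  x <- rbind(matrix(rnorm(10 * 30), 10, 30),
             matrix(rnorm(10 * 30, mean = 10), 10, 30))
  y <- rep(c("a", "b"), each = 10)
  fit <- pls_lda(x, y, n_components = 3)
  expect_equal(as.character(predict(fit, x)), y)      # training accuracy 1
  fit2 <- pls_lda(x, y, n_components = 3)
  expect_identical(fit$coefficients, fit2$coefficients)
  # latent scores are centered per component
  expect_lt(max(abs(colMeans(fit$scores))), 1e-10)
  # requesting more components than the data rank reduces with a warning
  expect_warning(pls_lda(x[1:4, ], y[c(1, 2, 11, 12)], n_components = 10),
                 "reduced")
})

test_that("PLS-LDA predictions are invariant to feature order and zero columns", {
  set.seed(2)
  x <- matrix(rnorm(24 * 15), 24, 15)
  y <- rep(c("a", "b"), 12)
  x[y == "b", 1:3] <- x[y == "b", 1:3] + 1.5
  base_pred <- predict(pls_lda(x, y, 4), x)
  perm <- sample(ncol(x))
  expect_equal(as.character(predict(pls_lda(x[, perm], y, 4), x[, perm])),
               as.character(base_pred))
  xz <- cbind(x, matrix(0, 24, 5))
  expect_equal(as.character(predict(pls_lda(xz, y, 4), xz)),
               as.character(base_pred))
})

test_that("full-component PLS reproduces least-squares fitted values", {
  set.seed(3)
  x <- matrix(rnorm(20 * 5), 20, 5)
  yv <- drop(x %*% c(1, -2, 0.5, 3, 1)) + rnorm(20)
  fit <- metabophen:::pls_regress(x, yv, n_components = 5)
  pls_fitted <- drop(sweep(x, 2, fit$xc) %*% fit$b) + fit$yc
  ls_fitted <- unname(fitted(lm(yv ~ x)))
  expect_equal(pls_fitted, ls_fitted, tolerance = 1e-8)
})

test_that("leave-one-out cross-validation aggregates honest fold predictions", {
  fm <- small_cohort(seed = 11)
  z <- zscore_normalize(fm)
  cv <- loo_cross_validate(z, study_labels(z), n_components = 5)
  expect_equal(sum(cv$table), 20)
  # per-class counts are consistent one-vs-rest decompositions
  for (cl in names(cv$per_class)) {
    m <- cv$per_class[[cl]]
    expect_equal(m$tp + m$fp + m$tn + m$fn, 20)
  }
  expect_gt(cv$accuracy, 0.7)     # genotype effect is detectable
  expect_match(cv$notes, "over-fitting")
  # a singleton class cannot be cross-validated
  expect_error(loo_cross_validate(matrix(rnorm(12), 4, 3),
                                  c("a", "a", "a", "b")), "2 samples per class")
})

test_that("score regression recovers an exact linear signal and rejects constants", {
  set.seed(4)
  x1 <- matrix(rnorm(15), 15, 1)
  scores <- drop(2.5 * x1 + 1)
  r <- regress_against_score(x1, scores, method = "pls", n_components = 1)
  expect_lt(max(abs(r$predicted - r$observed)), 1e-6)
  expect_gt(r$q2, 1 - 1e-10)
  # noiseless 5-feature combination: near-perfect LOO recovery
  x5 <- matrix(rnorm(40 * 5), 40, 5)
  s5 <- drop(x5 %*% c(1, 2, -1, 0.5, 1.5))
  r5 <- regress_against_score(x5, s5, method = "pls", n_components = 5)
  expect_gt(r5$q2, 0.9)
  expect_lt(abs(r5$slope - 1), 0.1)
  expect_error(regress_against_score(x5, rep(1, 40), method = "pls"),
               "constant")
})

test_that("null scores give negative Q2 and a flat identity-line fit", {
  q2 <- slope <- numeric(10)
  for (i in 1:10) {
    set.seed(i)
    x <- matrix(rnorm(20 * 50), 20, 50)
    s <- runif(20, 0, 8)
    r <- regress_against_score(x, s, method = "pls", n_components = 5)
    q2[i] <- r$q2; slope[i] <- r$slope
  }
  expect_lt(mean(q2), 0)
  expect_lt(abs(mean(slope)), 0.25)
})

test_that("random-forest regression branch is seed-deterministic", {
  set.seed(5)
  x <- matrix(rnorm(16 * 10), 16, 10)
  colnames(x) <- paste0("f", 1:10)
  s <- drop(x[, 1] * 2) + rnorm(16, 0, 0.1)
  a <- regress_against_score(x, s, method = "rf", num_trees = 100, seed = 9)
  b <- regress_against_score(x, s, method = "rf", num_trees = 100, seed = 9)
  expect_identical(a$predicted, b$predicted)
})

test_that("PCA overview orders variance and separates the dominant factor", {
  # rank-1 data: one component carries all variance
  u <- rnorm(10); v <- rnorm(6)
  p1 <- pca_overview(outer(u, v), n_components = 2)
  expect_equal(p1$explained[1], 1, tolerance = 1e-10)
  fm <- generate_cohort(cohort_config(
    n_per_group = c(WT6 = 8, KO6 = 8, WT18 = 8, KO18 = 8), n_qc = 2,
    n_features = 200, n_genotype_features = 15, genotype_effect = 1.3,
    age_effect = 3, age_feature_fraction = 0.4,
    noise_feature_fraction = 0), seed = 13)
  z <- zscore_normalize(fm)
  pc <- pca_overview(z, n_components = 2)
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1 + 1e-8)
  # dominant age effect: age groups separate better than genotype on PC1-2
  sil <- function(lab) {
    d <- as.matrix(dist(pc$coordinates))
    mean(vapply(seq_along(lab), function(i) {
      a <- mean(d[i, lab == lab[i] & seq_along(lab) != i])
      b <- min(vapply(setdiff(unique(lab), lab[i]),
                      function(l) mean(d[i, lab == l]), numeric(1)))
      (b - a) / max(a, b)
    }, numeric(1)))
  }
  age <- fm$sample_meta$age_group[!fm$sample_meta$qc_flag]
  geno <- study_labels(fm)
  expect_gt(sil(age), sil(geno))
})
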