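# Feature-permutation significance testing via classification cross-entropy.
#
# Procedure: fit a random-forest classifier repeatedly on the unpermuted
# data to obtain the mean and sigma of its out-of-bag classification
# cross-entropy; then, for each feature, permute its column (a fresh
# permutation per repeat), refit, and record the mean cross-entropy. A
# feature is flagged significant when the permuted-minus-baseline
# difference exceeds z_crit * sigma (default 1.96). One-sided normal
# p-values delta/sigma are corrected by Storey q-values.

#' Classification cross-entropy
#'
#' Negative mean natural-log probability assigned to the true class:
#' `-(1/N) * sum(log p_hat(true class))`. Probabilities are floored at
#' `eps` before taking the log.
#'
#' @param prob_matrix samples x classes probability matrix (rows must sum
#'   to 1 within 1e-9); column names are the class labels
#' @param labels true class per row
#' @param eps probability floor (default 1e-15)
#' @return cross-entropy in nats (non-negative)
#' @export
classification_cross_entropy <- function(prob_matrix, labels, eps = 1e-15) {
  prob_matrix <- as.matrix(prob_matrix)
  labels <- as.character(labels)
  if (any(abs(rowSums(prob_matrix) - 1) > 1e-9))
    stop("probability rows must sum to 1", call. = FALSE)
  j <- match(labels, colnames(prob_matrix))
  if (anyNA(j))
    stop("label(s) outside the class set: ",
         paste(unique(labels[is.na(j)]), collapse = ", "), call. = FALSE)
  p <- pmax(prob_matrix[cbind(seq_along(j), j)], eps)
  -mean(log(p))
}

# One RF fit -> out-of-bag (or training) cross-entropy. Samples never
# out-of-bag (possible at very low tree counts) fall back to uniform
# class probabilities.
rf_cross_entropy <- function(x, y, num_trees, seed,
                             eval = c("oob", "training"), eps = 1e-15) {
  eval <- match.arg(eval)
  fit <- ranger::ranger(x = x, y = y, num.trees = num_trees,
                        probability = TRUE, seed = seed, num.threads = 1)
  prob <- if (eval == "oob") fit$predictions
  else stats::predict(fit, data = x, num.threads = 1)$predictions
  bad <- !is.finite(rowSums(prob))
  if (any(bad)) prob[bad, ] <- 1 / ncol(prob)
  classification_cross_entropy(prob, y, eps = eps)
}

#' Baseline cross-entropy of the unpermuted classifier
#'
#' Fits the random-forest classifier `n_repeats` times on the unpermuted
#' data (distinct derived seeds) and returns the sample mean and standard
#' deviation of its out-of-bag classification cross-entropy. These define
#' the null scale sigma against which permuted features are judged.
#'
#' @param m matrix or [feature_matrix()] (QC rows excluded)
#' @param labels class labels (>= 2 classes)
#' @param n_repeats number of refits (default 100; must be >= 2 for sigma)
#' @param seed master seed; all repeats derive from it
#' @param num_trees trees per forest (default 500; mtry stays at the
#'   ranger default, floor(sqrt(p)))
#' @param eval `"oob"` (default, honest error) or `"training"`
#' @return list with `mean`, `sigma`, and the individual `values`
#' @export
baseline_cross_entropy <- function(m, labels, n_repeats = 100, seed = 1L,
                                   num_trees = 500, eval = "oob") {
  if (n_repeats < 2)
    stop("n_repeats must be >= 2 (sigma undefined otherwise)", call. = FALSE)
  xy <- as_xy(m, labels)
  seeds <- derive_seeds(seed, n_repeats)
  values <- vapply(seeds, function(s)
    rf_cross_entropy(xy$x, xy$y, num_trees, s, eval = eval), numeric(1))
  list(mean = mean(values), sigma = stats::sd(values), values = values)
}

as_xy <- function(m, labels) {
  if (inherits(m, "feature_matrix")) {
    keep <- non_qc_idx(m)
    if (length(labels) == nrow(m$intensities)) labels <- labels[keep]
    m <- m$intensities[keep, , drop = FALSE]
  }
  y <- droplevels(as.factor(labels))
  if (nlevels(y) < 2) stop("need at least 2 classes", call. = FALSE)
  list(x = as.matrix(m), y = y)
}

#' Feature-permutation importance test
#'
#' For each feature, its column is permuted across samples (a fresh
#' permutation per repeat by default), the classifier refitted, and the
#' mean out-of-bag cross-entropy over `n_repeats` compared with the
#' unpermuted baseline. Permuting an informative feature destroys its
#' association with the labels and raises the cross-entropy; the feature
#' is flagged significant when the increase `delta` exceeds
#' `z_crit * sigma` of the baseline repeats. One-sided normal p-values
#' `P(Z > delta/sigma)` are corrected by [storey_qvalues()].
#'
#' @inheritParams baseline_cross_entropy
#' @param z_crit significance multiple of sigma (default 1.96)
#' @param fresh_permutation permute anew each repeat (default); `FALSE`
#'   reuses one fixed permutation per feature
#' @return object of class `perm_importance`: data.frame `results`
#'   (feature_id, permuted_mean_ce, delta, significant, p_value, q_value)
#'   plus `baseline_mean_ce`, `baseline_sigma` and the settings
#' @export
permutation_feature_test <- function(m, labels, n_repeats = 100,
                                     z_crit = 1.96, seed = 1L,
                                     num_trees = 500, eval = "oob",
                                     fresh_permutation = TRUE) {
  xy <- as_xy(m, labels)
  feature_ids <- colnames(xy$x) %||% paste0("F", seq_len(ncol(xy$x)))
  base <- baseline_cross_entropy(xy$x, xy$y, n_repeats = n_repeats,
                                 seed = seed, num_trees = num_trees,
                                 eval = eval)
  p <- ncol(xy$x)
  n <- nrow(xy$x)
  feat_seeds <- derive_seeds(seed + 1L, p)
  permuted_mean <- numeric(p)
  for (j in seq_len(p)) {
    rep_seeds <- derive_seeds(feat_seeds[j], n_repeats)
    xp <- xy$x
    perm0 <- with_seed(feat_seeds[j], sample.int(n))
    ces <- vapply(seq_len(n_repeats), function(r) {
      perm <- if (fresh_permutation)
        with_seed(rep_seeds[r] + 1L, sample.int(n)) else perm0
      xp[, j] <- xy$x[perm, j]
      rf_cross_entropy(xp, xy$y, num_trees, rep_seeds[r], eval = eval)
    }, numeric(1))
    permuted_mean[j] <- mean(ces)
  }
  delta <- permuted_mean - base$mean
  sig <- is.finite(z_crit * base$sigma) & delta > z_crit * base$sigma
  pval <- if (base$sigma > 0) stats::pnorm(delta / base$sigma, lower.tail = FALSE)
  else as.numeric(delta <= 0)
  qval <- storey_qvalues(pval)
  structure(list(results = data.frame(feature_id = feature_ids,
                                      permuted_mean_ce = permuted_mean,
                                      delta = delta, significant = sig,
                                      p_value = pval, q_value = qval,
                                      stringsAsFactors = FALSE),
                 baseline_mean_ce = base$mean, baseline_sigma = base$sigma,
                 settings = list(n_repeats = n_repeats, z_crit = z_crit,
                                 num_trees = num_trees, eval = eval,
                                 fresh_permutation = fresh_permutation,
                                 seed = seed)),
            class = "perm_importance")
}

#' @export
print.perm_importance <- function(x, n = 10, ...) {
  cat(sprintf("Feature-permutation test: baseline CE %.4f (sigma %.4f), %d repeats, z_crit %.2f\n",
              x$baseline_mean_ce, x$baseline_sigma,
              x$settings$n_repeats, x$settings$z_crit))
  cat(sum(x$results$significant), "of", nrow(x$results),
      "features significant by the", sprintf("%.2f", x$settings$z_crit),
      "sigma rule\n")
  ord <- order(-x$results$delta)
  print(utils::head(x$results[ord, ], n), row.names = FALSE)
  invisible(x)
}

#' Storey q-values
#'
#' False-discovery-rate q-values with the null proportion pi0 estimated
#' from the p-value distribution: pi0(lambda) = #\{p > lambda\} /
#' (m (1 - lambda)) over the grid lambda = 0.05, 0.10, ..., 0.95, smoothed
#' by a cubic smoothing spline and extrapolated to lambda = 1. For fewer
#' than 100 p-values the smoother is unstable and the conservative
#' fallback pi0 = min(1, 2 * mean(p)) is used. q-values are the
#' step-up-minimised pi0 * m * p / rank, clipped to [0, 1] and monotone in
#' p. Forcing `pi0 = 1` reduces exactly to Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param p_values numeric vector in [0, 1]
#' @param lambda tuning grid for the pi0 estimate
#' @param pi0 optional fixed null proportion overriding estimation
#' @return q-values in the input order; `attr(, "pi0")` records the
#'   estimate
#' @export
storey_qvalues <- function(p_values, lambda = seq(0.05, 0.95, by = 0.05),
                           pi0 = NULL) {
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (is.null(pi0)) {
    if (m < 100) {
      pi0 <- min(1, 2 * mean(p_values))
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p_values > l) / (1 - l),
                      numeric(1))
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = 1)$y
    }
    pi0 <- min(max(pi0, 1 / m), 1)     # guard degenerate estimates
  }
  ord <- order(p_values, decreasing = TRUE)
  q <- numeric(m)
  ranks <- m:1                          # rank of the i-th largest p
  q[ord] <- cummin(pi0 * m * p_values[ord] / ranks)
  q <- pmin(q, 1)
  attr(q, "pi0") <- pi0
  q
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (monotone, clipped to [0, 1]);
#' delegates to [stats::p.adjust()].
#'
#' @param p_values numeric vector in [0, 1]
#' @return adjusted p-values in the input order
#' @export
benjamini_hochberg <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}
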