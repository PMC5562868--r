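# Classification performance statistics and regression diagnostics.

#' Confusion-table metrics for one class
#'
#' Computes the standard binary metrics from true/false positive/negative
#' counts: recall = tp/(tp+fn), precision = tp/(tp+fp), sensitivity =
#' recall, specificity = tn/(tn+fp), F-measure = harmonic mean of
#' precision and recall, accuracy = (tp+tn)/n, and Cohen's kappa =
#' (p_o - p_e)/(1 - p_e) where p_o is the observed agreement and p_e the
#' chance agreement from the table margins. Ratios with a zero denominator
#' are returned as `NA` (flagged undefined), never silently zero.
#'
#' @param tp,fp,tn,fn non-negative integer counts
#' @return a list of class `confusion_metrics` with the counts and all
#'   derived metrics
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  n <- sum(counts)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  recall <- ratio(tp, tp + fn)
  precision <- ratio(tp, tp + fp)
  specificity <- ratio(tn, tn + fp)
  f_measure <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  accuracy <- ratio(tp + tn, n)
  # chance agreement from the 2x2 margins
  p_e <- if (n > 0)
    ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2 else NA_real_
  kappa <- if (!is.na(p_e) && p_e < 1) (accuracy - p_e) / (1 - p_e) else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 recall = recall, precision = precision,
                 sensitivity = recall, specificity = specificity,
                 f_measure = f_measure, accuracy = accuracy, kappa = kappa),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, digits = 2, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  m <- unlist(x[c("recall", "precision", "sensitivity", "specificity",
                  "f_measure", "accuracy", "kappa")])
  print(round_half_up(m, digits))
  invisible(x)
}

#' Leave-one-out cross-validation of a PLS-LDA classifier
#'
#' For each sample the model is refitted on the remaining samples and the
#' held-out sample is predicted; held-out predictions are aggregated into
#' per-class one-vs-rest confusion counts with full derived metrics,
#' overall accuracy and Cohen's kappa (computed from the pooled k x k
#' table). With many more features than samples all data are effectively
#' used in training the final model, so a standard over-fitting caveat is
#' recorded in the result's `notes`.
#'
#' @param m numeric matrix or [feature_matrix()] (QC rows excluded)
#' @param labels per-sample class labels; every class needs >= 2 samples
#' @param n_components latent variables per fold (default 5)
#' @param ... passed to [pls_lda()]
#' @return an object of class `confusion_result`: list with `table` (k x k
#'   contingency, rows = truth), `per_class` (named list of
#'   [confusion_metrics()]), `accuracy`, `kappa`, `predictions`, `notes`
#' @export
loo_cross_validate <- function(m, labels, n_components = 5, ...) {
  if (inherits(m, "feature_matrix")) {
    keep <- non_qc_idx(m)
    if (length(labels) == nrow(m$intensities)) labels <- labels[keep]
    m <- m$intensities[keep, , drop = FALSE]
  }
  x <- as.matrix(m)
  y <- droplevels(as.factor(labels))
  if (any(table(y) < 2))
    stop("leave-one-out needs >= 2 samples per class; class(es) with 1: ",
         paste(names(which(table(y) < 2)), collapse = ", "), call. = FALSE)
  n <- nrow(x)
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  for (i in seq_len(n)) {
    fit <- suppressWarnings(
      pls_lda(x[-i, , drop = FALSE], y[-i], n_components = n_components, ...))
    pred[i] <- predict(fit, x[i, , drop = FALSE])
  }
  confusion_result(y, pred,
                   notes = if (ncol(x) > n)
                     "features greatly outnumber samples: leave-one-out estimates may be optimistic (over-fitting not ruled out)"
                   else character())
}

# Aggregate truth/prediction factors into a full confusion result.
confusion_result <- function(truth, pred, notes = character()) {
  truth <- as.factor(truth)
  pred <- factor(pred, levels = levels(truth))
  tab <- table(truth = truth, predicted = pred)
  n <- sum(tab)
  per_class <- lapply(levels(truth), function(cl) {
    tp <- tab[cl, cl]
    fp <- sum(tab[, cl]) - tp
    fn <- sum(tab[cl, ]) - tp
    tn <- n - tp - fp - fn
    confusion_metrics(tp, fp, tn, fn)
  })
  names(per_class) <- levels(truth)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  structure(list(table = tab, per_class = per_class,
                 accuracy = p_o,
                 kappa = if (p_e < 1) (p_o - p_e) / (1 - p_e) else NA_real_,
                 predictions = pred, truth = truth, notes = notes),
            class = "confusion_result")
}

#' @export
print.confusion_result <- function(x, digits = 2, ...) {
  cat("Cross-validated confusion (rows = truth):\n")
  print(x$table)
  df <- do.call(rbind, lapply(names(x$per_class), function(cl) {
    m <- x$per_class[[cl]]
    data.frame(class = cl, TP = m$tp, FP = m$fp, TN = m$tn, FN = m$fn,
               recall = round_half_up(m$recall, digits),
               precision = round_half_up(m$precision, digits),
               sensitivity = round_half_up(m$sensitivity, digits),
               specificity = round_half_up(m$specificity, digits),
               F = round_half_up(m$f_measure, digits))
  }))
  print(df, row.names = FALSE)
  cat(sprintf("Overall accuracy %.2f, Cohen's kappa %.2f\n",
              round_half_up(x$accuracy, digits), round_half_up(x$kappa, digits)))
  for (nte in x$notes) cat("  note:", nte, "\n")
  invisible(x)
}

#' Cross-validated regression of a clinical score on metabolite features
#'
#' Builds a predictive regression of a continuous score (e.g. a colitis
#' activity score) on the feature matrix, by PLS regression or random
#' forest, with leave-one-out cross-validation, and summarises how far the
#' cross-validated predictions deviate from the identity line: the slope
#' and intercept of predicted-vs-observed and the cross-validated R^2
#' (Q^2 = 1 - PRESS/TSS, which is negative when the model predicts worse
#' than the observed mean).
#'
#' @param m matrix or [feature_matrix()] (QC rows excluded)
#' @param scores numeric response, one per sample; samples with `NA` score
#'   are dropped
#' @param method `"pls"` or `"rf"` (random forest)
#' @param n_components latent variables for the PLS branch
#' @param num_trees trees for the RF branch
#' @param seed RNG seed (the RF branch is deterministic given it)
#' @return object of class `regression_diagnostics`: `observed`,
#'   `predicted` (cross-validated), `q2`, `slope`, `intercept`, `method`
#' @export
regress_against_score <- function(m, scores, method = c("pls", "rf"),
                                  n_components = 5, num_trees = 500,
                                  seed = 1L) {
  method <- match.arg(method)
  if (inherits(m, "feature_matrix")) {
    keep <- non_qc_idx(m)
    if (length(scores) == nrow(m$intensities)) scores <- scores[keep]
    m <- m$intensities[keep, , drop = FALSE]
  }
  x <- as.matrix(m)
  ok <- !is.na(scores)
  x <- x[ok, , drop = FALSE]
  yv <- scores[ok]
  if (stats::sd(yv) == 0)
    stop("scores are constant: regression undefined", call. = FALSE)
  n <- nrow(x)
  pred <- numeric(n)
  seeds <- derive_seeds(seed, n)
  for (i in seq_len(n)) {
    if (method == "pls") {
      fit <- pls_regress(x[-i, , drop = FALSE], yv[-i], n_components)
      pred[i] <- drop(sweep(x[i, , drop = FALSE], 2, fit$xc) %*% fit$b) + fit$yc
    } else {
      rf <- ranger::ranger(x = x[-i, , drop = FALSE], y = yv[-i],
                           num.trees = num_trees, seed = seeds[i],
                           num.threads = 1)
      pred[i] <- stats::predict(rf, data = x[i, , drop = FALSE],
                                num.threads = 1)$predictions
    }
  }
  press <- sum((pred - yv)^2)
  tss <- sum((yv - mean(yv))^2)
  fit_line <- stats::lm(pred ~ yv)
  structure(list(observed = yv, predicted = pred,
                 q2 = 1 - press / tss,
                 slope = unname(stats::coef(fit_line)[2]),
                 intercept = unname(stats::coef(fit_line)[1]),
                 method = method),
            class = "regression_diagnostics")
}

# Univariate-response NIPALS PLS (PLS1), shared by the regression branch.
pls_regress <- function(x, yv, n_components) {
  xc <- colMeans(x); yc <- mean(yv)
  X <- sweep(x, 2, xc); Yd <- yv - yc
  A <- min(n_components, nrow(x) - 1, ncol(x))
  W <- NULL; P <- NULL; Q <- numeric(0)
  for (a in seq_len(A)) {
    w <- crossprod(X, Yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    tt <- X %*% w
    qq <- sum(Yd * tt) / sum(tt^2)
    pp <- crossprod(X, tt) / sum(tt^2)
    X <- X - tcrossprod(tt, pp)
    Yd <- Yd - qq * tt
    W <- cbind(W, w); P <- cbind(P, pp); Q <- c(Q, qq)
  }
  if (is.null(W)) return(list(b = matrix(0, ncol(x), 1), xc = xc, yc = yc))
  b <- W %*% solve(crossprod(P, W), Q)
  list(b = b, xc = xc, yc = yc)
}

#' @export
print.regression_diagnostics <- function(x, ...) {
  cat(sprintf("%s regression (leave-one-out): Q^2 = %.3f\n",
              toupper(x$method), x$q2))
  cat(sprintf("predicted-vs-observed: slope %.3f, intercept %.3f (identity line: 1, 0)\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Principal component overview
#'
#' Centered (optionally unit-variance scaled) PCA of the study samples
#' with explained-variance fractions sorted in decreasing order.
#' Deterministic sign convention: each component is flipped so its
#' largest-magnitude loading is positive.
#'
#' @param m matrix or [feature_matrix()] (QC rows excluded)
#' @param n_components number of components to return
#' @param scale. unit-variance scale before decomposition
#' @return object of class `ordination_result` with `coordinates`
#'   (samples x axes), `explained` (variance fractions, all components),
#'   `loadings`, `method = "pca"`
#' @export
pca_overview <- function(m, n_components = 2, scale. = FALSE) {
  if (inherits(m, "feature_matrix"))
    m <- m$intensities[non_qc_idx(m), , drop = FALSE]
  x <- as.matrix(m)
  if (scale.) {
    s <- apply(x, 2, stats::sd)
    x <- x[, s > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$x))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  coords <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      coords[, j] <- -coords[, j]
    }
  }
  structure(list(coordinates = coords, explained = expl, loadings = rot,
                 negative_eigenvalues = numeric(0), method = "pca"),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  k <- ncol(x$coordinates)
  cat("<ordination_result> ", x$method, ": ", nrow(x$coordinates),
      " samples x ", k, " axes\n", sep = "")
  cat("  explained:", paste0(sprintf("%.1f%%", 100 * x$explained[seq_len(min(k, length(x$explained)))]),
                             collapse = ", "), "\n")
  if (length(x$negative_eigenvalues))
    cat("  ", length(x$negative_eigenvalues),
        " negative eigenvalue(s) excluded from coordinates\n", sep = "")
  invisible(x)
}
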