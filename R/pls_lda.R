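#' Partial least squares linear discriminant analysis
#'
#' Fits a PLS2 regression of the one-hot class indicator matrix on the
#' feature matrix by iterative latent-variable extraction with deflation
#' (NIPALS), then classifies by the class whose predicted indicator
#' response is maximal. This is the common "PLS-LDA" reading in
#' chemometrics; an alternative that fits a linear discriminant on the
#' latent scores is available via `lda_on_scores = TRUE`.
#'
#' The fit is deterministic: no randomness is involved. Ties in the
#' response argmax are broken toward the class listed first in the
#' encoding (the first factor level).
#'
#' @param x numeric matrix (samples x features) or a [feature_matrix()]
#'   (QC rows are excluded automatically).
#' @param y class labels, one per sample (coerced to factor; its levels
#'   define the class encoding order).
#' @param n_components number of latent variables (default 5). Values
#'   exceeding the data rank are reduced with a warning recorded in the
#'   model's `notes`.
#' @param center,scale. center/scale columns before extraction. Data that
#'   have been Z-score normalized need no further scaling, hence
#'   `scale. = FALSE` by default.
#' @param lda_on_scores fit `MASS::lda` on the latent scores instead of
#'   classifying by the maximal predicted response.
#' @return an object of class `pls_lda` with components `weights` (W),
#'   `loadings` (P), `y_loadings` (Q), `scores` (T), `coefficients`
#'   (regression coefficients on the original feature scale), `classes`,
#'   `x_center`, `x_scale`, `y_center`, `n_components`, `notes`.
#' @seealso [predict.pls_lda()], [loo_cross_validate()]
#' @export
pls_lda <- function(x, y, n_components = 5, center = TRUE, scale. = FALSE,
                    lda_on_scores = FALSE) {
  if (inherits(x, "feature_matrix")) {
    keep <- non_qc_idx(x)
    if (length(y) == nrow(x$intensities)) y <- y[keep]
    x <- x$intensities[keep, , drop = FALSE]
  }
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("need at least 2 classes", call. = FALSE)
  if (length(y) != nrow(x)) stop("labels must match sample count", call. = FALSE)
  n <- nrow(x); p <- ncol(x); k <- nlevels(y)

  xc <- if (center) colMeans(x) else rep(0, p)
  xs <- if (scale.) {
    s <- apply(x, 2, stats::sd); s[s == 0] <- 1; s
  } else rep(1, p)
  X <- sweep(sweep(x, 2, xc), 2, xs, `/`)
  Ymat <- stats::model.matrix(~ y - 1)
  colnames(Ymat) <- levels(y)
  yc <- colMeans(Ymat)
  Y <- sweep(Ymat, 2, yc)

  A <- min(n_components, n - 1, p)
  notes <- character()
  if (A < n_components)
    notes <- c(notes, sprintf(
      "n_components reduced from %d to %d (limited by min(n-1, p))",
      n_components, A))

  W <- matrix(0, p, A); P <- matrix(0, p, A); Q <- matrix(0, k, A)
  Tm <- matrix(0, n, A)
  Xd <- X; Yd <- Y
  a <- 0
  tol <- 1e-12
  for (comp in seq_len(A)) {
    u <- Yd[, which.max(apply(Yd, 2, stats::var))]
    if (sum(u^2) < tol || sum(Xd^2) < tol) break
    t_old <- rep(0, n)
    for (it in seq_len(500)) {
      w <- crossprod(Xd, u)
      nw <- sqrt(sum(w^2))
      if (nw < tol) break
      w <- w / nw
      tt <- Xd %*% w
      qq <- crossprod(Yd, tt) / sum(tt^2)
      u <- Yd %*% qq / sum(qq^2)
      if (sum((tt - t_old)^2) < tol * max(1, sum(tt^2))) break
      t_old <- tt
    }
    if (nw < tol || sum(tt^2) < tol) break
    pp <- crossprod(Xd, tt) / sum(tt^2)
    Xd <- Xd - tcrossprod(tt, pp)
    Yd <- Yd - tcrossprod(tt, qq)
    a <- a + 1
    W[, a] <- w; P[, a] <- pp; Q[, a] <- qq; Tm[, a] <- tt
  }
  if (a < A) {
    notes <- c(notes, sprintf(
      "extraction stopped after %d component(s): residual rank exhausted", a))
    W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
    Q <- Q[, seq_len(a), drop = FALSE]; Tm <- Tm[, seq_len(a), drop = FALSE]
  }
  if (a == 0) stop("no latent variable could be extracted", call. = FALSE)
  if (length(notes)) warning(paste(notes, collapse = "; "), call. = FALSE)

  # B maps (centered, scaled) X to centered Y: B = W (P'W)^-1 Q'
  B <- W %*% solve(crossprod(P, W), t(Q))
  dimnames(B) <- list(colnames(x), levels(y))

  lda_fit <- NULL
  if (lda_on_scores) {
    if (!requireNamespace("MASS", quietly = TRUE))
      stop("lda_on_scores = TRUE requires the MASS package", call. = FALSE)
    lda_fit <- MASS::lda(Tm, grouping = y)
  }

  structure(list(weights = W, loadings = P, y_loadings = Q, scores = Tm,
                 coefficients = B, classes = levels(y), y = y,
                 x_center = xc, x_scale = xs, y_center = yc,
                 n_components = a, lda_fit = lda_fit, notes = notes,
                 call = match.call()),
            class = "pls_lda")
}

#' Predict method for PLS-LDA models
#'
#' @param object a [pls_lda()] model
#' @param newdata matrix or [feature_matrix()] of samples to classify
#' @param type `"class"` (default) for predicted labels, `"response"` for
#'   the predicted class-indicator matrix, `"scores"` for latent-variable
#'   projections
#' @param ... unused
#' @return factor, matrix of responses, or matrix of scores
#' @export
predict.pls_lda <- function(object, newdata,
                            type = c("class", "response", "scores"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_matrix"))
    newdata <- newdata$intensities[non_qc_idx(newdata), , drop = FALSE]
  X <- sweep(sweep(as.matrix(newdata), 2, object$x_center), 2,
             object$x_scale, `/`)
  if (type == "scores" || !is.null(object$lda_fit)) {
    # project through the deflation basis: T = X W (P'W)^-1
    Tn <- X %*% object$weights %*%
      solve(crossprod(object$loadings, object$weights))
    if (type == "scores") return(Tn)
  }
  if (!is.null(object$lda_fit))
    return(stats::predict(object$lda_fit, Tn)$class)
  resp <- sweep(X %*% object$coefficients, 2, object$y_center, `+`)
  if (type == "response") return(resp)
  factor(object$classes[max.col(resp, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.pls_lda <- function(x, ...) {
  cat("PLS-LDA model: ", x$n_components, " latent variable(s), ",
      length(x$classes), " classes (", paste(x$classes, collapse = ", "),
      "), ", nrow(x$coefficients), " features\n", sep = "")
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' @export
coef.pls_lda <- function(object, ...) object$coefficients

#' @export
summary.pls_lda <- function(object, ...) {
  # fitted training responses are the accumulated t_a q_a' contributions
  pred <- factor(object$classes[max.col(
    sweep(object$scores %*% t(object$y_loadings), 2, object$y_center, `+`),
    ties.method = "first")], levels = object$classes)
  tab <- table(truth = object$y, predicted = pred)
  out <- list(model = object, training_table = tab)
  class(out) <- "summary.pls_lda"
  out
}

#' @export
print.summary.pls_lda <- function(x, ...) {
  print(x$model)
  cat("training confusion (rows = truth):\n")
  print(x$training_table)
  invisible(x)
}
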