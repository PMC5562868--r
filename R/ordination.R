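# Beta-diversity statistics for pathway-abundance count tables.

#' Rarefy a count table
#'
#' Subsamples every row without replacement to exactly `depth` counts;
#' samples whose total falls below `depth` are dropped and reported.
#' Deterministic given the seed.
#'
#' @param m a [feature_matrix()] of non-negative integer counts
#' @param depth target per-sample total; `NULL` (default) uses the minimum
#'   row total
#' @param seed RNG seed
#' @return a [feature_matrix()]; `attr(, "dropped")` lists removed samples
#' @export
rarefy <- function(m, depth = NULL, seed = 1L) {
  stopifnot(inherits(m, "feature_matrix"))
  x <- m$intensities
  if (any(x != round(x)) || any(x < 0))
    stop("rarefaction needs non-negative integer counts", call. = FALSE)
  totals <- rowSums(x)
  if (is.null(depth)) depth <- min(totals)
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  keep <- totals >= depth
  dropped <- m$sample_meta$sample_id[!keep]
  x <- x[keep, , drop = FALSE]
  out <- with_seed(seed, {
    t(apply(x, 1, function(row) {
      if (sum(row) == depth) return(row)
      # draw `depth` individuals without replacement from the row's pool
      picked <- sample.int(sum(row), depth)
      breaks <- c(0, cumsum(row))
      as.numeric(table(factor(findInterval(picked, breaks, left.open = TRUE),
                              levels = seq_along(row))))
    }))
  })
  dimnames(out) <- dimnames(x)
  fm <- feature_matrix(out, m$sample_meta[keep, , drop = FALSE], m$feature_meta)
  attr(fm, "dropped") <- dropped
  fm
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(a, b) = sum|a_i - b_i| / sum(a_i + b_i)` between non-negative
#' abundance rows; bounded in [0, 1], 0 for identical rows, 1 for
#' disjoint supports.
#'
#' @param m a [feature_matrix()] or non-negative numeric matrix
#' @return object of class `dist_matrix`: square symmetric matrix with a
#'   zero diagonal, dimnames = sample ids
#' @export
bray_curtis <- function(m) {
  x <- if (inherits(m, "feature_matrix")) m$intensities else as.matrix(m)
  if (any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  zero <- rowSums(x) == 0
  if (any(zero))
    stop("all-zero row(s): ",
         paste(rownames(x)[zero] %||% which(zero), collapse = ", "),
         call. = FALSE)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    num <- rowSums(abs(sweep(x[(i + 1):n, , drop = FALSE], 2, x[i, ])))
    den <- rowSums(sweep(x[(i + 1):n, , drop = FALSE], 2, x[i, ], `+`))
    d[i, (i + 1):n] <- d[(i + 1):n, i] <- num / den
  }
  structure(d, class = c("dist_matrix", "matrix"))
}

as_dist_matrix <- function(d) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d))
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric",
                                       call. = FALSE)
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal",
                                      call. = FALSE)
  d
}

#' Principal coordinate analysis
#'
#' Classical metric scaling of a dissimilarity matrix: Gower
#' double-centering followed by eigen-decomposition. Axes with negative
#' eigenvalues (non-Euclidean dissimilarities) are reported, not silently
#' dropped; coordinates use positive-eigenvalue axes only. Explained
#' fractions are eigenvalues over the sum of positive eigenvalues. Sign
#' convention: each axis is flipped so its largest-magnitude coordinate is
#' positive.
#'
#' @param d square symmetric dissimilarity matrix (e.g. [bray_curtis()])
#' @param n_axes number of axes to return (default: all positive)
#' @return object of class `ordination_result` with `coordinates`,
#'   `explained`, `eigenvalues`, `negative_eigenvalues`
#' @export
pcoa <- function(d, n_axes = NULL) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  # double-centering: B = -0.5 * J D^2 J
  a <- -0.5 * d^2
  B <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  e <- eigen(B, symmetric = TRUE)
  pos <- e$values > max(1e-9 * abs(e$values[1]), 1e-12)
  neg <- e$values[e$values < -max(1e-9 * abs(e$values[1]), 1e-12)]
  k_pos <- sum(pos)
  k <- if (is.null(n_axes)) k_pos else min(n_axes, k_pos)
  coords <- if (k > 0)
    e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(e$values[seq_len(k)]), k)
  else matrix(0, n, 0)
  for (j in seq_len(k)) {
    if (coords[which.max(abs(coords[, j])), j] < 0)
      coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(d)
  colnames(coords) <- if (k > 0) paste0("PCo", seq_len(k))
  expl <- if (k_pos > 0) e$values[seq_len(k_pos)] / sum(e$values[seq_len(k_pos)])
  else numeric(0)
  structure(list(coordinates = coords, explained = expl,
                 eigenvalues = e$values, negative_eigenvalues = neg,
                 method = "pcoa"),
            class = "ordination_result")
}

#' Permutational multivariate analysis of variance (one-way)
#'
#' Partitions the total sum of squared dissimilarities into between- and
#' within-group components (Gower-centered decomposition), forms the
#' pseudo-F statistic, and assesses significance by seeded label
#' permutation: `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations)`.
#' With `n_permutations = "exhaustive"` all distinct label arrangements
#' are enumerated (feasible for small n) and the p-value is exact.
#'
#' @param d square symmetric dissimilarity matrix
#' @param grouping factor-like group label per sample (>= 2 groups)
#' @param n_permutations count of random permutations (default 999) or
#'   `"exhaustive"`
#' @param seed RNG seed for the permutations
#' @return object of class `permanova_result` with `pseudo_f`,
#'   `r_squared`, `p_value`, `df_between`, `df_within`, `n_permutations`
#' @export
permanova <- function(d, grouping, n_permutations = 999, seed = 1L) {
  d <- as_dist_matrix(d)
  g <- droplevels(as.factor(grouping))
  n <- nrow(d)
  stopifnot(length(g) == n)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  stat <- function(grp) {
    # SS_total = sum of squared d over all pairs / n; SS_within summed per
    # group the same way; McArdle-Anderson partition.
    d2 <- d^2
    ss_total <- sum(d2[upper.tri(d2)]) / n
    ss_within <- 0
    for (lev in levels(grp)) {
      i <- which(grp == lev)
      if (length(i) > 1) {
        sub <- d2[i, i]
        ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(i)
      }
    }
    c(ss_total = ss_total, ss_within = ss_within)
  }
  k <- nlevels(g)
  obs <- stat(g)
  ss_between <- obs["ss_total"] - obs["ss_within"]
  df_b <- k - 1
  df_w <- n - k
  f_obs <- (ss_between / df_b) / (obs["ss_within"] / df_w)
  r2 <- ss_between / obs["ss_total"]

  f_of <- function(grp) {
    s <- stat(grp)
    ((s["ss_total"] - s["ss_within"]) / df_b) / (s["ss_within"] / df_w)
  }
  if (identical(n_permutations, "exhaustive")) {
    # the statistic depends only on which samples share a label, so
    # enumerate the distinct labeled group assignments (multinomial many)
    assignments <- enumerate_groupings(as.integer(table(g)))
    f_perm <- vapply(assignments, function(idx) {
      grp <- integer(n)
      for (lev in seq_along(idx)) grp[idx[[lev]]] <- lev
      f_of(factor(grp))
    }, numeric(1))
    p <- mean(f_perm >= f_obs - 1e-12)
    n_perm <- length(assignments)
  } else {
    f_perm <- with_seed(seed, vapply(seq_len(n_permutations),
                                     function(i) f_of(g[sample.int(n)]),
                                     numeric(1)))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_permutations)
    n_perm <- n_permutations
  }
  structure(list(pseudo_f = unname(f_obs), r_squared = unname(r2),
                 p_value = unname(p), df_between = df_b, df_within = df_w,
                 n_permutations = n_perm),
            class = "permanova_result")
}

# All distinct assignments of 1..sum(sizes) into labeled groups of the
# given sizes (used for exact PERMANOVA on tiny n). Each assignment is a
# list of index vectors, one per group.
enumerate_groupings <- function(sizes) {
  rec <- function(avail, sizes_left) {
    if (length(sizes_left) == 1) return(list(list(avail)))
    cs <- utils::combn(avail, sizes_left[1], simplify = FALSE)
    out <- vector("list", 0)
    for (cc in cs) {
      for (r in rec(setdiff(avail, cc), sizes_left[-1]))
        out[[length(out) + 1]] <- c(list(cc), r)
    }
    out
  }
  rec(seq_len(sum(sizes)), sizes)
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (one-way): pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$pseudo_f, x$r_squared, x$p_value, x$n_permutations))
  invisible(x)
}
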