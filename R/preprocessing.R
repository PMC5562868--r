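# Reliability filtering and normalization of an aligned feature matrix.
# Canonical pipeline order: noise threshold -> singleton removal -> QC
# reliability -> correlation filter -> Z-score normalization; each filter
# removes columns only and appends a filter_report entry.

filter_report <- function(name, params, features_in, removed_ids, notes = character()) {
  structure(list(name = name, params = params,
                 features_in = features_in,
                 features_out = features_in - length(removed_ids),
                 removed = removed_ids, notes = notes),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> ", x$name, ": ", x$features_in, " -> ", x$features_out,
      " features (", length(x$removed), " removed)\n", sep = "")
  if (length(x$params))
    cat("  params: ", paste(names(x$params), unlist(x$params), sep = "=",
                            collapse = ", "), "\n", sep = "")
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

drop_features <- function(m, drop_idx) {
  if (!length(drop_idx)) return(m)
  rt <- attr(m, "rt_obs")
  out <- m[, -drop_idx]
  if (!is.null(rt)) attr(out, "rt_obs") <- rt[, -drop_idx, drop = FALSE]
  out
}

#' Remove low-intensity noise features
#'
#' Drops features whose maximum intensity across study (non-QC) samples
#' falls below the noise threshold. Sample rows are untouched.
#'
#' @param m a [feature_matrix()]
#' @param threshold noise threshold in intensity units (the routine
#'   first-pass value is 1e5; a stricter re-processing pass uses 1e6)
#' @return list with elements `matrix` (filtered [feature_matrix()]) and
#'   `report` (a `filter_report`)
#' @export
noise_threshold_filter <- function(m, threshold = 1e5) {
  stopifnot(inherits(m, "feature_matrix"), threshold >= 0)
  idx <- non_qc_idx(m)
  if (!length(idx)) idx <- seq_len(nrow(m$intensities))
  maxima <- apply(m$intensities[idx, , drop = FALSE], 2, max)
  drop <- which(maxima < threshold)
  rep <- filter_report("noise_threshold", list(threshold = threshold),
                       ncol(m$intensities), m$feature_meta$feature_id[drop])
  list(matrix = drop_features(m, drop), report = rep)
}

#' Remove singleton features
#'
#' Drops features detected (intensity above the floor) in exactly one study
#' sample — the standard reading of "singleton" removal in untargeted
#' metabolomics.
#'
#' @param m a [feature_matrix()]
#' @param detection_floor intensity above which a feature counts as detected
#' @return list with `matrix` and `report`
#' @export
singleton_filter <- function(m, detection_floor = 0) {
  stopifnot(inherits(m, "feature_matrix"))
  idx <- non_qc_idx(m)
  n_det <- colSums(m$intensities[idx, , drop = FALSE] > detection_floor)
  drop <- which(n_det == 1L)
  rep <- filter_report("singleton", list(detection_floor = detection_floor),
                       ncol(m$intensities), m$feature_meta$feature_id[drop])
  list(matrix = drop_features(m, drop), report = rep)
}

#' Per-feature pooled-QC statistics
#'
#' For every feature: the fraction of QC injections in which it is detected
#' (intensity above the detection floor), the relative standard deviation
#' (sd/mean) of its QC peak areas, and — when a per-injection RT matrix is
#' available — the RSD of its QC retention times. RSD is flagged `NA` when
#' the QC mean is zero.
#'
#' @param m a [feature_matrix()] containing at least 2 QC rows
#' @param rt_obs optional numeric matrix of per-injection retention times,
#'   same dimensions as the intensity matrix (generated cohorts attach one
#'   as `attr(m, "rt_obs")`)
#' @param detection_floor detection threshold for QC presence
#' @return data.frame of class `qc_stats` with columns `feature_id`,
#'   `qc_presence`, `area_rsd`, `rt_rsd`
#' @export
qc_stats <- function(m, rt_obs = attr(m, "rt_obs"), detection_floor = 0) {
  stopifnot(inherits(m, "feature_matrix"))
  qi <- qc_idx(m)
  if (length(qi) < 2)
    stop("QC statistics require at least 2 QC rows (found ", length(qi), ")",
         call. = FALSE)
  q <- m$intensities[qi, , drop = FALSE]
  presence <- colMeans(q > detection_floor)
  area_rsd <- apply(q, 2, rsd)
  rt_rsd <- rep(NA_real_, ncol(q))
  if (!is.null(rt_obs)) {
    stopifnot(all(dim(rt_obs) == dim(m$intensities)))
    rt_rsd <- apply(rt_obs[qi, , drop = FALSE], 2, rsd)
  }
  structure(data.frame(feature_id = m$feature_meta$feature_id,
                       qc_presence = presence, area_rsd = area_rsd,
                       rt_rsd = rt_rsd, row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("qc_stats", "data.frame"))
}

#' QC reliability filter
#'
#' Keeps features that are reproducible across the pooled-QC injections:
#' detected in at least `min_presence` of QCs, with peak-area RSD at most
#' `max_area_rsd`, and (when RT observations are supplied) retention-time
#' RSD at most `max_rt_rsd`. All supplied criteria must hold
#' simultaneously. QC statistics are returned for every feature, kept or
#' removed.
#'
#' @param m a [feature_matrix()] with >= 2 QC rows
#' @param min_presence minimum QC detection fraction (default 0.80)
#' @param max_area_rsd maximum peak-area RSD (default 0.30)
#' @param max_rt_rsd maximum retention-time RSD (default 0.05)
#' @param rt_obs optional per-injection RT matrix; when absent the RT
#'   criterion is skipped and the report says so
#' @param detection_floor detection threshold for presence
#' @return list with `matrix`, `stats` (a [qc_stats()] frame) and `report`
#' @export
qc_reliability_filter <- function(m, min_presence = 0.80, max_area_rsd = 0.30,
                                  max_rt_rsd = 0.05,
                                  rt_obs = attr(m, "rt_obs"),
                                  detection_floor = 0) {
  st <- qc_stats(m, rt_obs = rt_obs, detection_floor = detection_floor)
  bad <- st$qc_presence < min_presence |
    is.na(st$area_rsd) | st$area_rsd > max_area_rsd
  notes <- character()
  if (is.null(rt_obs)) {
    notes <- "RT observations absent: retention-time RSD criterion skipped"
  } else {
    bad <- bad | is.na(st$rt_rsd) | st$rt_rsd > max_rt_rsd
  }
  drop <- which(bad)
  rep <- filter_report("qc_reliability",
                       list(min_presence = min_presence,
                            max_area_rsd = max_area_rsd,
                            max_rt_rsd = if (is.null(rt_obs)) NA else max_rt_rsd),
                       ncol(m$intensities),
                       m$feature_meta$feature_id[drop], notes)
  list(matrix = drop_features(m, drop), stats = st, report = rep)
}

#' Correlation filter
#'
#' Greedy de-duplication of highly correlated features: features are
#' scanned in column order; each retained feature removes every later
#' feature whose absolute correlation with it reaches the threshold. The
#' result contains no retained pair with |r| >= threshold. Zero-variance
#' columns are treated as uncorrelated with everything and retained (noted
#' in the report).
#'
#' @param m a [feature_matrix()] with >= 2 samples
#' @param threshold absolute correlation at or above which the later
#'   feature is removed (default 0.98)
#' @param method `"pearson"` (default) or `"spearman"`
#' @param keep `"first"` (default, order-stable) or `"variance"` (keep the
#'   higher-variance member of each correlated set)
#' @return list with `matrix` and `report`
#' @export
correlation_filter <- function(m, threshold = 0.98,
                               method = c("pearson", "spearman"),
                               keep = c("first", "variance")) {
  stopifnot(inherits(m, "feature_matrix"), nrow(m$intensities) >= 2)
  method <- match.arg(method)
  keep <- match.arg(keep)
  idx <- non_qc_idx(m)
  if (!length(idx)) idx <- seq_len(nrow(m$intensities))
  x <- m$intensities[idx, , drop = FALSE]
  p <- ncol(x)
  v <- apply(x, 2, stats::var)
  const <- v == 0 | is.na(v)
  order_idx <- seq_len(p)
  if (keep == "variance") order_idx <- order(-v)
  # correlation on non-constant columns only; computed in one pass (p is a
  # few thousand at most after upstream filters)
  live <- which(!const)
  removed <- logical(p)
  if (length(live) >= 2) {
    cm <- abs(stats::cor(x[, live, drop = FALSE], method = method))
    pos <- match(order_idx, live)          # scan position within `live`
    for (k in seq_along(order_idx)) {
      j <- pos[k]
      if (is.na(j) || removed[order_idx[k]]) next
      later <- pos[seq_along(order_idx) > k]
      later <- later[!is.na(later)]
      hit <- later[cm[j, later] >= threshold & !removed[live[later]]]
      removed[live[hit]] <- TRUE
    }
  }
  drop <- which(removed)
  notes <- if (any(const))
    paste0(sum(const), " zero-variance column(s) treated as uncorrelated and retained")
  else character()
  rep <- filter_report("correlation",
                       list(threshold = threshold, method = method, keep = keep),
                       p, m$feature_meta$feature_id[drop], notes)
  list(matrix = drop_features(m, drop), report = rep)
}

#' Z-score normalization
#'
#' Scales every feature column to mean 0, standard deviation 1 (the unit
#' variance scaling convention of multivariate chemometrics software:
#' weight 1/sd_j around the mean). Location and scale are computed over
#' study (non-QC) samples with the population (n) denominator; QC rows are
#' transformed with the same parameters. Zero-variance columns map to all
#' zero and are flagged in `attr(, "zero_variance")`.
#'
#' @param m a [feature_matrix()] with >= 2 study samples
#' @return a [feature_matrix()]; attributes `center`, `scale`,
#'   `zero_variance` record the transform
#' @export
zscore_normalize <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  idx <- non_qc_idx(m)
  if (!length(idx)) idx <- seq_len(nrow(m$intensities))
  stopifnot(length(idx) >= 2)
  x <- m$intensities[idx, , drop = FALSE]
  n <- nrow(x)
  mu <- colMeans(x)
  sdp <- sqrt(colMeans(sweep(x, 2, mu)^2))        # population denominator
  zero <- sdp == 0
  sdp[zero] <- 1
  z <- sweep(sweep(m$intensities, 2, mu), 2, sdp, `/`)
  z[, zero] <- 0
  out <- m
  out$intensities <- z
  attr(out, "center") <- mu
  attr(out, "scale") <- sdp
  attr(out, "zero_variance") <- m$feature_meta$feature_id[zero]
  attr(out, "normalized") <- TRUE
  out
}

#' Internal-standard ratio normalization
#'
#' Divides every feature's intensity by the internal standard's intensity
#' in the same sample (endogenous compounds such as creatine or histidine
#' serve as the standard), cancelling per-sample dilution. The standard
#' column becomes all ones.
#'
#' @param m a [feature_matrix()]
#' @param standard_feature_id feature id of the internal standard; must be
#'   strictly positive in every sample
#' @return a [feature_matrix()]
#' @export
internal_standard_ratio <- function(m, standard_feature_id) {
  stopifnot(inherits(m, "feature_matrix"))
  j <- match(standard_feature_id, m$feature_meta$feature_id)
  if (is.na(j))
    stop("internal standard '", standard_feature_id, "' not found", call. = FALSE)
  s <- m$intensities[, j]
  bad <- which(!(s > 0))
  if (length(bad))
    stop("internal standard '", standard_feature_id,
         "' is zero or missing in sample(s): ",
         paste(m$sample_meta$sample_id[bad], collapse = ", "), call. = FALSE)
  out <- m
  out$intensities <- m$intensities / s
  out
}
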