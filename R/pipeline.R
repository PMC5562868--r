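# End-to-end pipeline runner: filtering -> normalization -> analyses, with
# a JSON report and a replayable run manifest.

pipeline_defaults <- function() list(
  input_dir = NULL,            # CSV triplet directory; NULL -> synthetic cohort
  synthetic = list(),          # overrides passed to cohort_config()
  out_dir = NULL,              # where report.json / manifest.json are written
  seed = 1L,
  noise_threshold = 1e5,
  singleton_filter = TRUE,
  qc_filter = TRUE,
  qc_min_presence = 0.80,
  qc_max_area_rsd = 0.30,
  qc_max_rt_rsd = 0.05,
  corr_threshold = 0.98,
  zscore = TRUE,
  discriminate = TRUE,         # PLS-LDA leave-one-out on the label column
  label_column = "genotype",
  n_components = 5L,
  regress = FALSE,             # score regression (rf) on score_column
  score_column = "colitis_score",
  regress_method = "rf",
  permtest = FALSE,            # feature-permutation importance test
  perm_repeats = 100L,
  perm_z_crit = 1.96,
  perm_num_trees = 500L)

#' Assemble a pipeline configuration
#'
#' Validated key-value configuration for [run_pipeline()]. Unknown keys
#' are rejected; every random stage draws from the single `seed`.
#'
#' @param ... configuration overrides; see the source of
#'   `metabophen:::pipeline_defaults` for the full key set
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg, m) {
  if (isTRUE(cfg$discriminate) && !cfg$label_column %in% names(m$sample_meta))
    stop("discrimination requested but label column '", cfg$label_column,
         "' is absent from sample metadata", call. = FALSE)
  if (isTRUE(cfg$permtest) && !cfg$label_column %in% names(m$sample_meta))
    stop("permutation test requested but label column '", cfg$label_column,
         "' is absent from sample metadata", call. = FALSE)
  if (isTRUE(cfg$regress) && !cfg$score_column %in% names(m$sample_meta))
    stop("regression requested but score column '", cfg$score_column,
         "' is absent from sample metadata", call. = FALSE)
  invisible(cfg)
}

#' Run the full preprocessing and analysis pipeline
#'
#' Stage order: noise threshold filter, singleton removal, QC reliability
#' filter, correlation filter, Z-score normalization, then the requested
#' analyses (PLS-LDA leave-one-out discrimination, score regression,
#' feature-permutation importance). QC rows inform the filter statistics
#' and are excluded before modelling. Input files are never mutated; all
#' artifacts go to `out_dir` (when set): a deterministic `report.json`
#' and a `manifest.json` echoing the configuration, seeds and filter
#' chain so the run can be replayed bit-identically.
#'
#' @param config a [pipeline_config()]
#' @param matrix optional [feature_matrix()] overriding the configured
#'   input source
#' @return list of class `run_manifest` (invisibly written to
#'   `manifest.json`); its `report` element holds the analysis results
#' @export
run_pipeline <- function(config = pipeline_config(), matrix = NULL) {
  cfg <- config
  m <- matrix
  if (is.null(m)) {
    m <- if (!is.null(cfg$input_dir)) read_feature_matrix(cfg$input_dir)
    else generate_cohort(do.call(cohort_config, cfg$synthetic), seed = cfg$seed)
  }
  validate_pipeline_config(cfg, m)
  chain <- list()
  push <- function(rep) chain[[length(chain) + 1]] <<- rep

  nf <- noise_threshold_filter(m, cfg$noise_threshold)
  m2 <- nf$matrix; push(nf$report)
  if (isTRUE(cfg$singleton_filter)) {
    sf <- singleton_filter(m2)
    m2 <- sf$matrix; push(sf$report)
  }
  qc_stats_out <- NULL
  if (isTRUE(cfg$qc_filter)) {
    rt <- attr(m, "rt_obs")
    if (!is.null(rt))
      rt <- rt[, match(m2$feature_meta$feature_id, m$feature_meta$feature_id),
               drop = FALSE]
    qf <- qc_reliability_filter(m2, cfg$qc_min_presence, cfg$qc_max_area_rsd,
                                cfg$qc_max_rt_rsd, rt_obs = rt)
    m2 <- qf$matrix; qc_stats_out <- qf$stats; push(qf$report)
  }
  cf <- correlation_filter(m2, cfg$corr_threshold)
  m2 <- cf$matrix; push(cf$report)
  if (isTRUE(cfg$zscore)) m2 <- zscore_normalize(m2)

  study <- non_qc_idx(m2)
  report <- list(
    features_in = ncol(m$intensities),
    features_out = ncol(m2$intensities),
    filter_chain = lapply(chain, function(r)
      list(name = r$name, params = r$params, features_in = r$features_in,
           features_out = r$features_out, n_removed = length(r$removed))))

  if (isTRUE(cfg$discriminate)) {
    labels <- m2$sample_meta[[cfg$label_column]][study]
    cv <- loo_cross_validate(m2, labels, n_components = cfg$n_components)
    report$discrimination <- list(
      accuracy = cv$accuracy, kappa = cv$kappa,
      table = as.data.frame.matrix(unclass(cv$table)),
      per_class = lapply(cv$per_class, function(pm)
        pm[c("tp", "fp", "tn", "fn", "recall", "precision", "sensitivity",
             "specificity", "f_measure")]))
  }
  if (isTRUE(cfg$regress)) {
    sc <- m2$sample_meta[[cfg$score_column]][study]
    rg <- regress_against_score(m2, sc, method = cfg$regress_method,
                                n_components = cfg$n_components,
                                seed = cfg$seed)
    report$regression <- rg[c("q2", "slope", "intercept", "method")]
  }
  if (isTRUE(cfg$permtest)) {
    labels <- m2$sample_meta[[cfg$label_column]][study]
    pt <- permutation_feature_test(m2, labels, n_repeats = cfg$perm_repeats,
                                   z_crit = cfg$perm_z_crit, seed = cfg$seed,
                                   num_trees = cfg$perm_num_trees)
    ord <- order(-pt$results$delta)
    report$permutation_test <- list(
      baseline_mean_ce = pt$baseline_mean_ce,
      baseline_sigma = pt$baseline_sigma,
      n_significant = sum(pt$results$significant),
      results = pt$results[ord, ])
  }

  cfg_echo <- unclass(cfg)
  if (!is.null(cfg_echo$synthetic$n_per_group))
    cfg_echo$synthetic$n_per_group <- as.list(cfg_echo$synthetic$n_per_group)
  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("metabophen")),
    config = cfg_echo,
    seed = cfg$seed,
    filter_chain = report$filter_chain,
    timestamp = format(Sys.time(), tz = "UTC"),
    report = report), class = "run_manifest")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest[setdiff(names(manifest), "report")],
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(manifest)
}

#' Replay a pipeline run from its manifest
#'
#' Re-executes [run_pipeline()] with the configuration echoed in a
#' `manifest.json`, reproducing the original report bit-identically (the
#' manifest records every seed actually used).
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [run_pipeline()], or a `run_manifest` object
#' @param out_dir optional output directory overriding the recorded one
#' @return the new `run_manifest`
#' @export
replay_manifest <- function(manifest_path, out_dir = NULL) {
  cfg <- if (inherits(manifest_path, "run_manifest")) manifest_path$config
  else jsonlite::read_json(manifest_path, simplifyVector = TRUE)$config
  cfg <- cfg[!vapply(cfg, function(v) is.null(v) || (is.list(v) && !length(v)),
                     logical(1)) | names(cfg) == "synthetic"]
  cfg$synthetic <- as.list(cfg$synthetic)
  if (!is.null(cfg$synthetic$n_per_group))
    cfg$synthetic$n_per_group <- unlist(cfg$synthetic$n_per_group)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  run_pipeline(do.call(pipeline_config, cfg))
}
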