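#' Construct a feature matrix
#'
#' The universal currency of the pipeline: a samples x features intensity
#' matrix bundled with per-sample metadata (genotype, age group, QC flag,
#' colitis score) and per-feature metadata (m/z, retention time, ionisation
#' mode, acquisition window, internal-standard flag).
#'
#' @param intensities numeric matrix, rows = samples, columns = features.
#'   Raw intensity tables are non-negative; normalized (Z-scored) tables
#'   may contain negative values. Row and column names are taken as
#'   sample/feature ids if
#'   `sample_meta`/`feature_meta` are not supplied.
#' @param sample_meta data.frame with columns `sample_id`, `genotype`
#'   (`"WT"`, `"KO"` or `"QC"`), `age_group` (`"6"`, `"18"` or `NA`),
#'   `qc_flag` (logical), `colitis_score` (non-negative numeric or `NA`).
#' @param feature_meta data.frame with columns `feature_id`, `mz` (Da),
#'   `rt` (minutes), `mode` (`"pos"`/`"neg"`), `window` (acquisition window
#'   label), `is_internal_standard` (logical). Generator output additionally
#'   carries ground-truth columns `is_genotype_feature`, `is_age_feature`,
#'   `is_noise_feature`.
#' @return An object of class `feature_matrix`: a list with elements
#'   `intensities`, `sample_meta`, `feature_meta`.
#' @export
feature_matrix <- function(intensities, sample_meta = NULL, feature_meta = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(sample_meta)) {
    ids <- rownames(intensities) %||% paste0("S", seq_len(nrow(intensities)))
    sample_meta <- data.frame(sample_id = ids, genotype = NA_character_,
                              age_group = NA_character_, qc_flag = FALSE,
                              colitis_score = NA_real_,
                              stringsAsFactors = FALSE)
  }
  if (is.null(feature_meta)) {
    ids <- colnames(intensities) %||% paste0("F", seq_len(ncol(intensities)))
    feature_meta <- data.frame(feature_id = ids, mz = NA_real_, rt = NA_real_,
                               mode = NA_character_, window = NA_character_,
                               is_internal_standard = FALSE,
                               stringsAsFactors = FALSE)
  }
  obj <- structure(list(intensities = intensities,
                        sample_meta = as.data.frame(sample_meta),
                        feature_meta = as.data.frame(feature_meta)),
                   class = "feature_matrix")
  validate_feature_matrix(obj)
}

validate_feature_matrix <- function(x) {
  stopifnot(inherits(x, "feature_matrix"))
  m <- x$intensities
  if (nrow(m) != nrow(x$sample_meta))
    stop("intensity rows (", nrow(m), ") != sample_meta rows (",
         nrow(x$sample_meta), ")", call. = FALSE)
  if (ncol(m) != nrow(x$feature_meta))
    stop("intensity columns (", ncol(m), ") != feature_meta rows (",
         nrow(x$feature_meta), ")", call. = FALSE)
  if (anyDuplicated(x$sample_meta$sample_id))
    stop("duplicate sample ids: ",
         paste(unique(x$sample_meta$sample_id[duplicated(x$sample_meta$sample_id)]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(x$feature_meta$feature_id))
    stop("duplicate feature ids: ",
         paste(unique(x$feature_meta$feature_id[duplicated(x$feature_meta$feature_id)]),
               collapse = ", "), call. = FALSE)
  rownames(x$intensities) <- x$sample_meta$sample_id
  colnames(x$intensities) <- x$feature_meta$feature_id
  x
}

#' @export
print.feature_matrix <- function(x, ...) {
  n_qc <- sum(x$sample_meta$qc_flag)
  cat("<feature_matrix> ", nrow(x$intensities), " samples (", n_qc, " QC) x ",
      ncol(x$intensities), " features\n", sep = "")
  grp <- table(paste0(x$sample_meta$genotype, x$sample_meta$age_group)[!x$sample_meta$qc_flag])
  if (length(grp)) {
    cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$intensities)

#' Subset a feature matrix by samples and/or features
#'
#' @param x a `feature_matrix`
#' @param i sample index (logical, integer or sample ids)
#' @param j feature index (logical, integer or feature ids)
#' @param ... unused
#' @return a `feature_matrix`
#' @export
`[.feature_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$intensities))
  if (missing(j)) j <- seq_len(ncol(x$intensities))
  if (is.character(i)) i <- match(i, x$sample_meta$sample_id)
  if (is.character(j)) j <- match(j, x$feature_meta$feature_id)
  feature_matrix(x$intensities[i, j, drop = FALSE],
                 x$sample_meta[i, , drop = FALSE],
                 x$feature_meta[j, , drop = FALSE])
}

# Convenience: rows that are study samples (not pooled QC injections).
non_qc_idx <- function(x) which(!x$sample_meta$qc_flag)
qc_idx <- function(x) which(x$sample_meta$qc_flag)

#' Write a feature matrix as a CSV triplet
#'
#' Writes `intensities.csv` (samples x features, first column `sample_id`),
#' `sample_meta.csv` and `feature_meta.csv` into `dir`. UTF-8, period
#' decimal separator, header rows.
#'
#' @param x a `feature_matrix`
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_feature_matrix <- function(x, dir) {
  stopifnot(inherits(x, "feature_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ints <- data.frame(sample_id = x$sample_meta$sample_id, x$intensities,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(ints, file.path(dir, "intensities.csv"), row.names = FALSE)
  utils::write.csv(x$sample_meta, file.path(dir, "sample_meta.csv"), row.names = FALSE)
  utils::write.csv(x$feature_meta, file.path(dir, "feature_meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a feature matrix from a CSV triplet
#'
#' Inverse of [write_feature_matrix()]. Validates id agreement between the
#' three files and fails with the offending ids on mismatch; rejects
#' non-numeric intensity cells (e.g. comma decimal separators) with a locale
#' hint.
#'
#' @param dir directory containing `intensities.csv`, `sample_meta.csv`,
#'   `feature_meta.csv`
#' @return a `feature_matrix`
#' @export
read_feature_matrix <- function(dir) {
  paths <- file.path(dir, c("intensities.csv", "sample_meta.csv", "feature_meta.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "), call. = FALSE)
  ints <- utils::read.csv(paths[1], check.names = FALSE, stringsAsFactors = FALSE)
  smeta <- utils::read.csv(paths[2], stringsAsFactors = FALSE)
  fmeta <- utils::read.csv(paths[3], stringsAsFactors = FALSE)
  for (nm in c("sample_id")) if (!nm %in% names(ints))
    stop("intensities.csv lacks column '", nm, "'", call. = FALSE)
  req_s <- c("sample_id", "genotype", "age_group", "qc_flag", "colitis_score")
  req_f <- c("feature_id", "mz", "rt", "mode", "window", "is_internal_standard")
  if (length(miss <- setdiff(req_s, names(smeta))))
    stop("sample_meta.csv lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (length(miss <- setdiff(req_f, names(fmeta))))
    stop("feature_meta.csv lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  ids <- ints$sample_id
  mat_cols <- setdiff(names(ints), "sample_id")
  m <- as.matrix(ints[, mat_cols, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- mat_cols[!vapply(ints[mat_cols], is.numeric, logical(1))]
    stop("non-numeric intensities in column(s) ", paste(utils::head(bad, 5), collapse = ", "),
         "; check the decimal separator (period required, comma rejected)",
         call. = FALSE)
  }
  if (length(extra <- setdiff(ids, smeta$sample_id)))
    stop("samples in intensities but absent from metadata: ",
         paste(extra, collapse = ", "), call. = FALSE)
  if (length(extra <- setdiff(smeta$sample_id, ids)))
    stop("samples in metadata but absent from intensities: ",
         paste(extra, collapse = ", "), call. = FALSE)
  if (length(extra <- setdiff(mat_cols, fmeta$feature_id)))
    stop("features in intensities but absent from feature metadata: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  if (length(extra <- setdiff(fmeta$feature_id, mat_cols)))
    stop("features in feature metadata but absent from intensities: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  smeta <- smeta[match(ids, smeta$sample_id), , drop = FALSE]
  fmeta <- fmeta[match(mat_cols, fmeta$feature_id), , drop = FALSE]
  rownames(m) <- ids
  smeta$qc_flag <- as.logical(smeta$qc_flag)
  smeta$age_group <- as.character(smeta$age_group)
  fmeta$is_internal_standard <- as.logical(fmeta$is_internal_standard)
  for (nm in intersect(c("is_genotype_feature", "is_age_feature", "is_noise_feature"),
                       names(fmeta)))
    fmeta[[nm]] <- as.logical(fmeta[[nm]])
  feature_matrix(m, smeta, fmeta)
}
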