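#' Construct a feature matrix
#'
#' The central container of the package: a samples x features intensity
#' matrix together with aligned per-sample acquisition metadata (analytical
#' batch, injection order, QC flag) and optional biological covariates.
#'
#' @param intensities Numeric matrix, samples in rows, features in columns.
#'   Row names are sample ids, column names feature ids (generated when
#'   absent).  `NA` marks a missing (e.g. below-LOD) measurement.
#' @param batch Vector of batch labels, one per sample (coerced to factor).
#' @param injection_order Positive integers, one per sample, unique within
#'   each batch: the position of the sample in the acquisition sequence.
#' @param is_qc Logical vector flagging pooled QC injections.
#' @param covariates Optional `data.frame` of per-sample biological
#'   covariates (group, age, sex, ...), row-aligned with `intensities`.
#' @param scale_flag Either `"raw"` (native intensity scale) or `"log2"`.
#'
#' @return An object of class `feature_matrix` with fields `intensities`,
#'   `batch`, `injection_order`, `is_qc`, `covariates`, `scale_flag`.
#'
#' @examples
#' fm <- feature_matrix(matrix(rnorm(12), 4, 3),
#'                      batch = c("a", "a", "b", "b"),
#'                      injection_order = c(1, 2, 3, 4))
#' fm
#' @seealso [validate_feature_matrix()], [read_feature_table()]
#' @export
feature_matrix <- function(intensities, batch,
                           injection_order = seq_len(nrow(intensities)),
                           is_qc = rep(FALSE, nrow(intensities)),
                           covariates = NULL,
                           scale_flag = c("raw", "log2")) {
  scale_flag <- match.arg(scale_flag)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  n <- nrow(intensities)
  if (is.null(rownames(intensities)))
    rownames(intensities) <- paste0("sample_", seq_len(n))
  if (is.null(colnames(intensities)))
    colnames(intensities) <- paste0("feature_", seq_len(ncol(intensities)))
  if (length(batch) != n)
    stop("`batch` must have one label per sample (", n, " expected, got ",
         length(batch), ")", call. = FALSE)
  if (length(injection_order) != n || length(is_qc) != n)
    stop("`injection_order` and `is_qc` must have one entry per sample",
         call. = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n)
      stop("`covariates` must have one row per sample", call. = FALSE)
    rownames(covariates) <- rownames(intensities)
  }
  fm <- structure(
    list(intensities     = intensities,
         batch           = factor(batch),
         injection_order = as.integer(injection_order),
         is_qc           = as.logical(is_qc),
         covariates      = covariates,
         scale_flag      = scale_flag),
    class = "feature_matrix")
  issues <- validate_feature_matrix(fm)
  hard <- issues[vapply(issues, function(i) i$severity == "error", logical(1))]
  if (length(hard))
    stop("invalid feature_matrix: ",
         paste(vapply(hard, function(i) i$message, character(1)),
               collapse = "; "), call. = FALSE)
  fm
}

#' Validate a feature matrix
#'
#' Checks the container invariants and returns a machine-readable list of
#' issues instead of raising: each issue has a `severity` (`"error"` or
#' `"warning"`), a short `code`, the affected `ids` and a human-readable
#' `message`.  An empty list means the object satisfies all invariants.
#' Small batches (< 2 non-QC samples) are reported as warnings here; they
#' only become errors when a correction model is fitted.
#'
#' @param fm A `feature_matrix`.
#' @return A list of issue records; `list()` when the object is valid.
#' @examples
#' fm <- feature_matrix(matrix(1:4, 2, 2), batch = c("a", "b"))
#' validate_feature_matrix(fm)  # batches of size 1 -> SMALL_BATCH warnings
#' @export
validate_feature_matrix <- function(fm) {
  issues <- list()
  add <- function(severity, code, ids, message)
    issues[[length(issues) + 1L]] <<-
      list(severity = severity, code = code, ids = ids, message = message)

  n <- nrow(fm$intensities)
  sid <- rownames(fm$intensities)
  if (anyDuplicated(sid))
    add("error", "DUP_SAMPLE", unique(sid[duplicated(sid)]),
        "duplicated sample ids")
  fid <- colnames(fm$intensities)
  if (anyDuplicated(fid))
    add("error", "DUP_FEATURE", unique(fid[duplicated(fid)]),
        "duplicated feature ids")
  if (length(fm$batch) != n || length(fm$injection_order) != n ||
      length(fm$is_qc) != n)
    add("error", "META_MISALIGNED", character(0),
        "metadata length does not match sample count")
  if (anyNA(fm$batch))
    add("error", "BATCH_NA", sid[is.na(fm$batch)],
        "samples without a batch label")
  if (any(!is.na(fm$injection_order) & fm$injection_order < 1L))
    add("error", "ORDER_NONPOS", sid[fm$injection_order < 1L],
        "injection_order must be positive")
  for (b in levels(fm$batch)) {
    in_b <- which(fm$batch == b)
    ord <- fm$injection_order[in_b]
    if (anyDuplicated(ord))
      add("error", "ORDER_DUP", sid[in_b[duplicated(ord)]],
          paste0("duplicated injection_order within batch ", b))
    if (sum(!fm$is_qc[in_b]) < 2L)
      add("warning", "SMALL_BATCH", b,
          paste0("batch ", b, " has < 2 non-QC samples"))
  }
  if (!fm$scale_flag %in% c("raw", "log2"))
    add("error", "BAD_SCALE", fm$scale_flag, "unknown scale_flag")
  if (fm$scale_flag == "raw" &&
      any(fm$intensities < 0, na.rm = TRUE))
    add("warning", "NEG_RAW", character(0),
        "negative intensities on the raw scale")
  issues
}

#' @export
print.feature_matrix <- function(x, ...) {
  n <- nrow(x$intensities); g <- ncol(x$intensities)
  cat("feature_matrix: ", n, " samples x ", g, " features (",
      x$scale_flag, " scale)\n", sep = "")
  cat("  batches: ", nlevels(x$batch), " (",
      paste(utils::head(levels(x$batch), 8), collapse = ", "),
      if (nlevels(x$batch) > 8) ", ..." else "", ")\n", sep = "")
  cat("  QC samples: ", sum(x$is_qc), "\n", sep = "")
  nm <- sum(is.na(x$intensities))
  cat("  missing entries: ", nm, " (",
      format(100 * nm / (n * g), digits = 3), "%)\n", sep = "")
  if (!is.null(x$covariates))
    cat("  covariates: ", paste(names(x$covariates), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$intensities)

# ---- internal helpers shared by the correction engines ----------------------

sample_ids  <- function(fm) rownames(fm$intensities)
feature_ids <- function(fm) colnames(fm$intensities)

#' Subset a feature matrix
#'
#' @param fm A `feature_matrix`.
#' @param samples,features Index vectors (logical, integer or names); `NULL`
#'   keeps everything.
#' @return The subsetted `feature_matrix`.
#' @export
subset_feature_matrix <- function(fm, samples = NULL, features = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(fm$intensities))
  if (is.character(samples)) samples <- match(samples, sample_ids(fm))
  if (is.logical(samples)) samples <- which(samples)
  if (is.null(features)) features <- seq_len(ncol(fm$intensities))
  if (is.character(features)) features <- match(features, feature_ids(fm))
  if (is.logical(features)) features <- which(features)
  fm$intensities <- fm$intensities[samples, features, drop = FALSE]
  fm$batch <- droplevels(fm$batch[samples])
  fm$injection_order <- fm$injection_order[samples]
  fm$is_qc <- fm$is_qc[samples]
  if (!is.null(fm$covariates))
    fm$covariates <- fm$covariates[samples, , drop = FALSE]
  fm
}

# stop unless the matrix is complete (corrections need every entry)
assert_complete <- function(fm, what) {
  if (anyNA(fm$intensities))
    stop(what, " requires a complete matrix; ",
         sum(is.na(fm$intensities)),
         " missing entries present (impute or filter first)", call. = FALSE)
  invisible(fm)
}

# batch sizes among the samples used for fitting
fit_batch_sizes <- function(fm, use_qc = FALSE) {
  keep <- if (use_qc) rep(TRUE, length(fm$is_qc)) else !fm$is_qc
  table(droplevels(fm$batch[keep]))
}
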