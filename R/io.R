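#' Read an intensity table and its sample metadata
#'
#' Builds a [feature_matrix()] from two delimited text files: an intensity
#' table (samples x features or features x samples) and a per-sample
#' metadata table.  The two are joined on sample id; the order of rows in
#' either file is not significant.
#'
#' @param intensity_path Path to the intensity CSV/TSV.  The first column
#'   (or the column named in `layout$id_col`) holds ids.
#' @param metadata_path Path to the per-sample metadata CSV/TSV.
#' @param layout Named list (or path to a YAML file holding one) describing
#'   the tables: `id_col` (default `"sample_id"`), `batch_col`
#'   (`"batch"`), `order_col` (`"injection_order"`), `qc_col` (`"is_qc"`,
#'   optional), `covariate_cols` (character vector, optional),
#'   `orientation` (`"samples_as_rows"`, the canonical form, or
#'   `"features_as_rows"`), `zero_is_missing` (`FALSE`), `scale_flag`
#'   (`"raw"`), `sep` (`NULL` = auto-detect comma vs tab from the header
#'   line).
#'
#' @details Non-numeric intensity cells and the sentinels `""`, `"NA"`,
#'   `"NaN"` become missing values; `0` does too when
#'   `layout$zero_is_missing` is `TRUE` (untargeted exports often write 0
#'   for not-detected).  Mismatched sample ids between the two files are a
#'   hard error listing the asymmetric difference; batches with fewer than
#'   2 non-QC samples are recorded as warnings and only fail at correction
#'   time.
#'
#' @return A validated `feature_matrix`.
#' @seealso [write_feature_table()]
#' @export
read_feature_table <- function(intensity_path, metadata_path, layout = list()) {
  layout <- resolve_layout(layout)
  for (p in c(intensity_path, metadata_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)

  int_raw <- read_delim_auto(intensity_path, layout$sep)
  meta    <- read_delim_auto(metadata_path, layout$sep)

  id_col <- layout$id_col
  if (!id_col %in% names(meta))
    stop("metadata table lacks the id column '", id_col, "'", call. = FALSE)

  ids_int <- as.character(int_raw[[1L]])
  mat <- as.matrix(int_raw[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(mat) <- "double")   # non-numeric -> NA
  rownames(mat) <- ids_int
  if (identical(layout$orientation, "features_as_rows")) mat <- t(mat)
  if (isTRUE(layout$zero_is_missing)) mat[!is.na(mat) & mat == 0] <- NA_real_

  ids_meta <- as.character(meta[[id_col]])
  if (anyDuplicated(rownames(mat)))
    stop("duplicated sample ids in intensity table: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(mat)))
    stop("duplicated feature ids in intensity table: ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(ids_meta))
    stop("duplicated sample ids in metadata table: ",
         paste(unique(ids_meta[duplicated(ids_meta)]), collapse = ", "),
         call. = FALSE)

  only_int  <- setdiff(rownames(mat), ids_meta)
  only_meta <- setdiff(ids_meta, rownames(mat))
  if (length(only_int) || length(only_meta))
    stop("sample ids do not match between tables.",
         if (length(only_int))
           paste0(" Only in intensities: ",
                  paste(only_int, collapse = ", "), "."),
         if (length(only_meta))
           paste0(" Only in metadata: ",
                  paste(only_meta, collapse = ", "), "."),
         call. = FALSE)
  meta <- meta[match(rownames(mat), ids_meta), , drop = FALSE]

  need <- c(layout$batch_col, layout$order_col)
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  is_qc <- if (layout$qc_col %in% names(meta))
    parse_flag(meta[[layout$qc_col]]) else rep(FALSE, nrow(meta))
  cov_cols <- intersect(layout$covariate_cols, names(meta))
  covariates <- if (length(cov_cols)) meta[, cov_cols, drop = FALSE] else NULL

  feature_matrix(mat,
                 batch           = meta[[layout$batch_col]],
                 injection_order = as.integer(meta[[layout$order_col]]),
                 is_qc           = is_qc,
                 covariates      = covariates,
                 scale_flag      = layout$scale_flag)
}

#' Write a feature matrix to delimited text files
#'
#' Inverse of [read_feature_table()]: writes the intensity matrix
#' (samples as rows) and the sample metadata as two CSV files.  Missing
#' entries are written as empty cells; re-reading reproduces finite
#' intensities bit-equal and preserves the missingness pattern and all
#' metadata.
#'
#' @param fm A valid `feature_matrix` with at least one feature.
#' @param intensity_path,metadata_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_feature_table <- function(fm, intensity_path, metadata_path) {
  if (ncol(fm$intensities) == 0L)
    stop("refusing to write a feature_matrix with 0 features", call. = FALSE)
  # %.17g guarantees the decimal text re-reads to the identical double
  chr <- matrix(sprintf("%.17g", fm$intensities),
                nrow(fm$intensities), ncol(fm$intensities),
                dimnames = dimnames(fm$intensities))
  chr[is.na(fm$intensities)] <- ""
  df <- data.frame(sample_id = sample_ids(fm),
                   chr, check.names = FALSE, stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.csv(df, intensity_path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("cannot write intensity table to '", intensity_path, "': ",
         conditionMessage(ok), call. = FALSE)
  meta <- data.frame(sample_id       = sample_ids(fm),
                     batch           = as.character(fm$batch),
                     injection_order = fm$injection_order,
                     is_qc           = fm$is_qc,
                     check.names = FALSE)
  if (!is.null(fm$covariates)) meta <- cbind(meta, fm$covariates)
  utils::write.csv(meta, metadata_path, row.names = FALSE, na = "")
  invisible(c(intensity_path, metadata_path))
}

# ---- internals --------------------------------------------------------------

default_layout <- function() {
  list(id_col = "sample_id", batch_col = "batch",
       order_col = "injection_order", qc_col = "is_qc",
       covariate_cols = character(0),
       orientation = "samples_as_rows",
       zero_is_missing = FALSE, scale_flag = "raw", sep = NULL)
}

resolve_layout <- function(layout) {
  if (is.character(layout) && length(layout) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML layout file requires the 'yaml' package",
           call. = FALSE)
    layout <- yaml::read_yaml(layout)
  }
  stopifnot(is.list(layout))
  out <- utils::modifyList(default_layout(), layout)
  if (!out$orientation %in% c("samples_as_rows", "features_as_rows"))
    stop("layout$orientation must be 'samples_as_rows' or 'features_as_rows'",
         call. = FALSE)
  out
}

read_delim_auto <- function(path, sep = NULL) {
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    na.strings = c("", "NA", "NaN"),
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}

parse_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(trimws(as.character(x)))
  x %in% c("true", "t", "1", "yes", "qc")
}
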