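#' Log2-transform raw intensities
#'
#' Replaces every finite entry y by log2(y + offset) and flips the scale
#' flag to `"log2"`.  Missing entries stay missing.  Strictly monotone
#' entry-wise, so within-feature orderings are preserved.
#'
#' @param fm A `feature_matrix` on the raw scale.
#' @param offset Non-negative pseudo-intensity added before the log; the
#'   default 0 assumes strictly positive measurements.
#' @return The transformed `feature_matrix` (`scale_flag == "log2"`).
#' @export
log2_transform <- function(fm, offset = 0) {
  if (fm$scale_flag != "raw")
    stop("log2_transform expects raw-scale intensities (scale_flag is '",
         fm$scale_flag, "')", call. = FALSE)
  if (offset < 0) stop("`offset` must be non-negative", call. = FALSE)
  bad <- which(!is.na(fm$intensities) & fm$intensities + offset <= 0,
               arr.ind = TRUE)
  if (nrow(bad)) {
    b <- bad[1L, ]
    stop("log2 undefined: intensity + offset <= 0 at (sample '",
         sample_ids(fm)[b[1L]], "', feature '", feature_ids(fm)[b[2L]],
         "')", if (nrow(bad) > 1L) paste0(" and ", nrow(bad) - 1L, " more"),
         call. = FALSE)
  }
  fm$intensities <- log2(fm$intensities + offset)
  fm$scale_flag <- "log2"
  fm
}

#' Filter features by presence in study samples
#'
#' Keeps features observed (non-missing) in at least `min_presence` of the
#' non-QC samples; QC injections do not count towards presence.
#'
#' @param fm A `feature_matrix`.
#' @param min_presence Required fraction of non-QC samples with an observed
#'   value, in `[0, 1]`.  0 keeps every feature.
#' @return The filtered `feature_matrix`; removed feature ids are recorded
#'   in `attr(, "removed_features")`.
#' @export
filter_features <- function(fm, min_presence = 0.8) {
  stopifnot(min_presence >= 0, min_presence <= 1)
  study <- !fm$is_qc
  frac <- colMeans(!is.na(fm$intensities[study, , drop = FALSE]))
  keep <- frac >= min_presence
  removed <- feature_ids(fm)[!keep]
  out <- subset_feature_matrix(fm, features = which(keep))
  attr(out, "removed_features") <- removed
  out
}

#' Impute missing intensities
#'
#' Missingness in MS feature tables is predominantly left-censored
#' (below-LOD), so the default replaces a feature's missing entries by half
#' of its minimum observed value on the current scale (`half_min`).  The
#' `knn` alternative replaces them by the mean of the `k` features most
#' correlated with the target feature, computed over samples where both are
#' observed.
#'
#' @param fm A `feature_matrix` in which every feature has at least one
#'   observed value (run [filter_features()] first otherwise).
#' @param method `"half_min"` (default) or `"knn"`.
#' @param k Number of neighbour features for `knn`.
#' @return A complete `feature_matrix`; observed entries are untouched.
#' @export
impute_missing <- function(fm, method = c("half_min", "knn"), k = 5L) {
  method <- match.arg(method)
  x <- fm$intensities
  n_obs <- colSums(!is.na(x))
  if (any(n_obs == 0L))
    stop("feature(s) entirely missing: ",
         paste(utils::head(feature_ids(fm)[n_obs == 0L], 5), collapse = ", "),
         ". Filter them out first (filter_features).", call. = FALSE)
  if (!anyNA(x)) return(fm)

  if (method == "half_min") {
    half_min <- apply(x, 2L, function(col) min(col, na.rm = TRUE) / 2)
    for (g in which(colSums(is.na(x)) > 0L))
      x[is.na(x[, g]), g] <- half_min[g]
  } else {
    stopifnot(k >= 1L)
    cc <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
    diag(cc) <- NA
    for (g in which(colSums(is.na(x)) > 0L)) {
      ord <- order(abs(cc[, g]), decreasing = TRUE, na.last = TRUE)
      nb <- ord[seq_len(min(k, sum(!is.na(cc[, g]))))]
      miss <- which(is.na(x[, g]))
      fill <- rowMeans(x[miss, nb, drop = FALSE], na.rm = TRUE)
      # neighbours can be jointly missing on a row; fall back to half-min
      fill[is.nan(fill)] <- min(x[, g], na.rm = TRUE) / 2
      x[miss, g] <- fill
    }
  }
  fm$intensities <- x
  fm
}
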