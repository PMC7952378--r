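#' QC-based lowess signal-drift correction
#'
#' The classical QC-sample comparator: per feature (and per batch by
#' default), a locally weighted regression (tricube weights, robustness
#' iterations) of the QC intensities on injection order estimates the
#' drift curve; the curve is evaluated at every sample's injection order by
#' linear interpolation between QC positions (constant extrapolation
#' beyond the first/last QC), and each intensity is scaled back to the
#' feature's reference level, defined as its median QC intensity.  On the
#' raw scale the correction is the ratio `y * reference / fitted`; on the
#' log2 scale it is the difference `y - (fitted - reference)`, the same
#' correction under the log.
#'
#' Features quantifiable in fewer than 3 QC injections in any required
#' fitting window are dropped and reported in `dropped_features` — the
#' structural weakness of QC-based correction: a compound below the
#' detection limit in the pooled QCs (a low-abundance metabolite diluted by
#' pooling) cannot be drift-corrected and is lost, even when it is
#' well measured in the study samples.
#'
#' @param fm A `feature_matrix` with QC injections flagged and
#'   `injection_order` present for all samples; missing values are allowed
#'   (missing study-sample entries stay missing).
#' @param frac Lowess span: fraction of QC points in the local window.
#' @param per_batch Fit one drift curve per batch (default) or a single
#'   curve over the whole run order.
#' @param iter Robustness iterations of the lowess fit.
#' @return A `batch_correction` fit; `internals$drift` holds, per kept
#'   feature and window, the QC orders and fitted drift levels;
#'   `internals$reference` the per-feature reference level.
#' @export
lowess_correct <- function(fm, frac = 0.5, per_batch = TRUE, iter = 2L) {
  stopifnot(frac > 0, frac <= 1)
  if (!any(fm$is_qc))
    stop("no QC samples present: QC-based lowess correction is impossible. ",
         "Use a statistical model instead (ber, ber_bagged, ",
         "combat_parametric, combat_nonparametric).", call. = FALSE)
  if (anyNA(fm$injection_order))
    stop("injection_order must be present for all samples", call. = FALSE)

  windows <- if (per_batch) split(seq_len(nrow(fm$intensities)), fm$batch)
             else list(all = seq_len(nrow(fm$intensities)))
  G <- ncol(fm$intensities)
  corrected <- fm$intensities
  dropped <- character(0)
  drop_reason <- character(0)
  drift <- vector("list", G)
  names(drift) <- feature_ids(fm)
  reference <- rep(NA_real_, G)
  names(reference) <- feature_ids(fm)
  log2_scale <- fm$scale_flag == "log2"

  qc_all <- fm$is_qc
  for (g in seq_len(G)) {
    y <- fm$intensities[, g]
    ref <- stats::median(y[qc_all], na.rm = TRUE)
    reference[g] <- ref
    fitted_all <- rep(NA_real_, length(y))
    reason <- NULL
    curves <- list()
    for (w in names(windows)) {
      rows <- windows[[w]]
      qc <- rows[qc_all[rows] & !is.na(y[rows])]
      if (length(qc) < 3L) {
        reason <- paste0("LOW_QC: < 3 non-missing QC measurements in ",
                         if (per_batch) paste0("batch ", w) else "the run")
        break
      }
      ord <- fm$injection_order[qc]
      o <- order(ord)
      lw <- stats::lowess(ord[o], y[qc][o], f = frac, iter = iter)
      fitted_all[rows] <- stats::approx(lw$x, lw$y,
                                        xout = fm$injection_order[rows],
                                        rule = 2, ties = mean)$y
      curves[[w]] <- list(qc_order = lw$x, fitted = lw$y)
    }
    if (is.null(reason) && !log2_scale &&
        any(fitted_all <= 0, na.rm = TRUE))
      reason <- "NONPOS_FIT: fitted drift level <= 0 on the raw scale"
    if (!is.null(reason)) {
      dropped <- c(dropped, feature_ids(fm)[g])
      drop_reason <- c(drop_reason, reason)
      next
    }
    corrected[, g] <- if (log2_scale) y - (fitted_all - ref)
                      else y * ref / fitted_all
    drift[[g]] <- curves
  }

  keep <- setdiff(feature_ids(fm), dropped)
  out <- subset_feature_matrix(fm, features = keep)
  out$intensities <- corrected[, keep, drop = FALSE]
  names(drop_reason) <- dropped
  internals <- list(drift = drift[keep], reference = reference[keep],
                    frac = frac, per_batch = per_batch, iter = iter)
  new_batch_correction(out, "qc_lowess", internals,
                       dropped_features = structure(dropped,
                                                    names = drop_reason),
                       runtime_log = if (length(dropped))
                       paste0("DROPPED ", dropped, " (", drop_reason, ")")
                       else character(0),
                       input = fm)
}
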