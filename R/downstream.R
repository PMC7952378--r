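#' Pearson correlation with a Fisher-z confidence interval
#'
#' Computes Pearson's r, its Fisher transform z = atanh(r), and the
#' normal-approximation confidence interval z +/- z_(1-alpha/2)/sqrt(n-3),
#' reported on the z scale and back-transformed to the r scale.
#'
#' @param x,y Finite numeric vectors of equal length, n >= 4.
#' @param alpha Two-sided error rate (default 0.05, i.e. a 95% interval).
#' @return A list: `r`, `z`, `ci_low`, `ci_high` (z scale), `ci_low_r`,
#'   `ci_high_r` (back-transformed), `n`, `alpha`.
#' @export
pearson_fisher <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4L) stop("need n >= 4", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input: correlation undefined", call. = FALSE)
  n <- length(x)
  r <- stats::cor(x, y)
  z <- atanh(r)
  w <- stats::qnorm(1 - alpha / 2) / sqrt(n - 3)
  list(r = r, z = z, ci_low = z - w, ci_high = z + w,
       ci_low_r = tanh(z - w), ci_high_r = tanh(z + w),
       n = n, alpha = alpha)
}

#' Covariate-adjusted association scan of an outcome on each feature
#'
#' For every feature, fits `outcome ~ feature + covariates` by ordinary
#' least squares and reports the feature coefficient, its two-sided
#' p-value, and the Bonferroni-adjusted p (multiplied by the number of
#' scanned features, capped at 1).  Samples with a missing outcome,
#' covariate or feature value are dropped per feature; a subset of samples
#' (e.g. the participants with complete clinical metadata) can be selected
#' up front.
#'
#' @param fm A `feature_matrix` (QC injections are excluded).
#' @param outcome Numeric vector, one value per sample of `fm` (NA allowed:
#'   those samples are skipped), e.g. an estimated glomerular filtration
#'   rate.
#' @param covariates Character vector naming adjustment columns of
#'   `fm$covariates` (e.g. age, sex), or `NULL`.
#' @param samples Optional sample subset (ids, indices or logical).
#' @return A `data.frame`, one row per feature: `feature`, `coefficient`,
#'   `p`, `p_bonferroni`, `n`, `note` (non-empty when a feature's fit
#'   failed, e.g. collinear design; the scan continues).
#' @export
association_scan <- function(fm, outcome, covariates = NULL,
                             samples = NULL) {
  if (length(outcome) != nrow(fm$intensities))
    stop("`outcome` must have one value per sample", call. = FALSE)
  keep <- !fm$is_qc
  if (!is.null(samples)) {
    sel <- rep(FALSE, nrow(fm$intensities))
    if (is.character(samples)) samples <- match(samples, sample_ids(fm))
    if (is.logical(samples)) samples <- which(samples)
    sel[samples] <- TRUE
    keep <- keep & sel
  }
  covdf <- if (!is.null(covariates)) {
    miss <- setdiff(covariates, names(fm$covariates))
    if (length(miss))
      stop("unknown covariate(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    fm$covariates[, covariates, drop = FALSE]
  } else NULL

  G <- ncol(fm$intensities)
  out <- data.frame(feature = feature_ids(fm),
                    coefficient = NA_real_, p = NA_real_,
                    p_bonferroni = NA_real_, n = NA_integer_,
                    note = "", stringsAsFactors = FALSE)
  for (g in seq_len(G)) {
    df <- data.frame(.outcome = outcome, .feature = fm$intensities[, g])
    if (!is.null(covdf)) df <- cbind(df, covdf)
    df <- df[keep, , drop = FALSE]
    df <- df[stats::complete.cases(df), , drop = FALSE]
    out$n[g] <- nrow(df)
    if (nrow(df) < ncol(df) + 2L) {
      out$note[g] <- "too few complete observations"
      next
    }
    fit <- stats::lm(.outcome ~ ., data = df)
    cf <- summary(fit)$coefficients
    if (!".feature" %in% rownames(cf) || anyNA(stats::coef(fit))) {
      out$note[g] <- "collinear design; coefficient not estimable"
      next
    }
    out$coefficient[g] <- cf[".feature", "Estimate"]
    out$p[g] <- cf[".feature", "Pr(>|t|)"]
  }
  out$p_bonferroni <- pmin(out$p * G, 1)
  out
}

#' Two-group differential analysis of a feature table
#'
#' Per feature: the log2 fold change (difference of group means on the
#' log2 scale), a two-sided equal-variance linear-model t-test, and
#' Benjamini-Hochberg adjustment across features.  A feature is called
#' significant when |log2FC| exceeds `lfc_threshold` and the BH-adjusted
#' p-value is below `alpha`.  The output is sorted for volcano plotting
#' (log2FC against -log10 adjusted p).
#'
#' @param fm A `feature_matrix` on the log2 scale (QC injections are
#'   excluded).
#' @param group A two-level factor (or vector), one value per sample; the
#'   fold change is level 2 minus level 1.  Each group needs >= 2 samples.
#' @param lfc_threshold Absolute log2 fold-change cutoff (default 1.5).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return A `data.frame`: `feature`, `log2fc`, `p`, `p_bh`,
#'   `significant`, sorted by `p_bh` then |log2fc| descending.
#' @export
differential_analysis <- function(fm, group, lfc_threshold = 1.5,
                                  alpha = 0.05) {
  if (length(group) != nrow(fm$intensities))
    stop("`group` must have one value per sample", call. = FALSE)
  keep <- !fm$is_qc & !is.na(group)
  group <- droplevels(factor(group[keep]))
  if (nlevels(group) != 2L)
    stop("`group` must have exactly 2 levels among non-QC samples (got ",
         nlevels(group), ")", call. = FALSE)
  if (any(table(group) < 2L))
    stop("each group needs >= 2 samples; sizes: ",
         paste(table(group), collapse = ", "), call. = FALSE)
  x <- fm$intensities[keep, , drop = FALSE]
  g1 <- group == levels(group)[1L]
  G <- ncol(x)
  lfc <- p <- rep(NA_real_, G)
  for (g in seq_len(G)) {
    y <- x[, g]
    obs <- !is.na(y)
    y1 <- y[obs & g1]; y2 <- y[obs & !g1]
    if (length(y1) < 2L || length(y2) < 2L) next
    lfc[g] <- mean(y2) - mean(y1)
    fit <- stats::lm(y[obs] ~ group[obs])
    p[g] <- summary(fit)$coefficients[2L, "Pr(>|t|)"]
  }
  p_bh <- stats::p.adjust(p, method = "BH")
  out <- data.frame(feature = colnames(x), log2fc = lfc, p = p,
                    p_bh = p_bh,
                    significant = !is.na(lfc) & !is.na(p_bh) &
                      abs(lfc) > lfc_threshold & p_bh < alpha,
                    stringsAsFactors = FALSE)
  out[order(out$p_bh, -abs(out$log2fc)), , drop = FALSE]
}
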