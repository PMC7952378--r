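#' Two-stage regression batch correction (ber)
#'
#' Removes additive and multiplicative batch effects by two stages of
#' least squares, fitted per feature.  Stage 1 regresses intensity on
#' optional biological covariates plus batch indicators under the
#' sample-size-weighted sum-to-zero constraint and subtracts the fitted
#' batch offsets.  Stage 2 estimates a per-batch residual scale from the
#' stage-1 residuals, divides each residual by its batch scale and
#' multiplies by the pooled scale, then re-adds the grand mean and the
#' covariate fit.  With no covariates the corrected per-batch feature means
#' are all equal and the per-batch feature variances are all equal, by
#' construction.
#'
#' @param fm A complete `feature_matrix` with >= 2 non-QC samples per
#'   batch.
#' @param covariates Optional character vector naming columns of
#'   `fm$covariates` to preserve during correction (biology enters the
#'   stage-1 fit and is re-added, never removed).
#' @param use_qc If `FALSE` (default) QC injections are excluded from
#'   parameter estimation but corrected alongside with their batch's
#'   parameters.
#' @return A `batch_correction` fit (see [batch_correct()]).  `internals`
#'   holds `location_coef` (features x batches additive offsets
#'   \eqn{\hat\gamma_{ig}}), `scale_factor` (features x batches residual
#'   scales \eqn{\hat s_{ig}}), `pooled_scale`, `covariate_coef`,
#'   `grand_mean`, `n_boot = 0`, `seed = NA`.
#' @references Giordan, M. (2014) A two-stage procedure for the removal of
#'   batch effects in microarray studies. Statistics in Biosciences 6,
#'   73-84.
#' @export
ber_correct <- function(fm, covariates = NULL, use_qc = FALSE) {
  prep <- ber_prepare(fm, covariates, use_qc)
  par <- ber_fit_params(prep$Y_fit, prep$batch_fit, prep$X_fit)
  ber_apply(fm, prep, par, model_name = "ber",
            extra = list(n_boot = 0L, seed = NA_integer_))
}

#' Bootstrap-bagged ber correction
#'
#' Stabilizes the ber parameter estimates by a stratified bootstrap:
#' samples are resampled with replacement within each batch, the stage-1
#' location offsets and stage-2 scale factors are re-estimated on every
#' replicate, and the per-parameter mean over replicates is used.  This is
#' a partial bagging: the parameters are bagged, the correction is applied
#' once to the original data with the aggregated parameters.
#'
#' @inheritParams ber_correct
#' @param n_boot Number of bootstrap replicates (default 150).
#' @param seed Integer seed making the resampling reproducible; the
#'   caller's RNG state is left untouched.
#' @return A `batch_correction` fit; `internals` as for [ber_correct()]
#'   with the bagged parameter values, plus `n_boot` and `seed`.
#' @export
ber_bagged <- function(fm, covariates = NULL, n_boot = 150L, seed = 1L,
                       use_qc = FALSE) {
  stopifnot(n_boot >= 1L)
  prep <- ber_prepare(fm, covariates, use_qc)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
  }
  by_batch <- split(seq_along(prep$batch_fit), prep$batch_fit)
  gam_sum <- NULL; s_sum <- NULL; pool_sum <- 0
  for (b in seq_len(n_boot)) {
    idx <- ber_boot_indices(by_batch)
    par_b <- ber_fit_params(prep$Y_fit[idx, , drop = FALSE],
                            prep$batch_fit[idx],
                            prep$X_fit[idx, , drop = FALSE])
    if (is.null(gam_sum)) {
      gam_sum <- par_b$gamma; s_sum <- par_b$s
    } else {
      gam_sum <- gam_sum + par_b$gamma; s_sum <- s_sum + par_b$s
    }
    pool_sum <- pool_sum + par_b$s_pool
  }
  # aggregated location/scale; grand mean and covariate fit from the full data
  par_full <- ber_fit_params(prep$Y_fit, prep$batch_fit, prep$X_fit)
  par <- list(mu = par_full$mu, beta = par_full$beta,
              gamma = gam_sum / n_boot, s = s_sum / n_boot,
              s_pool = pool_sum / n_boot, log = par_full$log)
  ber_apply(fm, prep, par, model_name = "ber_bagged",
            extra = list(n_boot = as.integer(n_boot),
                         seed = if (is.null(seed)) NA_integer_
                                else as.integer(seed)))
}

# ---- internals --------------------------------------------------------------

ber_prepare <- function(fm, covariates, use_qc) {
  assert_complete(fm, "ber")
  fit_rows <- if (use_qc) seq_len(nrow(fm$intensities)) else which(!fm$is_qc)
  batch_fit <- droplevels(fm$batch[fit_rows])
  if (nlevels(droplevels(fm$batch)) > nlevels(batch_fit))
    stop("batch(es) consisting only of QC samples cannot be estimated: ",
         paste(setdiff(levels(droplevels(fm$batch)), levels(batch_fit)),
               collapse = ", "), call. = FALSE)
  sizes <- table(batch_fit)
  if (any(sizes < 2L))
    stop("each batch needs >= 2 samples for correction; too small: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  X_all <- covariate_design(fm, covariates, rows = seq_len(nrow(fm$intensities)))
  list(Y_fit = fm$intensities[fit_rows, , drop = FALSE],
       batch_fit = batch_fit,
       X_fit = if (is.null(X_all)) NULL else
         X_all[fit_rows, , drop = FALSE],
       X_all = X_all, fit_rows = fit_rows)
}

# stratified within-batch resampling; degenerate replicates (a batch
# collapsing onto a single original sample) are redrawn
ber_boot_indices <- function(by_batch, max_redraw = 100L) {
  for (attempt in seq_len(max_redraw)) {
    idx <- unlist(lapply(by_batch, function(ii)
      ii[sample.int(length(ii), replace = TRUE)]), use.names = FALSE)
    # a batch is degenerate when all resampled rows are one original sample
    pos <- 0L; ok <- TRUE
    for (ii in by_batch) {
      sel <- idx[pos + seq_along(ii)]
      pos <- pos + length(ii)
      if (length(unique(sel)) < 2L) { ok <- FALSE; break }
    }
    if (ok) return(idx)
  }
  stop("bootstrap failed: a batch degenerated in ", max_redraw,
       " consecutive redraws", call. = FALSE)
}

# the two-stage parameter estimates on one (possibly resampled) dataset
ber_fit_params <- function(Y, batch, X) {
  fit <- fit_location_model(Y, batch, X)
  n <- nrow(Y)
  fitted_sys <- systematic_part(fit, fit$X, n)
  resid <- Y - fitted_sys - fit$gamma[as.character(batch), , drop = FALSE]
  sizes <- fit$sizes
  B <- length(sizes); G <- ncol(Y)
  v <- matrix(0, B, G, dimnames = list(names(sizes), colnames(Y)))
  for (i in seq_len(B)) {
    ri <- resid[batch == names(sizes)[i], , drop = FALSE]
    v[i, ] <- colSums(ri * ri) / (nrow(ri) - 1L)
  }
  s_pool2 <- colSums(v * (as.vector(sizes) - 1L)) / (n - B)
  log_msgs <- character(0)
  # zero within-batch variance: skip the scale step for that (g, i)
  zero <- v <= s_pool2[col(v)] * 1e-12 | v == 0
  if (any(zero)) {
    v[zero] <- s_pool2[col(v)][zero]
    log_msgs <- paste0("DEGENERATE_SCALE: scale step skipped for ",
                       sum(zero), " (feature, batch) cell(s) with zero ",
                       "within-batch variance")
    # fully degenerate feature: leave residuals untouched
    allzero <- s_pool2 == 0
    if (any(allzero)) v[, allzero] <- 1
  }
  s_pool2[s_pool2 == 0] <- 1
  list(mu = fit$mu, beta = fit$beta, gamma = t(fit$gamma),  # G x B
       s = t(sqrt(v)), s_pool = sqrt(s_pool2), log = log_msgs)
}

# apply location/scale parameters to the full matrix (QCs included)
ber_apply <- function(fm, prep, par, model_name, extra) {
  n <- nrow(fm$intensities)
  sys_all <- matrix(rep(par$mu, each = n), n, length(par$mu))
  if (nrow(par$beta)) sys_all <- sys_all + prep$X_all %*% par$beta
  bidx <- match(as.character(fm$batch), colnames(par$gamma))
  gam_rows <- t(par$gamma)[bidx, , drop = FALSE]      # n x G
  s_rows   <- t(par$s)[bidx, , drop = FALSE]
  resid <- fm$intensities - sys_all - gam_rows
  corrected <- sys_all +
    resid / s_rows * matrix(par$s_pool, n, length(par$s_pool), byrow = TRUE)
  dimnames(corrected) <- dimnames(fm$intensities)
  out <- fm
  out$intensities <- corrected
  internals <- c(list(location_coef = par$gamma,
                      scale_factor  = par$s,
                      pooled_scale  = par$s_pool,
                      covariate_coef = par$beta,
                      grand_mean    = par$mu),
                 extra)
  new_batch_correction(out, model_name, internals,
                       runtime_log = par$log, input = fm)
}
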