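#' Fit a batch-effect correction model
#'
#' Single front end over the package's correction models.  Dispatches on
#' `model` and returns a classed fit object carrying the corrected feature
#' matrix, the estimated batch parameters and per-feature provenance.
#'
#' @param fm A complete [feature_matrix()] (lowess tolerates missingness;
#'   the statistical models require a complete matrix).
#' @param model One of `"ber"`, `"ber_bagged"`, `"combat_parametric"`,
#'   `"combat_nonparametric"`, `"qc_lowess"`, or `"raw"` (identity, useful
#'   as a baseline in comparisons).
#' @param ... Passed to the model engine: see [ber_correct()],
#'   [ber_bagged()], [combat_correct()], [lowess_correct()].
#' @return An object of class `batch_correction` (see Details).
#'
#' @details A `batch_correction` object has fields
#' \describe{
#'   \item{corrected}{the corrected `feature_matrix` (same samples; features
#'     minus `dropped_features`, same `scale_flag`);}
#'   \item{model_name}{which model produced it;}
#'   \item{internals}{model-specific parameter record (batch location/scale
#'     estimates, EB priors and posteriors, lowess drift curves);}
#'   \item{dropped_features}{named character vector of removed feature ids
#'     (names are the reasons), e.g. features absent from all QCs under
#'     lowess;}
#'   \item{runtime_log}{character vector of structured messages;}
#'   \item{input}{the uncorrected input, retained for `residuals()`.}
#' }
#' Methods: `print`, `summary`, `coef` (per-feature-by-batch location
#' offsets), `residuals` (corrected minus input intensities), `plot`
#' (before/after PCA panel).
#'
#' @examples
#' sim <- simulate_batches(preset_config("untargeted_tissue",
#'                                       n_features = 30), seed = 1)
#' fit <- batch_correct(impute_missing(sim$fm), "ber")
#' fit
#' max(batch_adj_r2(fit$corrected))
#' @export
batch_correct <- function(fm,
                          model = c("ber", "ber_bagged", "combat_parametric",
                                    "combat_nonparametric", "qc_lowess",
                                    "raw"),
                          ...) {
  valid <- c("ber", "ber_bagged", "combat_parametric",
             "combat_nonparametric", "qc_lowess", "raw")
  if (!is.character(model) || length(model) != 1L || !model %in% valid) {
    hint <- if (is.character(model) && length(model) == 1L) {
      d <- utils::adist(model, valid)
      paste0("; did you mean \"", valid[which.min(d)], "\"?")
    } else ""
    stop("unknown model '", paste(model, collapse = ","),
         "'. Valid models: ", paste(valid, collapse = ", "), hint,
         call. = FALSE)
  }
  switch(model,
         ber                  = ber_correct(fm, ...),
         ber_bagged           = ber_bagged(fm, ...),
         combat_parametric    = combat_correct(fm, mode = "parametric", ...),
         combat_nonparametric = combat_correct(fm, mode = "nonparametric",
                                               ...),
         qc_lowess            = lowess_correct(fm, ...),
         raw                  = new_batch_correction(fm, "raw",
                                                     internals = list(),
                                                     input = fm))
}

new_batch_correction <- function(corrected, model_name, internals,
                                 dropped_features = character(0),
                                 runtime_log = character(0), input) {
  structure(list(corrected        = corrected,
                 model_name       = model_name,
                 internals        = internals,
                 dropped_features = dropped_features,
                 runtime_log      = runtime_log,
                 input            = input),
            class = "batch_correction")
}

#' @export
print.batch_correction <- function(x, ...) {
  cat("batch_correction fit, model = ", x$model_name, "\n", sep = "")
  cat("  ", nrow(x$corrected$intensities), " samples, ",
      ncol(x$corrected$intensities), " features kept, ",
      length(x$dropped_features), " dropped\n", sep = "")
  if (length(x$dropped_features))
    cat("  dropped: ",
        paste(utils::head(x$dropped_features, 5), collapse = ", "),
        if (length(x$dropped_features) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
summary.batch_correction <- function(object, ...) {
  r2_in  <- tryCatch(batch_adj_r2(object$input), error = function(e) NULL)
  r2_out <- tryCatch(batch_adj_r2(object$corrected), error = function(e) NULL)
  out <- list(model_name = object$model_name,
              n_samples = nrow(object$corrected$intensities),
              n_features = ncol(object$corrected$intensities),
              dropped_features = object$dropped_features,
              score_before = if (!is.null(r2_in)) model_score(r2_in),
              score_after = if (!is.null(r2_out)) model_score(r2_out),
              runtime_log = object$runtime_log)
  class(out) <- "summary.batch_correction"
  out
}

#' @export
print.summary.batch_correction <- function(x, ...) {
  cat("Batch correction summary (model = ", x$model_name, ")\n", sep = "")
  cat("  samples: ", x$n_samples, ", features kept: ", x$n_features,
      ", dropped: ", length(x$dropped_features), "\n", sep = "")
  if (!is.null(x$score_before))
    cat("  batch dependence score (max adj-R2, clipped to [0,1]):\n",
        "    before: ", format(x$score_before$score, digits = 4),
        "   after: ", format(x$score_after$score, digits = 4), "\n",
        sep = "")
  if (length(x$runtime_log))
    cat("  log:\n", paste0("    ", x$runtime_log, collapse = "\n"), "\n",
        sep = "")
  invisible(x)
}

#' Extract estimated batch location offsets
#'
#' @param object A `batch_correction` fit.
#' @param ... Unused.
#' @return For the regression/EB models, the features x batches matrix of
#'   estimated additive batch offsets (for ComBat on the standardized scale,
#'   the EB-adjusted `gamma_star`); `NULL` for models without one.
#' @export
coef.batch_correction <- function(object, ...) {
  int <- object$internals
  if (!is.null(int$location_coef)) return(int$location_coef)
  if (!is.null(int$gamma_star)) return(int$gamma_star)
  NULL
}

#' @export
residuals.batch_correction <- function(object, ...) {
  keep <- feature_ids(object$corrected)
  object$corrected$intensities -
    object$input$intensities[, keep, drop = FALSE]
}

#' Before/after PCA panel for a correction fit
#'
#' @param x A `batch_correction` fit.
#' @param ... Passed on to [plot_pca()].
#' @return Invisibly `x`; draws a 1x2 panel of PCA score plots coloured by
#'   batch, input on the left, corrected on the right.
#' @export
plot.batch_correction <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  keep <- feature_ids(x$corrected)
  plot_pca(subset_feature_matrix(x$input, features = keep),
           main = "raw", ...)
  plot_pca(x$corrected, main = x$model_name, ...)
  invisible(x)
}
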