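#' Correct with several models, score and rank them
#'
#' The end-to-end workflow: fit every requested correction model, compute
#' the per-feature batch adj-R-squared of the raw and each corrected
#' dataset, score and rank the models, and optionally write the corrected
#' tables and the score report to disk.  A model that fails (e.g. lowess
#' without QC injections) is skipped with a warning and recorded; the run
#' only errors when every requested model fails.
#'
#' @param fm A `feature_matrix`.
#' @param models Character vector of model names accepted by
#'   [batch_correct()] (`"raw"` is always scored as the baseline and need
#'   not be listed).
#' @param out_dir Optional directory: writes
#'   `corrected_<model>_{intensities,metadata}.csv` per model and
#'   `score_report.csv`.
#' @param ... Shared engine options passed to [batch_correct()]
#'   (e.g. `covariates`, `seed`, `frac`).
#' @return A list of class `model_comparison`:
#' \describe{
#'   \item{fits}{named list of `batch_correction` objects (successful
#'     models only);}
#'   \item{adj_r2}{named list of per-feature adj-R2 vectors, `raw`
#'     included;}
#'   \item{ranking}{the [rank_models()] table over `raw` + successes;}
#'   \item{failed}{named character vector of error messages for skipped
#'     models.}
#' }
#' @examples
#' sim <- simulate_batches(sim_config(n_batches = 3, n_features = 20),
#'                         seed = 2)
#' cmp <- compare_models(sim$fm, c("ber", "combat_parametric"))
#' cmp$ranking
#' @export
compare_models <- function(fm, models = c("ber", "combat_parametric"),
                           out_dir = NULL, ...) {
  if (!length(models)) stop("no models requested", call. = FALSE)
  opts <- list(...)
  fits <- list()
  failed <- character(0)
  for (m in unique(setdiff(models, "raw"))) {
    eng_opts <- opts[names(opts) %in% engine_formals(m)]
    fit <- tryCatch(do.call(batch_correct, c(list(fm, model = m), eng_opts)),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("model '", m, "' failed and was skipped: ",
              conditionMessage(fit), call. = FALSE)
      failed[m] <- conditionMessage(fit)
    } else fits[[m]] <- fit
  }
  if (!length(fits))
    stop("all requested models failed:\n",
         paste0("  ", names(failed), ": ", failed, collapse = "\n"),
         call. = FALSE)
  adj <- c(list(raw = batch_adj_r2(fm)),
           lapply(fits, function(f) batch_adj_r2(f$corrected)))
  ranking <- rank_models(adj)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (m in names(fits))
      write_feature_table(fits[[m]]$corrected,
                          file.path(out_dir,
                                    paste0("corrected_", m,
                                           "_intensities.csv")),
                          file.path(out_dir,
                                    paste0("corrected_", m,
                                           "_metadata.csv")))
    utils::write.csv(ranking, file.path(out_dir, "score_report.csv"),
                     row.names = FALSE)
  }
  structure(list(fits = fits, adj_r2 = adj, ranking = ranking,
                 failed = failed),
            class = "model_comparison")
}

engine_formals <- function(model) {
  fn <- switch(model,
               ber = ber_correct, ber_bagged = ber_bagged,
               combat_parametric = combat_correct,
               combat_nonparametric = combat_correct,
               qc_lowess = lowess_correct,
               return(character(0)))
  setdiff(names(formals(fn)), c("fm", "mode"))
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("model_comparison over ", length(x$fits), " model(s) + raw\n",
      sep = "")
  print(x$ranking, digits = 4)
  if (length(x$failed))
    cat("skipped: ", paste(names(x$failed), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' @export
plot.model_comparison <- function(x, ...) {
  plot_score(x$ranking, ...)
  invisible(x)
}
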