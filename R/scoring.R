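#' Per-feature batch dependence: adjusted R-squared on batch
#'
#' For every feature, the adjusted coefficient of determination of the
#' one-way regression of intensity on batch membership:
#' \deqn{R^2_g = SS_{between}/SS_{total}, \qquad
#'   adjR^2_g = 1 - (1 - R^2_g)\frac{n_g - 1}{n_g - B},}
#' the fraction of the feature's variance explained by batch, penalized
#' for the B batch degrees of freedom.  This is the quantity the package's
#' model-selection score summarizes: near 1 means the feature is dominated
#' by batch, near (or below) 0 means no detectable batch dependence —
#' slightly negative values are the signature of a batch regression with
#' no explanatory power.
#'
#' QC injections are excluded; missing entries are excluded pairwise, so
#' \eqn{n_g} is per feature.  A zero-variance feature is reported as 0 with
#' a warning.
#'
#' @param fm A `feature_matrix` with >= 2 batches and more non-QC samples
#'   than batches.
#' @return Named numeric vector of per-feature adjusted R-squared values
#'   (can be negative; always <= 1).
#' @seealso [model_score()], [rank_models()]
#' @export
batch_adj_r2 <- function(fm) {
  keep <- !fm$is_qc
  x <- fm$intensities[keep, , drop = FALSE]
  batch <- droplevels(fm$batch[keep])
  B <- nlevels(batch)
  if (B < 2L) stop("batch_adj_r2 needs >= 2 batches", call. = FALSE)
  out <- rep(NA_real_, ncol(x))
  names(out) <- colnames(x)
  zero_var <- character(0)
  for (g in seq_len(ncol(x))) {
    obs <- !is.na(x[, g])
    n <- sum(obs)
    bg <- droplevels(batch[obs])
    if (n <= nlevels(bg) || nlevels(bg) < 2L)
      stop("feature '", colnames(x)[g], "': n (", n,
           ") must exceed the number of batches (", nlevels(bg), ")",
           call. = FALSE)
    y <- x[obs, g]
    tot <- sum((y - mean(y))^2)
    if (tot == 0) {
      out[g] <- 0
      zero_var <- c(zero_var, colnames(x)[g])
      next
    }
    m <- tapply(y, bg, mean)
    nb <- tapply(y, bg, length)
    between <- sum(nb * (m - mean(y))^2)
    r2 <- between / tot
    out[g] <- 1 - (1 - r2) * (n - 1) / (n - nlevels(bg))
  }
  if (length(zero_var))
    warning("zero total variance; adj-R2 reported as 0 for: ",
            paste(utils::head(zero_var, 5), collapse = ", "),
            call. = FALSE)
  out
}

#' Model-performance score from per-feature adj-R-squared
#'
#' The score of a (raw or corrected) dataset is the worst remaining batch
#' dependence: the maximum over features of the batch adjusted R-squared,
#' clipped below at 0 so it lives in \[0, 1\].  The lower the score, the
#' better the correction.  The unclipped maximum is kept alongside (after
#' an effective correction every per-feature value is slightly negative,
#' and the clipped score is exactly 0).
#'
#' @param adj_r2 Non-empty numeric vector from [batch_adj_r2()].
#' @return A list with `score` (clipped to `[0, 1]`), `raw_max` (unclipped
#'   maximum), `mean_adj_r2` (consistency summary used as ranking
#'   tie-break) and `n_features`.
#' @export
model_score <- function(adj_r2) {
  adj_r2 <- adj_r2[!is.na(adj_r2)]
  if (!length(adj_r2)) stop("empty adj-R2 vector", call. = FALSE)
  raw_max <- max(adj_r2)
  list(score = min(max(raw_max, 0), 1),
       raw_max = raw_max,
       mean_adj_r2 = mean(adj_r2),
       n_features = length(adj_r2))
}

#' Rank correction models by batch-dependence score
#'
#' Ascending sort by score (lower = better correction); exact ties are
#' broken by the mean adj-R-squared — a model that is consistently low
#' across all features beats one with the same worst case but a worse
#' bulk — then alphabetically by model name.
#'
#' @param scores Named list: for each model, either the output of
#'   [model_score()] or a per-feature adj-R2 vector (scored on the fly).
#' @return A `data.frame` with one row per model, in rank order: `rank`,
#'   `model`, `score`, `raw_max`, `mean_adj_r2`, `rationale`.
#' @export
rank_models <- function(scores) {
  stopifnot(length(scores) >= 1L, !is.null(names(scores)))
  rec <- lapply(scores, function(s)
    if (is.list(s)) s else model_score(s))
  df <- data.frame(model = names(rec),
                   score = vapply(rec, `[[`, numeric(1), "score"),
                   raw_max = vapply(rec, `[[`, numeric(1), "raw_max"),
                   mean_adj_r2 = vapply(rec, `[[`, numeric(1),
                                        "mean_adj_r2"),
                   stringsAsFactors = FALSE, row.names = NULL)
  o <- order(df$score, df$mean_adj_r2, df$model)
  df <- df[o, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df$rationale <- paste0("max batch adj-R2 ",
                         format(df$score, digits = 3), " (unclipped ",
                         format(df$raw_max, digits = 3), "), mean ",
                         format(df$mean_adj_r2, digits = 3))
  rownames(df) <- NULL
  df[, c("rank", "model", "score", "raw_max", "mean_adj_r2", "rationale")]
}
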