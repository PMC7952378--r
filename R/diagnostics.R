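#' PCA of a feature table
#'
#' Sample-level view of batch structure: column-wise mean-centered
#' (and by default unit-variance scaled, since metabolite intensities live
#' on heterogeneous scales) singular value decomposition.  Component signs
#' are fixed by forcing the largest-magnitude loading of each component
#' positive, so scores are reproducible across platforms.
#'
#' @param fm A complete `feature_matrix`.
#' @param n_components Number of components to return (>= 1).
#' @param scale. Unit-variance scaling (default `TRUE`); constant features
#'   are left unscaled.
#' @return A list: `scores` (samples x components, with batch labels and
#'   QC flags as attributes-free columns of the accompanying
#'   `data.frame`), `loadings`, `explained` (variance fractions,
#'   non-increasing, summing to <= 1), `batch`, `is_qc`.
#' @export
pca_scores <- function(fm, n_components = 2L, scale. = TRUE) {
  if (n_components < 1L) stop("n_components must be >= 1", call. = FALSE)
  x <- fm$intensities
  if (any(!is.finite(x)))
    stop("PCA requires finite intensities throughout (impute first)",
         call. = FALSE)
  k_max <- min(nrow(x), ncol(x))
  if (n_components > k_max)
    stop("n_components exceeds min(n_samples, n_features) = ", k_max,
         call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  pc <- stats::prcomp(x, center = TRUE,
                      scale. = if (scale.) ifelse(sds > 0, sds, 1) else FALSE)
  k <- n_components
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sco <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {       # deterministic sign convention
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) { rot[, j] <- -rot[, j]; sco[, j] <- -sco[, j] }
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = sco, loadings = rot,
       explained = expl[seq_len(k)],
       batch = fm$batch, is_qc = fm$is_qc)
}

#' Hierarchical clustering of samples
#'
#' Euclidean distance on (optionally standardized) samples, agglomerated
#' with Ward, complete or average linkage.  `hclust` breaks ties by the
#' lower merge index, so the tree is deterministic given the input order.
#'
#' @param fm A complete `feature_matrix` with >= 2 samples.
#' @param linkage `"ward"` (Ward's D2 on Euclidean distances),
#'   `"complete"` or `"average"`.
#' @param standardize Scale features to unit variance first (default).
#' @return An object of class `hclust` (merge tree with heights), with the
#'   batch labels attached as `attr(, "batch")`.
#' @export
hca_dendrogram <- function(fm, linkage = c("ward", "complete", "average"),
                           standardize = TRUE) {
  linkage <- match.arg(linkage)
  x <- fm$intensities
  if (nrow(x) < 2L) stop("need >= 2 samples to cluster", call. = FALSE)
  if (any(!is.finite(x)))
    stop("clustering requires finite intensities throughout", call. = FALSE)
  if (standardize) {
    sds <- apply(x, 2L, stats::sd)
    x <- scale(x, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  }
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = switch(linkage, ward = "ward.D2",
                                      complete = "complete",
                                      average = "average"))
  attr(hc, "batch") <- fm$batch
  hc
}

#' Per-batch distribution summary of one feature
#'
#' Feature-level view of a batch effect: for a single metabolite, per-batch
#' Gaussian kernel density estimates (Silverman's rule bandwidth) on a
#' shared grid, box/violin statistics (median, quartiles, mean, per-sample
#' points), and a two-sided t-test of each batch against the first batch
#' with the conventional star annotation (* p < 0.05, ** < 0.01,
#' *** < 0.001, **** < 0.0001).
#'
#' @param fm A `feature_matrix`.
#' @param feature_id A feature name present in `fm`.
#' @param include_qc Include QC injections (default `FALSE`).
#' @return A list with `feature_id`, `grid` (shared density grid),
#'   `densities` (per-batch KDE values on the grid, `NULL` where a batch
#'   has < 2 observations), `stats` (per-batch `data.frame`: n, mean,
#'   median, q1, q3, t-test p vs first batch, stars), and `points`
#'   (per-sample values with batch).
#' @export
feature_distribution_summary <- function(fm, feature_id,
                                         include_qc = FALSE) {
  g <- match(feature_id, feature_ids(fm))
  if (is.na(g))
    stop("unknown feature '", feature_id, "'", call. = FALSE)
  keep <- if (include_qc) rep(TRUE, nrow(fm$intensities)) else !fm$is_qc
  y <- fm$intensities[keep, g]
  batch <- droplevels(fm$batch[keep])
  obs <- !is.na(y)
  y <- y[obs]; batch <- droplevels(batch[obs])
  rng <- range(y)
  pad <- diff(rng) * 0.15 + 1e-8
  grid <- seq(rng[1] - pad, rng[2] + pad, length.out = 512L)

  lv <- levels(batch)
  dens <- stats::setNames(vector("list", length(lv)), lv)
  st <- data.frame(batch = lv, n = NA_integer_, mean = NA_real_,
                   median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                   p_vs_first = NA_real_, stars = "",
                   stringsAsFactors = FALSE)
  y1 <- y[batch == lv[1L]]
  for (i in seq_along(lv)) {
    yi <- y[batch == lv[i]]
    st$n[i] <- length(yi)
    st$mean[i] <- mean(yi)
    st$median[i] <- stats::median(yi)
    qs <- stats::quantile(yi, c(0.25, 0.75), names = FALSE)
    st$q1[i] <- qs[1]; st$q3[i] <- qs[2]
    if (length(yi) >= 2L && stats::sd(yi) > 0) {
      d <- stats::density(yi, bw = "nrd0", from = grid[1L],
                          to = grid[length(grid)], n = length(grid))
      dens[[i]] <- d$y
    } else if (length(yi) < 2L) {
      warning("batch ", lv[i], " has ", length(yi),
              " observation(s); KDE skipped", call. = FALSE)
    }
    if (i > 1L && length(yi) >= 2L && length(y1) >= 2L)
      st$p_vs_first[i] <- tryCatch(
        stats::t.test(yi, y1, alternative = "two.sided")$p.value,
        error = function(e) NA_real_)
  }
  st$stars <- p_stars(st$p_vs_first)
  list(feature_id = feature_id, grid = grid, densities = dens,
       stats = st,
       points = data.frame(batch = batch, value = y,
                           stringsAsFactors = FALSE))
}

#' Significance stars for p-values
#'
#' @param p Numeric vector of p-values (NA allowed).
#' @return Character vector: `"****"` for p < 1e-4, `"***"` < 1e-3,
#'   `"**"` < 0.01, `"*"` < 0.05, `""` otherwise.
#' @export
p_stars <- function(p) {
  out <- rep("", length(p))
  out[!is.na(p) & p < 0.05]   <- "*"
  out[!is.na(p) & p < 0.01]   <- "**"
  out[!is.na(p) & p < 0.001]  <- "***"
  out[!is.na(p) & p < 0.0001] <- "****"
  out
}

# ---- plotting ---------------------------------------------------------------

#' PCA score plot coloured by batch
#'
#' @param fm A complete `feature_matrix`.
#' @param components Which two components to draw.
#' @param main Plot title.
#' @param ... Further arguments to [graphics::plot()].
#' @return Invisibly, the [pca_scores()] result.
#' @export
plot_pca <- function(fm, components = c(1L, 2L), main = "PCA", ...) {
  pc <- pca_scores(fm, n_components = max(components))
  cols <- grDevices::hcl.colors(nlevels(pc$batch), "Dark 3")
  graphics::plot(pc$scores[, components[1L]], pc$scores[, components[2L]],
                 col = cols[as.integer(pc$batch)],
                 pch = ifelse(pc$is_qc, 17, 19),
                 xlab = sprintf("PC%d (%.1f%%)", components[1L],
                                100 * pc$explained[components[1L]]),
                 ylab = sprintf("PC%d (%.1f%%)", components[2L],
                                100 * pc$explained[components[2L]]),
                 main = main, ...)
  invisible(pc)
}

#' Bar plot of model scores
#'
#' @param ranking Output of [rank_models()].
#' @param ... Further arguments to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot_score <- function(ranking, ...) {
  graphics::barplot(ranking$score, names.arg = ranking$model,
                    ylab = "max batch adj-R2 (clipped)", las = 2,
                    ...)
}

#' Per-batch density panel for one feature
#'
#' @param summary Output of [feature_distribution_summary()].
#' @param ... Further arguments to [graphics::plot()].
#' @return Invisibly `NULL`.
#' @export
plot_feature_density <- function(summary, ...) {
  keep <- !vapply(summary$densities, is.null, logical(1))
  ylim <- c(0, max(unlist(summary$densities[keep])))
  cols <- grDevices::hcl.colors(length(summary$densities), "Dark 3")
  graphics::plot(NA, xlim = range(summary$grid), ylim = ylim,
                 xlab = summary$feature_id, ylab = "density", ...)
  for (i in which(keep))
    graphics::lines(summary$grid, summary$densities[[i]], col = cols[i])
  graphics::legend("topright", legend = names(summary$densities)[keep],
                   col = cols[keep], lty = 1, cex = 0.7, bty = "n")
  invisible(NULL)
}
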