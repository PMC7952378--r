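#' Simulation configuration for multi-batch acquisitions
#'
#' Defines the generating model of [simulate_batches()].  On the log2
#' scale, the intensity of feature g in sample j of batch i is
#' \deqn{y_{ijg} = \mu_g + group_j b_g + \gamma_{ig} +
#'   drift_{ig}(order_j - \overline{order}_i) + \delta_{ig}\,\epsilon,
#'   \qquad \epsilon \sim N(0, \sigma^2),}
#' i.e. a location/scale batch model (additive offset \eqn{\gamma_{ig}},
#' multiplicative residual scale \eqn{\delta_{ig}}) plus a linear
#' within-batch signal drift over injection order.  Pooled QC injections
#' share the batch and drift effects but sit at the feature's pooled mean
#' (\eqn{\mu_g + } `group_fraction` \eqn{\cdot b_g}); they are inserted at
#' the start of each batch and after every `qc_every` study samples.
#' Entries below the feature's detection limit (`mu_g - lod_offset`)
#' become missing.
#'
#' @param n_batches Number of analytical batches.
#' @param samples_per_batch Study (non-QC) samples per batch.
#' @param n_features Number of measured features.
#' @param qc_every Insert a QC after every this many study samples
#'   (plus one at each batch start); `Inf` disables QCs.
#' @param group_fraction Fraction of study samples in biological group 2.
#' @param mu_mean,mu_sd Distribution of per-feature baselines \eqn{\mu_g}
#'   (log2 units).
#' @param b_sd SD of the per-feature biological group contrast \eqn{b_g};
#'   0 disables biology.
#' @param gamma_sd SD of the additive batch offsets
#'   \eqn{\gamma_{ig} \sim N(0, \code{gamma_sd}^2)} per (feature, batch).
#' @param delta_sdlog Log-SD of the multiplicative batch scales
#'   \eqn{\delta_{ig} \sim LogNormal(0, \code{delta_sdlog}^2)}.
#' @param drift_sd SD of the per-(feature, batch) linear drift slope
#'   (log2 units per injection); 0 disables drift.
#' @param sinusoidal_drift If `TRUE` the within-batch drift follows a half
#'   sine over the batch (amplitude `drift_sd` scaled) instead of a line,
#'   for exercising curvature.
#' @param noise_sd Residual SD \eqn{\sigma} (log2 units).
#' @param lod_offset Detection limit is `mu_g - lod_offset`; `Inf` (the
#'   default) disables below-LOD missingness.
#' @return A classed list of generator settings (`sim_config`).
#' @seealso [preset_config()] for configurations mirroring a targeted
#'   cohort and an untargeted tissue study.
#' @export
sim_config <- function(n_batches = 3L, samples_per_batch = 20L,
                       n_features = 100L, qc_every = 10L,
                       group_fraction = 0.5,
                       mu_mean = 18, mu_sd = 2, b_sd = 0,
                       gamma_sd = 2, delta_sdlog = 0.2,
                       drift_sd = 0, sinusoidal_drift = FALSE,
                       noise_sd = 0.5, lod_offset = Inf) {
  cfg <- list(n_batches = as.integer(n_batches),
              samples_per_batch = as.integer(samples_per_batch),
              n_features = as.integer(n_features),
              qc_every = qc_every, group_fraction = group_fraction,
              mu_mean = mu_mean, mu_sd = mu_sd, b_sd = b_sd,
              gamma_sd = gamma_sd, delta_sdlog = delta_sdlog,
              drift_sd = drift_sd, sinusoidal_drift = sinusoidal_drift,
              noise_sd = noise_sd, lod_offset = lod_offset)
  if (cfg$n_batches < 1L) stop("n_batches must be >= 1", call. = FALSE)
  if (cfg$samples_per_batch < 2L)
    stop("samples_per_batch must be >= 2", call. = FALSE)
  if (!is.infinite(cfg$qc_every) && cfg$qc_every < 1)
    stop("qc_every must be >= 1 (or Inf for no QCs)", call. = FALSE)
  if (cfg$group_fraction < 0 || cfg$group_fraction > 1)
    stop("group_fraction must be in [0, 1]", call. = FALSE)
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Preset simulator configurations
#'
#' Two documented configurations emulating the structure (scaled down to
#' seconds of compute) of the studies the package targets:
#' \describe{
#'   \item{`targeted_cohort`}{a large targeted plasma cohort: 11 batches x
#'     20 samples, 100 features, QCs every 10 injections; strong additive
#'     batch offsets (`gamma_sd = 2`), mild scale effects
#'     (`delta_sdlog = 0.2`), residual noise 0.5 (all log2 units), no
#'     below-LOD censoring.}
#'   \item{`untargeted_tissue`}{an untargeted tissue set acquired in 3
#'     analytical runs: 3 batches x 25 samples, 500 features, QCs every 8,
#'     a two-group design (`b_sd = 1`), within-batch drift
#'     (`drift_sd = 0.02`) and below-LOD missingness
#'     (`lod_offset = 3`).}
#' }
#'
#' @param name `"targeted_cohort"` or `"untargeted_tissue"`.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
preset_config <- function(name = c("targeted_cohort", "untargeted_tissue"),
                          ...) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("targeted_cohort", "untargeted_tissue"))
    stop("unknown preset '", paste(name, collapse = ","),
         "'; available: targeted_cohort, untargeted_tissue", call. = FALSE)
  base <- switch(name,
    targeted_cohort = list(n_batches = 11L, samples_per_batch = 20L,
                           n_features = 100L, qc_every = 10L,
                           gamma_sd = 2, delta_sdlog = 0.2,
                           noise_sd = 0.5, drift_sd = 0, b_sd = 0,
                           lod_offset = Inf),
    untargeted_tissue = list(n_batches = 3L, samples_per_batch = 25L,
                             n_features = 500L, qc_every = 8L,
                             gamma_sd = 2, delta_sdlog = 0.2,
                             noise_sd = 0.5, drift_sd = 0.02, b_sd = 1,
                             lod_offset = 3))
  do.call(sim_config, utils::modifyList(base, list(...)))
}

#' Simulate a multi-batch metabolomics acquisition with known truth
#'
#' Draws a dataset from the generating model of [sim_config()] and returns
#' both the observable [feature_matrix()] and the ground-truth parameters,
#' so correction models can be validated by parameter recovery.
#' Fully reproducible given `seed`; the caller's RNG state is untouched.
#'
#' @param config A [sim_config()] (or [preset_config()]).
#' @param seed Integer seed.
#' @return A list:
#' \describe{
#'   \item{fm}{the simulated `feature_matrix` (log2 scale, QCs flagged,
#'     `group` covariate attached when `b_sd > 0` or always as a factor);}
#'   \item{truth}{a `simulation_truth` record: `mu`, `b`, `gamma_true`
#'     (features x batches), `delta_true`, `drift_slope`, `lod`,
#'     `noise_sd`, `seed`, `config`.}
#' }
#' @examples
#' sim <- simulate_batches(sim_config(n_batches = 2, n_features = 10),
#'                         seed = 7)
#' sim$fm
#' @export
simulate_batches <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))

  B <- config$n_batches; G <- config$n_features
  nb <- config$samples_per_batch
  fid <- sprintf("feature_%03d", seq_len(G))
  blab <- sprintf("batch_%02d", seq_len(B))

  mu <- stats::rnorm(G, config$mu_mean, config$mu_sd)
  b  <- if (config$b_sd > 0) stats::rnorm(G, 0, config$b_sd) else
    numeric(G)
  gamma <- matrix(stats::rnorm(G * B, 0, config$gamma_sd), G, B,
                  dimnames = list(fid, blab))
  if (config$gamma_sd == 0) gamma[] <- 0
  delta <- matrix(exp(stats::rnorm(G * B, 0, config$delta_sdlog)), G, B,
                  dimnames = list(fid, blab))
  if (config$delta_sdlog == 0) delta[] <- 1
  drift <- matrix(stats::rnorm(G * B, 0, config$drift_sd), G, B,
                  dimnames = list(fid, blab))
  if (config$drift_sd == 0) drift[] <- 0
  lod <- mu - config$lod_offset

  # acquisition layout: one QC at each batch start, then a QC after every
  # qc_every study samples; injection order runs through the whole study
  rows <- list()
  inj <- 0L
  for (i in seq_len(B)) {
    since_qc <- 0L
    if (!is.infinite(config$qc_every)) {
      inj <- inj + 1L
      rows[[length(rows) + 1L]] <- list(batch = i, order = inj, qc = TRUE)
    }
    for (s in seq_len(nb)) {
      inj <- inj + 1L
      rows[[length(rows) + 1L]] <- list(batch = i, order = inj, qc = FALSE)
      since_qc <- since_qc + 1L
      if (!is.infinite(config$qc_every) && since_qc == config$qc_every) {
        inj <- inj + 1L
        rows[[length(rows) + 1L]] <- list(batch = i, order = inj, qc = TRUE)
        since_qc <- 0L
      }
    }
  }
  batch_i <- vapply(rows, `[[`, integer(1), "batch")
  order_j <- vapply(rows, `[[`, integer(1), "order")
  is_qc   <- vapply(rows, `[[`, logical(1), "qc")
  n <- length(rows)

  group <- integer(n)                 # 0/1; QCs carry the pooled level
  study <- which(!is_qc)
  group[study] <- stats::rbinom(length(study), 1L, config$group_fraction)

  ord_center <- stats::ave(order_j, batch_i)   # per-batch mean order
  Y <- matrix(NA_real_, n, G)
  for (i in seq_len(B)) {
    ri <- which(batch_i == i)
    eps <- matrix(stats::rnorm(length(ri) * G, 0, config$noise_sd),
                  length(ri), G)
    d_ord <- order_j[ri] - ord_center[ri]
    if (config$sinusoidal_drift) {
      span <- max(order_j[ri]) - min(order_j[ri])
      d_ord <- sin(pi * (order_j[ri] - min(order_j[ri])) / span) *
        span / pi  # comparable slope scale
    }
    base <- matrix(mu, length(ri), G, byrow = TRUE) +
      outer(ifelse(is_qc[ri], config$group_fraction, group[ri]), b) +
      matrix(gamma[, i], length(ri), G, byrow = TRUE) +
      outer(d_ord, drift[, i])
    Y[ri, ] <- base + eps * matrix(delta[, i], length(ri), G, byrow = TRUE)
  }
  colnames(Y) <- fid
  rownames(Y) <- ifelse(is_qc, sprintf("qc_%03d", cumsum(is_qc)),
                        sprintf("sample_%03d", cumsum(!is_qc)))
  below <- sweep(Y, 2L, lod, `<`)
  Y[below] <- NA_real_

  covariates <- data.frame(group = factor(ifelse(is_qc, NA,
                                                 ifelse(group == 1L,
                                                        "g2", "g1"))),
                           row.names = rownames(Y))
  fm <- feature_matrix(Y, batch = blab[batch_i],
                       injection_order = order_j, is_qc = is_qc,
                       covariates = covariates, scale_flag = "log2")
  truth <- structure(list(mu = stats::setNames(mu, fid),
                          b = stats::setNames(b, fid),
                          gamma_true = gamma, delta_true = delta,
                          drift_slope = drift,
                          lod = stats::setNames(lod, fid),
                          noise_sd = config$noise_sd,
                          seed = as.integer(seed), config = config),
                     class = "simulation_truth")
  list(fm = fm, truth = truth)
}

#' Raw-scale export of a simulated dataset
#'
#' The generator works on the log2 scale (where the corrections operate);
#' this helper returns the same matrix as raw intensities (2^y), e.g. for
#' exercising [log2_transform()].
#'
#' @param fm A log2-scale `feature_matrix`.
#' @return The `feature_matrix` with intensities 2^y and
#'   `scale_flag = "raw"`.
#' @export
unlog2 <- function(fm) {
  stopifnot(fm$scale_flag == "log2")
  fm$intensities <- 2^fm$intensities
  fm$scale_flag <- "raw"
  fm
}

#' Identifiable part of simulated batch offsets
#'
#' Under the sample-size-weighted sum-to-zero constraint, only batch
#' offsets centered per feature are estimable; this centers `gamma_true`
#' (or `drift_slope` etc.) the same way the fitters constrain their
#' estimates, for parameter-recovery comparisons.
#'
#' @param truth A `simulation_truth`.
#' @param weights Per-batch weights (default: the study-sample counts,
#'   equal under the built-in layouts).
#' @return The features x batches matrix of centered true offsets.
#' @export
centered_gamma_true <- function(truth, weights = NULL) {
  g <- truth$gamma_true
  if (is.null(weights)) weights <- rep(1, ncol(g))
  w <- weights / sum(weights)
  sweep(g, 1L, as.vector(g %*% w), `-`)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("simulation_truth: ", length(x$mu), " features x ",
      ncol(x$gamma_true), " batches (seed ", x$seed, ")\n", sep = "")
  cat("  gamma sd ", format(stats::sd(x$gamma_true), digits = 3),
      ", delta geometric sd ",
      format(exp(stats::sd(log(x$delta_true))), digits = 3),
      ", noise sd ", x$noise_sd, "\n", sep = "")
  invisible(x)
}
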