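#' Empirical-Bayes location/scale batch correction (ComBat)
#'
#' Three-step empirical-Bayes adjustment of per-batch location and scale,
#' borrowing strength across features.
#'
#' **Step 1 (standardize).** Per feature g, fit
#' \eqn{y = \alpha_g + X\beta_g + \gamma_{ig} + \epsilon} by constrained
#' least squares (sample-size-weighted sum-to-zero batch offsets), pool the
#' residual variance \eqn{\hat\sigma_g^2} over all fitted samples, and form
#' \eqn{Z_{ijg} = (Y_{ijg} - \hat\alpha_g - X_j\hat\beta_g)/\hat\sigma_g}.
#'
#' **Step 2 (estimate and shrink).** \eqn{\hat\gamma_{ig}} and
#' \eqn{\hat\delta^2_{ig}} are the batch-i mean and variance of Z.  In
#' parametric mode the priors are Normal for \eqn{\gamma} and inverse-gamma
#' for \eqn{\delta^2}, with hyperparameters set by method of moments across
#' features, and the EB estimators are the fixed point of
#' \deqn{\gamma^*_{ig} = \frac{n_i\bar\tau_i^2\hat\gamma_{ig} +
#'   \delta^{*2}_{ig}\bar\gamma_i}{n_i\bar\tau_i^2 + \delta^{*2}_{ig}},
#'   \quad
#'   \delta^{*2}_{ig} = \frac{\bar\theta_i + \tfrac12\sum_j (Z_{ijg} -
#'   \gamma^*_{ig})^2}{n_i/2 + \bar\lambda_i - 1}.}
#' In nonparametric mode the posteriors are weighted averages of the other
#' features' \eqn{(\hat\gamma, \hat\delta^2)}, weighted by the Gaussian
#' likelihood of the batch-i data of feature g under those parameters
#' (leave-one-out, weights normalized to sum to 1).
#'
#' **Step 3 (adjust).** \eqn{Y^*_{ijg} = \hat\sigma_g (Z_{ijg} -
#' \gamma^*_{ig})/\delta^*_{ig} + \hat\alpha_g + X_j\hat\beta_g}.
#'
#' @inheritParams ber_correct
#' @param mode `"parametric"` (Normal / inverse-gamma priors) or
#'   `"nonparametric"` (likelihood-weighted posterior means).
#' @param tol Convergence tolerance of the parametric fixed-point
#'   iteration: maximum absolute relative parameter change.
#' @param max_iter Iteration cap; exceeding it is an error (with trace).
#' @return A `batch_correction` fit whose `internals` record every quantity
#'   of the EB procedure: `alpha`, `beta`, `sigma2`, `z`, `gamma_hat`,
#'   `delta2_hat`, `prior_gamma_mean`, `prior_gamma_var`, `prior_lambda`,
#'   `prior_theta`, `gamma_star`, `delta2_star`, `mode`, `n_iter`,
#'   `converged`.  Batch-indexed matrices are batches x features.
#' @references Johnson, W.E., Li, C., Rabinovic, A. (2007) Adjusting batch
#'   effects in microarray expression data using empirical Bayes methods.
#'   Biostatistics 8, 118-127.
#' @export
combat_correct <- function(fm, covariates = NULL,
                           mode = c("parametric", "nonparametric"),
                           tol = 1e-4, max_iter = 500L, use_qc = FALSE) {
  mode <- match.arg(mode)
  assert_complete(fm, "ComBat")
  G <- ncol(fm$intensities)
  if (G < 2L)
    stop("ComBat needs >= 2 features: the EB priors are moments across ",
         "features", call. = FALSE)
  fit_rows <- if (use_qc) seq_len(nrow(fm$intensities)) else which(!fm$is_qc)
  batch_fit <- droplevels(fm$batch[fit_rows])
  if (nlevels(batch_fit) < 2L)
    stop("ComBat needs >= 2 batches", call. = FALSE)
  sizes <- table(batch_fit)
  if (any(sizes < 2L))
    stop("each batch needs >= 2 samples; too small: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)

  X_all <- covariate_design(fm, covariates, rows = seq_len(nrow(fm$intensities)))
  X_fit <- if (is.null(X_all)) NULL else X_all[fit_rows, , drop = FALSE]
  Y_fit <- fm$intensities[fit_rows, , drop = FALSE]

  # -- step 1: standardize
  fit <- fit_location_model(Y_fit, batch_fit, X_fit)
  n_fit <- length(fit_rows)
  sys_fit <- systematic_part(fit, X_fit, n_fit)
  resid_full <- Y_fit - sys_fit -
    fit$gamma[as.character(batch_fit), , drop = FALSE]
  sigma2 <- colSums(resid_full^2) / n_fit
  if (any(sigma2 <= 0))
    stop("zero pooled variance for feature(s): ",
         paste(utils::head(colnames(Y_fit)[sigma2 <= 0], 5), collapse = ", "),
         call. = FALSE)
  sigma <- sqrt(sigma2)
  Z_fit <- (Y_fit - sys_fit) / matrix(sigma, n_fit, G, byrow = TRUE)

  # -- step 2: batch moments of Z
  B <- length(sizes)
  lv <- names(sizes)
  gamma_hat <- matrix(0, B, G, dimnames = list(lv, colnames(Y_fit)))
  delta2_hat <- gamma_hat
  for (i in seq_len(B)) {
    Zi <- Z_fit[batch_fit == lv[i], , drop = FALSE]
    gamma_hat[i, ] <- colMeans(Zi)
    delta2_hat[i, ] <- apply(Zi, 2L, stats::var)
  }

  if (mode == "parametric") {
    eb <- combat_parametric_eb(Z_fit, batch_fit, sizes, gamma_hat,
                               delta2_hat, tol, max_iter)
  } else {
    eb <- combat_nonparametric_eb(Z_fit, batch_fit, sizes, gamma_hat,
                                  delta2_hat)
  }

  # -- step 3: adjust every sample (QCs with their batch's parameters)
  n <- nrow(fm$intensities)
  sys_all <- matrix(rep(fit$mu, each = n), n, G)
  if (nrow(fit$beta)) sys_all <- sys_all + X_all %*% fit$beta
  Z_all <- (fm$intensities - sys_all) / matrix(sigma, n, G, byrow = TRUE)
  bidx <- match(as.character(fm$batch), lv)
  if (anyNA(bidx))
    stop("batch(es) consisting only of QC samples cannot be estimated: ",
         paste(setdiff(unique(as.character(fm$batch)), lv), collapse = ", "),
         call. = FALSE)
  gs <- eb$gamma_star[bidx, , drop = FALSE]
  ds <- sqrt(eb$delta2_star)[bidx, , drop = FALSE]
  corrected <- (Z_all - gs) / ds * matrix(sigma, n, G, byrow = TRUE) + sys_all
  dimnames(corrected) <- dimnames(fm$intensities)

  out <- fm
  out$intensities <- corrected
  internals <- list(alpha = fit$mu, beta = fit$beta, sigma2 = sigma2,
                    z = Z_fit, gamma_hat = gamma_hat,
                    delta2_hat = delta2_hat,
                    prior_gamma_mean = eb$prior_gamma_mean,
                    prior_gamma_var = eb$prior_gamma_var,
                    prior_lambda = eb$prior_lambda,
                    prior_theta = eb$prior_theta,
                    gamma_star = eb$gamma_star,
                    delta2_star = eb$delta2_star,
                    mode = mode, n_iter = eb$n_iter,
                    converged = eb$converged)
  new_batch_correction(out, paste0("combat_", mode), internals,
                       runtime_log = eb$log, input = fm)
}

# ---- EB engines -------------------------------------------------------------

combat_parametric_eb <- function(Z, batch, sizes, gamma_hat, delta2_hat,
                                 tol, max_iter) {
  B <- length(sizes); G <- ncol(Z); lv <- names(sizes)
  gbar <- rowMeans(gamma_hat)
  t2   <- apply(gamma_hat, 1L, stats::var)
  Vbar <- rowMeans(delta2_hat)
  S2   <- apply(delta2_hat, 1L, stats::var)
  if (any(S2 <= 0))
    stop("degenerate inverse-gamma prior (zero cross-feature variance of ",
         "delta2_hat); try mode = 'nonparametric'", call. = FALSE)
  lambda <- (Vbar^2 + 2 * S2) / S2
  theta  <- (Vbar^3 + Vbar * S2) / S2
  if (any(lambda <= 1))
    stop("inverse-gamma prior has no mean (lambda <= 1) for batch(es) ",
         paste(lv[lambda <= 1], collapse = ", "),
         "; try mode = 'nonparametric'", call. = FALSE)

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  trace <- numeric(0)
  n_iter <- 0L
  for (i in seq_len(B)) {
    Zi <- Z[batch == lv[i], , drop = FALSE]
    n_i <- sizes[[i]]
    g_old <- gamma_hat[i, ]; d_old <- delta2_hat[i, ]
    it <- 0L
    repeat {
      it <- it + 1L
      g_new <- (n_i * t2[i] * gamma_hat[i, ] + d_old * gbar[i]) /
        (n_i * t2[i] + d_old)
      ss <- colSums(sweep(Zi, 2L, g_new, "-")^2)
      d_new <- (theta[i] + 0.5 * ss) / (n_i / 2 + lambda[i] - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / d_old)
      g_old <- g_new; d_old <- d_new
      trace <- c(trace, change)
      if (change < tol) break
      if (it >= max_iter)
        stop("EB fixed point did not converge in ", max_iter,
             " iterations (batch ", lv[i], "); last relative changes: ",
             paste(format(utils::tail(trace, 5), digits = 3),
                   collapse = ", "), call. = FALSE)
    }
    n_iter <- max(n_iter, it)
    gamma_star[i, ] <- g_old
    delta2_star[i, ] <- d_old
  }
  list(gamma_star = gamma_star, delta2_star = delta2_star,
       prior_gamma_mean = gbar, prior_gamma_var = t2,
       prior_lambda = lambda, prior_theta = theta,
       n_iter = n_iter, converged = TRUE, log = character(0))
}

# posterior means weighted by the Gaussian likelihood of batch-i data of
# feature g under every other feature's (gamma_hat, delta2_hat); log-sum-exp
# for numerical stability
combat_nonparametric_eb <- function(Z, batch, sizes, gamma_hat, delta2_hat) {
  B <- length(sizes); G <- ncol(Z); lv <- names(sizes)
  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  for (i in seq_len(B)) {
    Zi <- Z[batch == lv[i], , drop = FALSE]
    n_i <- sizes[[i]]
    sx <- colSums(Zi)
    ss <- colSums(Zi^2)
    gh <- gamma_hat[i, ]; d2 <- delta2_hat[i, ]
    for (g in seq_len(G)) {
      others <- setdiff(seq_len(G), g)
      # sum_j (Z_ijg - gh[g'])^2 expanded for all g' at once
      A <- ss[g] - 2 * gh[others] * sx[g] + n_i * gh[others]^2
      loglik <- -0.5 * n_i * log(2 * pi * d2[others]) -
        A / (2 * d2[others])
      w <- exp(loglik - max(loglik))
      w <- w / sum(w)
      gamma_star[i, g] <- sum(w * gh[others])
      delta2_star[i, g] <- sum(w * d2[others])
    }
  }
  list(gamma_star = gamma_star, delta2_star = delta2_star,
       prior_gamma_mean = rowMeans(gamma_hat),
       prior_gamma_var = apply(gamma_hat, 1L, stats::var),
       prior_lambda = rep(NA_real_, B), prior_theta = rep(NA_real_, B),
       n_iter = 0L, converged = TRUE, log = character(0))
}
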