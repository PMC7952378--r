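# Shared constrained least-squares machinery for the location/scale models.
#
# All correction engines fit, per feature,
#     y = mu + X beta + gamma_batch + e
# under the sample-size-weighted identifiability constraint
#     sum_i n_i gamma_i = 0,
# so that mu is the grand mean of the fitted samples and the batch offsets
# are deviations from it.  The constraint is imposed by reparameterizing the
# last batch: gamma_B = -sum_{i<B} (n_i/n_B) gamma_i.

# contrast columns encoding the weighted sum-to-zero batch parameterization
batch_contrasts <- function(batch, sizes) {
  lv <- names(sizes)
  B <- length(lv)
  if (B < 2L) return(matrix(0, length(batch), 0L))
  C <- matrix(0, length(batch), B - 1L,
              dimnames = list(NULL, paste0("batch", lv[-B])))
  last <- batch == lv[B]
  for (i in seq_len(B - 1L)) {
    C[batch == lv[i], i] <- 1
    C[last, i] <- -sizes[[i]] / sizes[[B]]
  }
  C
}

# model matrix for user-named covariates; NULL when none requested
covariate_design <- function(fm, covariates, rows) {
  if (is.null(covariates) || !length(covariates)) return(NULL)
  if (is.null(fm$covariates))
    stop("covariates requested (", paste(covariates, collapse = ", "),
         ") but the feature_matrix carries none", call. = FALSE)
  miss <- setdiff(covariates, names(fm$covariates))
  if (length(miss))
    stop("unknown covariate(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- fm$covariates[, covariates, drop = FALSE]
  if (anyNA(df[rows, , drop = FALSE]))
    stop("missing covariate values among the samples to be corrected; ",
         "complete them or drop the affected samples", call. = FALSE)
  X <- stats::model.matrix(~ ., data = df)[, -1L, drop = FALSE]
  X
}

# one multi-feature constrained LS fit on the fitting rows.
# Y: n_fit x G, batch: factor over fitting rows (all levels present),
# X: covariate design over fitting rows or NULL.
fit_location_model <- function(Y, batch, X = NULL) {
  sizes <- table(batch)
  if (any(sizes < 1L)) stop("empty batch in fit", call. = FALSE)
  C <- batch_contrasts(as.character(batch), sizes)
  D <- cbind(`(Intercept)` = 1, X, C)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[qrD$pivot[(qrD$rank + 1L):ncol(D)]]
    stop("singular design: column(s) ", paste(bad, collapse = ", "),
         " are collinear (batch confounded with a covariate?)",
         call. = FALSE)
  }
  coefs <- qr.coef(qrD, Y)            # (1 + p + B-1) x G
  B <- length(sizes)
  p <- if (is.null(X)) 0L else ncol(X)
  mu <- coefs[1L, ]
  beta <- if (p) coefs[1L + seq_len(p), , drop = FALSE] else
    matrix(0, 0L, ncol(Y))
  gam_free <- if (B > 1L)
    coefs[1L + p + seq_len(B - 1L), , drop = FALSE] else
    matrix(0, 0L, ncol(Y))
  gamma <- matrix(0, B, ncol(Y),
                  dimnames = list(names(sizes), colnames(Y)))
  if (B > 1L) {
    gamma[seq_len(B - 1L), ] <- gam_free
    gamma[B, ] <- -colSums(gam_free * as.vector(sizes[seq_len(B - 1L)])) /
      as.vector(sizes[B])
  }
  list(mu = mu, beta = beta, gamma = gamma, sizes = sizes,
       X = X, design = D, qr = qrD)
}

# batch-free systematic part (mu + X beta) for arbitrary rows
systematic_part <- function(fit, X_rows, n_rows) {
  out <- matrix(rep(fit$mu, each = n_rows), n_rows, length(fit$mu))
  if (nrow(fit$beta)) out <- out + X_rows %*% fit$beta
  out
}
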