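# Independent reference implementations used as oracles.  These are written
# as naive per-feature closed forms / loops, deliberately separate from the
# vectorized package code paths.

# two-stage location/scale correction, covariate-free closed form:
# stage 1 removes batch means, stage 2 equalizes within-batch variances
oracle_ber <- function(y, batch) {
  batch <- factor(batch)
  grand <- mean(y)
  bm <- tapply(y, batch, mean)
  r <- y - bm[batch]
  v <- tapply(r, batch, stats::var)
  nb <- tapply(r, batch, length)
  s_pool <- sqrt(sum((nb - 1) * v) / (length(y) - nlevels(batch)))
  as.vector(grand + r / sqrt(v[batch]) * s_pool)
}

# EB fixed point, one feature set, naive loops following the update
# equations directly
oracle_combat_parametric <- function(Y, batch, tol = 1e-4,
                                     max_iter = 500) {
  batch <- factor(batch)
  n <- nrow(Y); G <- ncol(Y)
  lv <- levels(batch)
  ni <- sapply(lv, function(l) sum(batch == l))

  # standardization: per feature, weighted-constraint one-way fit
  alpha <- numeric(G); sigma2 <- numeric(G)
  Z <- Y * NA
  for (g in seq_len(G)) {
    y <- Y[, g]
    bm <- tapply(y, batch, mean)
    alpha[g] <- sum(ni * bm) / n          # weighted grand mean
    resid <- y - bm[batch]
    sigma2[g] <- sum(resid^2) / n
    Z[, g] <- (y - alpha[g]) / sqrt(sigma2[g])
  }
  gamma_hat <- sapply(seq_len(G), function(g) tapply(Z[, g], batch, mean))
  delta2_hat <- sapply(seq_len(G), function(g) tapply(Z[, g], batch,
                                                      stats::var))
  gamma_star <- gamma_hat * NA
  delta2_star <- delta2_hat * NA
  for (i in seq_along(lv)) {
    gh <- gamma_hat[i, ]; d2 <- delta2_hat[i, ]
    gbar <- mean(gh); t2 <- stats::var(gh)
    V <- mean(d2); S2 <- stats::var(d2)
    lambda <- (V^2 + 2 * S2) / S2
    theta <- (V^3 + V * S2) / S2
    g_old <- gh; d_old <- d2
    for (it in seq_len(max_iter)) {
      g_new <- (ni[i] * t2 * gh + d_old * gbar) / (ni[i] * t2 + d_old)
      d_new <- sapply(seq_len(G), function(g) {
        zi <- Z[batch == lv[i], g]
        (theta + 0.5 * sum((zi - g_new[g])^2)) / (ni[i] / 2 + lambda - 1)
      })
      ch <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                abs(d_new - d_old) / d_old)
      g_old <- g_new; d_old <- d_new
      if (ch < tol) break
    }
    gamma_star[i, ] <- g_old
    delta2_star[i, ] <- d_old
  }
  out <- Y * NA
  for (g in seq_len(G)) for (j in seq_len(n)) {
    i <- as.integer(batch[j])
    out[j, g] <- sqrt(sigma2[g]) *
      (Z[j, g] - gamma_star[i, g]) / sqrt(delta2_star[i, g]) + alpha[g]
  }
  list(corrected = out, gamma_hat = gamma_hat, gamma_star = gamma_star,
       delta2_star = delta2_star)
}

# adjusted R^2 of intensity on batch via R's own linear model summary
oracle_adj_r2 <- function(y, batch) {
  summary(stats::lm(y ~ factor(batch)))$adj.r.squared
}

# mean silhouette of batch labels on a 1-d projection
silhouette_1d <- function(x, lab) {
  lab <- factor(lab)
  s <- vapply(seq_along(x), function(i) {
    d <- abs(x - x[i])
    a <- mean(d[lab == lab[i]][-match(i, which(lab == lab[i]))])
    if (is.nan(a)) a <- 0
    b <- min(vapply(setdiff(levels(lab), lab[i]),
                    function(l) mean(d[lab == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
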