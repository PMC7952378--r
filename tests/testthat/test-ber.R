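test_that("two-batch toy has the closed-form correction", {
  fm <- toy_fm(c(1, 2, 3, 11, 12, 13), batch = rep(c("b1", "b2"), each = 3))
  fit <- ber_correct(fm)
  expect_equal(unname(fit$corrected$intensities[, 1]),
               c(6, 7, 8, 6, 7, 8), tolerance = 1e-12)
  expect_equal(unname(fit$internals$location_coef[1, ]), c(-5, 5))
  expect_equal(fit$internals$grand_mean[[1]], 7)
})

test_that("a single batch is corrected to itself", {
  set.seed(5)
  fm <- toy_fm(matrix(rnorm(30, 10), 10, 3), batch = rep("only", 10))
  fit <- ber_correct(fm)
  expect_equal(fit$corrected$intensities, fm$intensities,
               tolerance = 1e-10)
})

test_that("ber matches the independent two-stage oracle entry-wise", {
  set.seed(11)
  fm <- random_batched(n_per_batch = 7, n_batches = 2, n_features = 5)
  fit <- ber_correct(fm)
  for (g in seq_len(5)) {
    expect_equal(unname(fit$corrected$intensities[, g]),
                 unname(oracle_ber(fm$intensities[, g], fm$batch)),
                 tolerance = 1e-8)
  }
})

test_that("corrected per-batch means and variances are equal, even unbalanced", {
  set.seed(21)
  batch <- rep(c("b1", "b2", "b3"), times = c(5, 9, 14))
  y <- rnorm(length(batch), rep(c(0, 4, -3), times = c(5, 9, 14)),
             rep(c(1, 2.5, 0.7), times = c(5, 9, 14)))
  fm <- toy_fm(cbind(y, y * 2 + rnorm(length(y))), batch = batch)
  fit <- ber_correct(fm)
  for (g in 1:2) {
    yc <- fit$corrected$intensities[, g]
    m <- tapply(yc, fm$batch, mean)
    v <- tapply(yc, fm$batch, var)
    expect_lt(diff(range(m)), 1e-8)
    expect_lt(diff(range(v)) / mean(v), 1e-6)
  }
})

test_that("internals satisfy the identifiability and positivity constraints", {
  set.seed(31)
  fm <- random_batched(6, 3, 10)
  fit <- ber_correct(fm)
  sizes <- table(fm$batch)
  wsum <- fit$internals$location_coef %*% as.vector(sizes)
  expect_lt(max(abs(wsum)), 1e-8)
  expect_true(all(fit$internals$scale_factor > 0))
})

test_that("ber is idempotent", {
  set.seed(41)
  fm <- random_batched(8, 3, 6)
  once <- ber_correct(fm)$corrected
  twice <- ber_correct(once)$corrected
  sdref <- sd(once$intensities)
  expect_lt(max(abs(twice$intensities - once$intensities)),
            1e-6 * sdref)
})

test_that("biological covariates are preserved, not removed", {
  set.seed(51)
  n <- 60
  batch <- rep(c("b1", "b2", "b3"), each = 20)
  group <- factor(rep(rep(c("g1", "g2"), each = 10), 3))
  b_true <- 2
  y <- 10 + ifelse(group == "g2", b_true, 0) +
    rep(c(-3, 0, 3), each = 20) + rnorm(n, 0, 0.4)
  fm <- feature_matrix(cbind(f1 = y, f2 = rnorm(n, 12)), batch = batch,
                       covariates = data.frame(group = group),
                       scale_flag = "log2")
  fit <- ber_correct(fm, covariates = "group")
  yc <- fit$corrected$intensities[, "f1"]
  est <- mean(yc[group == "g2"]) - mean(yc[group == "g1"])
  expect_equal(est, b_true, tolerance = 0.3)
  expect_equal(rownames(fit$internals$covariate_coef), "groupg2")
})

test_that("degenerate designs error with an explanation", {
  fm <- toy_fm(rnorm(4, 10), batch = c("a", "a", "b", "b"),
               covariates = data.frame(x = c(0, 0, 1, 1)))
  expect_error(ber_correct(fm, covariates = "x"), "collinear")

  small <- toy_fm(rnorm(3, 10), batch = c("a", "a", "b"))
  expect_error(ber_correct(small), ">= 2 samples")

  miss <- toy_fm(c(1, NA, 3, 4), batch = c("a", "a", "b", "b"))
  expect_error(ber_correct(miss), "complete")
})

test_that("QC samples are corrected alongside but excluded from fitting", {
  set.seed(61)
  n <- 24
  batch <- rep(c("b1", "b2"), each = 12)
  is_qc <- rep(c(TRUE, rep(FALSE, 11)), 2)
  y <- 10 + ifelse(batch == "b2", 5, 0) + rnorm(n, 0, 0.5)
  y[is_qc] <- y[is_qc] + 100          # wildly off QCs must not disturb fit
  fm <- feature_matrix(cbind(f1 = y, f2 = y + 1), batch = batch, is_qc = is_qc,
                       scale_flag = "log2")
  fit <- ber_correct(fm)
  expect_equal(nrow(fit$corrected$intensities), n)
  study_means <- tapply(fit$corrected$intensities[!is_qc, 1],
                        batch[!is_qc], mean)
  expect_lt(diff(range(study_means)), 1e-8)
  # QC rows moved by their batch's offset, i.e. stay near 110 not 10
  expect_true(all(fit$corrected$intensities[is_qc, 1] > 100))
})

test_that("bagged ber is deterministic given a seed", {
  set.seed(71)
  fm <- random_batched(6, 2, 4)
  a <- ber_bagged(fm, n_boot = 25, seed = 99)
  b <- ber_bagged(fm, n_boot = 25, seed = 99)
  expect_identical(a$corrected$intensities, b$corrected$intensities)
  expect_identical(a$internals$location_coef, b$internals$location_coef)
  c2 <- ber_bagged(fm, n_boot = 25, seed = 100)
  expect_false(identical(a$corrected$intensities,
                         c2$corrected$intensities))
})

test_that("bagged location parameters converge to the plain ber estimates", {
  set.seed(81)
  fm <- random_batched(20, 2, 8, gamma_sd = 2, noise_sd = 0.5)
  plain <- ber_correct(fm)
  bag <- ber_bagged(fm, n_boot = 2000, seed = 7)
  # bootstrap SE of an aggregated batch mean ~ sd/sqrt(n * n_boot)
  tol <- 3 * 0.5 / sqrt(20 * 2000) * 5
  expect_lt(max(abs(bag$internals$location_coef -
                    plain$internals$location_coef)), tol)
})

test_that("the default bootstrap replicate count is 150", {
  expect_equal(eval(formals(ber_bagged)$n_boot), 150L)
})
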