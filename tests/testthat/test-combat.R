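test_that("parametric EB matches the independently coded oracle", {
  set.seed(101)
  n <- 16
  batch <- rep(c("b1", "b2"), each = n / 2)
  Y <- matrix(rnorm(n * 3, mean = rep(c(10, 12, 14), each = n)), n, 3) +
    ifelse(batch == "b2", 2, 0)
  fm <- feature_matrix(Y, batch = batch, scale_flag = "log2")
  fit <- combat_correct(fm, mode = "parametric")
  orc <- oracle_combat_parametric(fm$intensities, fm$batch)
  expect_equal(unname(fit$corrected$intensities),
               unname(orc$corrected), tolerance = 1e-6)
  expect_equal(unname(fit$internals$gamma_star), unname(orc$gamma_star),
               tolerance = 1e-6)
  expect_equal(unname(fit$internals$delta2_star),
               unname(orc$delta2_star), tolerance = 1e-6)
})

test_that("parametric shrinkage is a convex pull towards the prior mean", {
  set.seed(111)
  fm <- random_batched(10, 4, 25, gamma_sd = 2, noise_sd = 1)
  fit <- combat_correct(fm, mode = "parametric")
  int <- fit$internals
  for (i in seq_len(nrow(int$gamma_hat))) {
    lo <- pmin(int$gamma_hat[i, ], int$prior_gamma_mean[i])
    hi <- pmax(int$gamma_hat[i, ], int$prior_gamma_mean[i])
    expect_true(all(int$gamma_star[i, ] >= lo - 1e-10 &
                    int$gamma_star[i, ] <= hi + 1e-10))
  }
  expect_true(all(int$delta2_star > 0))
  expect_true(all(int$sigma2 > 0))
})

test_that("with no true batch effect the correction is nearly the identity", {
  set.seed(121)
  n_per <- 200
  batch <- rep(c("b1", "b2", "b3"), each = n_per)
  Y <- matrix(rnorm(3 * n_per * 50, 12, 1), 3 * n_per, 50)
  fm <- feature_matrix(Y, batch = batch, scale_flag = "log2")
  for (mode in c("parametric", "nonparametric")) {
    fit <- combat_correct(fm, mode = mode)
    rms <- sqrt(mean((fit$corrected$intensities - Y)^2))
    expect_lt(rms, 0.05 * sd(Y))
  }
})

test_that("corrected batch means approach the grand mean as batches grow", {
  dev <- sapply(c(5, 20, 100), function(n_per) {
    set.seed(131)
    fm <- random_batched(n_per, 3, 40, gamma_sd = 2, noise_sd = 1)
    fit <- combat_correct(fm, mode = "parametric")
    x <- fit$corrected$intensities
    max(abs(apply(x, 2, function(y) tapply(y, fm$batch, mean) - mean(y))))
  })
  expect_true(all(diff(dev) < 0))
})

test_that("parametric and nonparametric agree on large balanced data", {
  set.seed(141)
  fm <- random_batched(50, 3, 200, gamma_sd = 2, noise_sd = 1)
  par <- combat_correct(fm, mode = "parametric")
  np <- combat_correct(fm, mode = "nonparametric")
  d <- abs(par$corrected$intensities - np$corrected$intensities)
  expect_lt(median(d), 0.05 * sd(fm$intensities))
})

test_that("ComBat is idempotent up to residual re-shrinkage", {
  set.seed(151)
  fm <- random_batched(200, 3, 40, gamma_sd = 2, noise_sd = 1)
  once <- combat_correct(fm)$corrected
  twice <- combat_correct(once)$corrected
  rms <- sqrt(mean((twice$intensities - once$intensities)^2))
  expect_lt(rms, 0.05 * sd(once$intensities))
})

test_that("degenerate inputs produce instructive errors", {
  one_feat <- toy_fm(rnorm(8, 10), batch = rep(c("a", "b"), each = 4))
  expect_error(combat_correct(one_feat), ">= 2 features")

  # duplicated feature columns: zero cross-feature variance of delta2_hat
  set.seed(161)
  y <- rnorm(12, 10)
  dup <- toy_fm(cbind(f1 = y, f2 = y), batch = rep(c("a", "b"), each = 6))
  expect_error(combat_correct(dup, mode = "parametric"), "nonparametric")

  set.seed(171)
  fm <- random_batched(5, 2, 6)
  expect_error(combat_correct(fm, tol = 0, max_iter = 1),
               "did not converge")
})

test_that("parametric ComBat agrees with the reference Bioconductor fit", {
  skip_if_not_installed("sva")
  set.seed(181)
  fm <- random_batched(10, 3, 30, gamma_sd = 2, noise_sd = 1)
  fit <- combat_correct(fm, mode = "parametric")
  ref <- t(suppressMessages(
    sva::ComBat(dat = t(fm$intensities), batch = fm$batch,
                par.prior = TRUE, prior.plots = FALSE)))
  expect_lt(median(abs(fit$corrected$intensities - ref)),
            1e-3 * sd(fm$intensities))
})

test_that("batch_correct dispatches to the engines and catches typos", {
  set.seed(191)
  fm <- random_batched(6, 2, 4)
  expect_identical(batch_correct(fm, "ber")$corrected$intensities,
                   ber_correct(fm)$corrected$intensities)
  expect_identical(
    batch_correct(fm, "combat_parametric")$corrected$intensities,
    combat_correct(fm, mode = "parametric")$corrected$intensities)
  expect_error(batch_correct(fm, "combatt"), "combat_parametric")
  expect_identical(batch_correct(fm, "raw")$corrected$intensities,
                   fm$intensities)
})
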