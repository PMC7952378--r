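test_that("the generator is deterministic given a seed", {
  cfg <- sim_config(n_batches = 3, samples_per_batch = 10, n_features = 20,
                    drift_sd = 0.05, lod_offset = 2.5)
  a <- simulate_batches(cfg, seed = 17)
  b <- simulate_batches(cfg, seed = 17)
  expect_identical(a$fm$intensities, b$fm$intensities)
  expect_identical(a$truth$gamma_true, b$truth$gamma_true)
  c2 <- simulate_batches(cfg, seed = 18)
  expect_false(identical(a$fm$intensities, c2$fm$intensities))
})

test_that("null batch parameters produce no batch structure", {
  sim <- simulate_batches(sim_config(n_batches = 3, samples_per_batch = 30,
                                     n_features = 200, gamma_sd = 0,
                                     delta_sdlog = 0, drift_sd = 0,
                                     qc_every = Inf),
                          seed = 23)
  expect_true(all(sim$truth$gamma_true == 0))
  expect_true(all(sim$truth$delta_true == 1))
  r2 <- batch_adj_r2(sim$fm)
  expect_lt(abs(mean(r2)), 0.02)
})

test_that("strong batch offsets dominate the variance as designed", {
  sim <- simulate_batches(sim_config(n_batches = 3, samples_per_batch = 30,
                                     n_features = 100, gamma_sd = 2,
                                     noise_sd = 0.5, qc_every = Inf),
                          seed = 29)
  # expected R2 ~ var_between/(var_between + var_within) = 4/4.25
  expect_gt(median(batch_adj_r2(sim$fm)), 0.5)
})

test_that("presets mirror the two study layouts", {
  tc <- preset_config("targeted_cohort")
  expect_equal(tc$n_batches, 11L)
  expect_equal(tc$n_features, 100L)
  expect_equal(tc$qc_every, 10L)
  ut <- preset_config("untargeted_tissue")
  expect_equal(ut$n_batches, 3L)
  expect_error(preset_config("x"), "unknown preset")

  sim <- simulate_batches(tc, seed = 1)
  qc_per_batch <- tapply(sim$fm$is_qc, sim$fm$batch, sum)
  expect_true(all(qc_per_batch == 3L))     # bracketing QCs
  expect_equal(sum(!sim$fm$is_qc), 220L)
})

test_that("impossible configurations are rejected", {
  expect_error(sim_config(qc_every = 0), "qc_every")
  expect_error(sim_config(group_fraction = 1.5), "group_fraction")
  expect_error(sim_config(samples_per_batch = 1), "samples_per_batch")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
})

test_that("missingness is exactly left-censoring at the detection limit", {
  sim <- simulate_batches(sim_config(n_batches = 2, samples_per_batch = 40,
                                     n_features = 50, lod_offset = 2,
                                     qc_every = Inf),
                          seed = 37)
  x <- sim$fm$intensities
  expect_gt(sum(is.na(x)), 0)
  for (g in seq_len(ncol(x))) {
    obs <- x[!is.na(x[, g]), g]
    expect_true(all(obs >= sim$truth$lod[g]))
  }
  none <- simulate_batches(sim_config(n_batches = 2, lod_offset = Inf),
                           seed = 37)
  expect_false(anyNA(none$fm$intensities))
})

test_that("injection order is unique within batches and strictly ordered", {
  sim <- simulate_batches(preset_config("untargeted_tissue"), seed = 41)
  expect_identical(validate_feature_matrix(sim$fm), list())
  for (b in levels(sim$fm$batch)) {
    ord <- sim$fm$injection_order[sim$fm$batch == b]
    expect_false(is.unsorted(ord, strictly = TRUE))
  }
})

test_that("ber recovers the identifiable part of the simulated offsets", {
  sim <- simulate_batches(sim_config(n_batches = 3, samples_per_batch = 30,
                                     n_features = 200, gamma_sd = 2,
                                     noise_sd = 0.5, qc_every = Inf),
                          seed = 43)
  fit <- ber_correct(sim$fm)
  truth_c <- centered_gamma_true(sim$truth)
  est <- fit$internals$location_coef
  expect_gt(cor(as.vector(est), as.vector(truth_c)), 0.95)
  # RMSE bounded by twice the theoretical batch-mean noise sd / sqrt(n)
  sim2 <- simulate_batches(sim_config(n_batches = 3,
                                      samples_per_batch = 50,
                                      n_features = 200, gamma_sd = 2,
                                      delta_sdlog = 0, noise_sd = 0.5,
                                      qc_every = Inf),
                           seed = 47)
  fit2 <- ber_correct(sim2$fm)
  err <- fit2$internals$location_coef - centered_gamma_true(sim2$truth)
  expect_lt(sqrt(mean(err^2)), 2 * 0.5 / sqrt(50))
})

test_that("the raw-scale export inverts the log2 scale exactly", {
  sim <- simulate_batches(sim_config(n_batches = 2, n_features = 10),
                          seed = 53)
  raw <- unlog2(sim$fm)
  expect_equal(raw$scale_flag, "raw")
  back <- log2_transform(raw)
  expect_equal(back$intensities, sim$fm$intensities, tolerance = 1e-12)
})
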