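# build x, y with an exactly prescribed Pearson correlation
exact_cor_pair <- function(r, n, seed = 1) {
  set.seed(seed)
  x <- rnorm(n); z <- rnorm(n)
  x <- scale(x)[, 1]
  z <- scale(residuals(lm(z ~ x)))[, 1]
  list(x = x, y = r * x + sqrt(1 - r^2) * z)
}

test_that("Fisher-z transform and CI reproduce the printed cohort arithmetic", {
  p <- exact_cor_pair(0.18, 1079)
  res <- pearson_fisher(p$x, p$y)
  expect_equal(res$r, 0.18, tolerance = 1e-10)
  expect_equal(round(res$z, 2), 0.18)
  expect_equal(round(res$ci_low, 2), 0.12)
  expect_equal(round(res$ci_high, 2), 0.24)

  p2 <- exact_cor_pair(0.61, 1079)
  expect_equal(round(pearson_fisher(p2$x, p2$y)$z, 2), 0.71)
})

test_that("zero correlation gives z = 0 and a symmetric interval", {
  p <- exact_cor_pair(0, 50)
  res <- pearson_fisher(p$x, p$y)
  expect_equal(res$z, 0, tolerance = 1e-12)
  expect_equal(res$ci_low, -res$ci_high)
  # atanh/tanh round trip at machine precision
  expect_equal(atanh(tanh(res$ci_high)), res$ci_high, tolerance = 1e-14)
})

test_that("pearson_fisher guards its domain", {
  expect_error(pearson_fisher(1:3, 1:3), "n >= 4")
  expect_error(pearson_fisher(rep(1, 10), rnorm(10)), "zero-variance")
  expect_error(pearson_fisher(c(1:9, NA), 1:10), "finite")
})

test_that("association scan recovers a planted linear effect", {
  set.seed(301)
  n <- 200
  fm <- random_batched(n / 2, 2, 10, gamma_sd = 0, noise_sd = 1,
                       seed = 301)
  outcome <- 2 * fm$intensities[, 3] + rnorm(n, 0, 0.5)
  res <- association_scan(fm, outcome)
  hit <- res[res$feature == "feature_3", ]
  expect_lt(abs(hit$coefficient - 2), 0.2)
  expect_lt(hit$p_bonferroni, 0.05)
})

test_that("the scan controls family-wise error under the null", {
  set.seed(311)
  fm <- random_batched(30, 2, 100, gamma_sd = 0, noise_sd = 1, seed = 311)
  outcome <- rnorm(60)
  res <- association_scan(fm, outcome)
  expect_lte(sum(res$p_bonferroni < 0.05, na.rm = TRUE), 2L)
  # single feature: Bonferroni factor is 1
  one <- association_scan(subset_feature_matrix(fm, features = 1L), outcome)
  expect_equal(one$p_bonferroni, one$p)
})

test_that("covariate adjustment and sample subsetting work together", {
  set.seed(321)
  n <- 120
  age <- runif(n, 20, 70)
  sex <- factor(sample(c("f", "m"), n, replace = TRUE))
  feat <- rnorm(n, 12)
  outcome <- 100 - 0.5 * age + 3 * feat + rnorm(n, 0, 1)
  outcome[101:120] <- NA              # incomplete clinical metadata
  fm <- feature_matrix(cbind(creatinine = feat, other = rnorm(n)),
                       batch = rep(c("a", "b"), each = n / 2),
                       covariates = data.frame(age = age, sex = sex),
                       scale_flag = "log2")
  res <- association_scan(fm, outcome, covariates = c("age", "sex"),
                          samples = 1:100)
  hit <- res[res$feature == "creatinine", ]
  expect_equal(hit$n, 100L)
  expect_lt(abs(hit$coefficient - 3), 0.3)

  # collinear design: noted per feature, scan continues
  fm2 <- fm
  fm2$covariates$dup <- fm2$intensities[, "other"]
  res2 <- association_scan(fm2, outcome, covariates = "dup")
  expect_match(res2$note[res2$feature == "other"], "collinear")
  expect_false(is.na(res2$coefficient[res2$feature == "creatinine"]))
})

test_that("identical groups yield no differential features", {
  set.seed(331)
  fm <- random_batched(10, 2, 20, gamma_sd = 0, noise_sd = 1, seed = 331)
  grp <- rep(c("c", "t"), 10)
  res <- differential_analysis(fm, grp)
  expect_equal(sum(res$significant), 0L)
})

test_that("spiked features at log2FC 3 are recovered exactly", {
  set.seed(341)
  n <- 40; G <- 100
  grp <- rep(c("ctrl", "hfd"), each = n / 2)
  m <- matrix(rnorm(n * G, 14, 0.5), n, G,
              dimnames = list(NULL, sprintf("f%03d", 1:G)))
  spiked <- sprintf("f%03d", 1:10)
  m[grp == "hfd", spiked] <- m[grp == "hfd", spiked] + 3
  fm <- feature_matrix(m, batch = rep("b1", n), scale_flag = "log2")
  res <- differential_analysis(fm, grp, lfc_threshold = 1.5, alpha = 0.05)
  called <- res$feature[res$significant]
  expect_lte(length(setdiff(called, spiked)), 1L)   # BH guarantee slack
  expect_lte(length(setdiff(spiked, called)), 1L)
  expect_gt(min(res$log2fc[res$feature %in% spiked]), 1.5)
})

test_that("BH step-up arithmetic matches the hand computation", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  # monotone in raw-p order and never above Bonferroni
  set.seed(351)
  p <- runif(50)
  bh <- p.adjust(p, "BH"); bf <- p.adjust(p, "bonferroni")
  expect_true(all(diff(bh[order(p)]) >= -1e-15))
  expect_true(all(bh <= bf + 1e-15))
})

test_that("permuted labels keep the false-positive proportion near alpha", {
  set.seed(361)
  fm <- random_batched(12, 2, 50, gamma_sd = 0, noise_sd = 1, seed = 361)
  fp <- replicate(20, {
    grp <- sample(rep(c("a", "b"), 12))
    res <- differential_analysis(fm, grp, lfc_threshold = 0, alpha = 0.05)
    mean(res$significant)
  })
  expect_lte(mean(fp), 0.05)
})

test_that("group-shape errors are caught", {
  fm <- random_batched(5, 2, 4, seed = 371)
  expect_error(differential_analysis(fm, rep("only", 10)),
               "exactly 2 levels")
  expect_error(differential_analysis(fm, c("a", rep("b", 9))),
               ">= 2 samples")
})
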