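test_that("replicate averaging is the exact per-sample arithmetic mean", {
  wl <- seq(600, 800, by = 10)
  one <- sin(wl / 50) + 2
  # ten identical replicates collapse to the same spectrum
  ss <- spectrum_set(wl, matrix(rep(one, each = 10), nrow = 10, byrow = FALSE),
                     labels = rep("a", 10), sample_ids = rep("s1", 10))
  ss$intensities <- matrix(one, 10, length(wl), byrow = TRUE)
  avg <- average_replicates(ss)
  expect_equal(nrow(avg$intensities), 1L)
  expect_equal(avg$intensities[1, ], one)

  # rows 0..9 at every wavelength average to 4.5
  ss2 <- spectrum_set(wl, matrix(0:9, 10, length(wl)),
                      labels = rep("a", 10), sample_ids = rep("s1", 10))
  expect_true(all(average_replicates(ss2)$intensities == 4.5))

  # incomplete groups are named with their counts
  ss3 <- spectrum_set(wl, matrix(1, 7, length(wl)),
                      labels = rep("a", 7),
                      sample_ids = c(rep("s1", 5), rep("s2", 2)))
  expect_error(average_replicates(ss3), "s2 \\(n=2\\)")
})

test_that("generated spectra average back to their per-sample truth", {
  cfg <- generator_config(seed = 9, lif_noise_sd = 0, lif_sample_sd = 0.2,
                          lif_baseline = 3, n_locations = 10)
  ss <- simulate_lif(cfg, c("Hydrated skin", "Dry skin"), n_samples = 4)
  truth <- attr(ss, "truth")
  avg <- average_replicates(ss)
  peak_idx <- which(avg$wavelengths == 700)
  got <- avg$intensities[match(truth$sample_id, avg$sample_ids), peak_idx]
  expect_rel(got, 3 + truth$amplitude, 1e-12)
})

test_that("peak finding smooths, locates 700 nm, and breaks ties long-ward", {
  wl <- 300:900
  gauss <- 50 * exp(-(wl - 700)^2 / (2 * 25^2))
  pk <- find_main_peak(gauss + 1, wl)
  expect_lte(abs(pk$peak_wavelength - 700), 1)

  ramp <- find_main_peak(seq_along(wl) * 0.1, wl)
  expect_identical(ramp$peak_wavelength, 900L)

  two <- 10 * exp(-(wl - 650)^2 / 200) + 10 * exp(-(wl - 700)^2 / 200)
  expect_identical(find_main_peak(two, wl)$peak_wavelength, 700L)

  expect_error(find_main_peak(rep(1, 50), 1:50), "flat")
  expect_error(find_main_peak(1:4, 1:4), "5 grid points")
})

test_that("PLSR recovers exact low-rank structure and reduces to OLS at full rank", {
  set.seed(21)
  n <- 24; p <- 60
  t1 <- rnorm(n); t2 <- rnorm(n)
  x <- outer(t1, rnorm(p)) + outer(t2, rnorm(p))
  y <- 3 * t1 - 2 * t2 + 1
  m2 <- plsr_fit(x, y, 2)
  expect_lt(max(abs(fitted(m2) - y)), 1e-10)
  expect_equal(m2$r2, 1, tolerance = 1e-10)
  # one component cannot explain a two-factor response
  expect_lt(plsr_fit(x, y, 1)$r2, 1 - 1e-6)

  # full rank: fitted values equal the least-squares oracle
  n <- 30; p <- 12
  xf <- matrix(rnorm(n * p), n)
  yf <- rnorm(n)
  mf <- plsr_fit(xf, yf, p)
  ols <- stats::fitted(stats::lm(yf ~ xf))
  expect_lt(max(abs(fitted(mf) - ols)), 1e-8)

  # guards
  expect_error(plsr_fit(xf, yf, 0), "positive integer")
  expect_error(plsr_fit(xf, yf, p + 1), "exceeds")
  xr <- cbind(xf[, 1:3], xf[, 1:3] %*% matrix(rnorm(9), 3))  # rank 3
  expect_error(plsr_fit(xr, yf, 5), "only 3 component")
})

test_that("component scores are orthogonal and r2 is monotone in component count", {
  set.seed(31)
  x <- matrix(rnorm(40 * 25), 40)
  y <- rnorm(40)
  m <- plsr_fit(x, y, 8)
  g <- crossprod(m$scores)
  expect_lt(max(abs(g - diag(8))), 1e-8)
  expect_true(all(diff(m$r2_by_component) >= -1e-12))
  expect_true(all(m$r2_by_component >= 0 & m$r2_by_component <= 1))
})

test_that("predictions are invariant to constant shifts of the predictors", {
  set.seed(41)
  x <- matrix(rnorm(20 * 15), 20)
  y <- rnorm(20)
  shift <- matrix(rep(rnorm(15, sd = 100), each = 20), 20)
  m0 <- plsr_fit(x, y, 4)
  m1 <- plsr_fit(x + shift, y, 4)
  expect_equal(fitted(m0), fitted(m1), tolerance = 1e-8)
  xnew <- matrix(rnorm(5 * 15), 5)
  expect_equal(predict(m0, xnew), predict(m1, xnew + shift[1:5, ]),
               tolerance = 1e-8)
})

test_that("SIMPLS agrees with an independent NIPALS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(3)
  n <- 30; p <- 40
  x <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("v", 1:p)))
  y <- rnorm(n)
  mine <- plsr_fit(x, y, 5)
  ref <- mixOmics::pls(x, y, ncomp = 5, scale = FALSE, mode = "regression")
  ref_fit <- predict(ref, x)$predict[, 1, 5]
  expect_lt(max(abs(fitted(mine) - ref_fit)), 1e-10)
})

test_that("r_squared matches an independent projection computation", {
  set.seed(51)
  x <- matrix(rnorm(25 * 10), 25)
  y <- x %*% rnorm(10) + rnorm(25, sd = 0.1)
  m <- plsr_fit(x, y, 10)
  # independent: residual of orthogonal projection onto [1, X]
  fit_lm <- stats::lm(y ~ x)
  r2_ref <- 1 - sum(residuals(fit_lm)^2) / sum((y - mean(y))^2)
  expect_equal(r_squared(m, x, y), r2_ref, tolerance = 1e-10)
  expect_equal(r_squared(m, x, as.numeric(fitted(m))), 1, tolerance = 1e-9)
  expect_error(r_squared(m, x, rep(1, 25)), "zero-variance")
})

test_that("training r2 degrades as generator noise grows", {
  # sample-to-sample amplitude spread off, so spectral noise is the only
  # stochastic component degrading the fit
  sds <- c(0.5, 2, 8, 32)
  mean_r2 <- vapply(sds, function(sdv) {
    mean(vapply(1:20, function(s) {
      cfg <- generator_config(seed = s, lif_noise_sd = sdv, lif_sample_sd = 0,
                              n_locations = 1)
      ss <- simulate_lif(cfg, c("Hydrated skin", "Dry skin"), n_samples = 5)
      avg <- average_replicates(ss)
      y <- as.numeric(avg$labels == "Dry skin")
      plsr_fit(avg$intensities, y, 1)$r2
    }, numeric(1)))
  }, numeric(1))
  expect_lt(stats::cor(sds, mean_r2, method = "spearman"), 0)
})

test_that("cross-validated r2 is computable and bounded by the training fit", {
  set.seed(61)
  t1 <- rnorm(30)
  x <- outer(t1, rnorm(20)) + matrix(rnorm(600, sd = 0.2), 30)
  y <- t1 + rnorm(30, sd = 0.1)
  r2_cv <- cv_r_squared(x, y, 3, folds = 5, seed = 2)
  r2_tr <- plsr_fit(x, y, 3)$r2
  expect_lt(r2_cv, r2_tr + 1e-9)
  expect_gt(r2_cv, 0.5)
})
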