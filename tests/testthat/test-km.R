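test_that("two-flux coefficients follow the linear maps from optical properties", {
  cf <- km_coeffs_from_optical(optical_properties(0.84, 26.2))
  expect_equal(cf$a_km, 1.68)
  expect_equal(cf$s_km, 19.44)
  expect_equal(cf$x, 1.08641975308642, tolerance = 1e-12)
  expect_equal(cf$y, 0.42462675362765, tolerance = 1e-12)
  # defining identities
  expect_equal(cf$a_km, cf$s_km * (cf$x - 1), tolerance = 1e-12)
  expect_equal(cf$y, sqrt(cf$x^2 - 1), tolerance = 1e-12)

  # zero absorption collapses to x = 1, y = 0
  cf0 <- km_coeffs_from_optical(optical_properties(0, 4 / 3))
  expect_equal(unlist(cf0[c("a_km", "s_km", "x", "y")]),
               c(a_km = 0, s_km = 1, x = 1, y = 0))

  # boundary of two-flux validity
  expect_error(km_coeffs_from_optical(optical_properties(3, 1)), "S_KM")
  expect_false(is_km_valid(optical_properties(3, 1)))
})

test_that("forward model reproduces the closed-form values in both dialects", {
  cf <- km_coeffs_from_optical(optical_properties(0.84, 26.2))
  rt_p <- km_forward(cf, 0.2, "paper")
  expect_equal(rt_p$rd, 0.6273159779, tolerance = 1e-9)
  expect_equal(rt_p$td, 0.1061243966, tolerance = 1e-9)
  rt_c <- km_forward(cf, 0.2, "classical")
  expect_equal(rt_c$rd, 0.6478760196, tolerance = 1e-9)
  expect_equal(rt_c$td, 0.1096025832, tolerance = 1e-9)

  # vanishing-slab limit (classical): everything is transmitted
  rt0 <- km_forward(cf, 1e-9, "classical")
  expect_lt(rt0$rd, 1e-6)
  expect_gt(rt0$td, 1 - 1e-6)

  # conservative slab, classical series branch
  cfc <- km_coefficients(0, 2)
  rtc <- km_forward(cfc, 0.5, "classical")
  expect_equal(rtc$rd + rtc$td, 1)
  expect_equal(rtc$rd, 1 / (1 + 1))  # S*D = 1
  expect_error(km_forward(cfc, 0.5, "paper"), "zero absorption")

  # huge optical depth: scaled exponentials, no NaN/overflow
  big <- km_forward(km_coefficients(50, 100), 10)
  expect_true(is.finite(big$rd) && big$rd >= 0 && big$rd < 1)
  expect_true(is.finite(big$td) && big$td >= 0)
})

test_that("energy is conserved and deposits grow with absorption", {
  # rd + td < 1 whenever absorption is present, -> 1 as mua -> 0
  for (mua in c(0.05, 0.5, 2)) {
    rt <- km_forward(km_coeffs_from_optical(optical_properties(mua, 20)),
                     0.2, "classical")
    expect_lt(rt$rd + rt$td, 1)
  }
  rt_small <- km_forward(km_coeffs_from_optical(optical_properties(1e-9, 20)),
                         0.2, "classical")
  expect_gt(rt_small$rd + rt_small$td, 1 - 1e-6)

  # monotonicity on a 10x10 grid (classical, fixed D)
  muas <- seq(0.1, 3, length.out = 10)
  musps <- seq(5, 40, length.out = 10)
  td_grid <- rd_grid <- matrix(NA_real_, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    rt <- km_forward(km_coeffs_from_optical(optical_properties(muas[i], musps[j])),
                     0.2, "classical")
    rd_grid[i, j] <- rt$rd; td_grid[i, j] <- rt$td
  }
  expect_true(all(apply(td_grid, 2, diff) < 0))  # td decreasing in mua
  expect_true(all(apply(td_grid, 1, diff) < 0))  # td decreasing in musp
  expect_true(all(apply(rd_grid, 2, diff) < 0))  # rd decreasing in mua
})

test_that("x,y extraction inverts the classical forms and guards its domain", {
  cf <- km_coeffs_from_optical(optical_properties(0.84, 26.2))
  rt <- km_forward(cf, 0.2, "classical")
  xy <- xy_from_rt(rt$rd, rt$td)
  expect_equal(xy$x, cf$x, tolerance = 1e-12)
  expect_equal(xy$y, cf$y, tolerance = 1e-12)

  xy1 <- xy_from_rt(0.5, 0.5)  # conservative slab
  expect_identical(xy1$x, 1)
  expect_identical(xy1$y, 0)

  expect_error(xy_from_rt(0, 0.5), "rd")
  expect_error(xy_from_rt(0.6, 0.5), "energy")
})

test_that("round trip recovers the generating coefficients on the full panel grid", {
  panel <- make_phantom_panel()
  for (i in seq_len(nrow(panel))) for (D in c(0.1, 0.2, 0.3)) {
    pp <- optical_properties(panel$mua[i], panel$musp[i])

    # classical dialect: unique inversion, strict recovery
    rt <- km_forward(km_coeffs_from_optical(pp), D, "classical")
    rec <- km_invert(diffuse_measurement(rt$rd, rt$td, D), "classical")
    expect_rel(c(rec$mua, rec$musp), c(pp$mua, pp$musp), 1e-8)

    # paper dialect: the printed forms are two-to-one, so recovery is
    # set-valued; the generating pair must be among the exact preimages
    rtp <- km_forward(km_coeffs_from_optical(pp), D, "paper")
    meas <- diffuse_measurement(rtp$rd, rtp$td, D)
    recp <- km_invert(meas, "paper")
    alts <- attr(recp, "alternates")
    hit <- vapply(alts, function(a)
      abs(a$mua - pp$mua) <= 1e-8 * pp$mua &&
      abs(a$musp - pp$musp) <= 1e-8 * pp$musp, logical(1))
    expect_true(any(hit))
    # and every reported preimage must reproduce the measurement exactly
    for (a in alts) {
      back <- km_forward(km_coeffs_from_optical(a), D, "paper")
      expect_rel(c(back$rd, back$td), c(rtp$rd, rtp$td), 1e-11)
    }
    # a prior resolves the branch deterministically
    recn <- km_invert(meas, "paper", near = pp)
    expect_rel(c(recn$mua, recn$musp), c(pp$mua, pp$musp), 1e-8)
  }
})

test_that("inversion guards its domain", {
  expect_error(diffuse_measurement(0.6, 0.5, 0.2), "energy")
  expect_error(diffuse_measurement(0.6, 0.4, 0.2), "energy")  # rd+td = 1
  expect_error(diffuse_measurement(1.2, 0.1, 0.2), "rd")
  expect_error(diffuse_measurement(0.3, 0.1, -1), "thickness")
  # td too large for the paper arcosh branch: no admissible root
  expect_error(km_invert(diffuse_measurement(0.05, 0.9, 0.2), "paper"),
               "inversion-domain")
})

test_that("near-conservative measurements use the series branch stably", {
  # tiny absorption: forward then invert stays accurate through y ~ 1e-7
  pp <- optical_properties(1e-14, 10)
  rt <- km_forward(km_coeffs_from_optical(pp), 0.2, "classical")
  rec <- km_invert(diffuse_measurement(rt$rd, rt$td, 0.2), "classical")
  expect_equal(rec$musp, pp$musp, tolerance = 1e-6)
})

test_that("effective attenuation equals the two-flux identity S_KM * y", {
  p1 <- optical_properties(0.84, 26.2)
  expect_equal(effective_attenuation(p1), sqrt(3 * 0.84 * 27.04),
               tolerance = 1e-12)
  expect_equal(effective_attenuation(p1), 8.2547443, tolerance = 1e-6)
  expect_equal(effective_attenuation(optical_properties(0.34, 11.2)),
               3.4308600, tolerance = 1e-6)
  expect_identical(effective_attenuation(optical_properties(0, 5)), 0)

  # algebraic identity A(A + 2S) = 3 mua (mua + musp), hence S*y = mueff
  for (mua in seq(0.1, 3, length.out = 10))
    for (musp in seq(5, 40, length.out = 10)) {
      cf <- km_coeffs_from_optical(optical_properties(mua, musp))
      expect_rel(cf$a_km * (cf$a_km + 2 * cf$s_km), 3 * mua * (mua + musp), 1e-12)
      expect_rel(cf$s_km * cf$y,
                 effective_attenuation(optical_properties(mua, musp)), 1e-12)
    }
})

test_that("closed-form S_KM matches bisection on the Td equation", {
  set.seed(11)
  for (rep in 1:100) {
    mua <- stats::runif(1, 0.05, 3)
    musp <- stats::runif(1, 3, 40)
    D <- stats::runif(1, 0.05, 0.4)
    cf <- km_coeffs_from_optical(optical_properties(mua, musp))
    for (dl in c("paper", "classical")) {
      rt <- km_forward(cf, D, dl)
      s_bis <- oracle_bisect_s(cf$x, cf$y, rt$td, D, dl)
      expect_rel(s_bis, cf$s_km, 1e-10)
    }
  }
})

test_that("measurement-table fit aggregates replicates and predicts forward", {
  cfg <- generator_config(seed = 5, noise_sd_rt = 0, n_replicates = 3)
  m <- simulate_measurements(make_phantom_panel(), cfg, "classical")
  fit <- km_fit(m, "classical")
  expect_s3_class(fit, "km_fit")
  expect_rel(fit$coefficients$mua_cm1, m$mua_true, 1e-9)
  agg <- fit$aggregates
  expect_equal(nrow(agg), 12L)
  expect_true(all(agg$n == 3L))
  expect_true(all(agg$mua_sd < 1e-9))  # noiseless replicates agree
  # predict() at the observed thicknesses reproduces the observations
  pr <- predict(fit)
  expect_rel(pr$rd, m$rd, 1e-9)
  expect_lt(max(abs(residuals(fit))), 1e-9)
  expect_equal(colnames(coef(fit)), c("mua_cm1", "musp_cm1", "mueff_cm1"))
  expect_output(print(summary(fit)), "Replicate aggregates")
  expect_error(km_fit(data.frame(rd = 0.5), "paper"), "lacks column")
})
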