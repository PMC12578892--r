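test_that("SRS resolves a single-component mixture trivially", {
  mix <- scalar_multiply(fx_srs_config$divisor_A, 2.5)
  mix$label <- "AML only"
  r <- srs_resolve(mix, fx_srs_config)
  expect_equal(r$constant_I, 2.5, tolerance = 1e-10)
  expect_equal(r$constant_II, 0, tolerance = 1e-10)
  expect_lt(max(abs(r$spectrum_CHT$absorbance)), 1e-10)
})

test_that("SRS reconstructs every component of a noiseless ternary mixture", {
  concs <- c(TEL = 20, CHT = 40, AML = 25)
  mix <- fx_mixture(concs)
  r <- srs_resolve(mix, fx_srs_config)
  expect_equal(r$constant_I, 2.5, tolerance = 1e-8) # AML 25 / divisor 10
  expect_equal(r$constant_II, 2.0, tolerance = 1e-8) # TEL 20 / divisor 10

  for (a in c("TEL", "CHT", "AML")) {
    pure <- pure_spectrum(fx_profiles[[a]], concs[[a]])
    got <- r[[paste0("spectrum_", a)]]
    expect_lt(
      max(abs(got$absorbance - pure$absorbance)) / max(pure$absorbance),
      1e-8
    )
  }
  # conservation: components sum back to the input pointwise
  total <- r$spectrum_AML$absorbance + r$spectrum_TEL$absorbance +
    r$spectrum_CHT$absorbance
  expect_lt(max(abs(total - mix$absorbance)), 1e-8)
})

test_that("SDS applies the same scheme in first-derivative space", {
  # single component: constant is the concentration ratio
  only_aml <- fx_mixture(c(TEL = 0, CHT = 0, AML = 15))
  r0 <- sds_resolve(only_aml, fx_sds_config)
  expect_equal(r0$constant_I, 1.5, tolerance = 1e-8)

  concs <- c(TEL = 20, CHT = 40, AML = 20)
  mix <- fx_mixture(concs)
  r <- sds_resolve(mix, fx_sds_config)
  expect_equal(r$constant_I, 2.0, tolerance = 1e-8) # AML 20 / divisor 10
  expect_equal(r$constant_II, 4.0, tolerance = 1e-8) # TEL 20 / divisor 5

  d1 <- function(a) first_derivative(pure_spectrum(fx_profiles[[a]], concs[[a]]))
  for (a in c("TEL", "CHT", "AML")) {
    pure <- d1(a)
    got <- r[[paste0("spectrum_", a)]]
    expect_identical(got$derivative_order, 1L)
    expect_lt(
      max(abs(got$absorbance - pure$absorbance)) / max(abs(pure$absorbance)),
      1e-8
    )
  }
  dmix <- first_derivative(mix)
  total <- r$spectrum_AML$absorbance + r$spectrum_TEL$absorbance +
    r$spectrum_CHT$absorbance
  expect_lt(max(abs(total - dmix$absorbance)), 1e-8)

  # homogeneity: doubling the mixture doubles both constants
  r2 <- sds_resolve(fx_mixture(2 * concs), fx_sds_config)
  expect_equal(r2$constant_I, 2 * r$constant_I, tolerance = 1e-8)
  expect_equal(r2$constant_II, 2 * r$constant_II, tolerance = 1e-8)
})

test_that("predicted concentrations are invariant to the divisor concentration", {
  concs <- c(TEL = 24, CHT = 30, AML = 12)
  mix <- fx_mixture(concs)
  for (div_conc in c(5, 10)) {
    cfg <- srs_config(
      divisor_A = pure_spectrum(fx_profiles$AML, div_conc),
      divisor_T = pure_spectrum(fx_profiles$TEL, div_conc)
    )
    curves <- build_calibration_curves(cfg, fx_profiles)
    q <- quantify_mixture(mix, cfg, curves)
    expect_equal(q$conc_found, unname(concs[q$analyte]), tolerance = 1e-8)
  }
})

test_that("calibration fitting matches the least-squares oracle", {
  c1 <- fit_calibration(c(1, 2, 3), c(0.1, 0.2, 0.3))
  expect_equal(c1$slope, 0.1, tolerance = 1e-12)
  expect_equal(c1$intercept, 0, tolerance = 1e-12)
  expect_equal(c1$r, 1)
  expect_equal(c1$residual_sd, 0, tolerance = 1e-12)

  # noiseless generator responses: exact straight line through the origin
  levels <- c(5, 10, 15, 20, 30, 40)
  resp <- vapply(levels, function(cc) {
    amplitude(pure_spectrum(fx_profiles$TEL, cc), "peak_to_baseline", 295.7)
  }, numeric(1))
  cv <- fit_calibration(levels, resp, analyte = "TEL")
  expect_lt(abs(cv$r - 1), 1e-9)

  # independent oracle: stats::lm on a noisy set
  x <- c(5, 10, 15, 20, 30, 40)
  y <- 0.05 * x + 0.01 + c(0.002, -0.001, 0.0015, -0.002, 0.001, -0.0005)
  got <- fit_calibration(x, y)
  ref <- lm(y ~ x)
  expect_equal(got$slope, unname(coef(ref)[2]), tolerance = 1e-12)
  expect_equal(got$intercept, unname(coef(ref)[1]), tolerance = 1e-12)
  expect_equal(got$residual_sd, summary(ref)$sigma, tolerance = 1e-12)

  expect_error(fit_calibration(c(1, 1, 1), c(1, 2, 3)), "distinct")
  expect_error(fit_calibration(c(1, 2), c(1, 2)), "distinct")
})

test_that("concentration prediction inverts the curve and flags range", {
  curve <- structure(
    list(
      analyte = "x", response_type = "", slope = 0.1, intercept = 0,
      r = 1, residual_sd = 0, conc_range = c(1, 10)
    ),
    class = "calibration_curve"
  )
  expect_equal(as.numeric(predict_concentration(curve, 0.25)), 2.5)
  expect_equal(as.numeric(predict_concentration(curve, 0)), 0)
  expect_true(attr(predict_concentration(curve, 0), "out_of_range"))
  curve$slope <- 0
  expect_error(predict_concentration(curve, 0.5), "zero")

  # round trip through a fitted curve recovers design concentrations
  levels <- c(5, 9, 13, 17, 21, 25)
  resp <- vapply(levels, function(cc) {
    amplitude(pure_spectrum(fx_profiles$AML, cc), "peak_to_baseline", 359.5)
  }, numeric(1))
  cv <- fit_calibration(levels, resp, analyte = "AML")
  back <- as.numeric(predict_concentration(cv, resp))
  expect_equal(back, levels, tolerance = 1e-6)
})

test_that("LOD/LOQ follow the residual-SD rule with fixed ratio", {
  mk <- function(rsd, slope) {
    structure(
      list(
        analyte = "", response_type = "", slope = slope, intercept = 0,
        r = 1, residual_sd = rsd, conc_range = c(1, 10)
      ),
      class = "calibration_curve"
    )
  }
  expect_equal(unname(lod_loq(mk(0, 1))), c(0, 0))
  ll <- lod_loq(mk(0.033, 1))
  expect_equal(unname(ll["lod"]), 0.1089, tolerance = 1e-12)
  expect_equal(unname(ll["loq"]), 0.33, tolerance = 1e-12)
  for (rsd in c(0.01, 0.2)) {
    ll <- lod_loq(mk(rsd, 0.7))
    expect_equal(unname(ll["loq"] / ll["lod"]), 10 / 3.3, tolerance = 1e-12)
  }
  expect_error(lod_loq(mk(0.1, -1)), "positive")
})

test_that("quantification recovers dosage-ratio mixtures by both methods", {
  mix <- fx_mixture(fx_dosage)
  for (cfg_curves in list(
    list(fx_srs_config, fx_srs_curves),
    list(fx_sds_config, fx_sds_curves)
  )) {
    q <- quantify_mixture(mix, cfg_curves[[1]], cfg_curves[[2]], nominal = fx_dosage)
    expect_equal(q$recovery_pct, rep(100, 3), tolerance = 1e-4)
  }
  # nominal absent: concentrations only
  q2 <- quantify_mixture(mix, fx_srs_config, fx_srs_curves)
  expect_false("recovery_pct" %in% names(q2))
  expect_equal(q2$conc_found, unname(fx_dosage[q2$analyte]), tolerance = 1e-6)

  # response-type mismatch between curve and method is rejected
  expect_error(
    quantify_mixture(mix, fx_sds_config, fx_srs_curves),
    "response_type"
  )
})

test_that("noisy recoveries stay inside the validation envelope", {
  reps <- 60
  rec <- vapply(seq_len(reps), function(i) {
    mix <- fx_mixture(fx_dosage, noise = noise_model(0.002, seed = 2000 + i))
    q <- quantify_mixture(mix, fx_srs_config, fx_srs_curves, nominal = fx_dosage)
    stats::setNames(q$recovery_pct, q$analyte)
  }, numeric(3))
  for (a in c("TEL", "CHT", "AML")) {
    expect_gt(mean(rec[a, ]), 98)
    expect_lt(mean(rec[a, ]), 102)
    expect_lt(100 * sd(rec[a, ]) / mean(rec[a, ]), 2)
  }
})
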