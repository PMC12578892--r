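test_that("spectrum construction enforces the grid and value invariants", {
  expect_s3_class(new_spectrum(c(200, 200.1, 200.2), c(0, 0.1, 0.2)), "spectrum")
  expect_error(new_spectrum(c(200, 201, 203), c(0, 0.1, 0.2)), "non-uniform")
  expect_error(new_spectrum(c(200, 199), c(0, 0.1)), "increasing")
  expect_error(new_spectrum(200, 0.1), "length")
  expect_error(new_spectrum(c(200, 201), c(0, NaN)), "finite")
  expect_error(new_spectrum(c(200, 201), c(0, 1), derivative_order = 2), "derivative_order")
})

test_that("spectrum CSV round-trips values, derivative order and label", {
  s <- pure_spectrum(fx_profiles$TEL, 12.5, c(250, 350, 0.5))
  s$label <- "TEL 12.5 ug/mL"
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(s, path)
  r <- read_spectrum_csv(path)
  expect_equal(r$wavelengths, s$wavelengths, tolerance = 1e-12)
  expect_equal(r$absorbance, s$absorbance, tolerance = 1e-12)
  expect_identical(r$derivative_order, 0L)
  expect_identical(r$label, "TEL 12.5 ug/mL")

  d <- first_derivative(s)
  write_spectrum_csv(d, path)
  expect_identical(read_spectrum_csv(path)$derivative_order, 1L)
})

test_that("malformed spectrum CSVs are rejected with a useful message", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,absorbance", "200,0.0", "201,0.1", "203,0.2"), path)
  expect_error(read_spectrum_csv(path), "non-uniform grid")
  writeLines(c("wavelength_nm,absorbance", "200,0.0", "oops,0.1"), path)
  expect_error(read_spectrum_csv(path), "non-numeric")
})

test_that("linear_combination scales, cancels, and reproduces generator mixtures", {
  s <- pure_spectrum(fx_profiles$CHT, 10)
  doubled <- linear_combination(list(s), 2)
  expect_equal(doubled$absorbance, 2 * s$absorbance)
  zero <- linear_combination(list(s, s), c(1, -1))
  expect_true(all(zero$absorbance == 0))

  unit <- lapply(fx_profiles, pure_spectrum, concentration = 1, grid = fx_grid)
  combo <- linear_combination(unit[c("TEL", "CHT", "AML")], c(1, 2, 4))
  mix <- fx_mixture(c(TEL = 1, CHT = 2, AML = 4))
  expect_equal(combo$absorbance, mix$absorbance, tolerance = 1e-12)

  short <- pure_spectrum(fx_profiles$CHT, 10, c(200, 300, 0.1))
  expect_error(linear_combination(list(s, short), c(1, 1)), "grid")
})

test_that("ratio_spectrum divides, guards small divisors, and round-trips", {
  s <- pure_spectrum(fx_profiles$AML, 10)
  one <- ratio_spectrum(s, s)
  expect_equal(one$absorbance[one$valid], rep(1, sum(one$valid)))
  two <- ratio_spectrum(scalar_multiply(s, 2), s)
  expect_equal(two$absorbance[two$valid], rep(2, sum(two$valid)))

  mix <- fx_mixture(c(TEL = 0, CHT = 0, AML = 25))
  r <- ratio_spectrum(mix, s)
  idx <- which(r$wavelengths >= 355 & r$wavelengths <= 385)
  expect_true(all(r$valid[idx]))
  expect_equal(r$absorbance[idx], rep(2.5, length(idx)), tolerance = 1e-10)

  # multiply-back reconstruction at every valid point
  back <- pointwise_multiply(r, s)
  ok <- r$valid
  expect_equal(back$absorbance[ok], mix$absorbance[ok], tolerance = 1e-10)
})

test_that("subtract/multiply algebra reconstructs the mixture exactly", {
  mix <- fx_mixture(c(TEL = 20, CHT = 40, AML = 25))
  divisor <- pure_spectrum(fx_profiles$AML, 10)
  r <- ratio_spectrum(mix, divisor)
  cI <- plateau_constant(r, c(355, 385))$value
  recon <- linear_combination(
    list(
      pointwise_multiply(subtract_constant(r, cI), divisor),
      scalar_multiply(divisor, cI)
    ),
    c(1, 1)
  )
  ok <- r$valid
  expect_equal(recon$absorbance[ok], mix$absorbance[ok], tolerance = 1e-10)

  expect_equal(subtract_constant(mix, 0)$absorbance, mix$absorbance)
  flat <- new_spectrum(c(300, 301, 302), rep(2.5, 3))
  expect_true(all(subtract_constant(flat, 2.5)$absorbance == 0))
  ones <- new_spectrum(mix$wavelengths, rep(1, length(mix$wavelengths)))
  expect_equal(pointwise_multiply(mix, ones)$absorbance, mix$absorbance)
  expect_equal(scalar_multiply(mix, 1)$absorbance, mix$absorbance)
  expect_true(all(scalar_multiply(mix, 0)$absorbance == 0))
})

test_that("gap first derivative matches its closed-form cases and is linear", {
  wl <- seq(200, 400, 0.1)
  flat <- new_spectrum(wl, rep(0.7, length(wl)))
  d <- first_derivative(flat)
  expect_true(all(d$absorbance == 0))
  expect_identical(d$derivative_order, 1L)
  expect_equal(range(d$wavelengths), c(205, 395))

  # linear ramp A = 0.001*lambda: D1 = scaling * slope * delta = 10*0.001*10
  ramp <- new_spectrum(wl, 0.001 * wl)
  dr <- first_derivative(ramp)
  expect_equal(dr$absorbance, rep(0.1, length(dr$absorbance)), tolerance = 1e-12)

  # single Gaussian band: derivative crosses zero at the band centre
  dg <- first_derivative(pure_spectrum(fx_profiles$CHT, 10))
  inb <- dg$wavelengths > 250 & dg$wavelengths < 299
  zc <- dg$wavelengths[inb]
  i <- which(diff(sign(dg$absorbance[inb])) != 0)[1]
  expect_lt(abs(zc[i] - 275), 0.1 + 1e-9)

  s1 <- pure_spectrum(fx_profiles$TEL, 10)
  s2 <- pure_spectrum(fx_profiles$AML, 10)
  lhs <- first_derivative(linear_combination(list(s1, s2), c(2, -3)))
  rhs <- linear_combination(list(first_derivative(s1), first_derivative(s2)), c(2, -3))
  expect_equal(lhs$absorbance, rhs$absorbance, tolerance = 1e-10)

  expect_error(first_derivative(lhs), "zero-order")
  expect_error(
    first_derivative(flat, derivative_params(0.35, 10)),
    "integer multiple"
  )
})

test_that("plateau_constant estimates window means with a flatness diagnostic", {
  wl <- seq(300, 400, 0.1)
  flat <- new_spectrum(wl, rep(2, length(wl)))
  est <- plateau_constant(flat, c(320, 340))
  expect_equal(est$value, 2)
  expect_equal(est$rsd_percent, 0)
  expect_true(est$flat)

  # ratio of c1*S to c2*S is exactly c1/c2 with zero RSD
  s <- pure_spectrum(fx_profiles$AML, 10)
  r <- ratio_spectrum(scalar_multiply(s, 1.5), s)
  est2 <- plateau_constant(r, c(355, 385))
  expect_equal(est2$value, 1.5, tolerance = 1e-12)
  expect_equal(est2$rsd_percent, 0, tolerance = 1e-6)

  # noisy mixture: estimate close, RSD positive, reproducible
  mix <- fx_mixture(c(TEL = 0, CHT = 0, AML = 15), noise = noise_model(0.002, seed = 42))
  est3 <- plateau_constant(ratio_spectrum(mix, s), c(355, 385))
  expect_lt(abs(est3$value - 1.5), 0.05)
  expect_gt(est3$rsd_percent, 0)

  expect_error(plateau_constant(flat, c(500, 520)), "outside")
  rough <- new_spectrum(wl, seq(1, 3, length.out = length(wl)))
  expect_false(plateau_constant(rough, c(320, 340))$flat)
})

test_that("amplitude measures fixed-wavelength responses linearly", {
  wl <- seq(200, 400, 0.1)
  zero <- new_spectrum(wl, rep(0, length(wl)))
  expect_equal(amplitude(zero, "peak_to_baseline", 231), 0)
  expect_equal(amplitude(zero, "peak_to_peak", 231, 246), 0)

  vals <- rep(0, length(wl))
  vals[wl == 231] <- -0.4
  vals[wl == 246] <- 0.6
  s <- new_spectrum(wl, vals)
  expect_equal(amplitude(s, "peak_to_peak", 231, 246), 1.0)
  expect_equal(amplitude(s, "peak_to_baseline", 231), -0.4)

  d10 <- first_derivative(pure_spectrum(fx_profiles$TEL, 10))
  d25 <- first_derivative(pure_spectrum(fx_profiles$TEL, 25))
  a10 <- amplitude(d10, "peak_to_peak", 282.5, 313)
  a25 <- amplitude(d25, "peak_to_peak", 282.5, 313)
  expect_equal(a25 / a10, 2.5, tolerance = 1e-10)

  expect_error(amplitude(d10, "peak_to_baseline", 201), "off the grid")
  expect_error(amplitude(s, "peak_to_peak", 231), "lambda2")
})

test_that("resampling is explicit and linear interpolation is exact on lines", {
  wl <- seq(200, 300, 0.5)
  s <- new_spectrum(wl, 0.01 * wl)
  r <- resample_spectrum(s, c(210, 290, 0.1))
  expect_equal(grid_step(r), 0.1)
  expect_equal(r$absorbance, 0.01 * r$wavelengths, tolerance = 1e-12)
  expect_error(resample_spectrum(s, c(100, 290, 0.1)), "beyond")
})
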