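#' Configuration for successive ratio subtraction (SRS-CM)
#'
#' Successive ratio subtraction works in zero-order space, removing the most
#' spectrally extended component (AML) first, then the next (TEL), leaving
#' the least extended (CHT). Defaults follow the method's reference
#' operating conditions: AML divisor 10.0 ug/mL, TEL divisor 10.0 ug/mL,
#' plateau windows 355.0-385.0 nm (constant I, AML/AML') and 300.0-321.0 nm
#' (constant II, TEL/TEL'); each analyte is measured peak-to-baseline at its
#' zero-order absorption maximum (TEL 295.7, CHT 275.0, AML 359.5 nm).
#'
#' @param divisor_A Zero-order pure AML divisor spectrum (default
#'   concentration 10.0 ug/mL).
#' @param divisor_T Zero-order pure TEL divisor spectrum (10.0 ug/mL).
#' @param plateau_window_I,plateau_window_II `(nm, nm)` plateau windows for
#'   constants I and II; must be disjoint.
#' @param measurements Named list (`TEL`, `CHT`, `AML`) of lists
#'   `(mode, lambda1, lambda2)` passed to [amplitude()].
#' @param eps Division guard passed to [ratio_spectrum()] (`NULL` = default).
#' @param flatness_tol_percent Plateau flatness tolerance in percent.
#' @param estimator Plateau estimator, `"mean"` or `"median"`.
#' @return Object of class `resolution_config` with `method = "SRS"`.
#' @export
srs_config <- function(divisor_A, divisor_T,
                       plateau_window_I = c(355.0, 385.0),
                       plateau_window_II = c(300.0, 321.0),
                       measurements = list(
                         TEL = list(mode = "peak_to_baseline", lambda1 = 295.7),
                         CHT = list(mode = "peak_to_baseline", lambda1 = 275.0),
                         AML = list(mode = "peak_to_baseline", lambda1 = 359.5)
                       ),
                       eps = NULL, flatness_tol_percent = 2,
                       estimator = "mean") {
  new_resolution_config(
    "SRS", divisor_A, divisor_T, plateau_window_I, plateau_window_II,
    measurements, NULL, eps, flatness_tol_percent, estimator
  )
}

#' Configuration for successive derivative subtraction (SDS-CM)
#'
#' The same successive scheme applied in first-derivative space: divisors
#' are supplied as zero-order spectra and differentiated internally with the
#' configured [derivative_params()] (gap 10 nm, scaling 10). Defaults: AML
#' divisor 10.0 ug/mL, TEL divisor 5.0 ug/mL; plateau windows 375.0-390.0 nm
#' (constant I) and 305.0-325.0 nm (constant II); amplitudes peak-to-peak
#' 231.0-246.0 nm (AML), peak-to-peak 282.5-313.0 nm (TEL) and
#' peak-to-baseline 287.0 nm (CHT). Plateau constants use signed derivative
#' ratios, which are constant wherever a single component survives.
#'
#' @inheritParams srs_config
#' @param derivative A [derivative_params()] object.
#' @return Object of class `resolution_config` with `method = "SDS"`.
#' @export
sds_config <- function(divisor_A, divisor_T,
                       plateau_window_I = c(375.0, 390.0),
                       plateau_window_II = c(305.0, 325.0),
                       measurements = list(
                         TEL = list(mode = "peak_to_peak", lambda1 = 282.5, lambda2 = 313.0),
                         CHT = list(mode = "peak_to_baseline", lambda1 = 287.0),
                         AML = list(mode = "peak_to_peak", lambda1 = 231.0, lambda2 = 246.0)
                       ),
                       derivative = derivative_params(10, 10),
                       eps = NULL, flatness_tol_percent = 2,
                       estimator = "mean") {
  new_resolution_config(
    "SDS", divisor_A, divisor_T, plateau_window_I, plateau_window_II,
    measurements, derivative, eps, flatness_tol_percent, estimator
  )
}

new_resolution_config <- function(method, divisor_A, divisor_T,
                                  window_I, window_II, measurements,
                                  derivative, eps, flatness_tol_percent,
                                  estimator) {
  stopifnot(inherits(divisor_A, "spectrum"), inherits(divisor_T, "spectrum"))
  if (divisor_A$derivative_order != 0L || divisor_T$derivative_order != 0L) {
    stop("divisors must be supplied as zero-order spectra")
  }
  if (max(window_I[1], window_II[1]) <= min(window_I[2], window_II[2])) {
    stop("plateau windows must be disjoint")
  }
  stopifnot(all(c("TEL", "CHT", "AML") %in% names(measurements)))
  structure(
    list(
      method = method, divisor_A = divisor_A, divisor_T = divisor_T,
      plateau_window_I = as.numeric(window_I),
      plateau_window_II = as.numeric(window_II),
      measurements = measurements, derivative = derivative,
      eps = eps, flatness_tol_percent = flatness_tol_percent,
      estimator = estimator
    ),
    class = "resolution_config"
  )
}

resolve_successive <- function(mixture, divisor_A, divisor_T, config) {
  pc <- function(s, w) {
    plateau_constant(s, w,
      flatness_tol_percent = config$flatness_tol_percent,
      estimator = config$estimator
    )
  }
  ratio_I <- ratio_spectrum(mixture, divisor_A, eps = config$eps)
  est_I <- pc(ratio_I, config$plateau_window_I)
  spectrum_AML <- scalar_multiply(divisor_A, est_I$value)
  remainder <- pointwise_multiply(
    subtract_constant(ratio_I, est_I$value), divisor_A
  )
  # outside the divisor's support the guarded ratio carries no information;
  # the remainder there is the mixture itself minus the reconstructed component
  bad <- !ratio_I$valid
  if (any(bad)) {
    remainder$absorbance[bad] <-
      mixture$absorbance[bad] - spectrum_AML$absorbance[bad]
    remainder$valid[bad] <- mixture$valid[bad]
  }
  ratio_II <- ratio_spectrum(remainder, divisor_T, eps = config$eps)
  est_II <- pc(ratio_II, config$plateau_window_II)
  spectrum_TEL <- scalar_multiply(divisor_T, est_II$value)
  spectrum_CHT <- pointwise_multiply(
    subtract_constant(ratio_II, est_II$value), divisor_T
  )
  bad2 <- !ratio_II$valid
  if (any(bad2)) {
    spectrum_CHT$absorbance[bad2] <-
      remainder$absorbance[bad2] - spectrum_TEL$absorbance[bad2]
    spectrum_CHT$valid[bad2] <- remainder$valid[bad2]
  }
  warnings <- c(est_I$warning, est_II$warning)
  structure(
    list(
      method = config$method,
      constant_I = est_I$value, constant_II = est_II$value,
      spectrum_AML = spectrum_AML, spectrum_TEL = spectrum_TEL,
      spectrum_CHT = spectrum_CHT,
      diagnostics = list(
        plateau_I = est_I, plateau_II = est_II,
        warnings = warnings
      )
    ),
    class = "resolution_result"
  )
}

#' @export
print.resolution_result <- function(x, ...) {
  cat(sprintf(
    "<%s-CM resolution> constant I = %.6g, constant II = %.6g%s\n",
    x$method, x$constant_I, x$constant_II,
    if (length(x$diagnostics$warnings)) " [plateau warnings]" else ""
  ))
  invisible(x)
}

#' Successive ratio subtraction coupled with constant multiplication
#'
#' Resolves a zero-order three-component mixture spectrum:
#' constant I = plateau of `mixture / divisor_A` on window I (the AML/AML'
#' concentration ratio); `AML = constant I x divisor_A`; the remainder
#' `(mixture/divisor_A - constant I) x divisor_A` holds TEL + CHT, and the
#' same step with `divisor_T` on window II yields TEL and finally CHT.
#' The three reconstructed spectra sum to the input pointwise.
#'
#' @param mixture Zero-order mixture spectrum on the divisors' grid.
#' @param config An [srs_config()].
#' @return Object of class `resolution_result` with `constant_I`,
#'   `constant_II`, reconstructed `spectrum_AML` / `spectrum_TEL` /
#'   `spectrum_CHT` (zero-order) and plateau `diagnostics`.
#' @export
srs_resolve <- function(mixture, config) {
  stopifnot(inherits(config, "resolution_config"), config$method == "SRS")
  if (mixture$derivative_order != 0L) stop("mixture must be zero-order")
  check_same_grid(mixture, config$divisor_A)
  check_same_grid(mixture, config$divisor_T)
  resolve_successive(mixture, config$divisor_A, config$divisor_T, config)
}

#' Successive derivative subtraction coupled with constant multiplication
#'
#' The identical successive scheme applied in first-derivative space: the
#' mixture and both divisors are differentiated with the configured
#' [derivative_params()], and the outputs are first-derivative spectra whose
#' sum conserves `D1(mixture)` pointwise.
#'
#' @param mixture Zero-order mixture spectrum on the divisors' grid.
#' @param config An [sds_config()].
#' @return Object of class `resolution_result`; reconstructed spectra carry
#'   `derivative_order = 1`.
#' @export
sds_resolve <- function(mixture, config) {
  stopifnot(inherits(config, "resolution_config"), config$method == "SDS")
  if (mixture$derivative_order != 0L) stop("mixture must be zero-order")
  check_same_grid(mixture, config$divisor_A)
  check_same_grid(mixture, config$divisor_T)
  d1 <- function(s) first_derivative(s, config$derivative)
  resolve_successive(d1(mixture), d1(config$divisor_A), d1(config$divisor_T), config)
}

#' Ordinary least-squares calibration curve
#'
#' Fits `response = intercept + slope * concentration` with [stats::lm()],
#' returning slope, intercept, Pearson correlation and the residual standard
#' deviation `sqrt(sum(resid^2)/(n - 2))`.
#'
#' @param concentrations Concentrations in ug/mL (>= 3 distinct values).
#' @param responses Matching responses (absorbance or derivative amplitude).
#' @param analyte Analyte name carried in the result.
#' @param response_type Free-text description of the response, checked by
#'   [quantify_mixture()] against the method's measurement mode.
#' @return Object of class `calibration_curve` with `slope`, `intercept`,
#'   `r`, `residual_sd` and `conc_range`.
#' @export
fit_calibration <- function(concentrations, responses, analyte = "",
                            response_type = "") {
  stopifnot(length(concentrations) == length(responses))
  if (length(unique(concentrations)) < 3L) {
    stop("calibration needs at least 3 distinct concentrations")
  }
  if (stats::var(concentrations) == 0) stop("zero concentration variance")
  fit <- stats::lm(responses ~ concentrations)
  res <- stats::residuals(fit)
  n <- length(res)
  structure(
    list(
      analyte = analyte, response_type = response_type,
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r = stats::cor(concentrations, responses),
      residual_sd = sqrt(sum(res^2) / (n - 2)),
      conc_range = range(concentrations)
    ),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration %s> response = %.5g + %.5g x conc (r = %.5f, s_res = %.3g) on %g-%g ug/mL\n",
    x$analyte, x$intercept, x$slope, x$r, x$residual_sd,
    x$conc_range[1], x$conc_range[2]
  ))
  invisible(x)
}

#' Invert a calibration curve
#'
#' `(response - intercept) / slope`. Results outside the calibrated
#' concentration range are flagged with a warning attribute, never clipped.
#'
#' @param curve A [fit_calibration()] object.
#' @param response Response value(s) in the curve's units.
#' @return Concentration(s) in ug/mL; attribute `out_of_range` flags values
#'   outside `conc_range`.
#' @export
predict_concentration <- function(curve, response) {
  if (curve$slope == 0) stop("calibration slope is zero")
  conc <- (response - curve$intercept) / curve$slope
  oor <- conc < curve$conc_range[1] - 1e-9 | conc > curve$conc_range[2] + 1e-9
  attr(conc, "out_of_range") <- oor
  conc
}

#' Detection and quantitation limits from calibration residuals
#'
#' `LOD = 3.3 * residual_sd / slope`, `LOQ = 10 * residual_sd / slope`
#' (ICH residual-standard-deviation approach); their ratio is 10/3.3 for
#' any curve.
#'
#' @param curve A [fit_calibration()] object with positive slope.
#' @return Named numeric `c(lod, loq)` in ug/mL.
#' @export
lod_loq <- function(curve) {
  if (curve$slope <= 0) stop("lod_loq requires a positive slope")
  c(
    lod = 3.3 * curve$residual_sd / curve$slope,
    loq = 10 * curve$residual_sd / curve$slope
  )
}

measure_response <- function(spectrum, m) {
  amplitude(spectrum,
    mode = m$mode, lambda1 = m$lambda1,
    lambda2 = if (!is.null(m$lambda2)) m$lambda2 else NULL
  )
}

#' Resolve a mixture spectrum and quantify all three analytes
#'
#' Runs [srs_resolve()] or [sds_resolve()] per the config, measures each
#' reconstructed component spectrum at its configured wavelength/mode, and
#' inverts the matching calibration curve. If nominal concentrations are
#' supplied, recoveries `100 * found / nominal` are reported.
#'
#' @param mixture Zero-order mixture spectrum.
#' @param config An [srs_config()] or [sds_config()].
#' @param curves Named list (`TEL`, `CHT`, `AML`) of [fit_calibration()]
#'   curves whose `response_type` matches the method's measurement modes.
#' @param nominal Optional named numeric of nominal concentrations (ug/mL).
#' @return Data frame with one row per analyte: `analyte`, `method`,
#'   `constant_I`, `constant_II`, `response`, `conc_found` and (when nominal
#'   is given) `recovery_pct`.
#' @export
quantify_mixture <- function(mixture, config, curves, nominal = NULL) {
  stopifnot(all(c("TEL", "CHT", "AML") %in% names(curves)))
  expected_rt <- response_type_for(config)
  for (a in c("TEL", "CHT", "AML")) {
    rt <- curves[[a]]$response_type
    if (nzchar(rt) && rt != expected_rt[[a]]) {
      stop(sprintf(
        "curve for %s has response_type '%s'; method %s measures '%s'",
        a, rt, config$method, expected_rt[[a]]
      ))
    }
  }
  res <- if (config$method == "SRS") {
    srs_resolve(mixture, config)
  } else {
    sds_resolve(mixture, config)
  }
  spectra <- list(
    TEL = res$spectrum_TEL, CHT = res$spectrum_CHT, AML = res$spectrum_AML
  )
  rows <- lapply(c("TEL", "CHT", "AML"), function(a) {
    resp <- measure_response(spectra[[a]], config$measurements[[a]])
    conc <- as.numeric(predict_concentration(curves[[a]], resp))
    out <- data.frame(
      analyte = a, method = config$method,
      constant_I = res$constant_I, constant_II = res$constant_II,
      response = resp, conc_found = conc
    )
    if (!is.null(nominal)) out$recovery_pct <- 100 * conc / nominal[[a]]
    out
  })
  do.call(rbind, rows)
}

response_type_for <- function(config) {
  lapply(config$measurements, function(m) {
    if (m$mode == "peak_to_baseline") {
      sprintf("D%d@%.1f", if (config$method == "SRS") 0L else 1L, m$lambda1)
    } else {
      sprintf("D1pp@%.1f-%.1f", m$lambda1, m$lambda2)
    }
  })
}

#' Build univariate calibration curves from pure standards
#'
#' Constructs one calibration curve per analyte from noise-free (or noisy)
#' pure-component spectra at the given concentration levels, measuring each
#' spectrum the way the method's configuration prescribes (zero-order
#' absorbance at the analyte's maximum for SRS; derivative amplitude for
#' SDS). This mirrors bench practice, where calibration standards are pure
#' solutions scanned separately.
#'
#' @param config An [srs_config()] or [sds_config()].
#' @param profiles Named list of [component_profile()] objects.
#' @param levels Named list of concentration vectors (ug/mL) per analyte;
#'   defaults to six levels over TEL 5-40, CHT 10-100, AML 5-25.
#' @param noise A [noise_model()] applied to each standard spectrum.
#' @param grid `(start, stop, step)` in nm.
#' @return Named list of [fit_calibration()] curves.
#' @export
build_calibration_curves <- function(config, profiles = default_profiles(),
                                     levels = list(
                                       TEL = c(5, 10, 15, 20, 30, 40),
                                       CHT = c(10, 25, 40, 60, 80, 100),
                                       AML = c(5, 9, 13, 17, 21, 25)
                                     ),
                                     noise = noise_model(),
                                     grid = default_grid) {
  rts <- response_type_for(config)
  curves <- list()
  for (a in names(levels)) {
    resp <- vapply(seq_along(levels[[a]]), function(i) {
      seed_i <- if (is.null(noise$seed)) NULL else noise$seed + 1000L * match(a, names(levels)) + i
      s <- mixture_spectrum(
        profiles[a], levels[[a]][i],
        noise = noise_model(noise$additive_sd, seed_i), grid = grid
      )
      if (config$method == "SDS") s <- first_derivative(s, config$derivative)
      measure_response(s, config$measurements[[a]])
    }, numeric(1))
    curves[[a]] <- fit_calibration(levels[[a]], resp,
      analyte = a,
      response_type = rts[[a]]
    )
  }
  curves
}
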