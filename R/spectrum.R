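#' Spectrum objects on a uniform wavelength grid
#'
#' A `spectrum` is the package's basic data type: a strictly increasing,
#' uniformly spaced wavelength grid (nm) with one absorbance value (AU) per
#' grid point, a derivative-order tag (0 = zero-order absorbance trace,
#' 1 = first gap-derivative), a free-text label, and a logical validity mask.
#' Points masked invalid (e.g. by the division guard of [ratio_spectrum()])
#' are excluded from plateau and amplitude measurements downstream.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly increasing
#'   on a uniform grid (relative step tolerance 1e-9).
#' @param absorbance Numeric vector of absorbance values (AU), same length.
#' @param derivative_order Integer 0 or 1.
#' @param label Free-text label (analyte id, concentration annotation).
#' @param valid Logical mask, `TRUE` where the trace is usable.
#' @return An object of class `spectrum`.
#' @examples
#' s <- new_spectrum(seq(200, 400, 0.1), rep(0.5, 2001), label = "flat")
#' grid_step(s)
#' @export
new_spectrum <- function(wavelengths, absorbance, derivative_order = 0L,
                         label = "", valid = NULL) {
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.numeric(absorbance)
  n <- length(wavelengths)
  if (n < 2L || length(absorbance) != n) {
    stop("wavelengths and absorbance must have equal length >= 2")
  }
  d <- diff(wavelengths)
  if (any(d <= 0)) stop("wavelengths must be strictly increasing")
  step <- d[1]
  rel <- abs(d - step) / step
  if (any(rel > 1e-9)) {
    i <- which(rel > 1e-9)[1]
    stop(sprintf(
      "non-uniform grid: interval [%g, %g] has step %g, expected %g",
      wavelengths[i], wavelengths[i + 1], d[i], step
    ))
  }
  if (!all(is.finite(absorbance))) stop("all absorbance values must be finite")
  if (!derivative_order %in% c(0L, 1L)) stop("derivative_order must be 0 or 1")
  if (is.null(valid)) valid <- rep(TRUE, n)
  stopifnot(is.logical(valid), length(valid) == n)
  structure(
    list(
      wavelengths = wavelengths, absorbance = absorbance,
      derivative_order = as.integer(derivative_order),
      label = as.character(label), valid = valid
    ),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf(
    "<spectrum D%d> %d points, %.1f-%.1f nm (step %g nm)%s%s\n",
    x$derivative_order, length(x$wavelengths),
    min(x$wavelengths), max(x$wavelengths), grid_step(x),
    if (nzchar(x$label)) paste0(" label: ", x$label) else "",
    if (any(!x$valid)) sprintf(" [%d masked]", sum(!x$valid)) else ""
  ))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelengths, absorbance = x$absorbance)
}

#' Grid step of a spectrum
#' @param spectrum A [new_spectrum()] object.
#' @return Step in nm.
#' @export
grid_step <- function(spectrum) {
  (spectrum$wavelengths[length(spectrum$wavelengths)] - spectrum$wavelengths[1]) /
    (length(spectrum$wavelengths) - 1)
}

same_grid <- function(a, b) {
  length(a$wavelengths) == length(b$wavelengths) &&
    all(abs(a$wavelengths - b$wavelengths) <= 1e-9 * pmax(1, abs(a$wavelengths)))
}

check_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("spectra are not on the same wavelength grid")
}

window_index <- function(spectrum, window) {
  if (length(window) != 2L || window[1] >= window[2]) {
    stop("window must be an increasing (nm, nm) pair")
  }
  w <- spectrum$wavelengths
  if (window[1] < w[1] - 1e-9 || window[2] > w[length(w)] + 1e-9) {
    stop(sprintf(
      "window [%g, %g] lies outside the spectrum grid [%g, %g]",
      window[1], window[2], w[1], w[length(w)]
    ))
  }
  which(w >= window[1] - 1e-9 & w <= window[2] + 1e-9)
}

#' Derivative parameters for the gap first derivative
#'
#' The first derivative is computed as an instrument-style gap difference:
#' `D1(lambda) = scaling_factor * (A(lambda + delta/2) - A(lambda - delta/2))`,
#' without division by `delta_lambda`; the absolute scale is immaterial
#' because calibration regressions absorb it.
#'
#' @param delta_lambda Gap width in nm (default 10); `delta_lambda/2` must be
#'   an integer multiple of the grid step.
#' @param scaling_factor Dimensionless multiplier (default 10).
#' @return An object of class `derivative_params`.
#' @export
derivative_params <- function(delta_lambda = 10, scaling_factor = 10) {
  stopifnot(delta_lambda > 0, scaling_factor > 0)
  structure(list(delta_lambda = delta_lambda, scaling_factor = scaling_factor),
    class = "derivative_params"
  )
}

#' Read a spectrum from a two-column CSV file
#'
#' Expects columns `wavelength_nm,absorbance` (one optional header row) and
#' optional `# key: value` comment lines carrying `derivative_order` and
#' `label`. Rows are sorted by wavelength; a non-uniform grid is rejected.
#'
#' @param path File path.
#' @return A [new_spectrum()] object.
#' @seealso [write_spectrum_csv()]
#' @export
read_spectrum_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^\\s*#", lines, value = TRUE)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L) stop("no data rows in ", path)
  # drop a single non-numeric header row if present
  first <- strsplit(body[1], ",")[[1]]
  if (suppressWarnings(is.na(as.numeric(first[1])))) body <- body[-1]
  parts <- strsplit(body, ",")
  bad <- vapply(parts, function(p) {
    length(p) < 2L || any(is.na(suppressWarnings(as.numeric(p[1:2]))))
  }, logical(1))
  if (any(bad)) {
    stop(sprintf("non-numeric row %d in %s: '%s'", which(bad)[1], path, body[which(bad)[1]]))
  }
  wl <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
  ab <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  o <- order(wl)
  dorder <- 0L
  label <- ""
  for (m in meta) {
    kv <- sub("^\\s*#\\s*", "", m)
    if (grepl("^derivative_order\\s*:", kv)) {
      dorder <- as.integer(trimws(sub("^derivative_order\\s*:", "", kv)))
    }
    if (grepl("^label\\s*:", kv)) label <- trimws(sub("^label\\s*:", "", kv))
  }
  new_spectrum(wl[o], ab[o], derivative_order = dorder, label = label)
}

#' Write a spectrum to CSV
#'
#' Emits `# derivative_order` / `# label` comment lines, a
#' `wavelength_nm,absorbance` header and one row per grid point, in the
#' dialect read back by [read_spectrum_csv()].
#'
#' @param spectrum A spectrum.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# derivative_order: %d", spectrum$derivative_order), con)
  if (nzchar(spectrum$label)) writeLines(paste0("# label: ", spectrum$label), con)
  writeLines("wavelength_nm,absorbance", con)
  writeLines(
    sprintf("%.6f,%.12g", spectrum$wavelengths, spectrum$absorbance),
    con
  )
  invisible(path)
}

#' Linear combination of spectra
#'
#' Pointwise `sum_i coefficients[i] * spectra[[i]]`; Beer-Lambert additivity
#' makes a noiseless mixture exactly such a combination of its pure
#' components. All spectra must share grid and derivative order.
#'
#' @param spectra List of spectra on a common grid.
#' @param coefficients Numeric vector, one coefficient per spectrum.
#' @return A spectrum; validity masks are intersected.
#' @export
linear_combination <- function(spectra, coefficients) {
  stopifnot(length(spectra) >= 1L, length(spectra) == length(coefficients))
  ref <- spectra[[1]]
  acc <- rep(0, length(ref$wavelengths))
  valid <- rep(TRUE, length(ref$wavelengths))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    check_same_grid(ref, s)
    if (s$derivative_order != ref$derivative_order) {
      stop("all spectra must share derivative_order")
    }
    acc <- acc + coefficients[i] * s$absorbance
    valid <- valid & s$valid
  }
  new_spectrum(ref$wavelengths, acc,
    derivative_order = ref$derivative_order,
    label = "linear combination", valid = valid
  )
}

#' Ratio spectrum (pointwise division with a guard)
#'
#' Divides `numerator` by `divisor` pointwise. Where `|divisor| < eps` the
#' quotient is meaningless; those points are masked invalid (value 0, never
#' used downstream) rather than zero-filled, so spurious constants cannot
#' leak into plateau windows.
#'
#' @param numerator,divisor Spectra on a common grid with equal derivative
#'   order.
#' @param eps Division guard in AU; default `1e-6 * max(abs(divisor))`.
#' @return A spectrum of the pointwise ratio with guard mask applied.
#' @export
ratio_spectrum <- function(numerator, divisor, eps = NULL) {
  check_same_grid(numerator, divisor)
  if (numerator$derivative_order != divisor$derivative_order) {
    stop("numerator and divisor must share derivative_order")
  }
  if (is.null(eps)) eps <- 1e-6 * max(abs(divisor$absorbance))
  stopifnot(eps > 0)
  ok <- abs(divisor$absorbance) >= eps
  vals <- ifelse(ok, numerator$absorbance / ifelse(ok, divisor$absorbance, 1), 0)
  new_spectrum(numerator$wavelengths, vals,
    derivative_order = numerator$derivative_order,
    label = "ratio spectrum",
    valid = numerator$valid & divisor$valid & ok
  )
}

#' Subtract a constant from a spectrum
#' @param spectrum A spectrum.
#' @param c Dimensionless constant.
#' @return `spectrum - c` pointwise.
#' @export
subtract_constant <- function(spectrum, c) {
  new_spectrum(spectrum$wavelengths, spectrum$absorbance - c,
    derivative_order = spectrum$derivative_order,
    label = spectrum$label, valid = spectrum$valid
  )
}

#' Pointwise product of two spectra
#'
#' Used to multiply a (ratio minus constant) spectrum back by its divisor.
#' The derivative order of the result follows the first operand; the caller
#' asserts the semantics.
#'
#' @param a,b Spectra on a common grid.
#' @return Pointwise `a * b`.
#' @export
pointwise_multiply <- function(a, b) {
  check_same_grid(a, b)
  new_spectrum(a$wavelengths, a$absorbance * b$absorbance,
    derivative_order = a$derivative_order,
    label = a$label, valid = a$valid & b$valid
  )
}

#' Multiply a spectrum by a scalar
#' @param spectrum A spectrum.
#' @param c Dimensionless constant.
#' @return `c * spectrum` pointwise.
#' @export
scalar_multiply <- function(spectrum, c) {
  new_spectrum(spectrum$wavelengths, c * spectrum$absorbance,
    derivative_order = spectrum$derivative_order,
    label = spectrum$label, valid = spectrum$valid
  )
}

#' First gap derivative of a zero-order spectrum
#'
#' `D1(lambda) = scaling_factor * (A(lambda + delta/2) - A(lambda - delta/2))`.
#' The grid is trimmed by `delta_lambda/2` at each end; the result carries
#' `derivative_order = 1`. The operator is linear in the input spectrum.
#'
#' @param spectrum Zero-order spectrum spanning at least `delta_lambda`.
#' @param params A [derivative_params()] object.
#' @return The first-derivative spectrum on the trimmed grid.
#' @export
first_derivative <- function(spectrum, params = derivative_params()) {
  if (spectrum$derivative_order != 0L) {
    stop("first_derivative expects a zero-order spectrum")
  }
  step <- grid_step(spectrum)
  half <- params$delta_lambda / 2
  k <- half / step
  if (abs(k - round(k)) > 1e-6) {
    stop("delta_lambda/2 must be an integer multiple of the grid step")
  }
  k <- as.integer(round(k))
  n <- length(spectrum$wavelengths)
  if (n <= 2L * k) stop("spectrum span must exceed delta_lambda")
  idx <- (k + 1L):(n - k)
  vals <- params$scaling_factor *
    (spectrum$absorbance[idx + k] - spectrum$absorbance[idx - k])
  new_spectrum(spectrum$wavelengths[idx], vals,
    derivative_order = 1L, label = spectrum$label,
    valid = spectrum$valid[idx + k] & spectrum$valid[idx - k]
  )
}

#' Resample a spectrum onto a new uniform grid by linear interpolation
#'
#' Grid alignment between spectra is always explicit: arithmetic operations
#' require identical grids, and any interpolation must be invoked
#' deliberately through this function.
#'
#' @param spectrum A spectrum.
#' @param grid Numeric `(start, stop, step)` in nm, within the source span.
#' @return The resampled spectrum.
#' @export
resample_spectrum <- function(spectrum, grid) {
  stopifnot(length(grid) == 3L, grid[1] < grid[2], grid[3] > 0)
  wl <- seq(grid[1], grid[2], by = grid[3])
  rng <- range(spectrum$wavelengths)
  if (wl[1] < rng[1] - 1e-9 || wl[length(wl)] > rng[2] + 1e-9) {
    stop("target grid extends beyond the source spectrum")
  }
  ab <- stats::approx(spectrum$wavelengths, spectrum$absorbance, xout = wl)$y
  new_spectrum(wl, ab,
    derivative_order = spectrum$derivative_order,
    label = spectrum$label
  )
}

#' Plateau-constant estimate over a wavelength window
#'
#' Estimates the constant of a ratio spectrum in a region where it is
#' parallel to the wavelength axis. The estimator is the window mean
#' (`estimator = "median"` available for noise robustness), with the
#' percentage relative standard deviation over the window as a flatness
#' diagnostic: if `rsd_percent` exceeds `flatness_tol_percent` a non-fatal
#' warning flag is attached and the constant is still returned.
#'
#' @param spectrum A spectrum (typically a ratio spectrum).
#' @param window `(nm, nm)` closed interval within the grid.
#' @param flatness_tol_percent Flatness tolerance in percent (default 2).
#' @param estimator `"mean"` (default) or `"median"`.
#' @return An object of class `plateau_estimate` with fields `value`,
#'   `window`, `rsd_percent`, `n_points`, `flat` and `warning`.
#' @export
plateau_constant <- function(spectrum, window, flatness_tol_percent = 2,
                             estimator = c("mean", "median")) {
  estimator <- match.arg(estimator)
  stopifnot(flatness_tol_percent > 0)
  idx <- window_index(spectrum, window)
  idx <- idx[spectrum$valid[idx]]
  if (length(idx) < 3L) {
    stop(sprintf(
      "window [%g, %g] has fewer than 3 valid points (divisor invalid there?)",
      window[1], window[2]
    ))
  }
  v <- spectrum$absorbance[idx]
  value <- if (estimator == "mean") mean(v) else stats::median(v)
  s <- stats::sd(v)
  rsd <- if (abs(value) > 0) 100 * s / abs(value) else if (s == 0) 0 else Inf
  flat <- rsd <= flatness_tol_percent
  structure(
    list(
      value = value, window = as.numeric(window), rsd_percent = rsd,
      n_points = length(idx), flat = flat,
      warning = if (flat) {
        NULL
      } else {
        sprintf(
          "plateau RSD %.3g%% exceeds flatness tolerance %.3g%% on [%g, %g]",
          rsd, flatness_tol_percent, window[1], window[2]
        )
      }
    ),
    class = "plateau_estimate"
  )
}

#' @export
print.plateau_estimate <- function(x, ...) {
  cat(sprintf(
    "<plateau> value %.6g over [%g, %g] nm (n = %d, RSD %.3g%%)%s\n",
    x$value, x$window[1], x$window[2], x$n_points, x$rsd_percent,
    if (x$flat) "" else " [NOT FLAT]"
  ))
  invisible(x)
}

#' Peak amplitude measurement
#'
#' `peak_to_baseline` returns the (signed) trace value at `lambda1`;
#' `peak_to_peak` returns `|D(lambda2) - D(lambda1)|`. Wavelengths must lie
#' on the (possibly derivative-trimmed) grid.
#'
#' @param spectrum A spectrum.
#' @param mode `"peak_to_baseline"` or `"peak_to_peak"`.
#' @param lambda1 First wavelength (nm).
#' @param lambda2 Second wavelength (nm), required for `peak_to_peak`.
#' @return Amplitude in AU.
#' @export
amplitude <- function(spectrum, mode = c("peak_to_baseline", "peak_to_peak"),
                      lambda1, lambda2 = NULL) {
  mode <- match.arg(mode)
  at <- function(lambda) {
    i <- which(abs(spectrum$wavelengths - lambda) <= grid_step(spectrum) / 2 + 1e-12)
    if (length(i) == 0L) {
      stop(sprintf(
        "wavelength %g nm is off the grid [%g, %g]",
        lambda, min(spectrum$wavelengths), max(spectrum$wavelengths)
      ))
    }
    i <- i[which.min(abs(spectrum$wavelengths[i] - lambda))]
    if (!spectrum$valid[i]) stop(sprintf("point at %g nm is masked invalid", lambda))
    spectrum$absorbance[i]
  }
  if (mode == "peak_to_baseline") {
    at(lambda1)
  } else {
    if (is.null(lambda2)) stop("peak_to_peak requires lambda2")
    abs(at(lambda2) - at(lambda1))
  }
}
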