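#' Gaussian-band component profile
#'
#' Describes a pure analyte's absorptivity curve as a sum of Gaussian bands
#' with a hard support cutoff: the pure spectrum is identically zero for
#' wavelengths above `support_max`. The cutoff encodes the spectral-extension
#' ordering the successive-resolution algorithms rely on (the most extended
#' component absorbs alone at long wavelengths).
#'
#' @param name Component name.
#' @param bands Data frame or matrix with columns `center` (nm), `sigma` (nm),
#'   `height` (AU mL/ug).
#' @param support_max Wavelength (nm) beyond which absorptivity is zero.
#' @return An object of class `component_profile`.
#' @export
component_profile <- function(name, bands, support_max) {
  bands <- as.data.frame(bands)
  stopifnot(
    all(c("center", "sigma", "height") %in% names(bands)),
    all(bands$sigma > 0), all(bands$height >= 0), support_max > 0
  )
  structure(list(name = name, bands = bands, support_max = support_max),
    class = "component_profile"
  )
}

#' Default three-component profiles (TEL-, CHT- and AML-like)
#'
#' Synthetic surrogates for a ternary antihypertensive mixture
#' (telmisartan / chlorthalidone / amlodipine), tuned to the structural
#' features the resolution algorithms rely on, not to any instrument's
#' absolute absorptivities:
#'
#' * `CHT`: single band peaking at 275.0 nm, support ends at 299 nm (the
#'   least extended component);
#' * `TEL`: main band at 295.7 nm plus a short-wavelength band, support ends
#'   at 350 nm;
#' * `AML`: bands near 238 nm and at 359.5 nm, support to 400 nm (the most
#'   extended component).
#'
#' Consequently 300.0-321.0 nm sees TEL only once AML is removed, and
#' 355.0-385.0 nm sees AML alone - the plateau windows used by the
#' successive-resolution methods are exactly single-component regions.
#'
#' @return Named list of three [component_profile()] objects
#'   (`TEL`, `CHT`, `AML`).
#' @export
default_profiles <- function() {
  list(
    TEL = component_profile(
      "TEL",
      data.frame(
        center = c(225.0, 295.7), sigma = c(10, 14.1), height = c(0.045, 0.050)
      ),
      support_max = 350.0
    ),
    CHT = component_profile(
      "CHT",
      data.frame(center = 275.0, sigma = 7.0, height = 0.025),
      support_max = 299.0
    ),
    AML = component_profile(
      "AML",
      data.frame(
        center = c(238.0, 359.5), sigma = c(7.0, 13.0), height = c(0.050, 0.035)
      ),
      support_max = 400.0
    )
  )
}

#' Additive-noise model for synthetic spectra
#'
#' @param additive_sd Standard deviation of i.i.d. Gaussian absorbance noise
#'   in AU (default 0, i.e. noiseless).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(additive_sd = 0, seed = NULL) {
  stopifnot(additive_sd >= 0)
  structure(list(additive_sd = additive_sd, seed = seed), class = "noise_model")
}

default_grid <- c(200.0, 400.0, 0.1)

grid_wavelengths <- function(grid) {
  stopifnot(length(grid) == 3L, grid[1] < grid[2], grid[3] > 0)
  seq(grid[1], grid[2], by = grid[3])
}

#' Pure-component spectrum under Beer-Lambert proportionality
#'
#' `A(lambda) = concentration * sum_bands height * exp(-(lambda - center)^2 /
#' (2 sigma^2))`, clipped to zero for `lambda > support_max`. Strictly
#' proportional to concentration.
#'
#' @param profile A [component_profile()].
#' @param concentration Concentration in ug/mL (>= 0).
#' @param grid `(start, stop, step)` in nm; default 200.0-400.0 by 0.1.
#' @return A zero-order spectrum labelled `"<name> <conc> ug/mL"`.
#' @export
pure_spectrum <- function(profile, concentration, grid = default_grid) {
  if (concentration < 0) stop("concentration must be non-negative")
  wl <- grid_wavelengths(grid)
  a <- rep(0, length(wl))
  for (b in seq_len(nrow(profile$bands))) {
    bd <- profile$bands[b, ]
    a <- a + bd$height * exp(-(wl - bd$center)^2 / (2 * bd$sigma^2))
  }
  a[wl > profile$support_max] <- 0
  new_spectrum(wl, concentration * a,
    derivative_order = 0L,
    label = sprintf("%s %g ug/mL", profile$name, concentration)
  )
}

#' Additive mixture spectrum with optional Gaussian noise
#'
#' The noiseless call is exactly [linear_combination()] of the pure spectra;
#' noise is i.i.d. additive Gaussian, reproducible from `noise$seed`.
#'
#' @param profiles List of [component_profile()] objects.
#' @param concentrations Concentrations in ug/mL, one per profile.
#' @param noise A [noise_model()].
#' @param grid `(start, stop, step)` in nm.
#' @return A zero-order mixture spectrum.
#' @export
mixture_spectrum <- function(profiles, concentrations, noise = noise_model(),
                             grid = default_grid) {
  stopifnot(length(profiles) == length(concentrations))
  pures <- mapply(pure_spectrum, profiles, concentrations,
    MoreArgs = list(grid = grid), SIMPLIFY = FALSE
  )
  mix <- linear_combination(pures, rep(1, length(pures)))
  if (noise$additive_sd > 0) {
    eps <- with_seed(noise$seed, rnorm(length(mix$absorbance), 0, noise$additive_sd))
    mix <- new_spectrum(mix$wavelengths, mix$absorbance + eps,
      derivative_order = 0L, label = "mixture (noisy)"
    )
  } else {
    mix$label <- "mixture"
  }
  mix
}

#' Spectra matrix and concentration table from a calibration design
#'
#' Generates one mixture spectrum per design row on the chemometric grid
#' (default 270.0-400.0 nm at 0.1 nm, i.e. 1301 wavelengths) and returns the
#' samples-by-wavelengths absorbance matrix together with the aligned
#' concentration table. Each row's noise is drawn from an independent
#' substream derived from `noise$seed`, so the dataset is reproducible from
#' `(profiles, design, seed)`.
#'
#' @param design A [build_design()] object.
#' @param profiles Named list of profiles matching the design's factor names.
#' @param noise A [noise_model()].
#' @param grid `(start, stop, step)` in nm; default `c(270, 400, 0.1)`.
#' @return List with `sample_ids`, `X` (matrix, wavelength-named columns),
#'   and `concentrations` (data.frame with `sample_id`, one column per
#'   component, and `split`).
#' @export
dataset_from_design <- function(design, profiles = default_profiles(),
                                noise = noise_model(),
                                grid = c(270.0, 400.0, 0.1)) {
  conc <- design$concentrations
  factors <- design$factors
  stopifnot(all(factors %in% names(profiles)))
  wl <- grid_wavelengths(grid)
  n <- nrow(conc)
  X <- matrix(0, n, length(wl))
  for (i in seq_len(n)) {
    seed_i <- if (is.null(noise$seed)) NULL else noise$seed + i
    s <- mixture_spectrum(
      profiles[factors], as.numeric(conc[i, factors]),
      noise = noise_model(noise$additive_sd, seed_i), grid = grid
    )
    X[i, ] <- s$absorbance
  }
  ids <- sprintf("S%02d", seq_len(n))
  dimnames(X) <- list(ids, sprintf("%.1f", wl))
  tab <- cbind(
    data.frame(sample_id = ids),
    stats::setNames(conc[, factors, drop = FALSE], paste0(factors, "_ugml")),
    data.frame(split = design$split)
  )
  list(sample_ids = ids, X = X, concentrations = tab)
}

#' Write a samples-by-wavelengths matrix CSV
#'
#' First column `sample_id`, remaining columns named by wavelength with
#' 0.1 nm formatting (`"270.0"` ... `"400.0"`).
#'
#' @param X Matrix with sample-id rownames and wavelength-named columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(X, path) {
  df <- data.frame(sample_id = rownames(X), X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a samples-by-wavelengths matrix CSV
#' @param path Path written by [write_matrix_csv()].
#' @return Matrix with sample-id rownames and wavelength-named columns.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df[[1]]
  X
}

#' Planted-informative-band dataset for wavelength-selection benchmarks
#'
#' Generates a samples-by-wavelengths matrix in which only one contiguous
#' band of variables responds to the analyte: the band carries a Gaussian
#' signature proportional to `y`, while every region outside the band is
#' contaminated by interferent components with random per-sample loadings: a
#' region-wide baseline plus several smooth bump profiles, deliberately more
#' of them than a small latent-variable budget can span (plus i.i.d. noise
#' everywhere). A model restricted to the band therefore predicts well with
#' one latent variable, whereas any window outside the band imports
#' interferent variance the model cannot remove - the ground truth a
#' wavelength-selection method should recover.
#'
#' @param n Number of samples (default 20).
#' @param p Number of variables (default 200).
#' @param band Integer indices of the informative band (default 81:120).
#' @param n_interferents Number of smooth interfering components in addition
#'   to the region-wide baseline (default 6).
#' @param noise_sd I.i.d. absorbance noise SD (default 0.002 AU).
#' @param seed Integer seed.
#' @return List with `X` (wavelength-named columns), `y` (ug/mL) and `band`.
#' @export
planted_band_dataset <- function(n = 20, p = 200, band = 81:120,
                                 n_interferents = 6, noise_sd = 0.002,
                                 seed = 1) {
  stopifnot(all(band >= 1), all(band <= p))
  with_seed(seed, {
    y <- runif(n, 5, 25)
    X <- matrix(rnorm(n * p, 0, noise_sd), n, p)
    sig <- exp(-(seq_along(band) - length(band) / 2)^2 /
      (2 * (length(band) / 5)^2))
    X[, band] <- X[, band] + outer(y, 0.02 * sig)
    outside <- setdiff(seq_len(p), band)
    base <- rep(0, p)
    base[outside] <- 1
    X <- X + outer(runif(n, 0, 0.2), base)
    for (k in seq_len(n_interferents)) {
      centers <- sample(outside, 4)
      prof <- rep(0, p)
      for (cc in centers) {
        prof <- prof + exp(-(seq_len(p) - cc)^2 / (2 * (p / 40)^2))
      }
      prof[band] <- 0
      X <- X + outer(runif(n, 0, 0.3), prof)
    }
    colnames(X) <- sprintf("%.1f", 200 + 0.1 * (seq_len(p) - 1))
    rownames(X) <- sprintf("S%02d", seq_len(n))
    list(X = X, y = y, band = band)
  })
}
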