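# Shared fixtures, built once per test run. Everything is generated in code;
# noiseless objects are exact up to float rounding.

fx_profiles <- default_profiles()

fx_grid <- c(200.0, 400.0, 0.1)

fx_srs_config <- srs_config(
  divisor_A = pure_spectrum(fx_profiles$AML, 10, fx_grid),
  divisor_T = pure_spectrum(fx_profiles$TEL, 10, fx_grid)
)

fx_sds_config <- sds_config(
  divisor_A = pure_spectrum(fx_profiles$AML, 10, fx_grid),
  divisor_T = pure_spectrum(fx_profiles$TEL, 5, fx_grid)
)

fx_srs_curves <- build_calibration_curves(fx_srs_config, fx_profiles)
fx_sds_curves <- build_calibration_curves(fx_sds_config, fx_profiles)

fx_dosage <- c(TEL = 40, CHT = 12.5, AML = 5)

fx_mixture <- function(concs, noise = noise_model(), grid = fx_grid) {
  mixture_spectrum(fx_profiles[c("TEL", "CHT", "AML")],
    concs[c("TEL", "CHT", "AML")],
    noise = noise, grid = grid
  )
}

# Minimum-norm least-squares predictions, the independent oracle for PLS at
# full rank (computed from the singular value decomposition, no PLS code).
ls_min_norm_predict <- function(X, y, Xnew) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d) * 1e-10
  beta <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y - ym)) / sv$d[pos])
  drop(sweep(Xnew, 2, xm) %*% beta) + ym
}
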