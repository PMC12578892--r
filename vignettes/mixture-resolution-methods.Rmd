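---
title: "Resolving overlapped three-component UV-Vis spectra: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving overlapped three-component UV-Vis spectra: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvresolve)
```

# The problem

A fixed-dose antihypertensive tablet combines telmisartan (TEL), chlorthalidone
(CHT) and amlodipine (AML) in a 40 : 12.5 : 5 ratio. Their UV-Vis absorption
bands overlap severely across 200-400 nm, so no single wavelength isolates one
analyte. `uvresolve` implements two complementary answers:

1. **Successive resolution** (univariate): algebraic removal of one component
   at a time using ratio spectra and plateau constants;
2. **Multivariate calibration**: PLS1 regression on full spectra, sharpened by
   interval and genetic-algorithm wavelength selection.

Both run on the same `spectrum` primitives and are validated end to end on
synthetic Gaussian-band data whose structure reproduces the features the
algorithms rely on.

# Successive resolution

## The algebra

Under Beer-Lambert additivity a mixture spectrum is
$M(\lambda) = \sum_i c_i\,\varepsilon_i(\lambda)$. Dividing by a pure *divisor*
spectrum $D(\lambda) = c'_A\,\varepsilon_A(\lambda)$ gives

$$\frac{M(\lambda)}{D(\lambda)} \;=\; \frac{c_A}{c'_A}
  \;+\; \frac{\sum_{i \ne A} c_i\,\varepsilon_i(\lambda)}{D(\lambda)}.$$

Wherever only component $A$ absorbs, the second term vanishes and the ratio is
a flat *plateau* whose value is the concentration ratio $c_A / c'_A$
("constant I"). Multiplying the constant back onto the divisor reconstructs
$A$'s spectrum ("constant multiplication"); subtracting the constant from the
ratio and re-multiplying removes $A$ from the mixture. The components must be
removed **most spectrally extended first**: here AML absorbs beyond both
others, so AML is removed first (plateau 355.0-385.0 nm against a 10.0 ug/mL
AML divisor), then TEL (plateau 300.0-321.0 nm against a 10.0 ug/mL TEL
divisor), leaving CHT. Analytes are quantified at fixed wavelengths: TEL at
295.7 nm, CHT at 275.0 nm, AML at 359.5 nm, against ordinary least-squares
calibration lines.

`sds_resolve()` applies the identical scheme in first-derivative space with a
gap derivative $D^1(\lambda) = s\,[A(\lambda + \Delta\lambda/2) -
A(\lambda - \Delta\lambda/2)]$ ($\Delta\lambda = 10$ nm, $s = 10$), plateau
windows 375.0-390.0 and 305.0-325.0 nm, divisors AML 10.0 and TEL 5.0 ug/mL,
and amplitude measurements peak-to-peak 231.0-246.0 nm (AML), peak-to-peak
282.5-313.0 nm (TEL) and peak-to-baseline 287.0 nm (CHT). Because the
derivative operator is linear, the exactness and conservation properties carry
over unchanged: the reconstructed $D^1$ spectra sum to $D^1$ of the mixture
pointwise.

## Numerical choices

- **Gap derivative without $1/\Delta\lambda$.** Instrument software computes
  gap ("subtract algorithm") derivatives as scaled differences; the absolute
  scale is immaterial because the calibration regression absorbs it. The
  symmetric difference is a package definition, not a claim about any
  instrument's internals (pre-smoothing and end-point handling differ between
  vendors); the grid is trimmed by $\Delta\lambda/2$ at each end, and
  $\Delta\lambda/2$ must land on the grid.
- **Division guard.** Points where $|D(\lambda)| < \varepsilon$ (default
  $10^{-6} \max |D|$) are *masked*, not zero-filled, so meaningless quotients
  can never leak into a plateau window or an amplitude read-out. Where a
  ratio is masked, the successive scheme falls back to the algebraically
  equivalent form $M - c\,D$, which needs no division, so pointwise
  conservation holds on the full grid.
- **Plateau estimator.** The constant is the window *mean* (a median is
  available via `estimator = "median"`), with the percent RSD across the
  window as a flatness diagnostic: above the tolerance (default 2 %) a warning
  is attached but the constant is still returned, since a noisy plateau is
  degraded, not invalid. Signed derivative ratios are used in SDS plateaus -
  they are constant wherever a single component survives, and taking absolute
  values would fold noise asymmetrically around zero crossings.
- **Fixed measurement wavelengths.** Amplitudes are read at the configured
  wavelengths, never re-detected per sample; per-sample peak hunting would
  silently change what the calibration slope means.
- **No clipping.** Noise-induced negative reconstructed absorbances are kept;
  clipping at zero would bias low-concentration calibration.
- **Explicit grids.** All binary operations require identical grids;
  `resample_spectrum()` (linear interpolation) must be called deliberately.
  Windows are closed intervals in nm; no index arithmetic is exposed.

# Multivariate calibration

## Design

`build_design()` produces a 25-run, five-level, three-factor design from a
cyclic generator: a fixed base sequence of the five coded levels (-2..2),
25 long, in which every ordered level pair occurs exactly once at lag 1 *and*
lag 2; the three factors read the sequence at cyclic shifts 0, 1, 2. The
pair-uniformity gives each factor every level exactly five times and makes
every pair of factor columns jointly uniform, hence exactly uncorrelated -
a property that survives *any* monotone level-to-concentration map. The base
sequence was found once by exhaustive backtracking search and is frozen as a
design constant. Coded levels map affinely onto TEL 8.00-40.0, CHT 10.0-90.0
and AML 5.0-25.0 ug/mL. The 17-calibration / 8-validation split is a seeded
draw constrained so the calibration subset retains all five levels of every
factor.

## PLS1, cross-validation, and model size

`pls1_fit()` is a NIPALS PLS1: per latent variable the weight vector is
$X^\top y$ normalized, scores $t = Xw$, loadings by projection, then deflation.
Mean-centering is the default preprocessing; autoscaling is available but
rarely helps when all channels are on the same absorbance scale.
`cross_validate()` supports leave-one-out (default), venetian blinds,
contiguous blocks and seeded random subsets, and **re-preprocesses inside
every fold** - centering on the full data before splitting would leak
information into the held-out samples. The latent-variable count is chosen by
the PRESS F-ratio rule (`select_n_lv()`): the smallest count whose
PRESS ratio against the minimum is not significant against $F(n, n)$ at
$\alpha = 0.25$ ($\alpha$ configurable) - the most parsimonious model
statistically indistinguishable from the best.

## Wavelength selection

**Forward iPLS** (`ipls_select()`) partitions the axis into equal-width
contiguous intervals (balanced to within one variable; 1301 variables over 40
intervals gives widths 33 and 32). Each interval gets a local model
cross-validated at a consistent LV count; only intervals whose local RMSECV
beats the full-spectrum RMSECV are eligible, and forward accumulation starts
from the best one, adding intervals while the combined RMSECV improves. If
nothing beats the full spectrum the full-spectrum model is returned with an
explicit flag. The published description of this method family is ambiguous
about whether "interval size" counts a second granularity; this package
accepts either an interval count or an interval width and treats them as two
parametrizations of the same balanced partition.

**GA-PLS** (`ga_pls()`) switches windows of 5 variables on/off with binary
chromosomes; fitness is cross-validated RMSECV on the selected variables. The
loop is elitist (best fitness non-increasing, verified by test), with
rank-proportional parent selection, double-point crossover (single available),
per-gene mutation 0.005, initial inclusion 30 %, and early stop when 80 % of
the population equals the best chromosome. Defaults (population 64, 100
generations) are conventional values for spectroscopic GA selection, exposed
in the configuration; the test and acceptance runs use population 32 and 60
generations on 200-variable planted benchmarks, which those problem sizes
saturate. The initial population always contains the full-spectrum
chromosome, so the final fitness can never be worse than the full-spectrum
model's.

## Metrics

`model_metrics()` reports RMSE labelled by context (RMSEC / RMSECV / RMSEP),
mean signed bias, $Q^2 = 1 - \sum e^2 / \sum (y - \bar y)^2$, $R^2$ (squared
Pearson), recovery mean/SD/RSD, and a bias-corrected error
$\mathrm{BCMSEP} = \sum (e - \bar e)^2 / (n - 1)$. The bias-corrected
formula is this package's definition (the conventional decomposition of MSEP
into bias and spread); toolboxes differ in the exact convention.

# The synthetic generator

`default_profiles()` builds Gaussian-band surrogates, tuned only to the
structural features the algorithms need:

| Component | Bands (center nm / sigma nm / height AU·mL/ug) | Support ends |
|---|---|---|
| TEL | 225 / 10 / 0.045; 295.7 / 14.1 / 0.050 | 350 nm |
| CHT | 275 / 7 / 0.025 | 299 nm |
| AML | 238 / 7 / 0.050; 359.5 / 13 / 0.035 | 400 nm |

The hard support cutoffs encode the extension ordering (AML beyond TEL beyond
CHT) and make the plateau windows *exactly* single-component, which is what
the exactness theorem needs: on noiseless additive mixtures both successive
methods reconstruct each component to float precision, and tests assert this
at $10^{-8}$. Heights keep a 10 ug/mL spectrum near 0.25-0.5 AU and the whole
calibration range (CHT runs to 100 ug/mL) inside an instrument-linear
0.1-1.5 AU window; the CHT height is the binding compromise between those two
aims. The default additive noise SD, where noise is requested, is 0.002 AU -
typical short-term photometric noise of a bench double-beam instrument.

What the generator does **not** emulate: real absorptivity curves (no public
digitization exists for these analytes' measured spectra), stray light,
baseline drift, or wavelength-registration error. Passing tests therefore
demonstrate the *algebra and statistics* of the methods, not agreement with
any instrument's slopes; quantities that depend on measured spectra
(instrument-specific RMSECV values, real recovery tables) are out of scope by
design.

`planted_band_dataset()` is a separate benchmark generator for wavelength
selection: one contiguous band responds to the analyte, everything outside it
carries a region-wide baseline plus six smooth interferent components with
random per-sample loadings - deliberately more interferents than a small LV
budget can span, so including any out-of-band window measurably hurts
cross-validated error. That is the ground truth against which iPLS retention
and GA band-finding are scored.

# Quality statistics

- `content_uniformity()` implements the simplified acceptance-value rule
  $AV = k \cdot SD$ with $k = 2.4$ and limit $L_1 = 15$, valid when the mean
  lies in the 98.50-101.5 % reference window (reported as `mean_in_window`);
  `strict_usp = TRUE` applies the piecewise $|M - \bar X| + k\,s$ form with
  the reference value clamped to the window. SDs use the $n-1$ denominator
  throughout. `uniformity_report()` rounds half-up to 2 decimals at
  presentation only - and computes the printed AV row from the *displayed* SD,
  which is how published report tables are internally consistent.
- `lod_loq()` uses the ICH residual-SD route: $3.3\,s_{res}/b$ and
  $10\,s_{res}/b$; their ratio is $10/3.3$ for any curve, which the tests use
  as an identity check.
- `compare_methods()` defaults to the pooled-variance t test (Welch via flag)
  plus the variance-ratio F test with the larger variance on top, against
  two-sided critical values.
- `aggregate_scores()` is the arithmetic mean of percentage sub-scores at a
  stated rounding; composite sustainability indices use integer rounding,
  whiteness-style worksheet summaries one decimal. Note the two conventions
  disagree in the second decimal for means like 93.73; the package always
  reports the exact mean at the *requested* rounding.

# Problem sizes and reproducibility

The shipped tests and the acceptance script use: the full 25 x 1301
chemometric matrix for PLS (noiseless and 0.002 AU noise); 100 seeded
replicates for the univariate noise envelope; 20 x 200 planted benchmarks
with a 40-variable band for iPLS (20 intervals) and GA-PLS (5 seeds,
population 32, 60 generations). Every stochastic step takes an explicit
integer seed, flows it through a private RNG stream (the caller's RNG state
is untouched), and records it in its result or manifest, so every number in
the package's reports is reproducible from the inputs and the seed.

# Known limitations

- Three components only, with the fixed extension ordering; mixtures needing
  more successive stages are out of scope.
- Plateau windows are validated (flatness RSD) but never auto-discovered.
- PLS1 only - one response per model; no PLS2, no nonlinear kernels, and no
  selection heuristics beyond iPLS and GA.
- The divisor standards are treated as noise-free references; divisor noise
  propagates into the constants in a way the Monte-Carlo tests do not model.
- Spectrum I/O is the package's two CSV dialects; vendor formats (JCAMP-DX,
  binary) are not read.
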