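#' Recovery statistics
#'
#' Per-sample recovery `100 * found / nominal` with mean, SD (n-1
#' denominator) and RSD summary.
#'
#' @param found Found concentrations (ug/mL).
#' @param nominal Nominal concentrations (ug/mL), all positive.
#' @return List with `recovery_pct` (per sample), `mean`, `sd`, `rsd`, `n`.
#' @export
recovery_stats <- function(found, nominal) {
  stopifnot(length(found) == length(nominal))
  if (any(nominal <= 0)) stop("nominal concentrations must be positive")
  r <- 100 * found / nominal
  list(
    recovery_pct = r, mean = mean(r),
    sd = if (length(r) > 1) stats::sd(r) else 0,
    rsd = if (length(r) > 1) 100 * stats::sd(r) / mean(r) else 0,
    n = length(r)
  )
}

#' Replicate precision as percent RSD
#'
#' `RSD = 100 * sd / mean` per replicate set, flagged against the 2 percent
#' repeatability limit.
#'
#' @param replicate_sets List of numeric vectors (each >= 3 values).
#' @param limit RSD acceptance limit in percent (default 2).
#' @return Data frame with `set`, `n`, `mean`, `rsd_percent`, `pass`.
#' @export
precision_rsd <- function(replicate_sets, limit = 2) {
  if (!is.list(replicate_sets)) replicate_sets <- list(replicate_sets)
  rows <- lapply(seq_along(replicate_sets), function(i) {
    v <- replicate_sets[[i]]
    if (length(v) < 3L) stop("each replicate set needs at least 3 values")
    m <- mean(v)
    if (m == 0) stop("zero mean in replicate set ", i)
    rsd <- 100 * stats::sd(v) / abs(m)
    data.frame(set = i, n = length(v), mean = m, rsd_percent = rsd, pass = rsd < limit)
  })
  do.call(rbind, rows)
}

#' Content-uniformity acceptance value
#'
#' Summarizes per-tablet label-claim percentages and computes the
#' acceptance value. The default rule is the simplified one used in routine
#' reporting when the mean lies inside the 98.50-101.5 percent reference
#' window: `AV = k * SD` with acceptability constant `k = 2.4` and limit
#' `L1 = 15`. `strict_usp = TRUE` applies the full piecewise rule
#' `AV = |M - mean| + k * SD` with the reference value `M` clamped to the
#' window.
#'
#' @param values Per-tablet label-claim percentages (default expectation:
#'   exactly `n_expected` tablets).
#' @param k Acceptability constant (default 2.4).
#' @param l1 Acceptance limit L1 (default 15).
#' @param n_expected Required number of units (default 10); set `NULL` to
#'   accept any n >= 2.
#' @param strict_usp Use the piecewise reference-value rule.
#' @return Object of class `content_uniformity`: `values`, `mean`, `sd`
#'   (n-1), `rsd_percent`, `k`, `av`, `l1`, `pass` (`av <= l1`), and
#'   `mean_in_window` for the 98.50-101.5 window.
#' @export
content_uniformity <- function(values, k = 2.4, l1 = 15, n_expected = 10,
                               strict_usp = FALSE) {
  n <- length(values)
  if (n < 2L) stop("content uniformity needs at least 2 values")
  if (!is.null(n_expected) && n != n_expected) {
    stop(sprintf("expected %d units, got %d", n_expected, n))
  }
  m <- mean(values)
  s <- stats::sd(values)
  av <- if (strict_usp) {
    ref <- min(max(m, 98.5), 101.5)
    abs(ref - m) + k * s
  } else {
    k * s
  }
  structure(
    list(
      values = values, mean = m, sd = s,
      rsd_percent = 100 * s / m, k = k, av = av, l1 = l1,
      pass = av <= l1,
      mean_in_window = m >= 98.5 && m <= 101.5
    ),
    class = "content_uniformity"
  )
}

#' @export
print.content_uniformity <- function(x, ...) {
  cat(sprintf(
    "<content_uniformity> n = %d, mean %.2f%%, SD %.2f, AV %.2f (k = %g, L1 = %g) -> %s\n",
    length(x$values), x$mean, x$sd, x$av, x$k, x$l1,
    if (x$pass) "PASS" else "FAIL"
  ))
  invisible(x)
}

#' Standard-addition recovery of the added amount
#'
#' `recovery = 100 * (total_found - base_found) / added` per spiking level.
#'
#' @param base_found Concentration found in the unspiked sample (ug/mL).
#' @param added Added amounts (ug/mL), all positive.
#' @param total_found Concentrations found after each addition.
#' @return List with per-addition `recovery_pct`, `mean`, `sd`.
#' @export
standard_addition <- function(base_found, added, total_found) {
  stopifnot(length(added) == length(total_found))
  if (any(added <= 0)) stop("added amounts must be positive")
  r <- 100 * (total_found - base_found) / added
  list(
    recovery_pct = r, mean = mean(r),
    sd = if (length(r) > 1) stats::sd(r) else 0
  )
}

#' Two-sample t and F comparison of two methods
#'
#' Two-tailed two-sample t test (pooled variance by default, Welch via
#' `welch = TRUE`) and variance-ratio F test with the larger variance in
#' the numerator, each compared against its critical value at `alpha`.
#'
#' @param sample_a,sample_b Numeric vectors (>= 2 values each).
#' @param alpha Significance level (default 0.05).
#' @param welch Use the Welch t statistic instead of pooled variance.
#' @return Object of class `method_comparison`: `t_statistic`, `t_df`,
#'   `t_p`, `t_critical`, `f_statistic` (>= 1), `f_df`, `f_p`,
#'   `f_critical`, `significant_t`, `significant_f`, and `flag` for
#'   degenerate zero-variance input.
#' @export
compare_methods <- function(sample_a, sample_b, alpha = 0.05, welch = FALSE) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  na <- length(sample_a)
  nb <- length(sample_b)
  va <- stats::var(sample_a)
  vb <- stats::var(sample_b)
  flag <- NULL
  if (va == 0 && vb == 0) {
    flag <- "both samples have zero variance; t undefined"
    t_stat <- if (mean(sample_a) == mean(sample_b)) 0 else NA_real_
    t_df <- na + nb - 2
    t_p <- if (!is.na(t_stat)) 1 else NA_real_
  } else if (welch) {
    se2 <- va / na + vb / nb
    t_stat <- (mean(sample_a) - mean(sample_b)) / sqrt(se2)
    t_df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    t_p <- 2 * stats::pt(-abs(t_stat), t_df)
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    t_stat <- (mean(sample_a) - mean(sample_b)) / sqrt(sp2 * (1 / na + 1 / nb))
    t_df <- na + nb - 2
    t_p <- 2 * stats::pt(-abs(t_stat), t_df)
  }
  if (va >= vb) {
    f_stat <- if (vb > 0) va / vb else if (va == 0) 1 else Inf
    f_df <- c(na - 1, nb - 1)
  } else {
    f_stat <- vb / va
    f_df <- c(nb - 1, na - 1)
  }
  if (va == 0 || vb == 0) {
    flag <- c(flag, "zero variance in one sample; F degenerate")
  }
  f_p <- if (is.finite(f_stat)) 1 - stats::pf(f_stat, f_df[1], f_df[2]) else 0
  structure(
    list(
      t_statistic = t_stat, t_df = t_df, t_p = t_p,
      t_critical = stats::qt(1 - alpha / 2, t_df),
      f_statistic = f_stat, f_df = f_df, f_p = f_p,
      f_critical = stats::qf(1 - alpha / 2, f_df[1], f_df[2]),
      significant_t = !is.na(t_p) && t_p < alpha,
      significant_f = is.finite(f_stat) && f_p < alpha / 2,
      alpha = alpha, flag = flag
    ),
    class = "method_comparison"
  )
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf(
    "<method_comparison> t = %.4g (df %.3g, crit %.4g), F = %.4g (crit %.4g)%s\n",
    x$t_statistic, x$t_df[1], x$t_critical, x$f_statistic, x$f_critical,
    if (is.null(x$flag)) "" else paste0(" [", paste(x$flag, collapse = "; "), "]")
  ))
  invisible(x)
}

#' Aggregate percentage sub-scores by arithmetic mean
#'
#' Used for composite sustainability indices that average independent
#' percentage scores (e.g. need / quality / sustainability into one index,
#' or red / green / blue worksheet scores into a whiteness score).
#'
#' @param subscores Numeric vector of percentages in \[0, 100\].
#' @param digits Decimals for half-up rounding; 0 gives an integer score.
#' @return The rounded mean.
#' @export
aggregate_scores <- function(subscores, digits = 0) {
  if (length(subscores) == 0L) stop("no subscores given")
  if (any(subscores < 0 | subscores > 100)) stop("subscores must be in [0, 100]")
  round_half_up(mean(subscores), digits)
}

#' Per-tablet label-claim table for a marketed ternary tablet
#'
#' Ten individually assayed tablets of a fixed-dose telmisartan /
#' chlorthalidone / amlodipine combination, as label-claim percentages, one
#' column per analyte-method pair (SRS, SDS, iPLS, GA-PLS). Shipped as
#' plain CSV in `extdata`; used to exercise the content-uniformity
#' statistics on real reported values.
#'
#' @return Data frame with `tablet` plus 12 `<analyte>_<method>` columns.
#' @export
telma_uniformity_values <- function() {
  utils::read.csv(
    system.file("extdata", "telma_content_uniformity.csv",
      package = "uvresolve", mustWork = TRUE
    ),
    check.names = FALSE
  )
}

#' Content-uniformity report table at printed precision
#'
#' Builds the report rows (`Mean`, `SD`, `RSD%`, `AV`, `pass`) for each
#' column of a per-tablet label-claim table, rounded half-up to 2 decimals
#' as report tables print them. Following standard table practice, the AV
#' row is computed from the displayed (2-decimal) SD, so the printed rows
#' are mutually consistent.
#'
#' @param values_table Data frame of per-tablet percentages; a `tablet`
#'   column, if present, is ignored.
#' @param k Acceptability constant (default 2.4).
#' @param l1 Acceptance limit (default 15).
#' @return Data frame with one row per column: `column`, `mean`, `sd`,
#'   `rsd_percent`, `av`, `pass`.
#' @export
uniformity_report <- function(values_table, k = 2.4, l1 = 15) {
  cols <- setdiff(names(values_table), "tablet")
  rows <- lapply(cols, function(cn) {
    cu <- content_uniformity(values_table[[cn]], k = k, l1 = l1, n_expected = NULL)
    sd2 <- round_half_up(cu$sd, 2)
    av2 <- round_half_up(k * sd2, 2)
    data.frame(
      column = cn,
      mean = round_half_up(cu$mean, 2),
      sd = sd2,
      rsd_percent = round_half_up(cu$rsd_percent, 2),
      av = av2,
      pass = av2 <= l1
    )
  })
  do.call(rbind, rows)
}
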