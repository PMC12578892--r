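#' Five-level three-factor orthogonal calibration design
#'
#' Builds the 25-run multilevel calibration design used for three-component
#' mixture calibration. The construction is cyclic: a fixed base sequence of
#' the five coded levels (-2..2), 25 long, in which every ordered level pair
#' occurs exactly once at lag 1 *and* at lag 2; factor k reads the sequence
#' at cyclic shift k-1. Joint pair-uniformity gives each factor every level
#' exactly five times and makes the coded columns exactly uncorrelated -
#' for any order-preserving affine level-to-concentration map.
#'
#' Coded levels map affinely onto the per-factor concentration ranges
#' (defaults: TEL 8.00-40.0, CHT 10.0-90.0, AML 5.0-25.0 ug/mL, five equally
#' spaced levels each). Rows are split into a calibration and a validation
#' subset by a seeded draw constrained so the calibration subset retains all
#' five levels of every factor.
#'
#' @param ranges Named list of `(min, max)` concentration ranges in ug/mL.
#' @param n_calibration Number of calibration rows (default 17).
#' @param n_validation Number of validation rows (default 8).
#' @param seed Integer seed for the split.
#' @return Object of class `mixture_design`: list with `coded` (25 x 3
#'   matrix of -2..2), `concentrations` (25 x 3 data.frame in ug/mL),
#'   `factors`, `split` (character, `"calibration"`/`"validation"`).
#' @export
build_design <- function(ranges = list(
                           TEL = c(8.0, 40.0),
                           CHT = c(10.0, 90.0),
                           AML = c(5.0, 25.0)
                         ),
                         n_calibration = 17, n_validation = 8, seed = 1) {
  stopifnot(length(ranges) == 3L)
  # Base cyclic sequence over coded levels 0..4: every ordered pair occurs
  # exactly once at lag 1 and at lag 2 (found once by exhaustive search,
  # frozen here as a design constant).
  base_seq <- c(
    0, 0, 1, 0, 2, 2, 0, 3, 3, 1, 2, 1, 4, 0, 4,
    4, 2, 3, 2, 4, 1, 1, 3, 4, 3
  )
  n <- length(base_seq)
  if (n_calibration + n_validation != n) {
    stop(sprintf("n_calibration + n_validation must equal %d", n))
  }
  if (n_calibration < 5L) stop("calibration subset cannot cover all five levels")
  shift <- function(lag) base_seq[((seq_len(n) - 1 + lag) %% n) + 1]
  coded <- cbind(shift(0), shift(1), shift(2)) - 2L
  colnames(coded) <- names(ranges)
  conc <- coded
  for (j in seq_along(ranges)) {
    r <- ranges[[j]]
    stopifnot(r[1] < r[2])
    conc[, j] <- r[1] + (coded[, j] + 2) * (r[2] - r[1]) / 4
  }
  split <- with_seed(seed, {
    repeat {
      val <- sort(sample.int(n, n_validation))
      cal_coded <- coded[-val, , drop = FALSE]
      if (all(apply(cal_coded, 2, function(x) length(unique(x))) == 5L)) break
    }
    s <- rep("calibration", n)
    s[val] <- "validation"
    s
  })
  structure(
    list(
      coded = coded,
      concentrations = as.data.frame(conc),
      factors = names(ranges),
      split = split
    ),
    class = "mixture_design"
  )
}

#' @export
print.mixture_design <- function(x, ...) {
  cat(sprintf(
    "<mixture_design> %d runs, factors %s (%d calibration / %d validation)\n",
    nrow(x$coded), paste(x$factors, collapse = "/"),
    sum(x$split == "calibration"), sum(x$split == "validation")
  ))
  invisible(x)
}

#' Write a design's concentration table as CSV
#'
#' Columns `sample_id`, `<factor>_ugml` per factor, and
#' `split` in `{calibration, validation}`.
#'
#' @param design A [build_design()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  df <- cbind(
    data.frame(sample_id = sprintf("S%02d", seq_len(nrow(design$coded)))),
    stats::setNames(
      design$concentrations,
      paste0(design$factors, "_ugml")
    ),
    data.frame(split = design$split)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
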