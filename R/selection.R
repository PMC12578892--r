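#' Forward interval-PLS wavelength selection
#'
#' Partitions the wavelength axis into equal-width contiguous intervals
#' (the last may be short), cross-validates a local PLS model per interval
#' at a consistent LV count, and accumulates intervals forward: starting
#' from the interval with the lowest RMSECV, it keeps adding the interval
#' whose inclusion most improves the combined RMSECV, while improvement
#' lasts. Only intervals whose local RMSECV beats the full-spectrum RMSECV
#' are eligible, so every retained interval obeys the local-better-than-
#' global rule. If no interval beats the full-spectrum model, the
#' full-spectrum model is returned with an empty interval list and
#' `fallback_full_spectrum = TRUE`.
#'
#' @param X Samples-by-wavelengths matrix.
#' @param y Concentration vector.
#' @param n_intervals Number of equal-width intervals (give this or
#'   `interval_width`).
#' @param interval_width Interval width in variables.
#' @param max_lv Largest LV count considered.
#' @param scheme,n_folds,iterations,seed Passed to [cross_validate()].
#' @param n_lv Fixed LV count for local models; default selects it on the
#'   full spectrum by [select_n_lv()] (Haaland-Thomas).
#' @return Object of class `selection_result` with `method = "iPLS"`,
#'   `intervals` (data.frame start/stop variable indices and local RMSECV),
#'   `selected_variables`, `rmsecv` (of the retained union),
#'   `full_rmsecv`, and `final_model`.
#' @export
ipls_select <- function(X, y, n_intervals = NULL, interval_width = NULL,
                        max_lv = 6, scheme = "leave_one_out", n_folds = 5,
                        iterations = 1, seed = 1, n_lv = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(n_intervals) == is.null(interval_width)) {
    stop("give exactly one of n_intervals or interval_width")
  }
  if (is.null(n_intervals)) n_intervals <- ceiling(p / interval_width)
  bounds <- interval_partition(p, n_intervals)
  cv <- function(cols, lv) {
    cap <- min(lv, length(cols), nrow(X) - 2L)
    cross_validate(X[, cols, drop = FALSE], y, cap,
      scheme = scheme,
      n_folds = n_folds, iterations = iterations, seed = seed
    )
  }
  full_curve <- cross_validate(X, y, min(max_lv, nrow(X) - 2L, p),
    scheme = scheme, n_folds = n_folds, iterations = iterations, seed = seed
  )
  if (is.null(n_lv)) n_lv <- select_n_lv(full_curve, nrow(X))
  full_rmsecv <- full_curve[min(n_lv, length(full_curve))]
  local <- vapply(seq_len(nrow(bounds)), function(i) {
    curve <- cv(bounds$start[i]:bounds$stop[i], n_lv)
    curve[length(curve)]
  }, numeric(1))
  bounds$rmsecv <- local
  eligible <- which(local < full_rmsecv)
  if (length(eligible) == 0L) {
    final <- pls1_fit(X, y, min(n_lv, nrow(X) - 1L, p))
    return(structure(
      list(
        method = "iPLS", intervals = bounds[0, ],
        per_interval_rmsecv = local,
        selected_variables = seq_len(p), rmsecv = full_rmsecv,
        full_rmsecv = full_rmsecv, n_lv = n_lv,
        final_model = final, fallback_full_spectrum = TRUE, seed = seed
      ),
      class = "selection_result"
    ))
  }
  chosen <- eligible[which.min(local[eligible])]
  cols <- bounds$start[chosen]:bounds$stop[chosen]
  best <- {
    curve <- cv(cols, n_lv)
    curve[length(curve)]
  }
  remaining <- setdiff(eligible, chosen)
  repeat {
    if (length(remaining) == 0L) break
    trial <- vapply(remaining, function(i) {
      cc <- sort(union(cols, bounds$start[i]:bounds$stop[i]))
      curve <- cv(cc, n_lv)
      curve[length(curve)]
    }, numeric(1))
    if (min(trial) >= best) break
    take <- remaining[which.min(trial)]
    chosen <- c(chosen, take)
    cols <- sort(union(cols, bounds$start[take]:bounds$stop[take]))
    best <- min(trial)
    remaining <- setdiff(remaining, take)
  }
  final <- pls1_fit(
    X[, cols, drop = FALSE], y,
    min(n_lv, length(cols), nrow(X) - 1L)
  )
  structure(
    list(
      method = "iPLS", intervals = bounds[sort(chosen), ],
      per_interval_rmsecv = local,
      selected_variables = cols, rmsecv = best,
      full_rmsecv = full_rmsecv, n_lv = n_lv,
      final_model = final, fallback_full_spectrum = FALSE, seed = seed
    ),
    class = "selection_result"
  )
}

# Balanced contiguous partition: interval widths differ by at most one
# (e.g. 1301 variables over 40 intervals -> 21 of width 33, 19 of width 32).
interval_partition <- function(p, n_intervals) {
  stopifnot(n_intervals >= 1, n_intervals <= p)
  width <- rep(p %/% n_intervals, n_intervals)
  extra <- p %% n_intervals
  if (extra > 0) width[seq_len(extra)] <- width[seq_len(extra)] + 1L
  stop <- cumsum(width)
  data.frame(
    interval = seq_len(n_intervals),
    start = c(1L, stop[-n_intervals] + 1L),
    stop = stop
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<%s selection> %d variables retained (RMSECV %.4g vs full %.4g, %d LVs)\n",
    x$method, length(x$selected_variables), x$rmsecv, x$full_rmsecv, x$n_lv
  ))
  invisible(x)
}

#' Genetic-algorithm wavelength selection for PLS (GA-PLS)
#'
#' Binary chromosomes switch contiguous windows of `window_width` variables
#' on or off; fitness is the cross-validated RMSECV of a PLS model on the
#' selected variables (random-subset CV by default). The generational loop
#' is elitist - the best chromosome always survives, so the best fitness is
#' non-increasing - with rank-proportional parent selection, single or
#' double crossover, and per-gene mutation. The initial population contains
#' the full-spectrum chromosome, so selection can never end worse than the
#' full-spectrum model in fitness.
#'
#' @param X Samples-by-wavelengths matrix.
#' @param y Concentration vector.
#' @param window_width Variables per gene window (default 5).
#' @param population Population size (default 64, even, >= 2).
#' @param max_generations Generation cap (default 100).
#' @param mutation_rate Per-gene flip probability (default 0.005).
#' @param crossover `"double"` (default) or `"single"`.
#' @param init_inclusion Initial per-gene inclusion probability (default 0.3).
#' @param convergence Stop early when this fraction of the population is
#'   identical to the best chromosome (default 0.8).
#' @param max_lv Largest LV count for the fitness models.
#' @param scheme,n_folds,iterations Fitness cross-validation settings
#'   (default 5-subset random CV).
#' @param seed Seed controlling the whole run.
#' @return Object of class `selection_result` with `method = "GA"`,
#'   `selected_variables`, per-generation best-fitness `history`,
#'   `final_model` and the stored `seed`.
#' @export
ga_pls <- function(X, y, window_width = 5, population = 64,
                   max_generations = 100, mutation_rate = 0.005,
                   crossover = c("double", "single"), init_inclusion = 0.3,
                   convergence = 0.8, max_lv = 6,
                   scheme = "random_subsets", n_folds = 5, iterations = 1,
                   seed = 1) {
  crossover <- match.arg(crossover)
  X <- as.matrix(X)
  p <- ncol(X)
  if (population < 2) stop("population must be at least 2")
  n_genes <- ceiling(p / window_width)
  if (n_genes < 2) stop("need at least 2 gene windows; reduce window_width")
  gene_cols <- lapply(seq_len(n_genes), function(g) {
    (((g - 1) * window_width + 1):min(g * window_width, p))
  })
  cols_of <- function(chrom) unlist(gene_cols[as.logical(chrom)], use.names = FALSE)
  fitness <- function(chrom) {
    cols <- cols_of(chrom)
    if (length(cols) == 0L) return(Inf)
    cap <- min(max_lv, length(cols), nrow(X) - 2L)
    curve <- cross_validate(X[, cols, drop = FALSE], y, cap,
      scheme = scheme, n_folds = n_folds, iterations = iterations,
      seed = seed
    )
    min(curve)
  }
  with_seed(seed, {
    pop <- matrix(
      runif(population * n_genes) < init_inclusion,
      population, n_genes
    )
    pop[1, ] <- TRUE # full-spectrum chromosome seeds the elite
    empty <- rowSums(pop) == 0L
    for (i in which(empty)) pop[i, sample.int(n_genes, 1)] <- TRUE
    fit <- apply(pop, 1, fitness)
    history <- numeric(0)
    for (gen in seq_len(max_generations)) {
      ord <- order(fit)
      pop <- pop[ord, , drop = FALSE]
      fit <- fit[ord]
      history <- c(history, fit[1])
      same <- mean(apply(pop, 1, function(r) all(r == pop[1, ])))
      if (same >= convergence) break
      # rank-proportional parent choice, elitism keeps the best untouched
      rank_w <- rev(seq_len(population))
      nxt <- pop
      nxt[1, ] <- pop[1, ]
      i <- 2L
      while (i <= population) {
        par <- sample.int(population, 2, prob = rank_w)
        a <- pop[par[1], ]
        b <- pop[par[2], ]
        if (crossover == "single") {
          cut <- sample.int(n_genes - 1L, 1)
          c1 <- c(a[seq_len(cut)], b[(cut + 1L):n_genes])
          c2 <- c(b[seq_len(cut)], a[(cut + 1L):n_genes])
        } else {
          cuts <- sort(sample.int(n_genes - 1L, 2))
          mid <- (cuts[1] + 1L):cuts[2]
          c1 <- a
          c1[mid] <- b[mid]
          c2 <- b
          c2[mid] <- a[mid]
        }
        for (child in list(c1, c2)) {
          if (i > population) break
          flip <- runif(n_genes) < mutation_rate
          child <- xor(child, flip)
          if (!any(child)) child[sample.int(n_genes, 1)] <- TRUE
          nxt[i, ] <- child
          i <- i + 1L
        }
      }
      new_fit <- fit
      for (j in 2:population) new_fit[j] <- fitness(nxt[j, ])
      pop <- nxt
      fit <- new_fit
    }
    ord <- order(fit)
    best <- pop[ord[1], ]
    cols <- cols_of(best)
    if (length(cols) == 0L) stop("GA converged to an empty selection")
    final <- pls1_fit(
      X[, cols, drop = FALSE], y,
      min(max_lv, length(cols), nrow(X) - 1L)
    )
    structure(
      list(
        method = "GA", selected_variables = cols,
        chromosome = best, window_width = window_width,
        rmsecv = fit[ord[1]], history = history,
        final_model = final, seed = seed
      ),
      class = "selection_result"
    )
  })
}
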