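#' Column preprocessing for multivariate calibration
#'
#' Centers (and optionally scales) the spectral matrix and response,
#' storing the terms for inverse application at prediction time.
#' Mean-centering is the default throughout the package's calibration stack.
#'
#' @param X Samples-by-wavelengths matrix.
#' @param y Concentration vector.
#' @param method `"mean_center"`, `"autoscale"` or `"none"`.
#' @return List with transformed `X`, `y` and the stored terms
#'   `x_mean`, `x_scale`, `y_mean`.
#' @export
preprocess <- function(X, y, method = c("mean_center", "autoscale", "none")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  p <- ncol(X)
  if (method == "none") {
    return(list(
      X = X, y = y, x_mean = rep(0, p), x_scale = rep(1, p),
      y_mean = 0, method = method
    ))
  }
  x_mean <- colMeans(X)
  x_scale <- rep(1, p)
  if (method == "autoscale") {
    x_scale <- apply(X, 2, stats::sd)
    zv <- which(x_scale == 0)
    if (length(zv)) {
      nm <- colnames(X)[zv[1]]
      stop(sprintf(
        "autoscale: zero-variance column %s",
        if (is.null(nm)) as.character(zv[1]) else nm
      ))
    }
  }
  y_mean <- mean(y)
  list(
    X = sweep(sweep(X, 2, x_mean), 2, x_scale, "/"),
    y = y - y_mean,
    x_mean = x_mean, x_scale = x_scale, y_mean = y_mean, method = method
  )
}

#' PLS1 regression by NIPALS
#'
#' Single-response partial least squares: per latent variable, the weight
#' vector is `X'y` normalized, scores are `Xw`, loadings are projections of
#' `X` and `y` on the scores, and `X`/`y` are deflated. The regression
#' vector is `W (P'W)^{-1} q`. At full rank the fit reproduces the
#' minimum-norm least-squares solution.
#'
#' @param X Samples-by-wavelengths matrix.
#' @param y Concentration vector (non-degenerate).
#' @param n_lv Number of latent variables, `1 <= n_lv <= min(n - 1, p)`.
#' @param preprocessing Passed to [preprocess()].
#' @return Object of class `pls_model` with centering terms, per-LV
#'   `weights`, `x_loadings`, `y_loadings`, `scores` and the assembled
#'   `regression_vector`.
#' @export
pls1_fit <- function(X, y, n_lv, preprocessing = "mean_center") {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(length(y) == n)
  if (stats::var(y) == 0) stop("degenerate response: zero variance")
  if (n_lv < 1 || n_lv > min(n - 1, p)) {
    stop(sprintf("n_lv must be in [1, %d]", min(n - 1, p)))
  }
  pp <- preprocess(X, y, preprocessing)
  Xw <- pp$X
  yw <- pp$y
  W <- P <- matrix(0, p, n_lv)
  Q <- numeric(n_lv)
  Tm <- matrix(0, n, n_lv)
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(Xw, yw))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps^0.5) {
      # X exhausted: remaining LVs carry nothing
      W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      Tm <- Tm[, seq_len(a - 1), drop = FALSE]
      Q <- Q[seq_len(a - 1)]
      n_lv <- a - 1L
      break
    }
    w <- w / nw
    t <- drop(Xw %*% w)
    tt <- sum(t^2)
    pvec <- drop(crossprod(Xw, t)) / tt
    q <- sum(yw * t) / tt
    Xw <- Xw - tcrossprod(t, pvec)
    yw <- yw - q * t
    W[, a] <- w
    P[, a] <- pvec
    Q[a] <- q
    Tm[, a] <- t
  }
  if (n_lv == 0L) stop("no usable latent variables")
  B <- W %*% solve(crossprod(P, W), Q)
  structure(
    list(
      preprocessing = pp$method, n_lv = n_lv,
      x_mean = pp$x_mean, x_scale = pp$x_scale, y_mean = pp$y_mean,
      weights = W, x_loadings = P, y_loadings = Q, scores = Tm,
      regression_vector = drop(B)
    ),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf(
    "<pls_model> %d latent variables, %d wavelengths (%s)\n",
    x$n_lv, length(x$regression_vector), x$preprocessing
  ))
  invisible(x)
}

#' Predict concentrations from a PLS model
#'
#' @param object A [pls1_fit()] model.
#' @param newdata Samples-by-wavelengths matrix on the training wavelengths.
#' @param ... Unused.
#' @return Numeric vector of predicted concentrations.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  Xc <- sweep(sweep(newdata, 2, object$x_mean), 2, object$x_scale, "/")
  drop(Xc %*% object$regression_vector) + object$y_mean
}

cv_folds <- function(n, scheme, n_folds, seed) {
  switch(scheme,
    leave_one_out = as.list(seq_len(n)),
    venetian_blinds = {
      k <- min(n_folds, n)
      lapply(seq_len(k), function(i) seq(i, n, by = k))
    },
    contiguous_blocks = {
      k <- min(n_folds, n)
      split(seq_len(n), cut(seq_len(n), k, labels = FALSE))
    },
    random_subsets = {
      k <- min(n_folds, n)
      idx <- with_seed(seed, sample.int(n))
      split(idx, cut(seq_along(idx), k, labels = FALSE))
    },
    stop("unknown CV scheme: ", scheme)
  )
}

#' Cross-validated RMSECV curve for PLS1
#'
#' Refits the model in every fold - including re-preprocessing inside the
#' fold, so no centering information leaks from held-out samples - and
#' accumulates held-out squared errors per latent-variable count:
#' `RMSECV_k = sqrt(sum(e_k^2) / n)`. `random_subsets` averages the press
#' over `iterations` seeded re-splits.
#'
#' @param X Samples-by-wavelengths matrix.
#' @param y Concentration vector.
#' @param max_lv Largest LV count to assess (capped by fold geometry).
#' @param scheme `"leave_one_out"` (default), `"venetian_blinds"`,
#'   `"contiguous_blocks"` or `"random_subsets"`.
#' @param n_folds Fold/subset count for the non-LOO schemes.
#' @param iterations Number of seeded re-splits for `random_subsets`.
#' @param seed Seed for the random scheme.
#' @param preprocessing Passed to [pls1_fit()].
#' @return Numeric vector `rmsecv[k]`, `k = 1..max_lv`.
#' @export
cross_validate <- function(X, y, max_lv,
                           scheme = c(
                             "leave_one_out", "venetian_blinds",
                             "contiguous_blocks", "random_subsets"
                           ),
                           n_folds = 5, iterations = 1, seed = 1,
                           preprocessing = "mean_center") {
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(max_lv >= 1)
  iters <- if (scheme == "random_subsets") iterations else 1L
  press <- matrix(0, iters, max_lv)
  counted <- matrix(0, iters, max_lv)
  for (it in seq_len(iters)) {
    folds <- cv_folds(n, scheme, n_folds, seed + it - 1L)
    for (f in folds) {
      if (length(f) < 1L || length(f) >= n) stop("degenerate CV fold")
      tr <- setdiff(seq_len(n), f)
      cap <- min(max_lv, length(tr) - 1L, ncol(X))
      fit <- pls1_fit(X[tr, , drop = FALSE], y[tr], cap, preprocessing)
      for (k in seq_len(cap)) {
        sub <- truncate_pls(fit, k)
        e <- y[f] - predict(sub, X[f, , drop = FALSE])
        press[it, k] <- press[it, k] + sum(e^2)
        counted[it, k] <- counted[it, k] + length(f)
      }
      if (cap < max_lv && cap >= 1L) {
        # LV counts beyond the fold's rank reuse its largest model
        sub <- truncate_pls(fit, cap)
        e <- y[f] - predict(sub, X[f, , drop = FALSE])
        for (k in (cap + 1L):max_lv) {
          press[it, k] <- press[it, k] + sum(e^2)
          counted[it, k] <- counted[it, k] + length(f)
        }
      }
    }
  }
  sqrt(colMeans(press / counted))
}

# Reassemble a fitted model at a smaller LV count (NIPALS components nest).
truncate_pls <- function(fit, k) {
  if (k >= fit$n_lv) return(fit)
  W <- fit$weights[, seq_len(k), drop = FALSE]
  P <- fit$x_loadings[, seq_len(k), drop = FALSE]
  Q <- fit$y_loadings[seq_len(k)]
  fit$regression_vector <- drop(W %*% solve(crossprod(P, W), Q))
  fit$n_lv <- k
  fit
}

#' Choose the number of latent variables from an RMSECV curve
#'
#' `"min"` picks the global minimum. `"haaland_thomas"` applies the PRESS
#' F-ratio rule: with `PRESS(k) = n * rmsecv(k)^2`, it selects the smallest
#' `k` whose ratio `PRESS(k)/PRESS(k_min)` is not significant against
#' `F(n, n)` at level `alpha` (default 0.25), i.e. the most parsimonious
#' model statistically indistinguishable from the best.
#'
#' @param rmsecv Numeric RMSECV curve indexed by LV count.
#' @param n Number of calibration samples behind the curve.
#' @param method `"haaland_thomas"` (default) or `"min"`.
#' @param alpha Significance level for the F-ratio rule.
#' @return Selected LV count (integer).
#' @export
select_n_lv <- function(rmsecv, n, method = c("haaland_thomas", "min"),
                        alpha = 0.25) {
  method <- match.arg(method)
  stopifnot(length(rmsecv) >= 1)
  if (method == "min" || length(rmsecv) == 1L) {
    return(which.min(rmsecv))
  }
  k_min <- which.min(rmsecv)
  fcrit <- stats::qf(1 - alpha, n, n)
  ratios <- (rmsecv / rmsecv[k_min])^2
  cand <- which(ratios < fcrit)
  min(cand[cand <= k_min])
}
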