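#' Calibration / cross-validation / prediction error metrics
#'
#' Summarizes predicted against true concentrations the way multivariate
#' calibration tables report them:
#' root-mean-square error labelled by context (RMSEC, RMSECV or RMSEP),
#' mean signed prediction bias `mean(yhat - y)`, bias-corrected mean square
#' error `BCMSEP = sum((e - mean(e))^2) / (n - 1)`, predictive
#' `Q2 = 1 - sum(e^2) / sum((y - mean(y))^2)`, fitted `R2` (squared Pearson
#' correlation), and per-sample recovery statistics
#' (`100 * yhat / y`: mean, SD, RSD).
#'
#' @param y_true True concentrations (ug/mL), length >= 2.
#' @param y_pred Predicted concentrations.
#' @param context `"calibration"`, `"cross_validation"` or `"prediction"`.
#' @return Object of class `model_metrics`: list with `rmse`, `rmse_label`,
#'   `pred_bias`, `bcmsep`, `q2`, `r2`, `mean_recovery_pct`, `sd_recovery`,
#'   `rsd_recovery`, `n`.
#' @export
model_metrics <- function(y_true, y_pred,
                          context = c("calibration", "cross_validation", "prediction")) {
  context <- match.arg(context)
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  e <- y_pred - y_true
  n <- length(e)
  ssy <- sum((y_true - mean(y_true))^2)
  q2 <- if (ssy > 0) 1 - sum(e^2) / ssy else NA_real_
  r2 <- if (ssy > 0 && stats::var(y_pred) > 0) {
    stats::cor(y_true, y_pred)^2
  } else {
    NA_real_
  }
  rec <- 100 * y_pred / y_true
  structure(
    list(
      context = context,
      rmse = sqrt(mean(e^2)),
      rmse_label = switch(context,
        calibration = "RMSEC", cross_validation = "RMSECV",
        prediction = "RMSEP"
      ),
      pred_bias = mean(e),
      bcmsep = sum((e - mean(e))^2) / (n - 1),
      q2 = q2, r2 = r2,
      mean_recovery_pct = mean(rec),
      sd_recovery = stats::sd(rec),
      rsd_recovery = 100 * stats::sd(rec) / mean(rec),
      n = n
    ),
    class = "model_metrics"
  )
}

#' @export
print.model_metrics <- function(x, ...) {
  cat(sprintf(
    "<model_metrics %s> %s %.4g | bias %.4g | BCMSEP %.4g | Q2 %.4f | R2 %.4f | recovery %.2f%% (RSD %.2f%%)\n",
    x$context, x$rmse_label, x$rmse, x$pred_bias, x$bcmsep, x$q2, x$r2,
    x$mean_recovery_pct, x$rsd_recovery
  ))
  invisible(x)
}

#' One-row data frame view of model metrics
#' @param x A [model_metrics()] object.
#' @param ... Unused.
#' @return Data frame mirroring a calibration-table row.
#' @export
as.data.frame.model_metrics <- function(x, ...) {
  df <- data.frame(
    mean_recovery_pct = x$mean_recovery_pct,
    sd = x$sd_recovery, rsd = x$rsd_recovery
  )
  df[[x$rmse_label]] <- x$rmse
  if (x$context == "prediction") {
    df$pred_bias <- x$pred_bias
    df$bcmsep <- x$bcmsep
    df$q2 <- x$q2
  }
  df$r2 <- x$r2
  df
}
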