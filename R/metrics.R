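# The seven evaluation rates and their shared constants.
#
# Conventions fixed across the package:
#   * MST and MSE are both mean-normalized (1/m factors), so the identity
#     R^2 = 1 - MSE/MST holds with either the raw-sum or the mean form.
#   * SMAPE is stored on the fraction scale [0, 2]; 200% is a display
#     concern (multiply by 100 to get the percentage view).
#   * A metric that is mathematically undefined on its input raises a
#     condition of class "regeval_undefined_metric" naming metric and
#     cause; it is never silently patched by dropping points.

#' Mean of the actual values
#'
#' @param series a \code{\link{paired_series}}, or the actual vector when
#'   \code{predicted} is given.
#' @param predicted optional predicted vector (two-vector calling form).
#' @return The arithmetic mean of the actual values.
#' @export
mean_actual <- function(series, predicted = NULL) {
  series <- as_paired_series(series, predicted)
  mean(series$actual)
}

#' Mean total sum of squares
#'
#' The variance-like normalizer in the denominator of the coefficient of
#' determination: \eqn{(1/m) \sum_i (Y_i - \bar Y)^2}. Zero if and only if
#' the actual vector is constant.
#'
#' @inheritParams mean_actual
#' @return A non-negative real.
#' @export
mst <- function(series, predicted = NULL) {
  series <- as_paired_series(series, predicted)
  y <- series$actual
  mean((y - mean(y))^2)
}

#' Coefficient of determination (R-squared)
#'
#' \eqn{R^2 = 1 - \sum_i (X_i - Y_i)^2 / \sum_i (Y_i - \bar Y)^2}. Always
#' at most 1; 0 for the trivial mean predictor; unbounded below. Undefined
#' (error) when the actual vector is constant, since the total sum of
#' squares then vanishes.
#'
#' @inheritParams mean_actual
#' @return A real number in \eqn{(-\infty, 1]}.
#' @export
r_squared <- function(series, predicted = NULL) {
  series <- as_paired_series(series, predicted)
  y <- series$actual
  x <- series$predicted
  sst <- sum((y - mean(y))^2)
  if (sst == 0)
    undefined_metric_error("r_squared",
      "actual values are constant, so the total sum of squares is zero")
  1 - sum((x - y)^2) / sst
}

#' Mean squared error
#' @inheritParams mean_actual
#' @return A non-negative real; 0 means perfect prediction.
#' @export
mse <- function(series, predicted = NULL) {
  series <- as_paired_series(series, predicted)
  mean((series$predicted - series$actual)^2)
}

#' Root mean squared error
#' @inheritParams mean_actual
#' @return \code{sqrt(mse(series))}.
#' @export
rmse <- function(series, predicted = NULL) {
  sqrt(mse(series, predicted))
}

#' Mean absolute error
#' @inheritParams mean_actual
#' @return A non-negative real; 0 means perfect prediction.
#' @export
mae <- function(series, predicted = NULL) {
  series <- as_paired_series(series, predicted)
  mean(abs(series$predicted - series$actual))
}

#' Mean absolute percentage error
#'
#' \eqn{(1/m) \sum_i |Y_i - X_i| / |Y_i|}. Restricted by definition to
#' series whose actual values are all non-zero: any zero actual value
#' makes the metric undefined (an error, not a silent exclusion, since
#' dropping points changes the series length).
#'
#' @inheritParams mean_actual
#' @return A non-negative real.
#' @export
mape <- function(series, predicted = NULL) {
  series <- as_paired_series(series, predicted)
  y <- series$actual
  if (any(y == 0))
    undefined_metric_error("mape",
      "actual values contain zero; MAPE requires all Y_i != 0")
  mean(abs(y - series$predicted) / abs(y))
}

#' Single SMAPE term
#'
#' The contribution of one (prediction, actual) pair to SMAPE on the
#' fraction scale: \eqn{|a - b| / ((|a| + |b|)/2)}, which lies in
#' \eqn{[0, 2]}. The degenerate pair \eqn{a = b = 0} is an exact match and
#' contributes 0, preserving "SMAPE = 0 iff perfect prediction".
#'
#' @param a predicted value.
#' @param b actual value.
#' @return A real in \eqn{[0, 2]}; vectorized over \code{a}, \code{b}.
#' @export
smape_term <- function(a, b) {
  num <- abs(a - b)
  den <- (abs(a) + abs(b)) / 2
  ifelse(num == 0, 0, num / den)
}

#' Symmetric mean absolute percentage error
#'
#' Mean of \code{\link{smape_term}} over all pairs, on the fraction scale
#' \eqn{[0, 2]}: 0 is a perfect prediction, 2 the worst possible (attained
#' whenever actual and predicted always have opposite signs). The common
#' percentage view is \code{100 * smape(series)} (so the maximum reads
#' 200\%).
#'
#' @inheritParams mean_actual
#' @return A real in \eqn{[0, 2]}.
#' @export
smape <- function(series, predicted = NULL) {
  series <- as_paired_series(series, predicted)
  mean(smape_term(series$predicted, series$actual))
}

#' Complementary normalized SMAPE
#'
#' \eqn{cnSMAPE = 1 - SMAPE/2} on the fraction scale, so that 1 means a
#' perfect prediction and 0 the worst one — the same polarity as the
#' coefficient of determination, which makes the two directly comparable.
#'
#' @param smape_value a SMAPE value on the fraction scale, in \eqn{[0, 2]}.
#' @return A real in \eqn{[0, 1]}.
#' @export
cn_smape <- function(smape_value) {
  if (!is.numeric(smape_value) || any(!is.finite(smape_value)) ||
      any(smape_value < 0) || any(smape_value > 2))
    domain_error("cn_smape input must lie in [0, 2] (fraction-scale SMAPE)")
  1 - smape_value / 2
}

#' Evaluate every metric on a paired series
#'
#' Computes all seven rates plus the two shared constants (mean of the
#' actual values and MST) in one pass. MAPE on a series with a zero actual
#' value is reported as \code{NA} with an explanatory \code{mape_reason}
#' rather than raising, so a full report can still be produced; R-squared
#' on a constant actual vector has no defensible value and raises.
#'
#' @inheritParams mean_actual
#' @return An object of class \code{"metric_report"}: a list with fields
#'   \code{y_bar}, \code{mst}, \code{r_squared}, \code{mse}, \code{rmse},
#'   \code{mae}, \code{mape}, \code{mape_reason}, \code{smape},
#'   \code{cn_smape} and \code{m}.
#' @examples
#' evaluate_all(paired_series(c(1, 1, 1, 1, 1, 2, 3), rep(1, 7)))
#' @export
evaluate_all <- function(series, predicted = NULL) {
  series <- as_paired_series(series, predicted)
  mape_value <- NA_real_
  mape_reason <- NA_character_
  tryCatch(mape_value <- mape(series),
           regeval_undefined_metric = function(e) {
             mape_reason <<- conditionMessage(e)
           })
  smape_value <- smape(series)
  structure(list(
    y_bar = mean_actual(series),
    mst = mst(series),
    r_squared = r_squared(series),
    mse = mse(series),
    rmse = rmse(series),
    mae = mae(series),
    mape = mape_value,
    mape_reason = mape_reason,
    smape = smape_value,
    cn_smape = cn_smape(smape_value),
    m = series$m
  ), class = "metric_report")
}

metric_names <- function() {
  c("r_squared", "mse", "rmse", "mae", "mape", "smape", "cn_smape")
}

# Polarity of each rate: does a larger value mean a better model?
metric_polarity <- function(metric) {
  if (metric %in% c("r_squared", "cn_smape")) "higher_better" else "lower_better"
}

#' @export
print.metric_report <- function(x, digits = 6, ...) {
  cat(sprintf("Metric report on %d points (Ybar = %.6g, MST = %.6g)\n",
              x$m, x$y_bar, x$mst))
  vals <- unlist(x[metric_names()])
  out <- format(signif(vals, digits))
  if (is.na(x$mape)) out["mape"] <- "NA"
  for (nm in metric_names())
    cat(sprintf("  %-10s %s\n", nm, out[nm]))
  if (is.na(x$mape))
    cat(sprintf("  (MAPE undefined: %s)\n", x$mape_reason))
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(y_bar = x$y_bar, mst = x$mst, r_squared = x$r_squared,
             mse = x$mse, rmse = x$rmse, mae = x$mae, mape = x$mape,
             mape_reason = x$mape_reason, smape = x$smape,
             cn_smape = x$cn_smape, m = x$m,
             row.names = row.names, stringsAsFactors = FALSE)
}

#' Serialize a metric report to a one-row CSV file
#'
#' Undefined metrics are written as the literal token \code{NA} together
#' with a human-readable reason column.
#'
#' @param report a \code{"metric_report"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_metric_report <- function(report, path) {
  stopifnot(inherits(report, "metric_report"))
  write_metric_table(as.data.frame(report), path)
}
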