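#' Paired ground-truth/prediction series
#'
#' The universal input of every metric: a vector of observed target values
#' and an aligned vector of predicted values. Both must be finite numeric
#' vectors of the same positive length; missing values are rejected rather
#' than dropped, because silently changing the series length changes every
#' mean-based metric.
#'
#' @param actual numeric vector of observed target values.
#' @param predicted numeric vector of predicted values, same length.
#' @return An object of class \code{"paired_series"}: a list with elements
#'   \code{actual}, \code{predicted} and \code{m} (the common length).
#' @examples
#' ps <- paired_series(1:5, c(1, 2, 3, 5, 2))
#' ps$m
#' @export
paired_series <- function(actual, predicted) {
  actual <- as.numeric(actual)
  predicted <- as.numeric(predicted)
  if (length(actual) < 1L)
    domain_error("paired series must contain at least one point")
  if (length(actual) != length(predicted))
    domain_error("actual (%d) and predicted (%d) lengths differ",
                 length(actual), length(predicted))
  if (!all(is.finite(actual)) || !all(is.finite(predicted)))
    domain_error("paired series entries must all be finite (no NA/NaN/Inf)")
  structure(list(actual = actual, predicted = predicted,
                 m = length(actual)),
            class = "paired_series")
}

#' @export
print.paired_series <- function(x, ...) {
  cat(sprintf("Paired series with m = %d points\n", x$m))
  df <- data.frame(actual = x$actual, predicted = x$predicted)
  print(utils::head(df, 10L), ...)
  if (x$m > 10L) cat(sprintf("... %d more rows\n", x$m - 10L))
  invisible(x)
}

as_paired_series <- function(x, predicted = NULL) {
  if (inherits(x, "paired_series")) return(x)
  paired_series(x, predicted)
}

#' Read a paired series from a two-column CSV file
#'
#' Expects a header row \code{actual,predicted}, decimal point, comma
#' separator, UTF-8 encoding.
#'
#' @param path path to the CSV file.
#' @return A \code{\link{paired_series}} object.
#' @export
read_paired_series <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("actual", "predicted") %in% names(df)))
    domain_error("'%s' must have columns 'actual' and 'predicted'", path)
  paired_series(df$actual, df$predicted)
}

#' Write a paired series to a two-column CSV file
#'
#' @param series a \code{\link{paired_series}} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_paired_series <- function(series, path) {
  series <- as_paired_series(series)
  write_metric_table(
    data.frame(actual = series$actual, predicted = series$predicted), path)
}
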