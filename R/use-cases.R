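# Constructed use cases in which the coefficient of determination and
# SMAPE/cnSMAPE give discordant verdicts, plus the two in-text worked
# examples (an R^2 ~ 0 series and a SMAPE-maximum series). All series are
# regenerated from code (or shipped as printed-digit fixtures), so every
# result is reproducible bit-for-bit.

#' UC1: a perfect line with j points zeroed at every fifth index
#'
#' Ground truth is \code{1:100}; the prediction coincides with it except
#' at the first \code{j} indices congruent to 1 modulo 5 (1, 6, 11, ...,
#' 1-based), which are set to 0. As \code{j} grows, cnSMAPE decreases
#' linearly (\code{1 - j/100}) while R-squared falls much faster — the
#' rates disagree about how bad the degradation is.
#'
#' @param j integer number of zeroed points, between 0 and 20.
#' @return A \code{\link{paired_series}}.
#' @export
build_uc1 <- function(j) {
  j <- as.integer(j)
  if (length(j) != 1L || is.na(j) || j < 0L || j > 20L)
    domain_error("j must be a single integer in [0, 20], got %s", format(j))
  actual <- as.numeric(1:100)
  predicted <- actual
  if (j > 0L) predicted[5L * (0:(j - 1L)) + 1L] <- 0
  paired_series(actual, predicted)
}

#' UC2: ten zeroed points at the start, middle or end of the line
#'
#' Ground truth is \code{1:100}; the prediction zeroes indices 1-10
#' (\code{"start"}), 51-60 (\code{"middle"}) or 91-100 (\code{"end"}) and
#' matches the truth elsewhere. cnSMAPE is 0.9 in all three cases —
#' SMAPE counts mismatching points but ignores where they are — while
#' R-squared degrades sharply as the zeroed block moves to larger values.
#'
#' @param variant one of \code{"start"}, \code{"middle"}, \code{"end"}.
#' @return A \code{\link{paired_series}}.
#' @export
build_uc2 <- function(variant = c("start", "middle", "end")) {
  variant <- match.arg(variant)
  idx <- switch(variant, start = 1:10, middle = 51:60, end = 91:100)
  actual <- as.numeric(1:100)
  predicted <- actual
  predicted[idx] <- 0
  paired_series(actual, predicted)
}

#' Minimal-degree polynomial interpolant
#'
#' Returns an evaluator for the unique polynomial of degree at most
#' \eqn{n - 1} through \eqn{n} points with distinct abscissae, evaluated
#' with the barycentric Lagrange scheme (stable, and valid outside the
#' node range, where the interpolant is extrapolated).
#'
#' @param xs distinct abscissae.
#' @param ys ordinates, same length as \code{xs}.
#' @return A function mapping a numeric vector of evaluation points to
#'   interpolant values.
#' @examples
#' f <- interpolating_polynomial(c(0, 1, 2), c(1, 2, 5)) # x^2 + 1
#' f(3) # 10
#' @export
interpolating_polynomial <- function(xs, ys) {
  xs <- as.numeric(xs)
  ys <- as.numeric(ys)
  if (length(xs) != length(ys))
    domain_error("xs and ys must have the same length")
  if (anyDuplicated(xs))
    domain_error("interpolation abscissae must be pairwise distinct")
  # Barycentric weights w_j = 1 / prod_{k != j} (x_j - x_k); the second
  # (true) form of the barycentric formula is stable for interpolation
  # and, unlike naive Lagrange products, also well-behaved when
  # evaluating outside the node range.
  w <- vapply(seq_along(xs),
              function(j) 1 / prod(xs[j] - xs[-j]), numeric(1))
  function(x) {
    x <- as.numeric(x)
    vapply(x, function(xi) {
      hit <- which(xs == xi)
      if (length(hit)) return(ys[hit[1L]])  # interpolation condition
      q <- w / (xi - xs)
      sum(q * ys) / sum(q)
    }, numeric(1))
  }
}

#' UC3: overfit polynomial versus the true line on noisy data
#'
#' Twenty noisy observations of the line \eqn{y = x} are compared against
#' two regression models: the \emph{correct} model, the clean line itself
#' (predictions \code{1:20}), and the \emph{wrong} model, the
#' minimal-degree polynomial interpolant through the first 10 noisy points
#' evaluated at \code{x = 1:20}. The wrong model matches the data exactly
#' up to x = 10 and then diverges violently.
#'
#' @param noise_sd standard deviation of the i.i.d. Gaussian noise added
#'   to the line (default 0.5).
#' @param seed integer seed for the noise realization (default 42).
#' @return A list with components \code{x} (1:20), \code{actual} (noisy
#'   observations), \code{correct_preds} and \code{wrong_preds}.
#' @export
build_uc3 <- function(noise_sd = 0.5, seed = 42L) {
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0)
    domain_error("noise_sd must be a single positive number")
  xs <- as.numeric(1:20)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  actual <- xs + stats::rnorm(20L, mean = 0, sd = noise_sd)
  interp <- interpolating_polynomial(xs[1:10], actual[1:10])
  list(x = xs,
       actual = actual,
       correct_preds = xs,
       wrong_preds = interp(xs))
}

# Save/restore the global RNG state so generators are pure functions of
# their seed argument without clobbering the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Evaluate all metrics on the first N points of a pair of vectors
#'
#' @param actual numeric vector of observed values.
#' @param predicted numeric vector of predictions, same length.
#' @param N prefix length, between 2 and \code{length(actual)}.
#' @return A \code{"metric_report"} on the length-\code{N} prefix.
#' @export
evaluate_prefix <- function(actual, predicted, N) {
  N <- as.integer(N)
  if (length(actual) != length(predicted))
    domain_error("actual and predicted lengths differ")
  if (is.na(N) || N < 2L || N > length(actual))
    domain_error("N must lie in [2, %d], got %s", length(actual), format(N))
  evaluate_all(paired_series(actual[seq_len(N)], predicted[seq_len(N)]))
}

#' UC4: a constant prediction of a nearly constant target
#'
#' Actual values (1, 1, 1, 1, 1, 2, 3) predicted as all 1. The regression
#' predicts nothing but the majority value, yet SMAPE scores it 0.238
#' (88.1\% correct on the cnSMAPE scale) while R-squared is negative.
#'
#' @return A \code{\link{paired_series}}.
#' @export
build_uc4 <- function() {
  paired_series(c(1, 1, 1, 1, 1, 2, 3), rep(1, 7))
}

#' UC5: exhaustive enumeration of integer predictions of (1,2,3,4,5)
#'
#' Every prediction vector in \eqn{\{1,\dots,5\}^5} is evaluated against
#' the actual vector (1, 2, 3, 4, 5), giving all \eqn{5^5 = 3125} grid
#' points in lexicographic order. The scatter of cnSMAPE against the
#' entries with non-negative R-squared exposes predictions that SMAPE
#' rates highly while R-squared rates at zero.
#'
#' @return A data frame with columns \code{p1}..\code{p5},
#'   \code{r_squared} and \code{cn_smape}, one row per grid point.
#' @export
enumerate_uc5 <- function() {
  grid <- expand.grid(p5 = 1:5, p4 = 1:5, p3 = 1:5, p2 = 1:5, p1 = 1:5,
                      KEEP.OUT.ATTRS = FALSE)[, 5:1]
  actual <- as.numeric(1:5)
  sst <- sum((actual - mean(actual))^2)
  pred <- as.matrix(grid)
  res2 <- rowSums((pred - rep(actual, each = nrow(pred)))^2)
  r2 <- 1 - res2 / sst
  terms <- abs(pred - rep(actual, each = nrow(pred))) /
    ((abs(pred) + rep(abs(actual), each = nrow(pred))) / 2)
  cns <- 1 - rowMeans(terms) / 2
  out <- data.frame(grid, r_squared = r2, cn_smape = cns,
                    row.names = NULL)
  rownames(out) <- NULL
  out
}

#' Filter the UC5 enumeration to non-negative R-squared entries
#'
#' @param uc5 output of \code{\link{enumerate_uc5}} (computed if missing).
#' @return The subset of rows with \code{r_squared >= 0}.
#' @export
filter_uc5_nonnegative <- function(uc5 = enumerate_uc5()) {
  out <- uc5[uc5$r_squared >= 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

worked_example_fixture <- function(name) {
  path <- system.file("extdata", name, package = "regeval", mustWork = TRUE)
  read_paired_series(path)
}

#' Worked example: a far-from-perfect prediction with R-squared near zero
#'
#' Ten observed values with predictions scattered around the observed
#' mean, constructed so that MSE equals MST (both 1051.511) and hence the
#' coefficient of determination is numerically zero (about 1e-7) even
#' though the prediction tracks none of the variation.
#'
#' @return A \code{\link{paired_series}} with the ten printed-digit pairs.
#' @export
worked_example_r2_zero <- function() {
  worked_example_fixture("worked_example_r2_zero.csv")
}

#' Worked example: opposite signs drive SMAPE to its maximum
#'
#' A sign-alternating ground truth paired with predictions of uniformly
#' opposite sign. Every SMAPE term is then exactly 2 regardless of the
#' magnitudes, so SMAPE attains its worst value 2 (200\%) and cnSMAPE 0.
#'
#' @return A \code{\link{paired_series}} with the ten printed-digit pairs.
#' @export
worked_example_smape_max <- function() {
  worked_example_fixture("worked_example_smape_max.csv")
}
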