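# Independent naive-loop implementations of every rate, used as oracles.
# Deliberately scalar and loop-based so they share no code path with the
# package's vectorized implementations.

oracle_mean <- function(y) {
  s <- 0
  for (v in y) s <- s + v
  s / length(y)
}

oracle_mst <- function(y) {
  yb <- oracle_mean(y)
  s <- 0
  for (v in y) s <- s + (v - yb)^2
  s / length(y)
}

oracle_r_squared <- function(y, x) {
  yb <- oracle_mean(y)
  num <- 0
  den <- 0
  for (i in seq_along(y)) {
    num <- num + (x[i] - y[i])^2
    den <- den + (y[i] - yb)^2
  }
  1 - num / den
}

oracle_mse <- function(y, x) {
  s <- 0
  for (i in seq_along(y)) s <- s + (x[i] - y[i])^2
  s / length(y)
}

oracle_rmse <- function(y, x) sqrt(oracle_mse(y, x))

oracle_mae <- function(y, x) {
  s <- 0
  for (i in seq_along(y)) s <- s + abs(x[i] - y[i])
  s / length(y)
}

oracle_mape <- function(y, x) {
  s <- 0
  for (i in seq_along(y)) s <- s + abs(y[i] - x[i]) / abs(y[i])
  s / length(y)
}

oracle_smape <- function(y, x) {
  s <- 0
  for (i in seq_along(y)) {
    num <- abs(x[i] - y[i])
    if (num > 0) s <- s + num / ((abs(x[i]) + abs(y[i])) / 2)
  }
  s / length(y)
}

oracle_cn_smape <- function(y, x) 1 - oracle_smape(y, x) / 2

# Random paired series with non-constant actual values.
random_series <- function(m = sample(2:10, 1), scale = 10) {
  repeat {
    y <- round(stats::runif(m, -scale, scale), 6)
    if (length(unique(y)) > 1) break
  }
  x <- round(y + stats::rnorm(m, sd = scale / 4), 6)
  paired_series(y, x)
}

# Agreement to `digits` significant digits: relative tolerance, with a
# small absolute floor so that two quantities that are both zero up to
# floating-point cancellation compare as equal.
expect_signif_equal <- function(got, want, digits) {
  tol <- max(abs(want), abs(got)) * 10^(-digits) + 1e-14
  expect_lt(abs(got - want), tol)
}
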