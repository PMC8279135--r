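test_that("paired_series validates its input", {
  ps <- paired_series(1:3, c(1, 2, 4))
  expect_s3_class(ps, "paired_series")
  expect_equal(ps$m, 3L)
  expect_error(paired_series(1:3, 1:4), class = "regeval_domain_error")
  expect_error(paired_series(numeric(0), numeric(0)),
               class = "regeval_domain_error")
  expect_error(paired_series(c(1, NA), c(1, 2)),
               class = "regeval_domain_error")
  expect_error(paired_series(c(1, Inf), c(1, 2)),
               class = "regeval_domain_error")
})

test_that("mean and MST match hand arithmetic and the worked example", {
  expect_equal(mean_actual(paired_series(1:5, 1:5)), 3)
  expect_equal(mean_actual(paired_series(rep(7, 4), 1:4)), 7)
  expect_equal(mst(paired_series(1:5, 1:5)), 2)  # (4+1+0+1+4)/5
  expect_equal(mst(paired_series(rep(7, 4), 1:4)), 0)
  we <- worked_example_r2_zero()
  expect_equal(mean_actual(we), 45.91618, tolerance = 5e-6 / 45.91618)
  expect_lt(abs(mst(we) - 1051.511), 5e-4)
})

test_that("squared-error metrics match their printed and hand values", {
  # constructed example: residuals (1, -1)
  expect_equal(mse(paired_series(c(0, 2), c(1, 1))), 1)
  expect_equal(rmse(paired_series(c(0, 2), c(1, 1))), 1)
  we <- worked_example_r2_zero()
  expect_lt(abs(mse(we) - 1051.511), 5e-4)
  expect_lt(abs(rmse(we) - 32.4270), 5e-5)
  expect_lt(abs(r_squared(we)), 1e-6)
  # perfect prediction
  id <- paired_series(1:7, 1:7)
  expect_equal(r_squared(id), 1)
  expect_equal(mse(id), 0)
  expect_equal(rmse(id), 0)
})

test_that("R-squared handles its known special values and errors", {
  expect_lt(abs(r_squared(build_uc4()) - (-0.346)), 5e-4)
  expect_equal(r_squared(paired_series(1:5, c(1, 2, 3, 5, 2))), 0)
  expect_error(r_squared(paired_series(rep(2, 5), 1:5)),
               class = "regeval_undefined_metric")
})

test_that("MAE matches hand arithmetic and is shift-equivariant", {
  expect_equal(mae(build_uc4()), 3 / 7)
  expect_equal(mae(paired_series(1:6, 1:6)), 0)
  y <- c(2.5, -1, 4, 0)
  expect_equal(mae(paired_series(y, y + 1.75)), 1.75)
  expect_equal(mae(paired_series(y, y - 3)), 3)
})

test_that("MAPE matches hand arithmetic and rejects zero actuals", {
  expect_equal(mape(paired_series(c(1, 2, 4), c(2, 1, 2))), 2 / 3)
  expect_equal(mape(paired_series(1:4, 1:4)), 0)
  expect_error(mape(paired_series(c(1, 0, 2), c(1, 1, 1))),
               class = "regeval_undefined_metric")
})

test_that("SMAPE terms cover the degenerate and extreme cases", {
  expect_equal(smape_term(3.2, 3.2), 0)
  expect_equal(smape_term(0, 0), 0)        # exact match, not 0/0
  expect_equal(smape_term(0, 5), 2)        # zeroed prediction is maximal
  expect_equal(smape_term(-1.5, 1e6), 2)   # opposite signs are maximal
  expect_equal(smape_term(2, 1), 2 / 3)
})

test_that("SMAPE matches printed values and its extremes", {
  expect_lt(abs(smape(build_uc4()) - 0.238), 5e-4)
  expect_equal(smape(paired_series(1:9, 1:9)), 0)
  expect_equal(smape(worked_example_smape_max()), 2)
  expect_equal(cn_smape(smape(worked_example_smape_max())), 0)
  # negating the predictions aligns all signs; SMAPE drops below maximum
  we <- worked_example_smape_max()
  expect_lt(smape(paired_series(we$actual, -we$predicted)), 2)
})

test_that("cnSMAPE is the exact complement on [0, 2] and rejects outside", {
  expect_equal(cn_smape(0), 1)
  expect_equal(cn_smape(2), 0)
  expect_equal(cn_smape(0.238), 0.881)
  expect_error(cn_smape(2.1), class = "regeval_domain_error")
  expect_error(cn_smape(-0.01), class = "regeval_domain_error")
})

test_that("evaluate_all populates a full report with flagged MAPE", {
  rep <- evaluate_all(build_uc4())
  expect_s3_class(rep, "metric_report")
  expect_lt(abs(rep$r_squared - (-0.346)), 5e-4)
  expect_lt(abs(rep$smape - 0.238), 5e-4)
  expect_equal(rep$cn_smape, 1 - rep$smape / 2)
  expect_equal(rep$rmse, sqrt(rep$mse))

  perfect <- evaluate_all(paired_series(1:5, 1:5))
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$cn_smape, 1)

  uc5 <- evaluate_all(paired_series(1:5, c(1, 2, 3, 5, 2)))
  expect_equal(uc5$r_squared, 0)
  expect_equal(round(uc5$cn_smape, 3), 0.892)

  # zero actual: MAPE flagged NA with a reason, everything else computed
  withzero <- evaluate_all(paired_series(c(0, 1, 2), c(1, 1, 1)))
  expect_true(is.na(withzero$mape))
  expect_match(withzero$mape_reason, "zero")
  expect_false(is.na(withzero$smape))

  # constant actual: undefined R-squared propagates
  expect_error(evaluate_all(paired_series(rep(1, 3), c(1, 2, 3))),
               class = "regeval_undefined_metric")
})

test_that("all metrics agree with the naive-loop oracle on random series", {
  set.seed(101)
  for (i in 1:200) {
    ps <- random_series()
    y <- ps$actual
    x <- ps$predicted
    expect_signif_equal(mean_actual(ps), oracle_mean(y), 12)
    expect_signif_equal(mst(ps), oracle_mst(y), 12)
    expect_signif_equal(r_squared(ps), oracle_r_squared(y, x), 12)
    expect_signif_equal(mse(ps), oracle_mse(y, x), 12)
    expect_signif_equal(rmse(ps), oracle_rmse(y, x), 12)
    expect_signif_equal(mae(ps), oracle_mae(y, x), 12)
    if (all(y != 0)) expect_signif_equal(mape(ps), oracle_mape(y, x), 12)
    expect_signif_equal(smape(ps), oracle_smape(y, x), 12)
  }
})

test_that("metric identities and bounds hold on random series", {
  set.seed(202)
  for (i in 1:200) {
    ps <- random_series()
    rep <- evaluate_all(ps)
    if (rep$mst > 0)
      expect_signif_equal(rep$r_squared, 1 - rep$mse / rep$mst, 8)
    expect_signif_equal(rep$rmse, sqrt(rep$mse), 12)
    expect_lte(rep$r_squared, 1)
    expect_gte(rep$smape, 0)
    expect_lte(rep$smape, 2)
    expect_gte(rep$cn_smape, 0)
    expect_lte(rep$cn_smape, 1)
    expect_gte(rep$mae, 0)
    expect_gte(rep$mse, 0)
  }
})

test_that("SMAPE vanishes exactly when prediction equals truth", {
  set.seed(303)
  for (i in 1:50) {
    ps <- random_series()
    expect_equal(smape(paired_series(ps$actual, ps$actual)), 0)
    if (any(ps$predicted != ps$actual))
      expect_gt(smape(ps), 0)
  }
  # including an exactly-zero matched pair
  expect_equal(smape(paired_series(c(0, 1, -2), c(0, 1, -2))), 0)
})

test_that("R-squared is affine invariant but SMAPE is not", {
  set.seed(404)
  for (i in 1:50) {
    ps <- random_series()
    a <- stats::runif(1, 0.2, 3) * sample(c(-1, 1), 1)
    b <- stats::runif(1, -5, 5)
    tr <- paired_series(a * ps$actual + b, a * ps$predicted + b)
    expect_signif_equal(r_squared(tr), r_squared(ps), 8)
  }
  # witness that SMAPE lacks the same invariance: a pure shift changes it
  witness <- paired_series(c(1, 2, 3, 4), c(2, 1, 4, 3))
  shifted <- paired_series(witness$actual + 10, witness$predicted + 10)
  expect_gt(abs(smape(witness) - smape(shifted)), 0.1)
})

test_that("ranking by R-squared reverses ranking by MSE and RMSE", {
  set.seed(505)
  actual <- stats::runif(30, 1, 10)
  preds <- lapply(1:6, function(k) actual + stats::rnorm(30, sd = k / 2))
  names(preds) <- paste0("m", 1:6)
  r2 <- vapply(preds, function(p) r_squared(paired_series(actual, p)), 1)
  ms <- vapply(preds, function(p) mse(paired_series(actual, p)), 1)
  rm <- vapply(preds, function(p) rmse(paired_series(actual, p)), 1)
  expect_equal(order(-r2), order(ms))
  expect_equal(order(ms), order(rm))
})

test_that("paired series round-trip through CSV files", {
  ps <- paired_series(c(1.25, -2.5, 3.125), c(0.1, 0.2, 0.3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_paired_series(ps, path)
  back <- read_paired_series(path)
  expect_identical(back$actual, ps$actual)
  expect_identical(back$predicted, ps$predicted)
})

test_that("metric reports serialize with NA tokens and reasons", {
  rep <- evaluate_all(paired_series(c(0, 1, 2), c(1, 1, 1)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_metric_report(rep, path)
  back <- utils::read.csv(path)
  expect_true(is.na(back$mape))
  expect_match(back$mape_reason, "zero")
  expect_equal(as.numeric(back$r_squared), rep$r_squared)
})
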