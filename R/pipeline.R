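# Repeated-holdout, multi-model evaluation with per-metric rankings.
#
# One run = shuffle -> 80/20 split -> fit each model on the train part ->
# predict the test part -> score with every rate. Repeating the run over
# fresh splits and averaging per metric gives a mean table from which
# each metric induces its own ordering of the competing models; the
# orderings need not agree, and their disagreement is the object of
# study.

#' Declare a regression model for the evaluation pipeline
#'
#' @param name short identifier used in tables and rankings.
#' @param fit function \code{(features, target, seed)} returning a
#'   predictor, i.e. a function mapping a feature matrix to a numeric
#'   prediction vector. Stochastic learners must consume the supplied
#'   seed so a run is reproducible.
#' @return An object of class \code{"model_spec"}.
#' @export
model_spec <- function(name, fit) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fit))
  structure(list(name = name, fit = fit), class = "model_spec")
}

#' The default three-model set
#'
#' Linear regression (\code{stats::lm}), a regression tree
#' (\code{rpart}) and a random forest (\code{randomForest}) — the
#' standard trio of off-the-shelf tabular regressors. Hyperparameters
#' are exposed here rather than hard-coded.
#'
#' @param forest_trees number of trees for the random forest.
#' @param tree_cp complexity parameter for the regression tree.
#' @return A named list of \code{\link{model_spec}} objects.
#' @export
default_models <- function(forest_trees = 100L, tree_cp = 0.01) {
  as_df <- function(x) as.data.frame(x)
  linear <- model_spec("linear", function(x, y, seed) {
    fit <- stats::lm(y ~ ., data = cbind(as_df(x), y = y))
    function(newx) unname(stats::predict(fit, newdata = as_df(newx)))
  })
  tree <- model_spec("tree", function(x, y, seed) {
    fit <- rpart::rpart(y ~ ., data = cbind(as_df(x), y = y),
                        method = "anova", cp = tree_cp)
    function(newx) unname(stats::predict(fit, newdata = as_df(newx)))
  })
  forest <- model_spec("forest", function(x, y, seed) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    # ordinal level codes have few unique values, which trips the
    # forest's are-you-sure-this-is-regression heuristic; regression on
    # the numeric coding is intended here
    fit <- suppressWarnings(
      randomForest::randomForest(x = x, y = y, ntree = forest_trees))
    function(newx) unname(stats::predict(fit, newdata = newx))
  })
  list(linear = linear, tree = tree, forest = forest)
}

# MAPE is undefined on a zero actual value; ordinal codings that start at
# 0 (hepatitis-like levels 0..3) are therefore shifted up to start at 1
# before evaluation. The shift is affine with slope one, so it leaves the
# within-run model ordering by squared-error metrics intact.
shift_zero_levels <- function(ds) {
  if (any(ds$target == 0)) {
    offset <- 1 - min(ds$target)
    ds$target <- ds$target + offset
    message(sprintf(
      "target contains 0; shifting levels by +%g so MAPE is defined", offset))
  }
  ds
}

#' Run one shuffle/split/fit/score cycle
#'
#' All models share the identical split. The dataset must already be
#' complete (impute first); targets containing a zero level are shifted
#' up by a constant so MAPE is defined (a message reports the shift).
#'
#' @param ds a complete \code{"scenario_dataset"}.
#' @param models list of \code{\link{model_spec}} objects.
#' @param split_seed integer seed for the shuffle and any stochastic
#'   learner.
#' @param train_fraction train proportion (default 0.8).
#' @return A named list of \code{"metric_report"} objects, one per model,
#'   with the split seed attached as an attribute.
#' @export
run_single <- function(ds, models, split_seed = 1L, train_fraction = 0.8) {
  stopifnot(inherits(ds, "scenario_dataset"))
  if (any(is.na(ds$features)))
    domain_error("dataset contains missing values; impute before evaluation")
  ds <- shift_zero_levels(ds)
  parts <- shuffle_split(ds, train_fraction, seed = split_seed)
  reports <- lapply(models, function(m) {
    stopifnot(inherits(m, "model_spec"))
    predictor <- tryCatch(
      m$fit(parts$train$features, parts$train$target, as.integer(split_seed)),
      error = function(e) domain_error("model '%s' failed to fit: %s",
                                       m$name, conditionMessage(e)))
    preds <- predictor(parts$test$features)
    evaluate_all(paired_series(parts$test$target, preds))
  })
  names(reports) <- unname(vapply(models, `[[`, "", "name"))
  attr(reports, "split_seed") <- as.integer(split_seed)
  reports
}

#' Repeated-holdout evaluation with per-metric rankings
#'
#' Generates one dataset from the config, imputes it if needed, then runs
#' \code{n_runs} independent shuffle/split/fit/score cycles with per-run
#' seeds derived from the master seed. Means and standard deviations per
#' metric and model are tabulated, and each metric's ordering of the
#' models (best first, respecting the metric's polarity) is computed
#' from the means.
#'
#' @param config a \code{\link{scenario_config}} (its \code{seed} is the
#'   master seed), or an already-built \code{"scenario_dataset"} — e.g.
#'   one loaded from CSV with \code{\link{read_scenario_dataset}} — to be
#'   evaluated as-is.
#' @param models list of \code{\link{model_spec}}s
#'   (default \code{\link{default_models}()}).
#' @param n_runs number of repeated holdout runs.
#' @param train_fraction train proportion (default 0.8).
#' @param master_seed master seed for the per-run seeds; defaults to the
#'   config's seed (required when passing a dataset without a config).
#' @return An object of class \code{"ranking_table"}: methods, per-metric
#'   mean and sd matrices, per-run values, and per-metric orderings.
#' @export
run_repeated <- function(config, models = default_models(), n_runs = 100L,
                         train_fraction = 0.8, master_seed = NULL) {
  n_runs <- as.integer(n_runs)
  if (is.na(n_runs) || n_runs < 1L)
    domain_error("n_runs must be a positive integer")
  if (inherits(config, "scenario_dataset")) {
    ds <- config
    config <- ds$config
  } else {
    stopifnot(inherits(config, "scenario_config"))
    ds <- generate_dataset(config)
  }
  if (is.null(master_seed)) {
    if (is.null(config))
      domain_error("master_seed is required for a dataset without a config")
    master_seed <- config$seed
  }
  if (any(is.na(ds$features))) ds <- impute_simple(ds)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(master_seed))
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  method_names <- unname(vapply(models, `[[`, "", "name"))
  mets <- metric_names()
  per_run <- array(NA_real_,
                   dim = c(n_runs, length(models), length(mets)),
                   dimnames = list(NULL, method_names, mets))
  for (i in seq_len(n_runs)) {
    reports <- suppressMessages(
      run_single(ds, models, split_seed = run_seeds[i],
                 train_fraction = train_fraction))
    for (m in method_names)
      per_run[i, m, ] <- unlist(reports[[m]][mets])
  }
  mean_values <- apply(per_run, c(2, 3), mean)
  sd_values <- apply(per_run, c(2, 3), stats::sd)
  if (n_runs == 1L) sd_values[] <- 0  # no spread over a single run
  orderings <- lapply(mets, function(met) {
    rank_methods(mean_values[, met], metric_polarity(met))
  })
  names(orderings) <- mets
  structure(list(
    methods = method_names,
    metrics = mets,
    mean_values = mean_values,
    sd_values = sd_values,
    per_run = per_run,
    orderings = orderings,
    n_runs = n_runs,
    config = config
  ), class = "ranking_table")
}

#' Order methods by a metric's values
#'
#' Stable sort under the metric's polarity; ties are broken by
#' lexicographic method name so the ordering is deterministic. \code{NA}
#' values are excluded with a warning.
#'
#' @param values named numeric vector, one value per method.
#' @param polarity \code{"higher_better"} (e.g. R-squared, cnSMAPE) or
#'   \code{"lower_better"} (error rates).
#' @return Character vector of method names, best first.
#' @export
rank_methods <- function(values, polarity = c("higher_better", "lower_better")) {
  polarity <- match.arg(polarity)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    domain_error("rank_methods requires a fully named value vector")
  if (anyNA(values)) {
    warning(sprintf("excluding methods with NA values from ranking: %s",
                    paste(names(values)[is.na(values)], collapse = ", ")))
    values <- values[!is.na(values)]
  }
  key <- if (polarity == "higher_better") -values else values
  names(values)[order(key, names(values), method = "radix")]
}

#' Agreement between the rankings induced by each metric pair
#'
#' For each unordered pair of metrics, reports whether the two orderings
#' are identical and how many of the method pairs they order oppositely
#' (pairwise inversions, the unnormalized Kendall distance).
#'
#' @param table a \code{"ranking_table"}.
#' @return A data frame with columns \code{metric_a}, \code{metric_b},
#'   \code{identical}, \code{inversions}.
#' @export
ranking_agreement <- function(table) {
  stopifnot(inherits(table, "ranking_table"))
  mets <- names(table$orderings)
  pairs <- utils::combn(mets, 2)
  res <- apply(pairs, 2, function(pr) {
    o1 <- table$orderings[[pr[1]]]
    o2 <- table$orderings[[pr[2]]]
    c(identical = identical(o1, o2),
      inversions = count_inversions(o1, o2))
  })
  data.frame(metric_a = pairs[1, ], metric_b = pairs[2, ],
             identical = as.logical(res["identical", ]),
             inversions = as.integer(res["inversions", ]),
             stringsAsFactors = FALSE)
}

# Number of method pairs ordered oppositely by two orderings of the same
# method set (brute force over all pairs; method counts are tiny).
count_inversions <- function(o1, o2) {
  stopifnot(setequal(o1, o2))
  n <- length(o1)
  if (n < 2L) return(0L)
  inv <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- o1[i]; b <- o1[j]           # a before b in o1
      if (match(a, o2) > match(b, o2)) inv <- inv + 1L
    }
  }
  inv
}

#' @export
print.ranking_table <- function(x, digits = 3, ...) {
  cat(sprintf("Repeated-holdout ranking table (%d runs, %d methods)\n",
              x$n_runs, length(x$methods)))
  cat("\nMean metric values:\n")
  print(round(x$mean_values, digits))
  cat("\nRankings (best first):\n")
  ord <- do.call(cbind, x$orderings)
  rownames(ord) <- paste0(seq_len(nrow(ord)),
                          c("st", "nd", "rd", rep("th", 97))[seq_len(nrow(ord))])
  print(ord, quote = FALSE)
  invisible(x)
}

#' @export
summary.ranking_table <- function(object, ...) {
  agr <- ranking_agreement(object)
  cat(sprintf("Ranking table over %d runs\n", object$n_runs))
  n_distinct <- length(unique(lapply(object$orderings, paste, collapse = ">")))
  cat(sprintf("Distinct rankings across %d metrics: %d\n",
              length(object$orderings), n_distinct))
  cat("\nPairwise agreement:\n")
  print(agr, row.names = FALSE)
  invisible(agr)
}

#' Write a ranking table (means + rankings) and its sd companion as CSV
#'
#' The main file mirrors the published table layout: one row per method
#' with the six rates as columns, followed by a rankings block (one row
#' per rank position). The companion file carries the per-metric standard
#' deviations over runs.
#'
#' @param table a \code{"ranking_table"}.
#' @param path output CSV path for the means + rankings.
#' @param sd_path optional output path for the standard deviations
#'   (default: \code{path} with an \code{_sd} suffix).
#' @return \code{path}, invisibly.
#' @export
write_ranking_table <- function(table, path, sd_path = NULL) {
  stopifnot(inherits(table, "ranking_table"))
  if (is.null(sd_path))
    sd_path <- sub("(\\.csv)?$", "_sd\\1", path)
  means <- data.frame(method = rownames(table$mean_values),
                      table$mean_values, row.names = NULL,
                      stringsAsFactors = FALSE)
  ranks <- as.data.frame(do.call(cbind, table$orderings),
                         stringsAsFactors = FALSE)
  ranks <- cbind(method = paste0("rank_", seq_len(nrow(ranks))), ranks)
  write_metric_table(rbind(means, ranks), path)
  sds <- data.frame(method = rownames(table$sd_values), table$sd_values,
                    row.names = NULL, stringsAsFactors = FALSE)
  write_metric_table(sds, sd_path)
  invisible(path)
}
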