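# Synthetic EHR-like regression datasets with an ordinal numeric target.
#
# These stand in for the two public clinical tables the evaluation
# pipeline is modelled on: a hepatitis-C staging cohort (615 records,
# 4 ordered diagnosis levels, heavy class imbalance, some missing
# entries) and an obesity-level cohort (2111 records, 7 roughly balanced
# levels). The generator reproduces their target structure — level codes
# and per-level counts — while the features are class-conditional
# Gaussians whose only job is to give regressors a learnable, tunably
# noisy signal.

#' Configuration for a synthetic ordinal-target regression dataset
#'
#' @param n_samples number of rows to generate.
#' @param class_proportions positive weights, one per target level,
#'   summing to 1 (within 1e-9); rescaled counts are apportioned with the
#'   largest-remainder rule so realized counts are deterministic.
#' @param target_levels numeric codes of the ordered levels (e.g.
#'   \code{0:3} or \code{1:7}), same length as \code{class_proportions}.
#' @param n_features number of numeric feature columns.
#' @param class_separation distance between consecutive class-conditional
#'   feature means, in units of the (unit) feature standard deviation.
#'   0 means the features carry no signal about the target.
#' @param missing_rate probability in [0, 1) that a feature cell is
#'   masked as missing; the target is never masked.
#' @param seed integer seed; generation is a pure function of
#'   (config, seed).
#' @return An object of class \code{"scenario_config"}.
#' @seealso \code{\link{scenario_preset}} for ready-made configurations.
#' @export
scenario_config <- function(n_samples, class_proportions, target_levels,
                            n_features = 10L, class_separation = 1,
                            missing_rate = 0, seed = 1L) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L)
    domain_error("n_samples must be a positive integer")
  if (length(class_proportions) != length(target_levels))
    domain_error("class_proportions and target_levels lengths differ")
  if (any(class_proportions <= 0))
    domain_error("class_proportions must all be positive")
  if (abs(sum(class_proportions) - 1) > 1e-9)
    domain_error("class_proportions must sum to 1 (got %.12g)",
                 sum(class_proportions))
  if (missing_rate < 0 || missing_rate >= 1)
    domain_error("missing_rate must lie in [0, 1)")
  if (n_features < 1L)
    domain_error("n_features must be a positive integer")
  if (class_separation < 0)
    domain_error("class_separation must be non-negative")
  structure(list(
    n_samples = n_samples,
    class_proportions = as.numeric(class_proportions),
    target_levels = as.numeric(target_levels),
    n_features = as.integer(n_features),
    class_separation = as.numeric(class_separation),
    missing_rate = as.numeric(missing_rate),
    seed = as.integer(seed)
  ), class = "scenario_config")
}

#' Ready-made scenario configurations
#'
#' \code{"hepatitis-like"} mirrors the structure of a 615-record
#' hepatitis-C staging cohort: 4 ordinal levels coded 0..3 with counts
#' 540/24/21/30 (healthy controls vastly over-represented), 12 numeric
#' features, and a small amount of missingness. \code{"obesity-like"}
#' mirrors a 2111-record obesity cohort: 7 roughly balanced levels coded
#' 1..7 with counts 272/287/351/297/324/290/290, 16 features, no
#' missingness.
#'
#' @param name preset name.
#' @param seed integer seed stored in the config.
#' @param class_separation signal strength (see
#'   \code{\link{scenario_config}}); default 1.
#' @return A \code{"scenario_config"}.
#' @export
scenario_preset <- function(name = c("hepatitis-like", "obesity-like"),
                            seed = 1L, class_separation = 1) {
  name <- match.arg(name)
  switch(name,
    "hepatitis-like" = scenario_config(
      n_samples = 615L,
      class_proportions = c(540, 24, 21, 30) / 615,
      target_levels = 0:3,
      n_features = 12L,
      class_separation = class_separation,
      missing_rate = 0.01,
      seed = seed),
    "obesity-like" = scenario_config(
      n_samples = 2111L,
      class_proportions = c(272, 287, 351, 297, 324, 290, 290) / 2111,
      target_levels = 1:7,
      n_features = 16L,
      class_separation = class_separation,
      missing_rate = 0,
      seed = seed))
}

# Largest-remainder apportionment of n into integer counts proportional
# to p; ties on the fractional remainder go to the lower level index.
apportion_counts <- function(n, p) {
  raw <- n * p
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- raw - counts
    take <- order(frac, seq_along(frac), decreasing = c(TRUE, FALSE),
                  method = "radix")[seq_len(rem)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}

#' Generate a synthetic scenario dataset
#'
#' Per-level sample counts are fixed by largest-remainder apportionment
#' of \code{n_samples * class_proportions}, so the realized class balance
#' matches the preset exactly. Features are drawn class-conditionally
#' Gaussian: a sample at level index \eqn{k} (0-based) has every feature
#' distributed \eqn{N(k \cdot separation, 1)}. If the config requests
#' missingness it is injected with \code{\link{inject_missingness}}.
#'
#' @param config a \code{\link{scenario_config}}.
#' @return An object of class \code{"scenario_dataset"}: a list with a
#'   numeric \code{features} matrix (may contain \code{NA}), a numeric
#'   \code{target} vector, and the generating \code{config}.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  counts <- apportion_counts(config$n_samples, config$class_proportions)
  level_idx <- rep(seq_along(config$target_levels) - 1L, counts)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  mu <- level_idx * config$class_separation
  features <- matrix(
    stats::rnorm(config$n_samples * config$n_features,
                 mean = rep(mu, times = config$n_features), sd = 1),
    nrow = config$n_samples, ncol = config$n_features,
    dimnames = list(NULL, paste0("f", seq_len(config$n_features))))
  ds <- structure(list(
    features = features,
    target = config$target_levels[level_idx + 1L],
    config = config
  ), class = "scenario_dataset")
  if (config$missing_rate > 0)
    ds <- inject_missingness(ds, config$missing_rate,
                             seed = config$seed + 1L)
  ds
}

#' @export
print.scenario_dataset <- function(x, ...) {
  cat(sprintf("Synthetic scenario dataset: %d samples x %d features\n",
              nrow(x$features), ncol(x$features)))
  cat("Target level counts:\n")
  print(table(x$target))
  n_miss <- sum(is.na(x$features))
  if (n_miss > 0)
    cat(sprintf("%d missing feature cells (%.2f%%)\n", n_miss,
                100 * n_miss / length(x$features)))
  invisible(x)
}

#' Mask feature cells at random
#'
#' Each feature cell is independently replaced by \code{NA} with the
#' given probability; the target column is never masked.
#'
#' @param ds a \code{"scenario_dataset"}.
#' @param rate masking probability in [0, 1).
#' @param seed integer seed.
#' @return The dataset with masked cells.
#' @export
inject_missingness <- function(ds, rate, seed = 1L) {
  stopifnot(inherits(ds, "scenario_dataset"))
  if (rate < 0 || rate >= 1)
    domain_error("missingness rate must lie in [0, 1)")
  if (rate == 0) return(ds)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  mask <- stats::runif(length(ds$features)) < rate
  ds$features[mask] <- NA_real_
  ds
}

#' Column-mean imputation
#'
#' Replaces each missing feature cell with the mean of the observed
#' values in its column. This is a deliberately simple, deterministic
#' imputation — not predictive mean matching or any multiple-imputation
#' scheme — sufficient for the evaluation pipeline, whose subject is the
#' metrics rather than the imputation model.
#'
#' @param ds a \code{"scenario_dataset"} possibly containing \code{NA}s.
#' @return The dataset with no missing feature cells.
#' @export
impute_simple <- function(ds) {
  stopifnot(inherits(ds, "scenario_dataset"))
  for (j in seq_len(ncol(ds$features))) {
    col <- ds$features[, j]
    miss <- is.na(col)
    if (!any(miss)) next
    if (all(miss))
      domain_error("column %d is fully missing; cannot impute a mean", j)
    ds$features[miss, j] <- mean(col[!miss])
  }
  ds
}

#' Shuffle and split a dataset into train and test sets
#'
#' A uniform random row permutation under the seed; the first
#' \code{floor(n * train_fraction)} permuted rows form the training set
#' and the remainder the test set, so the two parts are an exact
#' partition of the rows.
#'
#' @param ds a \code{"scenario_dataset"}.
#' @param train_fraction fraction of rows for training, in (0, 1).
#' @param seed integer seed.
#' @return A list with \code{train} and \code{test} datasets.
#' @export
shuffle_split <- function(ds, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(ds, "scenario_dataset"))
  n <- nrow(ds$features)
  if (n < 2L)
    domain_error("need at least 2 rows to split, got %d", n)
  if (train_fraction <= 0 || train_fraction >= 1)
    domain_error("train_fraction must lie strictly between 0 and 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  n_train <- floor(n * train_fraction)
  if (n_train < 1L || n_train >= n)
    domain_error("train_fraction %.3f leaves an empty train or test set",
                 train_fraction)
  subset_ds <- function(idx) {
    structure(list(features = ds$features[idx, , drop = FALSE],
                   target = ds$target[idx],
                   config = ds$config),
              class = "scenario_dataset")
  }
  list(train = subset_ds(perm[seq_len(n_train)]),
       test = subset_ds(perm[(n_train + 1L):n]))
}

#' Write a scenario dataset as CSV
#'
#' Feature columns first, target last; missing cells are written as empty
#' fields.
#'
#' @param ds a \code{"scenario_dataset"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_scenario_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "scenario_dataset"))
  df <- as.data.frame(ds$features)
  df$target <- ds$target
  write_metric_table(df, path, na = "")
}

#' Read a scenario dataset from CSV
#'
#' @param path CSV path with feature columns and a \code{target} column;
#'   empty fields are treated as missing.
#' @return A \code{"scenario_dataset"} (with a \code{NULL} config).
#' @export
read_scenario_dataset <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8",
                        na.strings = c("", "NA"))
  if (!"target" %in% names(df))
    domain_error("'%s' must contain a 'target' column", path)
  target <- df$target
  if (any(is.na(target)))
    domain_error("target column must not contain missing values")
  features <- as.matrix(df[setdiff(names(df), "target")])
  structure(list(features = features, target = as.numeric(target),
                 config = NULL),
            class = "scenario_dataset")
}
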