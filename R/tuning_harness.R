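#' The six-hyperparameter search space of the boosted-tree regressor
#'
#' The tuned hyperparameters, in order, with their box bounds: learning
#' rate `eta` \[0.1, 0.9\] (continuous), `min_child_weight` \[1, 10\]
#' (continuous), `subsample` \[0.01, 1\] (continuous), `colsample_bytree`
#' \[0.01, 1\] (continuous), `max_depth` \[3, 10\] (integer), and the
#' split-loss regularizer `gamma` \[0, 0.8\] (continuous — this is the
#' booster's gamma, unrelated to the firefly absorption coefficient).
#' Solution vectors therefore have length six.
#'
#' @return A [search_space()] with six named dimensions.
#' @export
default_search_space <- function() {
  search_space(
    lower = c(0.1, 1, 0.01, 0.01, 3, 0),
    upper = c(0.9, 10, 1, 1, 10, 0.8),
    kind = c("continuous", "continuous", "continuous", "continuous",
             "integer", "continuous"),
    names = c("eta", "min_child_weight", "subsample", "colsample_bytree",
              "max_depth", "gamma")
  )
}

#' Decode a position vector into a named hyperparameter configuration
#'
#' @param position Numeric vector, one component per space dimension, all
#'   within bounds (an out-of-bounds component signals a missing repair).
#' @param space The hyperparameter [search_space()]; defaults to
#'   [default_search_space()].
#' @return A one-row tibble with one named column per hyperparameter;
#'   integer dimensions rounded half-up.
#' @examples
#' decode_position(c(0.1, 1, 0.01, 0.01, 6.7, 0))
#' @export
decode_position <- function(position, space = default_search_space()) {
  if (length(position) != space_dim(space)) {
    rlang::abort("`position` length does not match the search space.")
  }
  int <- space$kind == "integer"
  position[int] <- round_half_up(position[int])
  if (any(position < space$lower - 1e-9) || any(position > space$upper + 1e-9)) {
    bad <- space$name[position < space$lower - 1e-9 | position > space$upper + 1e-9]
    rlang::abort(paste0("Out-of-bounds component(s): ",
                        paste(bad, collapse = ", "),
                        ". Positions must be repaired before decoding."))
  }
  out <- tibble::as_tibble(as.list(stats::setNames(position, space$name)))
  out
}

#' Encode a hyperparameter configuration back into a position vector
#'
#' Inverse of [decode_position()] (exact for integral depths).
#'
#' @param config One-row tibble or named list of hyperparameter values.
#' @param space The hyperparameter [search_space()].
#' @return Numeric position vector in space order.
#' @export
encode_config <- function(config, space = default_search_space()) {
  as.numeric(unlist(config[space$name]))
}

#' Build a tuning problem from a monitoring dataset
#'
#' Performs the seeded random train/test row split (default 70/30; the
#' training count is `floor(n * train_fraction)`) and freezes everything
#' the fitness function needs: feature matrices, targets, and the backend
#' settings. Feature columns are ordered by name so the fitness is
#' invariant to the column order of the input table. The same problem
#' object — hence the identical split — is shared by every optimizer in a
#' comparison.
#'
#' @param data A monitoring dataset (tibble with numeric feature columns
#'   and the target column).
#' @param train_fraction Fraction of rows used for training, in (0, 1).
#' @param seed Integer seed for the row split and for the backend's own
#'   randomness (subsampling), making fitness evaluation deterministic.
#' @param target Name of the target column.
#' @param nrounds Boosting rounds of the backend (a fixed backend setting,
#'   not a tuned hyperparameter).
#' @param fitness_on Partition on which the fitness MSE is computed
#'   (`"test"`, the default, or `"train"`).
#' @return A list of class `tuning_problem`.
#' @export
split_dataset <- function(data, train_fraction = 0.7, seed = 1,
                          target = "BaP", nrounds = 30,
                          fitness_on = c("test", "train")) {
  fitness_on <- match.arg(fitness_on)
  if (!target %in% names(data)) {
    rlang::abort(paste0("Target column '", target, "' not found."))
  }
  n <- nrow(data)
  if (n < 10) rlang::abort("Need at least 10 rows to split.")
  if (train_fraction <= 0 || train_fraction >= 1) {
    rlang::abort("`train_fraction` must lie strictly between 0 and 1.")
  }
  feature_names <- sort(setdiff(
    names(data)[vapply(data, is.numeric, logical(1))], target))
  if (length(feature_names) == 0) rlang::abort("No numeric feature columns.")
  n_train <- floor(n * train_fraction)
  train_idx <- withr::with_seed(seed, sample.int(n, n_train))
  x <- as.matrix(data[feature_names])
  y <- data[[target]]
  problem <- list(
    train_x = x[train_idx, , drop = FALSE],
    train_y = y[train_idx],
    test_x = x[-train_idx, , drop = FALSE],
    test_y = y[-train_idx],
    feature_names = feature_names,
    target = target,
    train_fraction = train_fraction,
    seed = seed,
    nrounds = nrounds,
    fitness_on = fitness_on
  )
  class(problem) <- "tuning_problem"
  problem
}

#' @export
print.tuning_problem <- function(x, ...) {
  cat("<tuning_problem> target '", x$target, "'\n", sep = "")
  cat("  train: ", nrow(x$train_x), " rows; test: ", nrow(x$test_x),
      " rows; features: ", length(x$feature_names), "\n", sep = "")
  cat("  backend: ", x$nrounds, " boosting rounds; fitness on ",
      x$fitness_on, " partition; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Train the boosted-tree regressor for one hyperparameter configuration
#'
#' Squared-error regression objective, single-threaded, with the backend
#' RNG seeded from the problem seed so training is reproducible; all other
#' backend settings are left at their defaults.
#'
#' @param config One-row tibble as from [decode_position()].
#' @param problem A [split_dataset()] problem.
#' @return A fitted `xgb.Booster`.
#' @export
fit_boosted_model <- function(config, problem) {
  dtrain <- xgboost::xgb.DMatrix(problem$train_x, label = problem$train_y,
                                 nthread = 1)
  params <- list(
    objective = "reg:squarederror",
    eta = config$eta,
    min_child_weight = config$min_child_weight,
    subsample = config$subsample,
    colsample_bytree = config$colsample_bytree,
    max_depth = as.integer(config$max_depth),
    gamma = config$gamma,
    nthread = 1
  )
  withr::with_seed(problem$seed,
    xgboost::xgb.train(params = params, data = dtrain,
                       nrounds = problem$nrounds, verbose = 0))
}

#' Fitness of a position: held-out mean squared error
#'
#' Decodes the position, trains the booster on the training partition, and
#' returns the MSE on the fitness partition (the test split by default).
#' Deterministic for a fixed problem. A backend failure yields `+Inf`
#' fitness with a warning instead of crashing the optimizer run.
#'
#' @param position Numeric vector of length six (repaired into bounds).
#' @param problem A [split_dataset()] problem.
#' @return Scalar fitness (MSE, target units squared).
#' @export
evaluate_fitness <- function(position, problem) {
  config <- decode_position(position, default_search_space())
  model <- tryCatch(fit_boosted_model(config, problem), error = function(e) e)
  if (inherits(model, "error")) {
    rlang::warn(paste0("Backend training failed (", conditionMessage(model),
                       "); recording +Inf fitness."))
    return(Inf)
  }
  if (problem$fitness_on == "train") {
    pred <- predict(model, problem$train_x)
    mean((pred - problem$train_y)^2)
  } else {
    pred <- predict(model, problem$test_x)
    mean((pred - problem$test_y)^2)
  }
}

#' Objective closure for the optimizers
#'
#' @param problem A [split_dataset()] problem.
#' @return A function `position -> fitness` suitable for [run_sca()],
#'   [run_fa()] and [run_hsa_sca()].
#' @export
tuning_objective <- function(problem) {
  force(problem)
  function(position) evaluate_fitness(position, problem)
}

#' Held-out metrics of one hyperparameter configuration
#'
#' Refits the booster for `config` and evaluates [compute_metrics()] on the
#' test partition. Because training is seeded from the problem, the `mse`
#' entry reproduces the fitness of the corresponding position exactly.
#'
#' @param config One-row tibble as from [decode_position()].
#' @param problem A [split_dataset()] problem.
#' @return A one-row metrics tibble (see [compute_metrics()]).
#' @export
config_metrics <- function(config, problem) {
  model <- fit_boosted_model(config, problem)
  compute_metrics(problem$test_y, predict(model, problem$test_x))
}
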