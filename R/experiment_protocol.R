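#' Multi-run optimizer comparison on one tuning problem
#'
#' Runs every named optimizer `n_runs` times on the *same* tuning problem
#' (identical train/test split for all algorithms), with run `k` of every
#' algorithm sharing the seed `base_seed + k` so runs are paired across
#' algorithms. Defaults follow the study protocol: 20 runs, population 40,
#' 20 iterations. For every run the best decoded configuration is refitted
#' and its full held-out metric set recorded.
#'
#' @param problem A [split_dataset()] problem.
#' @param algorithms Character vector of registered optimizer names (see
#'   [register_optimizer()]).
#' @param n_runs Independent runs per algorithm (>= 2).
#' @param population Population size per run.
#' @param iterations Iterations per run.
#' @param base_seed Base seed; run `k` uses `base_seed + k`.
#' @return A tibble of class `hsasca_experiment`, one row per algorithm x
#'   run: `algorithm`, `run`, `seed`, `best_fitness`, and list-columns
#'   `config` (one-row tibble), `metrics` (one-row tibble), `convergence`
#'   (numeric vector). The problem is attached as attribute `problem`.
#' @export
run_experiment <- function(problem,
                           algorithms = c("hsa-sca", "sca", "fa"),
                           n_runs = 20, population = 40, iterations = 20,
                           base_seed = 1) {
  stopifnot(inherits(problem, "tuning_problem"))
  if (n_runs < 2) rlang::abort("`n_runs` must be at least 2.")
  fns <- lapply(algorithms, get_optimizer) # fails fast on unknown names
  names(fns) <- algorithms
  objective <- tuning_objective(problem)
  space <- default_search_space()
  grid <- tidyr::expand_grid(algorithm = algorithms, run = seq_len(n_runs))
  records <- purrr::pmap(grid, function(algorithm, run) {
    seed <- base_seed + run
    res <- fns[[algorithm]](objective, space, population, iterations, seed)
    best_config <- decode_position(as.numeric(res$best_position), space)
    best_metrics <- config_metrics(best_config, problem)
    tibble::tibble(
      algorithm = algorithm, run = run, seed = seed,
      best_fitness = res$best_fitness,
      config = list(best_config),
      metrics = list(best_metrics),
      convergence = list(res$convergence)
    )
  })
  out <- dplyr::bind_rows(records)
  attr(out, "problem") <- problem
  class(out) <- c("hsasca_experiment", class(out))
  out
}

#' Per-algorithm summary of best-per-run fitness
#'
#' Best, worst, mean, median, standard deviation and variance of the
#' best-per-run fitness values, per algorithm. Std and var use the sample
#' (n - 1) convention; a single run yields 0 for both, with a warning.
#'
#' @param records An experiment tibble (see [run_experiment()]) or any
#'   tibble with `algorithm` and `best_fitness` columns.
#' @return A tibble with columns `algorithm`, `best`, `worst`, `mean`,
#'   `median`, `std`, `var`, ordered by increasing mean.
#' @export
summarize_experiment <- function(records) {
  if (nrow(records) == 0) rlang::abort("No run records to summarize.")
  if (any(table(records$algorithm) < 2)) {
    rlang::warn("Single-run algorithm(s): std/var reported as 0.")
  }
  records |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::summarise(
      best = min(.data$best_fitness),
      worst = max(.data$best_fitness),
      mean = mean(.data$best_fitness),
      median = stats::median(.data$best_fitness),
      std = ifelse(dplyr::n() > 1, stats::sd(.data$best_fitness), 0),
      var = ifelse(dplyr::n() > 1, stats::var(.data$best_fitness), 0),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$mean)
}

#' Levene homoscedasticity test across algorithm run distributions
#'
#' One pooled k-group Levene test (Brown-Forsythe median centring) on the
#' per-run fitness distributions; the prerequisite check before parametric
#' comparison of optimizers.
#'
#' @param data Tibble of per-run results.
#' @param values,groups Bare column names of the values and the grouping
#'   factor (defaults `best_fitness`, `algorithm`).
#' @param alpha Decision threshold reported alongside the p-value.
#' @return One-row tibble: `statistic`, `p_value`, `alpha`,
#'   `homoscedastic` (p > alpha).
#' @export
homoscedasticity_test <- function(data, values = best_fitness,
                                  groups = algorithm, alpha = 0.05) {
  y <- dplyr::pull(data, {{ values }})
  g <- factor(dplyr::pull(data, {{ groups }}))
  if (nlevels(g) < 2) rlang::abort("Need at least two groups.")
  if (any(table(g) < 3)) rlang::abort("Every group needs at least 3 values.")
  lev <- car::leveneTest(y, g, center = stats::median)
  tibble::tibble(
    statistic = lev[1, "F value"],
    p_value = lev[1, "Pr(>F)"],
    alpha = alpha,
    homoscedastic = lev[1, "Pr(>F)"] > alpha
  )
}

#' Shapiro-Wilk normality test of one run distribution
#'
#' @param x Numeric sample (3 to 5000 values).
#' @return One-row tibble: `statistic`, `p_value`, plus the decisions
#'   `normal_at_0.05` and `normal_at_0.1` (TRUE when the null of normality
#'   is not rejected at that threshold).
#' @export
normality_test <- function(x) {
  if (length(x) < 3 || length(x) > 5000) {
    rlang::abort("Shapiro-Wilk needs between 3 and 5000 values.")
  }
  sw <- stats::shapiro.test(x)
  tibble::tibble(
    statistic = unname(sw$statistic),
    p_value = sw$p.value,
    `normal_at_0.05` = sw$p.value > 0.05,
    `normal_at_0.1` = sw$p.value > 0.1
  )
}

#' Paired-t comparison of two algorithms' best-per-run fitness
#'
#' Runs are paired by index (shared seeds and shared data split). First the
#' normality prerequisite of the paired-t test is checked with a
#' Shapiro-Wilk test on the absolute per-pair differences; if it fails at
#' `alpha` a warning is issued, but both numbers are still reported. The
#' t-test itself uses the signed differences.
#'
#' @param proposed,contender Equal-length (>= 3) numeric vectors of
#'   best-per-run fitness, paired by run index.
#' @param alpha Threshold for the normality pre-check.
#' @return One-row tibble: `shapiro_p` (on absolute differences),
#'   `t_statistic`, `t_p_value`, `mean_difference` (proposed - contender),
#'   `n`, `normality_ok`.
#' @export
paired_t_compare <- function(proposed, contender, alpha = 0.05) {
  if (length(proposed) != length(contender)) {
    rlang::abort("Paired samples must have equal length.")
  }
  if (length(proposed) < 3) rlang::abort("Need at least 3 paired runs.")
  d <- proposed - contender
  if (stats::sd(d) == 0) {
    rlang::abort(paste(
      "Zero-variance paired differences: the paired-t p-value is",
      "undefined (identical run results)."))
  }
  sw <- stats::shapiro.test(abs(d))
  ok <- sw$p.value > alpha
  if (!ok) {
    rlang::warn(paste0(
      "Normality of the paired differences is rejected (Shapiro-Wilk p = ",
      format(sw$p.value, digits = 3),
      "); the paired-t p-value may be unreliable."))
  }
  tt <- stats::t.test(proposed, contender, paired = TRUE)
  tibble::tibble(
    shapiro_p = sw$p.value,
    t_statistic = unname(tt$statistic),
    t_p_value = tt$p.value,
    mean_difference = mean(d),
    n = length(d),
    normality_ok = ok
  )
}

#' Full statistical-validation chain of an experiment
#'
#' Levene homoscedasticity across all algorithms, Shapiro-Wilk normality
#' per algorithm, and, for every contender, the Shapiro-Wilk pre-check on
#' absolute paired differences against the proposed algorithm followed by
#' the paired-t test.
#'
#' @param records An experiment tibble (see [run_experiment()]).
#' @param proposed Name of the algorithm the contenders are tested against.
#' @param alpha Decision threshold.
#' @return A list of class `stat_report`: `levene` (one-row tibble),
#'   `shapiro` (per-algorithm tibble), `paired` (per-contender tibble),
#'   `alpha`.
#' @export
stat_report <- function(records, proposed = "hsa-sca", alpha = 0.05) {
  algs <- unique(records$algorithm)
  if (!proposed %in% algs) {
    rlang::abort(paste0("Proposed algorithm '", proposed,
                        "' not present in the records."))
  }
  per_alg <- split(records, records$algorithm)
  bests <- lapply(per_alg, function(d) d$best_fitness[order(d$run)])
  shapiro <- purrr::map_dfr(algs, function(a) {
    dplyr::bind_cols(tibble::tibble(algorithm = a), normality_test(bests[[a]]))
  })
  paired <- purrr::map_dfr(setdiff(algs, proposed), function(a) {
    dplyr::bind_cols(tibble::tibble(contender = a),
                     paired_t_compare(bests[[proposed]], bests[[a]],
                                      alpha = alpha))
  })
  structure(list(
    levene = homoscedasticity_test(records, alpha = alpha),
    shapiro = shapiro,
    paired = paired,
    proposed = proposed,
    alpha = alpha
  ), class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat("<stat_report> proposed: ", x$proposed, " (alpha = ", x$alpha, ")\n",
      sep = "")
  cat("Levene p = ", format(x$levene$p_value, digits = 4), "\n", sep = "")
  cat("Shapiro-Wilk per algorithm:\n")
  print(x$shapiro)
  if (nrow(x$paired) > 0) {
    cat("Paired-t vs contenders:\n")
    print(x$paired)
  }
  invisible(x)
}

#' Export the comparison tables of an experiment
#'
#' Writes the study-style result files into `dir`: `summary.csv` (statistic
#' rows Best/Worst/Mean/Median/Std/Var, one column per algorithm) plus its
#' `summary.json` round-trip twin, `metrics.csv` (best-run held-out metrics
#' per algorithm, columns r2, r, mae, mse, rmse, ia), `hyperparams.csv`
#' (best-run decoded configurations), `stats.json` (the [stat_report()]),
#' and one `convergence/<algorithm>.csv` per algorithm with the per-run
#' convergence series.
#'
#' @param records An experiment tibble (see [run_experiment()]).
#' @param dir Output directory (created if needed).
#' @param stats A [stat_report()], or `NULL` to compute it when possible;
#'   if unavailable the stats file is omitted with a notice.
#' @param proposed Proposed algorithm for the default stats report.
#' @return Invisibly, the vector of files written.
#' @export
export_tables <- function(records, dir, stats = NULL, proposed = "hsa-sca") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "convergence"), showWarnings = FALSE)
  written <- character(0)

  summ <- summarize_experiment(records)
  wide <- tibble::tibble(statistic = c("Best", "Worst", "Mean", "Median",
                                       "Std", "Var"))
  for (a in summ$algorithm) {
    row <- summ[summ$algorithm == a, ]
    wide[[a]] <- c(row$best, row$worst, row$mean, row$median, row$std, row$var)
  }
  f <- file.path(dir, "summary.csv")
  readr::write_csv(wide, f); written <- c(written, f)
  f <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, f, digits = NA); written <- c(written, f)

  best_rows <- records |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::slice_min(.data$best_fitness, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  metrics <- dplyr::bind_cols(
    best_rows["algorithm"],
    dplyr::bind_rows(best_rows$metrics)
  )[, c("algorithm", "r2", "r", "mae", "mse", "rmse", "ia")]
  f <- file.path(dir, "metrics.csv")
  readr::write_csv(metrics, f); written <- c(written, f)

  configs <- dplyr::bind_cols(best_rows["algorithm"],
                              dplyr::bind_rows(best_rows$config))
  f <- file.path(dir, "hyperparams.csv")
  readr::write_csv(configs, f); written <- c(written, f)

  if (is.null(stats)) {
    n_runs <- min(table(records$algorithm))
    if (length(unique(records$algorithm)) >= 2 && n_runs >= 3 &&
        proposed %in% records$algorithm) {
      stats <- tryCatch(stat_report(records, proposed = proposed),
                        error = function(e) {
                          rlang::inform(paste0(
                            "Statistical report unavailable (",
                            conditionMessage(e), ")."))
                          NULL
                        })
    }
  }
  if (is.null(stats)) {
    rlang::inform("No statistical report available; stats.json omitted.")
  } else {
    f <- file.path(dir, "stats.json")
    jsonlite::write_json(
      list(levene = stats$levene, shapiro = stats$shapiro,
           paired = stats$paired, proposed = stats$proposed,
           alpha = stats$alpha),
      f, digits = NA, auto_unbox = TRUE)
    written <- c(written, f)
  }

  for (a in unique(records$algorithm)) {
    sub <- records[records$algorithm == a, ]
    conv <- purrr::map_dfr(seq_len(nrow(sub)), function(i) {
      tibble::tibble(run = sub$run[i],
                     iteration = seq_along(sub$convergence[[i]]),
                     best_fitness = sub$convergence[[i]])
    })
    f <- file.path(dir, "convergence", paste0(gsub("[^a-z0-9]+", "_", a), ".csv"))
    readr::write_csv(conv, f); written <- c(written, f)
  }
  invisible(written)
}
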