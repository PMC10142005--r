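test_that("the multi-run protocol keeps books and pairs runs across algorithms", {
  pr <- tiny_problem(seed = 23)
  rec <- run_experiment(pr, algorithms = c("hsa-sca", "sca"),
                        n_runs = 3, population = 4, iterations = 4,
                        base_seed = 100)
  expect_equal(nrow(rec), 6)
  expect_true(all(lengths(rec$convergence) == 4))
  expect_equal(rec$seed, c(101, 102, 103, 101, 102, 103))
  # run k of both algorithms shares seed and (by construction) the split
  expect_identical(attr(rec, "problem"), pr)
  # best fitness equals the refit metric-set MSE
  for (i in seq_len(nrow(rec))) {
    expect_equal(rec$best_fitness[i], rec$metrics[[i]]$mse)
  }
  expect_error(run_experiment(pr, algorithms = "pso", n_runs = 2,
                              population = 4, iterations = 2),
               "Unknown optimizer")
})

test_that("a repeated base seed reproduces the experiment byte-identically", {
  pr <- tiny_problem(seed = 29)
  a <- run_experiment(pr, algorithms = c("sca", "fa"), n_runs = 2,
                      population = 4, iterations = 3, base_seed = 7)
  b <- run_experiment(pr, algorithms = c("sca", "fa"), n_runs = 2,
                      population = 4, iterations = 3, base_seed = 7)
  expect_identical(a$best_fitness, b$best_fitness)
  expect_identical(a$convergence, b$convergence)
  expect_identical(a$config, b$config)
})

test_that("the summary computes the six per-algorithm statistics", {
  rec <- tibble::tibble(algorithm = "x", run = 1:3, best_fitness = c(2, 2, 2))
  s <- summarize_experiment(rec)
  expect_equal(unlist(s[c("best", "worst", "mean", "median")]),
               c(best = 2, worst = 2, mean = 2, median = 2))
  expect_equal(s$std, 0)
  expect_equal(s$var, 0)

  rec2 <- tibble::tibble(algorithm = "y", run = 1:4,
                         best_fitness = c(1, 2, 3, 4))
  s2 <- summarize_experiment(rec2)
  expect_equal(s2$mean, 2.5)
  expect_equal(s2$median, 2.5)
  expect_equal(s2$var, 5 / 3) # sample (n - 1) convention
  expect_equal(s2$std, sqrt(5 / 3))

  single <- tibble::tibble(algorithm = "z", run = 1, best_fitness = 3)
  expect_warning(s3 <- summarize_experiment(single), "Single-run")
  expect_equal(s3$std, 0)
  expect_error(summarize_experiment(single[0, ]), "No run records")
})

test_that("the summary ordering never drifts from the per-run means", {
  set.seed(61)
  rec <- tibble::tibble(
    algorithm = rep(c("a", "b", "c"), each = 8),
    run = rep(1:8, 3),
    best_fitness = c(rnorm(8, 3), rnorm(8, 2), rnorm(8, 4))
  )
  s <- summarize_experiment(rec)
  expect_equal(s$algorithm[which.min(s$mean)], s$algorithm[1])
  agg <- tapply(rec$best_fitness, rec$algorithm, mean)
  expect_equal(s$algorithm[1], names(which.min(agg)))
})

test_that("Levene test matches an independent reference and flags variance gaps", {
  # reference values computed with scipy.stats.levene(center='median')
  a <- c(2.1, 2.5, 1.9, 2.3, 2.8, 2.2, 2.6, 2.0)
  b <- c(3.1, 2.4, 3.8, 2.9, 4.2, 3.3, 2.7, 3.6)
  dat <- tibble::tibble(algorithm = rep(c("a", "b"), each = 8),
                        best_fitness = c(a, b))
  res <- homoscedasticity_test(dat)
  expect_equal(res$statistic, 3.098360655737705, tolerance = 1e-10)
  expect_equal(res$p_value, 0.1001912779219642, tolerance = 1e-10)

  same <- tibble::tibble(algorithm = rep(c("a", "b"), each = 5),
                         best_fitness = rep(c(1, 2, 3, 4, 5), 2))
  expect_gt(homoscedasticity_test(same)$p_value, 0.9)

  # 10x variance ratio, n = 20 each: detected in most seeded draws
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    d <- tibble::tibble(
      algorithm = rep(c("a", "b"), each = 20),
      best_fitness = c(rnorm(20, sd = 1), rnorm(20, sd = sqrt(10))))
    hits <- hits + (homoscedasticity_test(d)$p_value < 0.05)
  }
  expect_gte(hits, 7)

  one <- tibble::tibble(algorithm = "a", best_fitness = rnorm(5))
  expect_error(homoscedasticity_test(one), "two groups")
  expect_error(
    homoscedasticity_test(tibble::tibble(algorithm = c("a", "a", "a", "b", "b"),
                                         best_fitness = rnorm(5))),
    "at least 3")
})

test_that("Shapiro-Wilk separates normal from heavy-tailed samples", {
  expect_error(normality_test(c(1, 2)), "between 3 and 5000")
  normal_pass <- 0
  heavy_reject <- 0
  for (s in 1:200) {
    set.seed(s)
    normal_pass <- normal_pass + (normality_test(rnorm(20))$p_value > 0.05)
    heavy_reject <- heavy_reject +
      (normality_test(exp(rnorm(20, sd = 1.5)))$p_value < 0.05)
  }
  expect_gte(normal_pass, 180) # >= 90% of seeds
  expect_gt(heavy_reject, 100) # majority of seeds
})

test_that("paired-t comparison matches the reference and guards degeneracy", {
  a <- c(2.1, 2.5, 1.9, 2.3, 2.8, 2.2, 2.6, 2.0)
  b <- c(3.1, 2.4, 3.8, 2.9, 4.2, 3.3, 2.7, 3.6)
  res <- paired_t_compare(a, b)
  # reference values from scipy.stats.ttest_rel / scipy.stats.shapiro(|a-b|)
  expect_equal(res$t_statistic, -3.8, tolerance = 1e-10)
  expect_equal(res$t_p_value, 0.006714783958738417, tolerance = 1e-10)
  expect_equal(res$shapiro_p, 0.5910043919960738, tolerance = 1e-6)

  expect_error(paired_t_compare(a, a), "Zero-variance")
  expect_error(paired_t_compare(a, b[1:4]), "equal length")

  set.seed(77)
  strong <- rnorm(20, 0, 0.3)
  weak <- strong + rnorm(20, 0.7, 0.1) # clear one-directional shift
  expect_lt(suppressWarnings(paired_t_compare(weak, strong)$t_p_value), 0.05)
})

test_that("the full statistical report covers every contender", {
  set.seed(19)
  rec <- tibble::tibble(
    algorithm = rep(c("hsa-sca", "sca", "fa"), each = 10),
    run = rep(1:10, 3),
    best_fitness = c(rnorm(10, 2, 0.3), rnorm(10, 2.6, 0.3),
                     rnorm(10, 2.4, 0.3))
  )
  rep_ <- suppressWarnings(stat_report(rec))
  expect_s3_class(rep_, "stat_report")
  expect_equal(nrow(rep_$shapiro), 3)
  expect_setequal(rep_$paired$contender, c("sca", "fa"))
  expect_true(all(rep_$paired$t_p_value >= 0 & rep_$paired$t_p_value <= 1))
  expect_error(stat_report(rec, proposed = "pso"), "not present")
})

test_that("exported tables round-trip and follow the fixed layouts", {
  pr <- tiny_problem(seed = 37)
  rec <- run_experiment(pr, algorithms = c("hsa-sca", "sca", "fa"),
                        n_runs = 3, population = 4, iterations = 3,
                        base_seed = 50)
  dir <- withr::local_tempdir()
  files <- suppressWarnings(export_tables(rec, dir))
  expect_true(file.exists(file.path(dir, "summary.csv")))
  wide <- readr::read_csv(file.path(dir, "summary.csv"),
                          show_col_types = FALSE)
  expect_equal(names(wide), c("statistic", summarize_experiment(rec)$algorithm))
  expect_equal(wide$statistic, c("Best", "Worst", "Mean", "Median", "Std", "Var"))

  summ_back <- jsonlite::fromJSON(file.path(dir, "summary.json"))
  expect_equal(tibble::as_tibble(summ_back), summarize_experiment(rec),
               tolerance = 1e-12)

  metrics <- readr::read_csv(file.path(dir, "metrics.csv"),
                             show_col_types = FALSE)
  expect_equal(names(metrics), c("algorithm", "r2", "r", "mae", "mse",
                                 "rmse", "ia"))
  expect_true(file.exists(file.path(dir, "hyperparams.csv")))
  expect_true(file.exists(file.path(dir, "stats.json")))
  expect_true(file.exists(file.path(dir, "convergence", "hsa_sca.csv")))

  # stats omitted (with a notice) when the report cannot be computed
  dir2 <- withr::local_tempdir()
  two_runs <- rec[rec$run <= 2, ]
  expect_message(export_tables(two_runs, dir2), "omitted")
  expect_false(file.exists(file.path(dir2, "stats.json")))
})
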