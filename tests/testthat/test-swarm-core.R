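test_that("population initialization respects bounds and needs n >= 2", {
  sp <- search_space(rep(0, 3), rep(1, 3))
  set.seed(1)
  pop <- init_population(sp, 5, sphere)
  expect_equal(nrow(pop$positions), 5)
  expect_true(all(pop$positions >= 0 & pop$positions <= 1))
  expect_equal(pop$destination$fitness, min(pop$fitness))
  expect_equal(pop$evaluations, 5L)
  expect_error(init_population(sp, 1), ">= 2")
})

test_that("same seed reproduces the initial population bit-identically", {
  sp <- sphere_space(4)
  set.seed(99); a <- init_population(sp, 6, sphere)
  set.seed(99); b <- init_population(sp, 6, sphere)
  expect_identical(a$positions, b$positions)
  expect_identical(a$fitness, b$fitness)
})

test_that("sine-cosine step follows the update equation", {
  sp <- sphere_space(1, r = 10)
  # r1 = 0 collapses both branches to the current position
  expect_equal(sca_step(2, 5, sp, sca_control(r1 = 0)), 2)
  # x = destination and r3 = 1: |r3 * p - x| = 0
  expect_equal(sca_step(3, 3, sp, sca_control(r3 = 1)), 3)
  # independent scalar evaluation: x + 1 * sin(pi/2) * |1*3 - 1| = 3
  got <- sca_step(1, 3, sp,
                  sca_control(r1 = 1, r2 = pi / 2, r3 = 1, r4 = 0.3))
  expect_equal(got, 3.0)
  # cosine branch at r4 >= 0.5: x + 1 * cos(0) * |3 - 1| = 3
  expect_equal(sca_step(1, 3, sp,
                        sca_control(r1 = 1, r2 = 0, r3 = 1, r4 = 0.7)), 3.0)
})

test_that("firefly step follows the attraction equation", {
  sp <- sphere_space(1, r = 10)
  # attractor at self with no randomization: stationary
  expect_equal(fa_step(2, 2, sp, fa_control(alpha0 = 0)), 2)
  # beta0 = 1, gamma = 0, alpha = 0: full jump onto the attractor
  expect_equal(fa_step(0, 1, sp, fa_control(gamma = 0, alpha0 = 0)), 1.0)
  # huge absorption kills the attraction term
  expect_equal(fa_step(0, 4, sp, fa_control(gamma = 1e8, alpha0 = 0)), 0,
               tolerance = 1e-12)
})

test_that("search-mode decay follows the one-tenth rule", {
  expect_equal(decay_sm(0.8), 0.72)
  expect_equal(decay_sm(0), 0)
  sm <- 0.8
  for (k in 1:16) sm <- decay_sm(sm)
  expect_equal(sm, 0.14824161510814735, tolerance = 1e-12)
})

test_that("all three optimizers improve on the sphere and are seed-deterministic", {
  runs <- list(
    sca = function(seed) run_sca(sphere, sphere_space(5), 20, 100, seed),
    fa = function(seed) run_fa(sphere, sphere_space(2), 15, 50, seed),
    hsa = function(seed) run_hsa_sca(sphere, sphere_space(5), 20, 50, seed)
  )
  for (nm in names(runs)) {
    a <- runs[[nm]](7)
    b <- runs[[nm]](7)
    expect_identical(a, b)
    expect_lt(a$best_fitness, a$convergence[1])
    expect_true(all(diff(a$convergence) <= 0)) # elitist, monotone
    expect_equal(a$best_fitness, a$convergence[length(a$convergence)])
  }
})

test_that("a single iteration returns the elitist best after one sweep", {
  res <- run_sca(sphere, sphere_space(3), 10, 1, seed = 5)
  expect_length(res$convergence, 1)
  expect_equal(res$best_fitness, res$convergence[1])
  expect_equal(res$evaluations, 10L * 2L)
})

test_that("a coincident firefly swarm with no randomization is stationary", {
  sp <- sphere_space(2)
  ctl <- fa_control(alpha0 = 0)
  # with alpha = 0 and all solutions at the optimum, no move is possible
  expect_equal(fa_step(c(0, 0), c(0, 0), sp, ctl), c(0, 0))
  res <- run_fa(sphere, sp, 5, 3, seed = 3, fa_ctl = ctl)
  expect_true(all(diff(res$convergence) <= 0))
})

test_that("hybrid with the hybrid phase disabled reproduces pure SCA", {
  sp <- sphere_space(5)
  base <- run_sca(sphere, sp, 12, 30, seed = 21)
  off_vs <- run_hsa_sca(sphere, sp, 12, 30, seed = 21,
                        hybrid = hybrid_control(vs = 30))
  off_sm <- run_hsa_sca(sphere, sp, 12, 30, seed = 21,
                        hybrid = hybrid_control(sm0 = 1, decay = FALSE))
  expect_identical(base$convergence, off_vs$convergence)
  expect_identical(base$best_position, off_vs$best_position)
  expect_identical(base$convergence, off_sm$convergence)
  expect_identical(base$best_position, off_sm$best_position)
})

test_that("sm decays geometrically once the hybrid phase starts", {
  res <- run_hsa_sca(sphere, sphere_space(3), 8, 20, seed = 2,
                     hybrid = hybrid_control(vs = 5, sm0 = 0.8))
  # one decay per completed hybrid iteration: sm at iteration t (0-based)
  # is 0.8 * 0.9^k with k hybrid iterations already behind it
  expect_equal(res$sm_trace, 0.8 * 0.9^pmax(0, (0:19) - 5), tolerance = 1e-12)
})

test_that("hybrid matches or beats pure SCA on the sphere (paired seeds)", {
  sp <- sphere_space(10)
  seeds <- 1:10
  hsa <- vapply(seeds, function(s)
    run_hsa_sca(sphere, sp, 40, 20, s)$best_fitness, numeric(1))
  sca <- vapply(seeds, function(s)
    run_sca(sphere, sp, 40, 20, s)$best_fitness, numeric(1))
  expect_lte(mean(hsa), mean(sca))
})

test_that("optimizers beat random search at equal budget on the 2-D sphere", {
  sp <- sphere_space(2)
  n <- 10; iters <- 20; budget <- n * (iters + 1)
  seeds <- 1:20
  rs <- function(seed, m) {
    set.seed(seed)
    min(replicate(m, sphere(runif(2, -5, 5))))
  }
  for (runner in list(run_sca, run_fa, run_hsa_sca)) {
    opt <- vapply(seeds, function(s)
      runner(sphere, sp, n, iters, s)$best_fitness, numeric(1))
    equal_budget <- vapply(seeds, function(s) rs(s + 1000, budget), numeric(1))
    rich_budget <- vapply(seeds, function(s) rs(s + 2000, 10 * budget),
                          numeric(1))
    expect_lt(mean(opt), mean(equal_budget))
    d <- opt - rich_budget
    expect_lte(mean(d), 2 * sd(d) / sqrt(length(d))) # within sampling noise
  }
})

test_that("non-finite objective values are flagged and treated as worst", {
  bad <- function(x) if (x[1] > 0) NaN else sum(x^2)
  w <- capture_warnings(res <- run_sca(bad, sphere_space(1), 6, 5, seed = 4))
  expect_true(any(grepl("non-finite", w)))
  expect_true(is.finite(res$best_fitness))
  expect_lte(res$best_position[[1]], 0)
})

test_that("optimizer registry resolves built-ins and rejects unknown names", {
  expect_true(all(c("sca", "fa", "hsa-sca") %in% optimizer_names()))
  expect_error(get_optimizer("pso"), "Unknown optimizer")
  register_optimizer("null-search", function(objective, space, n, max_iter, seed, ...) {
    run_sca(objective, space, n, max_iter, seed, ...)
  })
  expect_true("null-search" %in% optimizer_names())
})

test_that("tidy and glance summarize a swarm result", {
  res <- run_sca(sphere, sphere_space(2), 8, 10, seed = 1)
  td <- tidy(res)
  expect_equal(nrow(td), 10)
  expect_equal(td$best_fitness, res$convergence)
  gl <- glance(res)
  expect_equal(gl$best_fitness, res$best_fitness)
  expect_equal(gl$evaluations, res$evaluations)
})
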