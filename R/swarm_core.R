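#' Control parameters for the sine cosine search
#'
#' The sine-cosine update is steered by four per-component parameters:
#' `r1` shrinks linearly over the run from `a` towards zero and balances
#' exploration against exploitation, `r2 ~ U(0, 2*pi)` sets the phase,
#' `r3 ~ U(0, 2)` scales the destination, and `r4 ~ U(0, 1)` picks the sine
#' or cosine branch. Fresh values of `r2`-`r4` are drawn for every component
#' of every solution. For testing, any of the four can be pinned to a fixed
#' value, which suppresses its random draw.
#'
#' @param a Positive amplitude constant of the `r1` schedule
#'   `r1 = a - t * a / max_iter` (default 2, the original SCA setting).
#' @param r1,r2,r3,r4 Optional fixed values overriding the schedule/draws.
#' @return A list of class `sca_control`.
#' @export
sca_control <- function(a = 2, r1 = NULL, r2 = NULL, r3 = NULL, r4 = NULL) {
  stopifnot(is.numeric(a), length(a) == 1, a > 0)
  structure(list(a = a, r1 = r1, r2 = r2, r3 = r3, r4 = r4),
            class = "sca_control")
}

#' Control parameters for the firefly search
#'
#' @param beta0 Attractiveness at zero distance (> 0).
#' @param gamma Light-absorption coefficient (>= 0); large values make the
#'   attraction decay quickly with distance.
#' @param alpha0 Initial randomization weight of the Gaussian walk term,
#'   expressed as a fraction of each dimension's range.
#' @param alpha_decay Per-iteration geometric decay of the randomization
#'   weight, `alpha_t = alpha0 * alpha_decay^t`, so the walk shrinks as the
#'   swarm converges.
#' @details Distances and the random walk operate on the range-normalized
#'   scale (each coordinate difference divided by its dimension's width),
#'   so one set of constants behaves consistently across search spaces of
#'   any units — the usual practice when the firefly update is applied to
#'   mixed-scale hyperparameter boxes.
#' @return A list of class `fa_control`.
#' @export
fa_control <- function(beta0 = 1, gamma = 1, alpha0 = 0.25, alpha_decay = 0.9) {
  stopifnot(beta0 > 0, gamma >= 0, alpha0 >= 0,
            alpha_decay > 0, alpha_decay <= 1)
  structure(list(beta0 = beta0, gamma = gamma, alpha0 = alpha0,
                 alpha_decay = alpha_decay),
            class = "fa_control")
}

#' Hybrid-phase control parameters
#'
#' The hybrid self-adaptive run starts as pure sine-cosine search and, once
#' the iteration counter reaches the varying-search threshold `vs`
#' (default `ceiling(max_iter / 5)`), lets each solution choose per
#' iteration between the sine-cosine move and a firefly move towards the
#' destination: a uniform draw below the search-mode probability `sm`
#' selects sine-cosine. `sm` starts at 0.8 and loses a tenth of its value
#' each hybrid iteration (see [decay_sm()]), shifting weight to the
#' exploitation-oriented firefly move late in the run.
#'
#' @param vs Iterations of pure sine-cosine search before the hybrid phase;
#'   `NULL` means `ceiling(max_iter / 5)`.
#' @param sm0 Initial search-mode probability in `[0, 1]`.
#' @param decay Logical; decay `sm` once per hybrid-phase iteration.
#' @return A list of class `hybrid_control`.
#' @export
hybrid_control <- function(vs = NULL, sm0 = 0.8, decay = TRUE) {
  stopifnot(is.null(vs) || (vs >= 0), sm0 >= 0, sm0 <= 1)
  structure(list(vs = vs, sm0 = sm0, decay = decay), class = "hybrid_control")
}

#' One decay step of the search-mode probability
#'
#' `sm` loses a tenth of its current value: `sm - sm / 10`, i.e. `0.9 * sm`.
#' Applied once per iteration while the hybrid phase is active, so after
#' `k` hybrid iterations `sm = sm0 * 0.9^k`.
#'
#' @param sm Current search-mode probability in `[0, 1]`.
#' @return The decayed value.
#' @examples
#' decay_sm(0.8) # 0.72
#' @export
decay_sm <- function(sm) {
  stopifnot(is.numeric(sm), length(sm) == 1, sm >= 0, sm <= 1)
  sm - sm / 10
}

#' Initialize a swarm population
#'
#' Draws `n` positions uniformly within the search-space bounds (integer
#' dimensions are repaired to integers), evaluates every solution, and sets
#' the destination to the fittest one.
#'
#' @param space A [search_space()].
#' @param n Population size (>= 2).
#' @param objective Function mapping a position vector to a scalar fitness
#'   to be minimized; `NULL` leaves fitness unset and the destination empty.
#' @return A list of class `swarm_population` with elements `positions`
#'   (n x l matrix), `fitness`, `destination` (list with `position`,
#'   `fitness`), and `evaluations`.
#' @export
init_population <- function(space, n, objective = NULL) {
  stopifnot(inherits(space, "search_space"))
  if (!is.numeric(n) || length(n) != 1 || n < 2) {
    rlang::abort("Population-based search needs `n` >= 2 solutions.")
  }
  n <- as.integer(n)
  l <- space_dim(space)
  positions <- matrix(stats::runif(n * l), nrow = n)
  positions <- sweep(positions, 2, space$upper - space$lower, `*`)
  positions <- sweep(positions, 2, space$lower, `+`)
  positions <- t(apply(positions, 1, repair_position, space = space))
  if (l == 1) positions <- matrix(as.numeric(positions), ncol = 1)
  colnames(positions) <- space$name
  pop <- list(positions = positions, fitness = rep(NA_real_, n),
              destination = list(position = NULL, fitness = Inf),
              evaluations = 0L)
  class(pop) <- "swarm_population"
  if (!is.null(objective)) pop <- evaluate_population(pop, objective)
  pop
}

# Evaluate all solutions, elitistly update the destination; non-finite
# objective values are recorded as +Inf so a single bad configuration can
# never crash or win a run.
evaluate_population <- function(pop, objective) {
  n <- nrow(pop$positions)
  bad <- 0L
  for (k in seq_len(n)) {
    val <- objective(as.numeric(pop$positions[k, ]))
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val)) {
      bad <- bad + 1L
      val <- Inf
    }
    pop$fitness[k] <- val
    if (val < pop$destination$fitness) {
      pop$destination <- list(position = as.numeric(pop$positions[k, ]),
                              fitness = val)
    }
  }
  if (bad > 0) {
    rlang::warn(sprintf(
      "%d objective evaluation(s) returned a non-finite value; recorded as +Inf fitness.",
      bad))
  }
  pop$evaluations <- pop$evaluations + n
  pop
}

#' Sine-cosine position update
#'
#' Moves one solution around the destination (best-so-far) point: per
#' component, with fresh control draws,
#' `x' = x + r1 * sin(r2) * |r3 * p - x|` when `r4 < 0.5`, and the cosine
#' branch otherwise. The result is repaired into the space.
#'
#' @param position Current position vector.
#' @param destination Destination (best-so-far) position vector.
#' @param space A [search_space()].
#' @param control An [sca_control()].
#' @param t Zero-based iteration index (drives the `r1` schedule).
#' @param max_iter Total iterations (drives the `r1` schedule).
#' @return The updated, repaired position.
#' @export
sca_step <- function(position, destination, space, control = sca_control(),
                     t = 0, max_iter = 1) {
  l <- space_dim(space)
  stopifnot(length(position) == l, length(destination) == l)
  r1 <- control$r1 %||% (control$a - t * control$a / max_iter)
  r2 <- control$r2 %||% stats::runif(l, 0, 2 * pi)
  r3 <- control$r3 %||% stats::runif(l, 0, 2)
  r4 <- control$r4 %||% stats::runif(l)
  trig <- ifelse(r4 < 0.5, sin(r2), cos(r2))
  out <- position + r1 * trig * abs(r3 * destination - position)
  repair_position(out, space)
}

#' Firefly position update
#'
#' Moves solution `i` towards a brighter (fitter) solution `j` with
#' distance-decaying attractiveness plus a Gaussian random walk:
#' `x' = x_i + beta0 * exp(-gamma * r_ij^2) * (x_j - x_i) + alpha_t * (kappa - 0.5)`
#' with `r_ij` the Euclidean distance between the two positions and `kappa`
#' a per-component standard-normal draw. The distance and the walk term are
#' taken on the range-normalized scale (see [fa_control()]); the result is
#' repaired into the space.
#'
#' @param position Position of the moving solution.
#' @param attractor Position of the brighter solution it moves towards.
#' @param space A [search_space()].
#' @param control An [fa_control()].
#' @param t Zero-based iteration index (drives the `alpha_t` schedule).
#' @return The updated, repaired position.
#' @export
fa_step <- function(position, attractor, space, control = fa_control(), t = 0) {
  l <- space_dim(space)
  stopifnot(length(position) == l, length(attractor) == l)
  alpha_t <- control$alpha0 * control$alpha_decay^t
  scale <- space$upper - space$lower
  r2 <- sum(((attractor - position) / scale)^2)
  kappa <- stats::rnorm(l)
  out <- position + control$beta0 * exp(-control$gamma * r2) *
    (attractor - position) + alpha_t * (kappa - 0.5) * scale
  repair_position(out, space)
}

# Shared engine behind run_sca() and run_hsa_sca(). One uniform mode-gate
# draw is consumed per solution per iteration in *both* algorithms (pure
# sine-cosine simply ignores it), so disabling the hybrid phase — vs =
# max_iter or sm pinned at 1 — reproduces the sine-cosine trajectory draw
# for draw under a shared seed.
swarm_engine <- function(objective, space, n, max_iter, seed,
                         vs, sm0, decay, sca_ctl, fa_ctl, algorithm) {
  stopifnot(max_iter >= 1)
  set.seed(seed)
  pop <- init_population(space, n, objective)
  convergence <- numeric(max_iter)
  sm <- sm0
  sm_trace <- numeric(max_iter)
  for (t in 0:(max_iter - 1)) {
    dest <- pop$destination$position
    for (k in seq_len(n)) {
      rnd <- stats::runif(1)
      use_sca <- (t < vs) || (rnd < sm)
      pos <- as.numeric(pop$positions[k, ])
      pop$positions[k, ] <- if (use_sca) {
        sca_step(pos, dest, space, sca_ctl, t = t, max_iter = max_iter)
      } else {
        fa_step(pos, dest, space, fa_ctl, t = t)
      }
    }
    pop <- evaluate_population(pop, objective)
    convergence[t + 1] <- pop$destination$fitness
    sm_trace[t + 1] <- sm
    if (decay && t >= vs) sm <- decay_sm(sm)
  }
  new_swarm_result(algorithm, space, pop, convergence, seed,
                   sm_trace = sm_trace)
}

new_swarm_result <- function(algorithm, space, pop, convergence, seed,
                             sm_trace = NULL) {
  best <- pop$destination$position
  names(best) <- space$name
  structure(list(
    algorithm = algorithm,
    best_position = best,
    best_fitness = pop$destination$fitness,
    convergence = convergence,
    evaluations = pop$evaluations,
    seed = seed,
    sm_trace = sm_trace
  ), class = "swarm_result")
}

#' Run the sine cosine algorithm
#'
#' Full elitist SCA loop: initialize and evaluate the population, then per
#' iteration move every solution with [sca_step()] around the best-so-far
#' destination and re-evaluate. The destination is never replaced by a
#' worse solution, so the convergence series is monotone non-increasing.
#'
#' @param objective Function from position vector to scalar fitness
#'   (minimized). Non-finite values are treated as `+Inf`.
#' @param space A [search_space()].
#' @param n Population size (>= 2).
#' @param max_iter Number of iterations.
#' @param seed Integer seed; fixed seed gives a bit-identical result.
#' @param sca_ctl An [sca_control()].
#' @return A `swarm_result`: best position and fitness, per-iteration
#'   convergence series, total objective evaluations, and the seed.
#' @examples
#' sphere <- function(x) sum(x^2)
#' sp <- search_space(rep(-5, 3), rep(5, 3))
#' run_sca(sphere, sp, n = 10, max_iter = 20, seed = 1)$best_fitness
#' @export
run_sca <- function(objective, space, n, max_iter, seed,
                    sca_ctl = sca_control()) {
  swarm_engine(objective, space, n, max_iter, seed,
               vs = max_iter, sm0 = 1, decay = FALSE,
               sca_ctl = sca_ctl, fa_ctl = fa_control(), algorithm = "sca")
}

#' Run the hybrid self-adaptive sine cosine algorithm
#'
#' Early iterations (`t < vs`) are pure sine-cosine exploration. From
#' iteration `vs` on, each solution draws a uniform `rnd` and performs the
#' sine-cosine move when `rnd < sm`, otherwise a firefly move attracted to
#' the destination point; `sm` decays by a tenth of its value each hybrid
#' iteration, handing the late search over to firefly exploitation. The
#' destination is elitist throughout.
#'
#' @inheritParams run_sca
#' @param hybrid A [hybrid_control()]; `vs = NULL` defaults to
#'   `ceiling(max_iter / 5)`.
#' @param fa_ctl An [fa_control()] for the hybrid-phase firefly move.
#' @return A `swarm_result` (see [run_sca()]); also carries the per-
#'   iteration `sm` schedule.
#' @examples
#' sphere <- function(x) sum(x^2)
#' sp <- search_space(rep(-5, 3), rep(5, 3))
#' run_hsa_sca(sphere, sp, n = 10, max_iter = 20, seed = 1)$best_fitness
#' @export
run_hsa_sca <- function(objective, space, n, max_iter, seed,
                        hybrid = hybrid_control(),
                        sca_ctl = sca_control(), fa_ctl = fa_control()) {
  vs <- hybrid$vs %||% ceiling(max_iter / 5)
  if (vs < 0 || vs > max_iter) {
    rlang::abort("`vs` must lie in [0, max_iter].")
  }
  swarm_engine(objective, space, n, max_iter, seed,
               vs = vs, sm0 = hybrid$sm0, decay = hybrid$decay,
               sca_ctl = sca_ctl, fa_ctl = fa_ctl, algorithm = "hsa-sca")
}

#' Run the firefly algorithm
#'
#' Classical firefly sweep: each solution moves towards every brighter
#' solution (brightness judged by the fitness snapshot taken at the start
#' of the iteration) via [fa_step()]; the brightest performs a pure random
#' walk. All solutions are re-evaluated once per iteration and the elitist
#' destination tracks the best ever seen.
#'
#' @inheritParams run_sca
#' @param fa_ctl An [fa_control()].
#' @return A `swarm_result` (see [run_sca()]).
#' @export
run_fa <- function(objective, space, n, max_iter, seed,
                   fa_ctl = fa_control()) {
  stopifnot(max_iter >= 1)
  set.seed(seed)
  pop <- init_population(space, n, objective)
  convergence <- numeric(max_iter)
  l <- space_dim(space)
  for (t in 0:(max_iter - 1)) {
    snapshot <- pop$fitness
    brightest <- which.min(snapshot)
    for (k in seq_len(n)) {
      if (k == brightest) {
        alpha_t <- fa_ctl$alpha0 * fa_ctl$alpha_decay^t
        kappa <- stats::rnorm(l)
        pop$positions[k, ] <- repair_position(
          as.numeric(pop$positions[k, ]) + alpha_t * (kappa - 0.5), space)
        next
      }
      for (j in seq_len(n)) {
        if (snapshot[j] < snapshot[k]) {
          pop$positions[k, ] <- fa_step(as.numeric(pop$positions[k, ]),
                                        as.numeric(pop$positions[j, ]),
                                        space, fa_ctl, t = t)
        }
      }
    }
    pop <- evaluate_population(pop, objective)
    convergence[t + 1] <- pop$destination$fitness
  }
  new_swarm_result("fa", space, pop, convergence, seed)
}

#' @export
print.swarm_result <- function(x, ...) {
  cat("<swarm_result> ", x$algorithm, "\n", sep = "")
  cat("  best fitness: ", format(x$best_fitness, digits = 7), "\n", sep = "")
  cat("  best position: ",
      paste(format(x$best_position, digits = 4), collapse = ", "), "\n",
      sep = "")
  cat("  iterations: ", length(x$convergence),
      "; evaluations: ", x$evaluations, "; seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Tidy a swarm optimizer result into its convergence series
#'
#' @param x A `swarm_result`.
#' @param ... Unused.
#' @return A tibble with columns `algorithm`, `iteration`, `best_fitness`.
#' @exportS3Method generics::tidy
tidy.swarm_result <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    iteration = seq_along(x$convergence),
    best_fitness = x$convergence
  )
}

#' One-row summary of a swarm optimizer result
#'
#' @param x A `swarm_result`.
#' @param ... Unused.
#' @return A one-row tibble: `algorithm`, `best_fitness`, `iterations`,
#'   `evaluations`, `seed`.
#' @exportS3Method generics::glance
glance.swarm_result <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    best_fitness = x$best_fitness,
    iterations = length(x$convergence),
    evaluations = x$evaluations,
    seed = x$seed
  )
}
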