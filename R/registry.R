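.optimizers <- new.env(parent = emptyenv())

#' Register an optimizer under a name
#'
#' The comparison protocol looks optimizers up by name, so contender
#' metaheuristics (GA, PSO, ABC, ...) can be dropped in without touching the
#' package: a registered function must accept
#' `(objective, space, n, max_iter, seed, ...)` and return a `swarm_result`
#' (or any list with `best_position`, `best_fitness`, `convergence`,
#' `evaluations`). The built-ins `"sca"`, `"fa"` and `"hsa-sca"` are
#' registered at load time.
#'
#' @param name Registry key.
#' @param fn Optimizer function.
#' @return `name`, invisibly.
#' @export
register_optimizer <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  assign(name, fn, envir = .optimizers)
  invisible(name)
}

#' @rdname register_optimizer
#' @export
optimizer_names <- function() sort(ls(.optimizers))

#' @rdname register_optimizer
#' @export
get_optimizer <- function(name) {
  if (!exists(name, envir = .optimizers, inherits = FALSE)) {
    rlang::abort(sprintf(
      "Unknown optimizer '%s'. Registered: %s.",
      name, paste(optimizer_names(), collapse = ", ")))
  }
  get(name, envir = .optimizers, inherits = FALSE)
}

register_builtin_optimizers <- function() {
  register_optimizer("sca", function(objective, space, n, max_iter, seed, ...) {
    run_sca(objective, space, n, max_iter, seed, ...)
  })
  register_optimizer("fa", function(objective, space, n, max_iter, seed, ...) {
    run_fa(objective, space, n, max_iter, seed, ...)
  })
  register_optimizer("hsa-sca", function(objective, space, n, max_iter, seed, ...) {
    run_hsa_sca(objective, space, n, max_iter, seed, ...)
  })
}

.onLoad <- function(libname, pkgname) {
  register_builtin_optimizers()
}
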