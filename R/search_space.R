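#' Define a box-bounded search space
#'
#' A search space is the rectangular domain the swarm optimizers explore:
#' one lower and upper bound per dimension, plus a kind flag saying whether
#' the dimension is continuous or integer-valued. Integer dimensions are
#' kept integral by [repair_position()] (round half-up, then clamp).
#'
#' @param lower,upper Numeric vectors of per-dimension bounds
#'   (`lower < upper` everywhere).
#' @param kind Character vector, `"continuous"` or `"integer"` per
#'   dimension; recycled if length 1.
#' @param names Optional dimension names.
#'
#' @return A tibble of class `search_space` with columns `name`, `lower`,
#'   `upper`, `kind` — one row per dimension.
#' @examples
#' search_space(lower = c(0, 3), upper = c(1, 10), kind = c("continuous", "integer"))
#' @export
search_space <- function(lower, upper, kind = "continuous", names = NULL) {
  if (length(lower) != length(upper)) {
    rlang::abort("`lower` and `upper` must have the same length.")
  }
  l <- length(lower)
  if (l < 1L) {
    rlang::abort("A search space needs at least one dimension.")
  }
  kind <- rep_len(match.arg(kind, c("continuous", "integer"), several.ok = TRUE), l)
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    rlang::abort("Bounds must be finite.")
  }
  if (any(lower >= upper)) {
    rlang::abort("Every lower bound must be strictly below its upper bound.")
  }
  int <- kind == "integer"
  if (any(int & (lower != round(lower) | upper != round(upper)))) {
    rlang::abort("Integer dimensions need integer-representable bounds.")
  }
  if (is.null(names)) names <- paste0("x", seq_len(l))
  out <- tibble::tibble(
    name = as.character(names),
    lower = as.numeric(lower),
    upper = as.numeric(upper),
    kind = kind
  )
  class(out) <- c("search_space", class(out))
  out
}

#' @export
print.search_space <- function(x, ...) {
  cat("<search_space> ", nrow(x), " dimension(s)\n", sep = "")
  NextMethod()
}

space_dim <- function(space) nrow(space)

#' Round half-up
#'
#' Deterministic rounding used for integer search dimensions: 5.5 -> 6,
#' 6.5 -> 7 (base `round()` rounds half to even, which would make repairs
#' depend on parity).
#' @param x Numeric vector.
#' @return `floor(x + 0.5)`.
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

#' Repair a position into its search space
#'
#' Clamps every component to its box bounds; integer dimensions are rounded
#' half-up before clamping. All step operators pass their proposals through
#' this, so every position the optimizers ever evaluate is feasible.
#'
#' @param position Numeric vector, one value per space dimension.
#' @param space A [search_space()].
#' @return Numeric vector of the same length, inside the bounds.
#' @examples
#' sp <- search_space(c(0, 3), c(1, 10), c("continuous", "integer"))
#' repair_position(c(-0.3, 5.4), sp)
#' @export
repair_position <- function(position, space) {
  if (length(position) != space_dim(space)) {
    rlang::abort("`position` length does not match the search space dimension.")
  }
  int <- space$kind == "integer"
  position[int] <- round_half_up(position[int])
  pmin(pmax(position, space$lower), space$upper)
}
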