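#' Regression evaluation metrics including the index of agreement
#'
#' Computes the six metrics used to judge a tuned model on held-out data:
#' mean squared error, its root, mean absolute error, the coefficient of
#' determination R^2, the Pearson correlation R, and Willmott's index of
#' agreement
#' \deqn{IA = 1 - \frac{\sum_i (a_i - \hat a_i)^2}
#'                     {\sum_i (|\hat a_i - \bar a| + |a_i - \bar a|)^2}}
#' with \eqn{\bar a} the mean of the observed values. IA lies in `[0, 1]`;
#' 1 is perfect agreement and 0 (e.g. for the mean-constant prediction)
#' means no match beyond the potential error. Error metrics are in target
#' units; R^2, R and IA are dimensionless.
#'
#' @param observed Numeric vector of observed target values (length >= 2,
#'   not all identical — otherwise R, R^2 and IA are undefined).
#' @param predicted Numeric vector of predictions, same length.
#' @return A one-row tibble with columns `mse`, `rmse`, `mae`, `r2`, `r`,
#'   `ia`.
#' @examples
#' compute_metrics(c(1, 2, 3), c(1, 2, 5))
#' @export
compute_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    rlang::abort("`observed` and `predicted` must have equal length.")
  }
  if (length(observed) < 2) {
    rlang::abort("Need at least two observations.")
  }
  if (anyNA(observed) || anyNA(predicted)) {
    rlang::abort("Missing values in `observed` or `predicted`.")
  }
  if (stats::sd(observed) == 0) {
    rlang::abort(paste(
      "All observed values are identical: R, R^2 and the index of",
      "agreement are undefined (zero-variance denominators)."))
  }
  err <- predicted - observed
  mse <- mean(err^2)
  abar <- mean(observed)
  potential <- sum((abs(predicted - abar) + abs(observed - abar))^2)
  tibble::tibble(
    mse = mse,
    rmse = sqrt(mse),
    mae = mean(abs(err)),
    r2 = 1 - sum(err^2) / sum((observed - abar)^2),
    r = if (stats::sd(predicted) == 0) NA_real_ else stats::cor(observed, predicted),
    ia = 1 - sum(err^2) / potential
  )
}
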