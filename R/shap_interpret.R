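#' Shapley attributions of a fitted boosted-tree model
#'
#' Computes exact tree-path-dependent Shapley values for every prediction
#' via the backend's TreeSHAP implementation. No reference sample is
#' needed: expectations are taken over the tree paths as weighted by the
#' training data, the standard TreeExplainer behaviour. The local-accuracy
#' identity — base value plus the row's attributions equals the model's
#' prediction — is verified for every row and an error is raised if it
#' fails beyond `1e-6 * max(1, |prediction|)`.
#'
#' @param model A fitted `xgb.Booster` (see [fit_boosted_model()]).
#' @param data Feature table (tibble/data.frame or matrix) whose columns
#'   match the model's training schema; typically the full dataset, since
#'   interpretation covers all observations.
#' @return A list of class `shap_attribution`: `shap` (rows x features
#'   matrix, target units), `base_value` (expected model output),
#'   `features` (column names), `feature_values` (the input table as a
#'   tibble), `prediction` (model output per row).
#' @export
compute_attributions <- function(model, data) {
  if (!inherits(model, "xgb.Booster")) {
    rlang::abort("`model` must be a fitted xgb.Booster tree ensemble.")
  }
  feats <- xgboost::getinfo(model, "feature_name")
  if (is.null(feats) || length(feats) == 0) feats <- colnames(data)
  if (!all(feats %in% colnames(data))) {
    rlang::abort("`data` is missing model feature column(s): schema mismatch.")
  }
  x <- as.matrix(as.data.frame(data)[, feats, drop = FALSE])
  contrib <- predict(model, x, predcontrib = TRUE)
  base_col <- ncol(contrib) # bias/intercept column is last
  shap <- contrib[, -base_col, drop = FALSE]
  base_value <- contrib[1, base_col]
  prediction <- predict(model, x)
  err <- abs(base_value + rowSums(shap) - prediction)
  tol <- 1e-6 * pmax(1, abs(prediction))
  if (any(err > tol)) {
    rlang::abort(sprintf(
      "Local accuracy violated on %d row(s) (max error %.3g): attributions do not reconstruct the predictions.",
      sum(err > tol), max(err)))
  }
  structure(list(
    shap = shap,
    base_value = base_value,
    features = colnames(shap),
    feature_values = tibble::as_tibble(as.data.frame(x)),
    prediction = prediction
  ), class = "shap_attribution")
}

#' @export
print.shap_attribution <- function(x, ...) {
  cat("<shap_attribution> ", nrow(x$shap), " predictions x ",
      length(x$features), " features; base value ",
      format(x$base_value, digits = 5), "\n", sep = "")
  invisible(x)
}

#' Tidy Shapley attributions into long form
#'
#' @param x A `shap_attribution`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `feature`, `feature_value`,
#'   `shap_value`.
#' @exportS3Method generics::tidy
tidy.shap_attribution <- function(x, ...) {
  long <- tibble::as_tibble(as.data.frame(x$shap))
  long$row <- seq_len(nrow(long))
  shap_long <- tidyr::pivot_longer(long, -"row", names_to = "feature",
                                   values_to = "shap_value")
  vals <- x$feature_values
  vals$row <- seq_len(nrow(vals))
  val_long <- tidyr::pivot_longer(vals, -"row", names_to = "feature",
                                  values_to = "feature_value")
  dplyr::left_join(shap_long, val_long, by = c("row", "feature"))[
    , c("row", "feature", "feature_value", "shap_value")]
}

#' Per-prediction relative Shapley shares
#'
#' The relative attribution of feature f for prediction i is its absolute
#' Shapley value divided by the total absolute attribution of that
#' prediction, `|phi(i,f)| / sum_g |phi(i,g)|` — a dimensionless share in
#' `[0, 1]`; every row sums to 1.
#'
#' @param attr A [compute_attributions()] result, or a plain numeric matrix
#'   of Shapley values (rows = predictions).
#' @return A matrix of shares with the same shape and column names.
#' @examples
#' relative_shap(matrix(c(2, -1, 1), nrow = 1))
#' @export
relative_shap <- function(attr) {
  m <- if (inherits(attr, "shap_attribution")) attr$shap else as.matrix(attr)
  a <- abs(m)
  totals <- rowSums(a)
  zero <- which(totals == 0)
  if (length(zero) > 0) {
    rlang::abort(paste0(
      "All-zero attribution row(s): ", paste(zero, collapse = ", "),
      ". Relative shares are undefined for predictions with no attributed importance."))
  }
  a / totals
}

#' Mean-absolute Shapley importance ranking
#'
#' Per feature: the mean absolute Shapley value (target units) and the mean
#' per-prediction relative share in percent, sorted by decreasing mean
#' absolute value. Because the relative share is defined per prediction,
#' the reported percentage is the mean of the per-prediction shares; the
#' alternative aggregate — each feature's share of the summed mean-absolute
#' values — is also included for transparency as `share_of_mean_abs_pct`.
#'
#' @param attr A [compute_attributions()] result (or Shapley-value matrix).
#' @return A tibble: `feature`, `mean_abs_shap`, `mean_relative_pct`,
#'   `share_of_mean_abs_pct`, ordered by decreasing `mean_abs_shap`.
#' @export
mean_abs_importance <- function(attr) {
  m <- if (inherits(attr, "shap_attribution")) attr$shap else as.matrix(attr)
  if (length(m) == 0) rlang::abort("Empty attribution matrix.")
  mean_abs <- colMeans(abs(m))
  rel <- relative_shap(attr)
  out <- tibble::tibble(
    feature = colnames(m) %||% paste0("x", seq_along(mean_abs)),
    mean_abs_shap = as.numeric(mean_abs),
    mean_relative_pct = 100 * as.numeric(colMeans(rel)),
    share_of_mean_abs_pct = 100 * as.numeric(mean_abs / sum(mean_abs))
  )
  dplyr::arrange(out, dplyr::desc(.data$mean_abs_shap))
}

#' Dependence-plot data for one feature
#'
#' The paired series (feature value, Shapley value) across all predictions,
#' sorted by feature value — the data behind a SHAP dependence plot showing
#' how a feature's attributed effect changes over its value range. An
#' optional second feature colours the points.
#'
#' @param attr A [compute_attributions()] result.
#' @param feature Feature name.
#' @param color Optional name of a colouring feature.
#' @return A tibble with columns `feature_value`, `shap_value` (and
#'   `color_value` if requested), one row per prediction.
#' @export
dependence_data <- function(attr, feature, color = NULL) {
  stopifnot(inherits(attr, "shap_attribution"))
  if (!feature %in% attr$features) {
    rlang::abort(paste0("Unknown feature '", feature, "'."))
  }
  out <- tibble::tibble(
    feature_value = attr$feature_values[[feature]],
    shap_value = attr$shap[, feature]
  )
  if (!is.null(color)) {
    if (!color %in% attr$features) {
      rlang::abort(paste0("Unknown colouring feature '", color, "'."))
    }
    out$color_value <- attr$feature_values[[color]]
  }
  dplyr::arrange(out, .data$feature_value)
}
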