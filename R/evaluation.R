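#' Partition a sample set by region tags
#'
#' The test set is every sample whose `region_tag` is in `test_regions`; the
#' training set is the complement. Useful for iterative region-holdout
#' designs (continental model, then adding regional and local samples).
#'
#' @param set An `sr_samples` set with populated `region_tag`.
#' @param test_regions Character vector of region tags held out for testing.
#' @return List with elements `train` and `test`, both `sr_samples`.
#' @export
split_by_region <- function(set, test_regions) {
  stopifnot(inherits(set, "sr_samples"))
  if (length(test_regions) == 0) stop("empty test-region list")
  if (all(is.na(set$region_tag))) stop("region_tag is not populated")
  in_test <- set$region_tag %in% test_regions
  if (!any(in_test)) {
    stop("empty test partition for regions: ",
         paste(test_regions, collapse = ", "))
  }
  if (all(in_test)) {
    stop("empty train partition: all samples match ",
         paste(test_regions, collapse = ", "))
  }
  list(train = set[!in_test, , drop = FALSE],
       test = set[in_test, , drop = FALSE])
}

.rmse <- function(y, yhat) sqrt(mean((y - yhat)^2))
.r2 <- function(y, yhat) {
  denom <- sum((y - mean(y))^2)
  if (denom == 0) {
    warning("zero-variance observations: R^2 undefined")
    return(NaN)
  }
  1 - sum((y - yhat)^2) / denom
}

.metrics_row <- function(label, obs_ratio, pred_logit, pred_ratio,
                         transform) {
  obs_logit <- to_logit(obs_ratio, transform)
  tibble::tibble(
    label = label, n = length(obs_ratio),
    rmse_logit = .rmse(obs_logit, pred_logit),
    r2_logit = .r2(obs_logit, pred_logit),
    rmse_raw = .rmse(obs_ratio, pred_ratio),
    r2_raw = .r2(obs_ratio, pred_ratio)
  )
}

#' RMSE and R-squared in logit and raw ratio units
#'
#' The point prediction is the posterior mean: the mean over draws in logit
#' space for the logit metrics, and the mean of the back-transformed draws
#' for the raw metrics (not the back-transform of the logit mean). Held-out
#' R-squared uses the test-set mean in its denominator.
#'
#' @param obs Observed ratios.
#' @param pred_draws Matrix of logit-scale posterior draws, rows aligned with
#'   `obs`.
#' @param transform An [sr_transform()].
#' @param label Report label.
#' @return One-row tibble: `label`, `n`, `rmse_logit`, `r2_logit`,
#'   `rmse_raw`, `r2_raw`.
#' @export
compute_metrics <- function(obs, pred_draws, transform = sr_transform(),
                            label = "model") {
  stopifnot(is.matrix(pred_draws), nrow(pred_draws) == length(obs),
            length(obs) >= 2)
  pred_logit <- rowMeans(pred_draws)
  pred_ratio <- rowMeans(from_logit(pred_draws, transform))
  .metrics_row(label, obs, pred_logit, pred_ratio, transform)
}

#' Score an externally supplied baseline prediction
#'
#' Applies the same metric formulas to deterministic ratio-scale predictions
#' (for example a mechanistic bedrock-model raster sampled at the test
#' locations). Baseline values outside the transform bounds are clamped with
#' a warning before the logit metrics are computed.
#'
#' @param obs Observed ratios.
#' @param baseline_pred Predicted ratios, aligned with `obs`.
#' @param transform An [sr_transform()].
#' @param label Report label.
#' @return One-row tibble in the [compute_metrics()] shape.
#' @export
evaluate_baseline <- function(obs, baseline_pred,
                              transform = sr_transform(),
                              label = "baseline") {
  stopifnot(length(obs) == length(baseline_pred), length(obs) >= 2)
  out_of_bounds <- baseline_pred < transform$lower |
    baseline_pred > transform$upper
  if (any(out_of_bounds)) {
    warning(sprintf("clamped %d baseline value(s) to [%g, %g]",
                    sum(out_of_bounds), transform$lower, transform$upper))
    baseline_pred <- pmin(pmax(baseline_pred, transform$lower),
                          transform$upper)
  }
  .metrics_row(label, obs, to_logit(baseline_pred, transform), baseline_pred,
               transform)
}
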