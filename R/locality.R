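#' Posterior-predictive local range at a location
#'
#' The predicted "local" strontium band at a site: the posterior predictive
#' distribution of a new measurement of the given sample type at the grid
#' cell containing the point. The interquartile range is the conventional
#' local band; the central 95% interval bounds the plausible extreme.
#'
#' @param fit A `bart_fit` with a recorded transform.
#' @param stack The `predictor_stack` used for prediction.
#' @param pca The training `blocked_pca` model.
#' @param x,y Point coordinates in the stack's CRS.
#' @param sample_type Tissue-relevant sample type (default `"plant"`).
#' @param site Optional site label carried into the result.
#' @return A `local_range`: site, coordinates, `median`, `q25`, `q75`,
#'   `ci025`, `ci975`, `n_draws`, and the ratio-scale `draws` themselves.
#' @export
local_range_at <- function(fit, stack, pca, x, y, sample_type = "plant",
                           site = NA_character_) {
  stopifnot(length(x) == 1, length(y) == 1)
  covs <- suppressWarnings(extract_covariates(stack, x, y))
  band_cols <- setdiff(names(covs), c("row", "col"))
  if (anyNA(covs[band_cols])) {
    stop("location is outside the stack extent or on a masked cell")
  }
  design <- assemble_design(covs[band_cols], pca, sample_type,
                            type_levels = fit$type_levels)
  draws <- from_logit(
    as.numeric(predict(fit, design, posterior_predictive = TRUE)),
    fit$transform)
  q <- quantile(draws, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
  structure(list(site = site, x = x, y = y, median = q[3], q25 = q[2],
                 q75 = q[4], ci025 = q[1], ci975 = q[5],
                 n_draws = length(draws), draws = draws),
            class = "local_range")
}

#' @export
print.local_range <- function(x, ...) {
  cat(sprintf(
    "<local_range>%s median %.4f, IQR [%.4f, %.4f], 95%% [%.4f, %.4f] (%d draws)\n",
    if (is.na(x$site)) "" else paste0(" ", x$site, ":"),
    x$median, x$q25, x$q75, x$ci025, x$ci975, x$n_draws))
  invisible(x)
}

.hazen_cdf <- function(draws, value) {
  (sum(draws < value) + 0.5 * sum(draws == value)) / length(draws)
}

.range_category <- function(value, range) {
  if (value >= range$q25 && value <= range$q75) "local"
  else if (value >= range$ci025 && value <= range$ci975) "marginal"
  else "nonlocal"
}

#' Assess a tissue value against a predicted local range
#'
#' Places a measured tissue ratio on a continuous spectrum of locality:
#' `locality_p` is the two-sided tail probability
#' \eqn{2\min(\hat F(v), 1-\hat F(v))} under the empirical CDF of the
#' posterior predictive draws (midpoint/Hazen ranks, so finite draw counts do
#' not saturate at 0 or 1), and `category` is `local` inside the IQR,
#' `marginal` between the IQR and the central 95% interval, and `nonlocal`
#' outside it. When a measurement 2-SE (`se`) is supplied, the value's
#' `[v - 2se, v + 2se]` interval is compared against the bands and the most
#' local category consistent with any point of the interval is reported, with
#' the overlap noted.
#'
#' @param value Measured ratio (sanity window 0.5--1.0).
#' @param range A `local_range` from [local_range_at()].
#' @param se One standard error of the measurement (0 or `NA` to ignore).
#' @param tissue_id Optional identifier carried into the result.
#' @return One-row tibble: `tissue_id`, `value`, `se`, `locality_p`,
#'   `category`, `note`.
#' @export
assess_tissue <- function(value, range, se = 0, tissue_id = NA_character_) {
  stopifnot(inherits(range, "local_range"), length(value) == 1)
  if (is.na(value) || value <= 0.5 || value >= 1.0) {
    stop("tissue ratio outside the sanity window (0.5, 1.0)")
  }
  if (length(range$draws) == 0) stop("local range carries no draws")
  f <- .hazen_cdf(range$draws, value)
  locality_p <- max(0, min(1, 2 * min(f, 1 - f)))
  point_cat <- .range_category(value, range)
  category <- point_cat
  note <- NA_character_
  if (!is.na(se) && se > 0) {
    lo <- value - 2 * se
    hi <- value + 2 * se
    category <- if (hi >= range$q25 && lo <= range$q75) "local"
      else if (hi >= range$ci025 && lo <= range$ci975) "marginal"
      else "nonlocal"
    if (!identical(category, point_cat)) {
      note <- sprintf("point value is %s; +/-2se interval overlaps the %s band",
                      point_cat, category)
    }
  }
  tibble::tibble(tissue_id = tissue_id, value = value,
                 se = ifelse(is.na(se), 0, se), locality_p = locality_p,
                 category = category, note = note)
}

#' Assess a table of tissue values
#'
#' @param tissues Data frame with columns `tissue_id`, `ratio`, and
#'   optionally `se2` (two standard errors; halved internally).
#' @param range A `local_range`.
#' @return `tissues` with `locality_p`, `category`, and `note` appended.
#' @export
assess_tissue_table <- function(tissues, range) {
  stopifnot(all(c("tissue_id", "ratio") %in% names(tissues)))
  se <- if ("se2" %in% names(tissues)) tissues$se2 / 2 else
    rep(0, nrow(tissues))
  res <- do.call(rbind, lapply(seq_len(nrow(tissues)), function(i) {
    assess_tissue(tissues$ratio[i], range, se = se[i],
                  tissue_id = as.character(tissues$tissue_id[i]))
  }))
  out <- tibble::as_tibble(tissues)
  out$locality_p <- res$locality_p
  out$category <- res$category
  out$note <- res$note
  out
}
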