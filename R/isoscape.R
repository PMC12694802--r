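.posterior_id <- function(fit) {
  # cheap content-derived identifier for provenance sidecars
  h <- sum(fit$tree_sizes) %% 100000L
  sprintf("bart-%d draws-%d-%05d", fit$config$m, length(fit$sigma), h)
}

.ratio_summaries <- function(ratio_draws) {
  qs <- t(apply(ratio_draws, 1, quantile,
                probs = c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE))
  list(ci025 = qs[, 1], q25 = qs[, 2], median = qs[, 3], q75 = qs[, 4],
       ci975 = qs[, 5], sd = apply(ratio_draws, 1, sd))
}

#' Predict an isoscape over a covariate grid
#'
#' Applies a fitted posterior across every unmasked cell of a predictor
#' stack. Per cell, posterior (predictive) draws are computed in logit space,
#' back-transformed to ratio units draw by draw, and only then summarized --
#' so the reported median and quantiles are genuine ratio-scale posterior
#' quantiles, free of transformation bias.
#'
#' @param fit A `bart_fit` whose `transform` was recorded at fit time (or
#'   supply `transform`).
#' @param stack A `predictor_stack` covering the model's covariates.
#' @param pca The `blocked_pca` model used in training.
#' @param sample_type Sample type the map represents (default `"plant"`, the
#'   bioavailable baseline convention).
#' @param posterior_predictive If `TRUE` (default) draws include the
#'   observation-noise term, giving predictive intervals for new
#'   measurements; `FALSE` gives mean-function credible intervals.
#' @param transform Overrides the transform stored in `fit`.
#' @param chunk_size Cells predicted per chunk (memory control).
#' @return An `sr_isoscape`: grid, ratio-unit layers (`median`, `q25`, `q75`,
#'   `ci025`, `ci975`, `sd`), and provenance.
#' @export
predict_isoscape <- function(fit, stack, pca, sample_type = "plant",
                             posterior_predictive = TRUE, transform = NULL,
                             chunk_size = 4096) {
  stopifnot(inherits(fit, "bart_fit"), inherits(stack, "predictor_stack"))
  transform <- transform %||% fit$transform
  if (is.null(transform)) stop("no sr_transform recorded or supplied")
  grid <- stack$grid
  rows_rm <- lapply(stack$bands, function(m) as.vector(t(m)))  # row-major
  covs <- as.data.frame(rows_rm)
  mask <- as.vector(t(stack$mask))
  live <- which(!mask)
  layers <- c("median", "q25", "q75", "ci025", "ci975", "sd")
  out <- setNames(replicate(length(layers),
                            matrix(NA_real_, grid$n_rows, grid$n_cols),
                            simplify = FALSE), layers)
  for (start in seq(1, length(live), by = chunk_size)) {
    idx <- live[start:min(start + chunk_size - 1, length(live))]
    design <- assemble_design(covs[idx, , drop = FALSE], pca, sample_type,
                              type_levels = fit$type_levels)
    draws <- predict(fit, design,
                     posterior_predictive = posterior_predictive)
    sm <- .ratio_summaries(from_logit(draws, transform))
    rr <- (idx - 1) %/% grid$n_cols + 1
    cc <- (idx - 1) %% grid$n_cols + 1
    out$median[cbind(rr, cc)] <- sm$median
    out$q25[cbind(rr, cc)] <- sm$q25
    out$q75[cbind(rr, cc)] <- sm$q75
    out$ci025[cbind(rr, cc)] <- sm$ci025
    out$ci975[cbind(rr, cc)] <- sm$ci975
    out$sd[cbind(rr, cc)] <- sm$sd
  }
  structure(list(
    grid = grid, layers = out, mask = stack$mask,
    provenance = list(posterior_id = .posterior_id(fit),
                      sample_type = sample_type,
                      posterior_predictive = posterior_predictive,
                      lower = transform$lower, upper = transform$upper,
                      epsilon = transform$epsilon)
  ), class = "sr_isoscape")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export an isoscape to ASCII grid layers plus a metadata sidecar
#'
#' Writes one georeferenced plain-text raster per layer
#' (`<basename>_<layer>.asc`, nodata -9999) and
#' `<basename>_metadata.txt` recording the posterior id, sample type, and
#' transform bounds.
#'
#' @param iso An `sr_isoscape`.
#' @param dir Output directory (created if needed).
#' @param basename File-name stem.
#' @return Named character vector of the files written, invisibly.
#' @export
export_isoscape <- function(iso, dir, basename = "isoscape") {
  stopifnot(inherits(iso, "sr_isoscape"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  for (nm in names(iso$layers)) {
    path <- file.path(dir, sprintf("%s_%s.asc", basename, nm))
    write_ascii_grid(iso$layers[[nm]], iso$grid, path)
    files[nm] <- path
  }
  meta <- file.path(dir, sprintf("%s_metadata.txt", basename))
  writeLines(c(
    sprintf("posterior_id: %s", iso$provenance$posterior_id),
    sprintf("sample_type: %s", iso$provenance$sample_type),
    sprintf("posterior_predictive: %s", iso$provenance$posterior_predictive),
    sprintf("transform_lower: %.17g", iso$provenance$lower),
    sprintf("transform_upper: %.17g", iso$provenance$upper),
    sprintf("crs_id: %s", iso$grid$crs_id),
    sprintf("layers: %s", paste(names(iso$layers), collapse = ", "))
  ), meta)
  files["metadata"] <- meta
  invisible(files)
}
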