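# shared fixtures for the synthetic-landscape pipeline

landscape_blocks <- c(
  dist_coast = "distance", age = "geology", precip = "climate",
  precip_season = "climate", dust = "aerosol", elevation = "terrain",
  noise = "other")

# extract covariates, fit the blocked PCA (or reuse one), assemble a design
build_design <- function(stack, samples, pca = NULL, type_levels = NULL) {
  covs <- extract_covariates(stack, samples$lon, samples$lat)
  cv <- covs[setdiff(names(covs), c("row", "col"))]
  if (is.null(pca)) pca <- fit_blocked_pca(cv, landscape_blocks)
  list(pca = pca,
       design = assemble_design(cv, pca, samples$sample_type,
                                type_levels = type_levels))
}

# a small fitted pipeline reused by isoscape/locality tests
small_pipeline <- function(seed = 2, n_samples = 250, grid_n = 24,
                           m = 30, n_burn = 200, n_draw = 200,
                           type_mix = c(plant = 1)) {
  cfg <- sim_config(grid_n = grid_n, n_samples = n_samples,
                    type_mix = type_mix, seed = seed)
  ls <- make_landscape(cfg)
  smp <- suppressMessages(
    filter_ratio_range(draw_samples(ls, cfg)$samples))
  stack <- landscape_stack(ls)
  bd <- build_design(stack, smp)
  tr <- sr_transform()
  fit <- fit_bart(bd$design, to_logit(smp$ratio, tr),
                  bart_config(m = m, n_burn = n_burn, n_draw = n_draw,
                              seed = seed + 1),
                  transform = tr)
  list(cfg = cfg, landscape = ls, samples = smp, stack = stack,
       pca = bd$pca, fit = fit, transform = tr)
}
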