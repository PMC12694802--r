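#' Configuration for the sum-of-trees sampler
#'
#' Defaults are the canonical regularization-prior settings of the BART
#' literature: `m = 200` trees, depth prior \eqn{P(split at depth d) =
#' \alpha (1+d)^{-\beta}} with \eqn{\alpha = 0.95, \beta = 2}, leaf shrinkage
#' `k = 2` (so that the sum of trees spans the centred response range at about
#' 2 prior standard deviations), and a scaled-inverse-\eqn{\chi^2} error
#' variance prior with `nu = 3` degrees of freedom whose scale `lambda` is
#' calibrated so the prior puts mass `q = 0.9` below a rough residual-sd
#' estimate.
#'
#' @param m Number of trees.
#' @param alpha,beta Depth-prior base and power.
#' @param k Leaf-shrinkage factor; the leaf prior sd is
#'   `(max z - min z) / (2 k sqrt(m))` on the centred response.
#' @param nu,q Error-variance prior degrees of freedom and calibration
#'   quantile.
#' @param n_burn,n_draw,thin Burn-in sweeps, retained draws, and thinning.
#' @param move_probs Probabilities of the grow/prune/change/swap proposals
#'   (must sum to 1).
#' @param n_cutpoints Maximum number of interior-quantile cutpoints per
#'   continuous variable; one-hot indicator columns always split at 0.5.
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @return A `bart_config` list.
#' @export
bart_config <- function(m = 200, alpha = 0.95, beta = 2, k = 2, nu = 3,
                        q = 0.90,
                        n_burn = 1000, n_draw = 1000, thin = 1,
                        move_probs = c(grow = 0.25, prune = 0.25,
                                       change = 0.40, swap = 0.10),
                        n_cutpoints = 100, seed = 1L) {
  stopifnot(m >= 1, alpha > 0, alpha < 1, beta >= 0, k > 0, nu > 0,
            q > 0, q < 1, n_burn >= 0, n_draw >= 1, thin >= 1,
            length(move_probs) == 4, all(move_probs >= 0),
            abs(sum(move_probs) - 1) < 1e-8, n_cutpoints >= 1)
  structure(list(m = as.integer(m), alpha = alpha, beta = beta, k = k,
                 nu = nu, q = q, n_burn = as.integer(n_burn),
                 n_draw = as.integer(n_draw), thin = as.integer(thin),
                 move_probs = unname(move_probs),
                 n_cutpoints = as.integer(n_cutpoints),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "bart_config")
}

.design_matrix <- function(design) {
  if (inherits(design, "sr_design")) design$x
  else if (is.matrix(design)) design
  else stop("design must be an sr_design or a numeric matrix")
}

.make_cutpoints <- function(x, n_cutpoints) {
  u <- unique(x)
  if (length(u) <= 1) return(numeric(0))
  if (all(u %in% c(0, 1))) return(0.5)
  qs <- unique(unname(quantile(x, probs = seq_len(n_cutpoints) /
                                 (n_cutpoints + 1))))
  qs <- qs[qs < max(x)]
  if (length(qs) == 0) {
    su <- sort(u)
    qs <- (su[-length(su)] + su[-1]) / 2
  }
  qs
}

#' Fit a Bayesian Additive Regression Trees model
#'
#' Runs `n_burn + n_draw * thin` backfitting MCMC sweeps over the sum-of-trees
#' model described in [bart_config()]. Each sweep proposes one
#' grow/prune/change/swap move per tree, accepted by Metropolis--Hastings on
#' the leaf-marginalized likelihood of the tree's partial residuals, then
#' redraws all leaf values from their normal full conditionals and the error
#' sd from its scaled-inverse-\eqn{\chi^2} full conditional. The response is
#' centred internally; the centring constant is stored and restored at
#' prediction.
#'
#' @param design An `sr_design` from [assemble_design()], or a plain numeric
#'   matrix.
#' @param z Numeric response in logit units (see [to_logit()]).
#' @param config A [bart_config()].
#' @param transform Optional [sr_transform()] recorded with the fit so that
#'   downstream prediction can return ratio units.
#' @param db_trace If `TRUE`, records the grow log-acceptance-ratio and its
#'   reversing prune log-ratio for every admissible grow proposal (a detailed
#'   balance diagnostic).
#' @param fixed_sigma For diagnostics only: a positive value freezes the error
#'   sd at that value instead of sampling it.
#' @return A `bart_fit` object.
#' @export
fit_bart <- function(design, z, config = bart_config(),
                     transform = NULL, db_trace = FALSE,
                     fixed_sigma = NULL) {
  x <- .design_matrix(design)
  stopifnot(is.numeric(z), nrow(x) == length(z))
  if (any(!is.finite(z))) stop("non-finite response")
  if (!is.null(config$seed)) set.seed(config$seed)
  center <- mean(z)
  zc <- z - center
  rng <- diff(range(zc))
  sigma_mu <- max(rng / (2 * config$k * sqrt(config$m)), 1e-6)
  sighat <- if (ncol(x) < nrow(x)) {
    fitlm <- try(suppressWarnings(lm(zc ~ x)), silent = TRUE)
    if (inherits(fitlm, "try-error")) sd(zc) else sd(resid(fitlm))
  } else sd(zc)
  sighat <- max(sighat, 1e-6, na.rm = TRUE)
  lambda <- sighat^2 * stats::qchisq(1 - config$q, config$nu) / config$nu
  cutpoints <- lapply(seq_len(ncol(x)), function(jj)
    .make_cutpoints(x[, jj], config$n_cutpoints))
  if (all(vapply(cutpoints, length, 1L) == 0)) {
    stop("degenerate design: no admissible cutpoints on any variable")
  }
  res <- cpp_bart(x, zc, config$m, config$alpha, config$beta, sigma_mu,
                  config$nu, lambda,
                  if (is.null(fixed_sigma)) sighat else fixed_sigma,
                  config$move_probs, cutpoints, config$n_burn, config$n_draw,
                  config$thin, is.null(fixed_sigma), db_trace)
  structure(list(
    nodes = res$nodes, tree_sizes = res$tree_sizes, sigma = res$sigma,
    split_counts = setNames(res$split_counts, colnames(x)),
    center = center, sigma_mu = sigma_mu, lambda = lambda,
    config = config, col_names = colnames(x),
    col_info = if (inherits(design, "sr_design")) design$col_info else NULL,
    type_levels = if (inherits(design, "sr_design")) design$type_levels
                  else NULL,
    transform = transform, cutpoints = cutpoints,
    db_trace = if (db_trace) list(grow = res$db_grow,
                                  prune_rev = res$db_prune_rev) else NULL
  ), class = "bart_fit")
}

#' @export
print.bart_fit <- function(x, ...) {
  cat(sprintf(
    "<bart_fit> %d trees, %d retained draws, %d predictors\n  posterior mean sigma (logit units): %.4f\n",
    x$config$m, length(x$sigma), length(x$col_names), mean(x$sigma)))
  invisible(x)
}

#' Posterior draws of the sum-of-trees function at new inputs
#'
#' @param object A `bart_fit`.
#' @param newdata An `sr_design` or numeric matrix with the training columns.
#' @param posterior_predictive If `TRUE`, adds \eqn{N(0, \sigma_d^2)}
#'   observation noise per draw, giving posterior-predictive draws for new
#'   observations; if `FALSE` (default), returns noiseless mean-function
#'   draws.
#' @param ... Unused.
#' @return Matrix of logit-scale draws, rows = input rows, columns = retained
#'   posterior draws.
#' @export
predict.bart_fit <- function(object, newdata, posterior_predictive = FALSE,
                             ...) {
  x <- .design_matrix(newdata)
  if (!is.null(object$col_names) && !is.null(colnames(x)) &&
      !identical(colnames(x), object$col_names)) {
    stop("design columns do not match the fitted model")
  }
  if (ncol(x) != length(object$split_counts)) {
    stop("design columns do not match the fitted model")
  }
  n_draw <- length(object$sigma)
  draws <- cpp_bart_predict(object$nodes, object$tree_sizes, x, n_draw,
                            object$config$m) + object$center
  if (posterior_predictive) {
    draws <- draws + matrix(rnorm(length(draws)), nrow(x), n_draw) *
      rep(object$sigma, each = nrow(x))
  }
  draws
}

#' Split-frequency variable importance
#'
#' The proportion of all split rules, across every tree of every retained
#' draw, that use each design column.
#'
#' @param fit A `bart_fit`.
#' @return Tibble with columns `name`, `splits`, `proportion` (sums to 1).
#' @export
variable_importance <- function(fit) {
  stopifnot(inherits(fit, "bart_fit"))
  total <- sum(fit$split_counts)
  prop <- if (total == 0) {
    warning("posterior contains no splits; importance undefined")
    rep(0, length(fit$split_counts))
  } else fit$split_counts / total
  tibble::tibble(
    name = if (is.null(names(fit$split_counts)))
      paste0("x", seq_along(fit$split_counts)) else names(fit$split_counts),
    splits = unname(fit$split_counts), proportion = unname(prop))
}

#' Log marginal likelihood of a leaf's residuals
#'
#' Closed form of \eqn{\log \int \prod_i N(r_i \mid \mu, \sigma^2)
#' N(\mu \mid 0, \sigma_\mu^2)\, d\mu}, the quantity the
#' Metropolis--Hastings tree moves compare. `n = 0` returns 0 (empty
#' product).
#'
#' @param n Number of residuals in the leaf.
#' @param sum_r,sum_r2 Sum and sum of squares of the residuals.
#' @param sigma Error sd; `sigma_mu` leaf prior sd. Both positive.
#' @param sigma_mu Leaf prior sd.
#' @return Log marginal likelihood (scalar).
#' @export
leaf_log_marginal <- function(n, sum_r, sum_r2, sigma, sigma_mu) {
  cpp_leaf_log_marginal(n, sum_r, sum_r2, sigma, sigma_mu)
}

#' Draw from the error-sd full conditional
#'
#' \eqn{\sigma^2 \sim (\nu\lambda + \sum r_i^2) / \chi^2_{\nu + n}}; with no
#' residuals this is the prior. Uses R's RNG, so draws are reproducible under
#' `set.seed()`.
#'
#' @param residuals Numeric vector (may be empty for prior draws).
#' @param nu,lambda Prior degrees of freedom and scale, both positive.
#' @param n_draws Number of draws.
#' @return Numeric vector of sd (not variance) draws.
#' @export
draw_sigma <- function(residuals, nu, lambda, n_draws = 1) {
  cpp_draw_sigma(as.numeric(residuals), nu, lambda, as.integer(n_draws))
}

.num_out <- function(x) sprintf("%.17g", x)

#' Serialize a fitted posterior to a single JSON file
#'
#' The container is versioned and lossless: every double is stored as a
#' 17-significant-digit decimal string, which round-trips IEEE doubles
#' exactly.
#'
#' @param fit A `bart_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bart <- function(fit, path) {
  stopifnot(inherits(fit, "bart_fit"))
  payload <- list(
    container = "srscape-bart-posterior", version = 1L,
    m = fit$config$m, n_draw = length(fit$sigma),
    config = fit$config[setdiff(names(fit$config), "move_probs")],
    move_probs = .num_out(fit$config$move_probs),
    nodes = .num_out(as.numeric(fit$nodes)),
    n_nodes = nrow(fit$nodes),
    tree_sizes = fit$tree_sizes,
    sigma = .num_out(fit$sigma),
    split_counts = .num_out(unname(fit$split_counts)),
    center = .num_out(fit$center), sigma_mu = .num_out(fit$sigma_mu),
    lambda = .num_out(fit$lambda),
    col_names = fit$col_names, type_levels = fit$type_levels,
    transform = if (!is.null(fit$transform))
      lapply(unclass(fit$transform), .num_out)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a serialized posterior
#'
#' @param path Path written by [write_bart()].
#' @return A `bart_fit`.
#' @export
read_bart <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$container, "srscape-bart-posterior")) {
    stop("not an srscape posterior container: ", path)
  }
  if (p$version != 1L) stop("unsupported container version: ", p$version)
  cfg <- p$config
  cfg$move_probs <- as.numeric(p$move_probs)
  cfg <- structure(cfg[c("m", "alpha", "beta", "k", "nu", "q", "n_burn",
                         "n_draw", "thin", "move_probs", "n_cutpoints",
                         "seed")], class = "bart_config")
  nodes <- matrix(as.numeric(p$nodes), nrow = p$n_nodes, ncol = 5)
  colnames(nodes) <- c("var", "cut", "left", "right", "value")
  structure(list(
    nodes = nodes, tree_sizes = as.integer(p$tree_sizes),
    sigma = as.numeric(p$sigma),
    split_counts = setNames(as.numeric(p$split_counts), p$col_names),
    center = as.numeric(p$center), sigma_mu = as.numeric(p$sigma_mu),
    lambda = as.numeric(p$lambda), config = cfg,
    col_names = p$col_names, col_info = NULL,
    type_levels = p$type_levels,
    transform = if (!is.null(p$transform))
      sr_transform(as.numeric(p$transform$lower),
                   as.numeric(p$transform$upper),
                   as.numeric(p$transform$epsilon)),
    cutpoints = NULL, db_trace = NULL
  ), class = "bart_fit")
}
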