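test_that("leaf marginal likelihood matches adaptive quadrature", {
  expect_equal(leaf_log_marginal(0, 0, 0, 1, 1), 0)
  expect_equal(leaf_log_marginal(1, 0, 0, 1, 1), dnorm(0, 0, sqrt(2),
                                                       log = TRUE),
               tolerance = 1e-10)
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:5, 1)
    r <- rnorm(n, 0, 0.8)
    sigma <- runif(1, 0.3, 2)
    sigma_mu <- runif(1, 0.2, 1.5)
    oracle <- log(integrate(function(mu) {
      vapply(mu, function(m)
        prod(dnorm(r, m, sigma)) * dnorm(m, 0, sigma_mu), 0)
    }, -Inf, Inf, rel.tol = 1e-12)$value)
    got <- leaf_log_marginal(n, sum(r), sum(r^2), sigma, sigma_mu)
    expect_equal(got, oracle, tolerance = 1e-8)
  }
  expect_error(leaf_log_marginal(1, NaN, 1, 1, 1), "non-finite")
  expect_error(leaf_log_marginal(1, 0, 1, -1, 1))
})

test_that("leaf full conditional matches its quadrature moments", {
  # mu | r ~ N(sigma_mu^2 sum r / (sigma^2 + n sigma_mu^2), ...)
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(2:6, 1)
    r <- rnorm(n, 0.5, 1)
    sigma <- runif(1, 0.4, 1.5)
    sigma_mu <- runif(1, 0.3, 1.2)
    norm <- integrate(function(mu) vapply(mu, function(m)
      prod(dnorm(r, m, sigma)) * dnorm(m, 0, sigma_mu), 0),
      -Inf, Inf, rel.tol = 1e-12)$value
    m1 <- integrate(function(mu) vapply(mu, function(m)
      m * prod(dnorm(r, m, sigma)) * dnorm(m, 0, sigma_mu), 0),
      -Inf, Inf, rel.tol = 1e-12)$value / norm
    m2 <- integrate(function(mu) vapply(mu, function(m)
      m^2 * prod(dnorm(r, m, sigma)) * dnorm(m, 0, sigma_mu), 0),
      -Inf, Inf, rel.tol = 1e-12)$value / norm
    post_var <- 1 / (n / sigma^2 + 1 / sigma_mu^2)
    post_mean <- post_var * sum(r) / sigma^2
    expect_equal(post_mean, m1, tolerance = 1e-8)
    expect_equal(post_var, m2 - m1^2, tolerance = 1e-8)
  }
})

test_that("sigma draws reproduce the prior moments with no data", {
  nu <- 6; lambda <- 0.4
  set.seed(13)
  draws <- draw_sigma(numeric(0), nu, lambda, 1e5)
  # prior mean of sigma^2 is nu*lambda/(nu-2)
  expect_equal(mean(draws^2), nu * lambda / (nu - 2), tolerance = 0.02)
  set.seed(13)
  expect_identical(draw_sigma(numeric(0), nu, lambda, 5),
                   {set.seed(13); draw_sigma(numeric(0), nu, lambda, 5)})
  # large n with tiny residuals concentrates near zero
  small <- draw_sigma(rep(1e-8, 5000), 3, 1e-10, 100)
  expect_lt(max(small), 1e-3)
})

test_that("a constant response is recovered exactly and deterministically", {
  set.seed(14)
  x <- matrix(runif(200), 100, 2)
  colnames(x) <- c("x1", "x2")
  cfg <- bart_config(m = 20, n_burn = 100, n_draw = 100, seed = 3)
  fit <- fit_bart(x, rep(2.5, 100), cfg)
  pred <- predict(fit, x)
  expect_lt(max(abs(pred - 2.5)), 1e-6)
  fit2 <- fit_bart(x, rep(2.5, 100), cfg)
  expect_identical(fit$sigma, fit2$sigma)
  expect_identical(fit$nodes, fit2$nodes)
})

test_that("a step function is recovered with held-out accuracy", {
  set.seed(15)
  n <- 500
  x <- matrix(runif(n * 2, -1, 1), n, 2)
  colnames(x) <- c("x1", "x2")
  z <- as.numeric(x[, 1] > 0) + rnorm(n, 0, 0.1)
  fit <- fit_bart(x, z, bart_config(seed = 15))  # default configuration
  xt <- matrix(runif(1000, -1, 1), 500, 2)
  colnames(xt) <- c("x1", "x2")
  pred <- rowMeans(predict(fit, xt))
  expect_lt(sqrt(mean((pred - as.numeric(xt[, 1] > 0))^2)), 0.15)
  vi <- variable_importance(fit)
  expect_equal(sum(vi$proportion), 1, tolerance = 1e-12)
  expect_gt(vi$proportion[vi$name == "x1"], vi$proportion[vi$name == "x2"])
})

test_that("grow proposals and their reversing prunes balance exactly", {
  set.seed(16)
  x <- matrix(runif(160), 80, 2)
  colnames(x) <- c("x1", "x2")
  z <- sin(4 * x[, 1]) + rnorm(80, 0, 0.2)
  fit <- fit_bart(x, z, bart_config(m = 10, n_burn = 400, n_draw = 400,
                                    seed = 5), db_trace = TRUE)
  expect_gt(length(fit$db_trace$grow), 1000)
  expect_lt(max(abs(fit$db_trace$grow + fit$db_trace$prune_rev)), 1e-10)
})

test_that("single-tree posterior matches exhaustive enumeration", {
  x <- matrix(c(1, 2, 3, 4, 5, 6), 6, 1)
  colnames(x) <- "x1"
  z <- c(-1.0, -0.6, -0.1, 0.2, 0.7, 1.3)
  sig <- 0.5
  cfg <- bart_config(m = 1, n_burn = 2000, n_draw = 40000, n_cutpoints = 2,
                     seed = 5)
  fit <- fit_bart(x, z, cfg, fixed_sigma = sig)
  cuts <- fit$cutpoints[[1]]
  expect_length(cuts, 2)
  zc <- z - mean(z)
  sigma_mu <- fit$sigma_mu
  psplit <- function(d) cfg$alpha * (1 + d)^(-cfg$beta)
  llm <- function(r) leaf_log_marginal(length(r), sum(r), sum(r^2), sig,
                                       sigma_mu)
  # enumerate every tree with nonempty leaves over the cutpoint grid,
  # weighting by the generative tree prior times the marginal likelihood
  enum <- function(obs, d) {
    out <- list(list(sig = "L", lp = log(1 - psplit(d)) + llm(zc[obs])))
    for (ci in seq_along(cuts)) {
      l <- obs[x[obs, 1] <= cuts[ci]]
      r <- setdiff(obs, l)
      if (length(l) == 0 || length(r) == 0) next
      for (tl in enum(l, d + 1)) for (tr in enum(r, d + 1)) {
        out[[length(out) + 1]] <- list(
          sig = paste0("S", ci, "(", tl$sig, ",", tr$sig, ")"),
          lp = log(psplit(d)) - log(length(cuts)) + tl$lp + tr$lp)
      }
    }
    out
  }
  trees <- enum(1:6, 0)
  lp <- vapply(trees, `[[`, 0, "lp")
  exact <- exp(lp - max(lp))
  exact <- setNames(exact / sum(exact), vapply(trees, `[[`, "", "sig"))

  offs <- cumsum(c(0, fit$tree_sizes))
  sig_of <- function(k) {
    b <- offs[k]
    rec <- function(id) {
      if (fit$nodes[b + id, 1] == 0) return("L")
      ci <- which(abs(cuts - fit$nodes[b + id, 2]) < 1e-12)
      paste0("S", ci, "(", rec(fit$nodes[b + id, 3]), ",",
             rec(fit$nodes[b + id, 4]), ")")
    }
    rec(1)
  }
  emp <- table(vapply(seq_along(fit$tree_sizes), sig_of, "")) /
    length(fit$tree_sizes)
  for (s in names(exact)) {
    got <- if (s %in% names(emp)) as.numeric(emp[[s]]) else 0
    expect_lt(abs(got - unname(exact[[s]])), 0.02)
  }
})

test_that("retained draws are a prefix-stable stream", {
  set.seed(17)
  x <- matrix(runif(120), 60, 2)
  colnames(x) <- c("x1", "x2")
  z <- x[, 1] + rnorm(60, 0, 0.3)
  short <- fit_bart(x, z, bart_config(m = 5, n_burn = 50, n_draw = 10,
                                      seed = 9))
  long <- fit_bart(x, z, bart_config(m = 5, n_burn = 50, n_draw = 30,
                                     seed = 9))
  expect_identical(short$sigma, long$sigma[1:10])
  n_nodes_short <- sum(short$tree_sizes)
  expect_identical(short$nodes[seq_len(n_nodes_short), ],
                   long$nodes[seq_len(n_nodes_short), ])
})

test_that("prediction validates columns and orders its quantiles", {
  set.seed(18)
  x <- matrix(runif(200), 100, 2)
  colnames(x) <- c("x1", "x2")
  z <- x[, 1] + rnorm(100, 0, 0.2)
  fit <- fit_bart(x, z, bart_config(m = 20, n_burn = 100, n_draw = 200,
                                    seed = 2))
  expect_error(predict(fit, x[, 1, drop = FALSE]), "do not match")
  xm <- x[c(1, 1, 2), ]
  pred <- predict(fit, xm)
  expect_identical(pred[1, ], pred[2, ])
  qs <- apply(predict(fit, x, posterior_predictive = TRUE), 1, quantile,
              probs = c(0.025, 0.25, 0.5, 0.75, 0.975))
  expect_true(all(diff(qs) >= 0))
})

test_that("all-stump posteriors yield a zero importance vector with warning", {
  set.seed(19)
  x <- matrix(runif(100), 50, 2)
  colnames(x) <- c("x1", "x2")
  z <- rnorm(50)
  fit <- fit_bart(x, z, bart_config(m = 5, n_burn = 20, n_draw = 20,
                                    move_probs = c(0, 0, 0.6, 0.4),
                                    seed = 1))
  expect_warning(vi <- variable_importance(fit), "no splits")
  expect_equal(vi$proportion, c(0, 0))
})

test_that("posterior mean error shrinks as training size grows", {
  # seed-averaged parameter recovery on the synthetic landscape
  rmse_at <- function(n_train, seed) {
    cfg <- sim_config(n_samples = n_train, type_mix = c(plant = 1),
                      seed = seed)
    ls <- make_landscape(cfg)
    smp <- suppressMessages(filter_ratio_range(draw_samples(ls, cfg)$samples))
    stack <- landscape_stack(ls)
    bd <- build_design(stack, smp)
    tr <- sr_transform()
    fit <- fit_bart(bd$design, to_logit(smp$ratio, tr),
                    bart_config(m = 30, n_burn = 250, n_draw = 250,
                                seed = seed + 1), transform = tr)
    iso <- predict_isoscape(fit, stack, bd$pca, "plant",
                            posterior_predictive = FALSE)
    recovery_report(ls, iso)$rmse
  }
  sizes <- c(50, 200, 800)
  avg <- vapply(sizes, function(n)
    mean(vapply(1:3, function(s) rmse_at(n, s), 0)), 0)
  expect_true(all(diff(avg) < 0))
})

test_that("posterior containers round-trip losslessly through JSON", {
  set.seed(20)
  x <- matrix(runif(100), 50, 2)
  colnames(x) <- c("x1", "x2")
  z <- x[, 1] + rnorm(50, 0, 0.2)
  fit <- fit_bart(x, z, bart_config(m = 8, n_burn = 50, n_draw = 40,
                                    seed = 4), transform = sr_transform())
  path <- withr::local_tempfile(fileext = ".json")
  write_bart(fit, path)
  back <- read_bart(path)
  expect_identical(back$nodes, fit$nodes)
  expect_identical(back$sigma, fit$sigma)
  expect_identical(back$center, fit$center)
  expect_equal(back$transform, fit$transform)
  expect_identical(predict(back, x), predict(fit, x))
  expect_error(suppressWarnings(
    read_bart(withr::local_tempfile(fileext = ".json"))))
})
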