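make_grid <- function(n = 4) grid_spec(0, n, 1, n, n, crs_id = "test")

test_that("ASCII grid files round-trip values, nodata, and georeferencing", {
  g <- make_grid(5)
  m <- matrix(rnorm(25), 5, 5)
  m[2, 3] <- NA
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(m, g, path)
  back <- read_ascii_grid(path, crs_id = "test")
  expect_equal(back$values, m, tolerance = 1e-8)
  expect_true(is.na(back$values[2, 3]))
  expect_equal(back$grid$origin_x, g$origin_x)
  expect_equal(back$grid$origin_y, g$origin_y)
  expect_equal(back$grid$cell_size, g$cell_size)
})

test_that("stack assembly enforces aligned grids and known blocks", {
  g <- make_grid(3)
  a <- matrix(1:9, 3, 3)
  b <- matrix(9:1, 3, 3)
  st <- predictor_stack(g, list(p1 = a, p2 = b),
                        c(p1 = "climate", p2 = "soil"))
  expect_named(st$bands, c("p1", "p2"))
  g2 <- grid_spec(0, 3, 0.5, 3, 3, crs_id = "test")
  expect_error(load_stack(list(p1 = list(grid = g, values = a),
                               p2 = list(grid = g2, values = b)),
                          c(p1 = "climate", p2 = "soil")),
               "grid mismatch")
  g3 <- grid_spec(0, 3, 1, 3, 3, crs_id = "other")
  expect_error(load_stack(list(p1 = list(grid = g, values = a),
                               p2 = list(grid = g3, values = b)),
                          c(p1 = "climate", p2 = "soil")),
               "CRS mismatch")
  expect_error(predictor_stack(g, list(p1 = a), c(p1 = "weather")),
               "unknown block")
  expect_error(predictor_stack(g, list(p1 = a), c(p2 = "climate")),
               "no block assigned")
})

test_that("point extraction follows the half-open cell convention", {
  g <- grid_spec(0, 2, 1, 2, 2, crs_id = "test")
  vals <- matrix(c(11, 21, 12, 22), 2, 2)  # vals[row, col]
  st <- predictor_stack(g, list(v = vals), c(v = "other"))
  # cell centres
  ex <- extract_covariates(st, c(0.5, 1.5, 0.5, 1.5), c(1.5, 1.5, 0.5, 0.5))
  expect_equal(ex$v, c(11, 12, 21, 22))
  # a point on the shared edge x = 1 belongs to the second column
  edge <- extract_covariates(st, 1, 1.5)
  expect_equal(edge$col, 2L)
  expect_equal(edge$v, 12)
  # outside the extent: missing marker plus a warning
  expect_warning(out <- extract_covariates(st, 5, 5), "outside")
  expect_true(is.na(out$v))
  # masked cell propagates missingness
  vals2 <- vals; vals2[1, 1] <- NA
  st2 <- predictor_stack(g, list(v = vals2), c(v = "other"))
  expect_warning(m <- extract_covariates(st2, 0.5, 1.5), "masked")
  expect_true(is.na(m$v))
})

test_that("extraction is invariant to translating grid and points together", {
  g <- grid_spec(0, 8, 1, 8, 8, crs_id = "test")
  vals <- matrix(rnorm(64), 8, 8)
  st <- predictor_stack(g, list(v = vals), c(v = "other"))
  set.seed(2)
  x <- runif(20, 0, 8); y <- runif(20, 0, 8)
  shift <- c(101.5, -40.25)
  g2 <- grid_spec(shift[1], 8 + shift[2], 1, 8, 8, crs_id = "test")
  st2 <- predictor_stack(g2, list(v = vals), c(v = "other"))
  expect_equal(extract_covariates(st2, x + shift[1], y + shift[2])$v,
               extract_covariates(st, x, y)$v)
})

test_that("blocked PCA matches a brute-force eigendecomposition", {
  set.seed(7)
  rows <- as.data.frame(matrix(rnorm(50 * 6), 50, 6))
  names(rows) <- paste0("v", 1:6)
  blocks <- c(v1 = "climate", v2 = "climate", v3 = "climate",
              v4 = "soil", v5 = "soil", v6 = "soil")
  pca <- fit_blocked_pca(rows, blocks, var_threshold = 1.0)
  for (b in c("climate", "soil")) {
    blk <- pca$blocks[[b]]
    xs <- scale(as.matrix(rows[, blk$vars]))
    eig <- eigen(cov(xs), symmetric = TRUE)   # independent eigen-solver
    expect_equal(blk$eigenvalues, eig$values, tolerance = 1e-8)
    expect_true(all(diff(blk$eigenvalues) <= 1e-10))
    # loadings agree up to per-component sign
    for (k in seq_len(3)) {
      expect_equal(abs(sum(blk$rotation[, k] * eig$vectors[, k])), 1,
                   tolerance = 1e-8)
    }
    # orthonormality: Gram matrix is the identity
    expect_equal(crossprod(blk$rotation), diag(3), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(blk$k, 3)  # var_threshold 1 retains every component
    # reconstruction with all components is lossless
    scores <- xs %*% blk$rotation
    expect_equal(scores %*% t(blk$rotation), xs, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("perfectly correlated variables collapse to one component", {
  set.seed(8)
  v <- rnorm(30)
  rows <- data.frame(a = v, b = 2 * v + 1, c = rnorm(30), d = rnorm(30))
  pca <- fit_blocked_pca(rows, c(a = "climate", b = "climate",
                                 c = "soil", d = "soil"),
                         var_threshold = 0.8)
  expect_equal(pca$blocks$climate$k, 1)
  expect_equal(pca$blocks$climate$eigenvalues[1] / 2, 1, tolerance = 1e-8)
  expect_error(fit_blocked_pca(rows[1, ], c(a = "climate", b = "climate")))
  expect_warning(
    fit_blocked_pca(cbind(rows, e = 1),
                    c(a = "climate", b = "climate", e = "climate")),
    "constant")
})

test_that("design assembly yields the contracted columns deterministically", {
  set.seed(9)
  rows <- as.data.frame(matrix(rnorm(40 * 7), 40, 7))
  names(rows) <- c(paste0("c", 1:3), paste0("s", 1:2), "dist", "age")
  blocks <- c(c1 = "climate", c2 = "climate", c3 = "climate",
              s1 = "soil", s2 = "soil", dist = "distance", age = "geology")
  pca <- fit_blocked_pca(rows, blocks, var_threshold = 0.8,
                         passthrough = c("distance", "geology"))
  types <- sample(c("plant", "water", "human"), 40, replace = TRUE)
  des <- assemble_design(rows, pca, types)
  k_total <- sum(vapply(pca$blocks, `[[`, 1L, "k"))
  expect_equal(ncol(des$x), k_total + 2 + 3)
  onehot <- des$x[, des$col_info$kind == "type", drop = FALSE]
  expect_true(all(rowSums(onehot) == 1))
  expect_identical(assemble_design(rows, pca, types)$x, des$x)
  # PC scores reproduce the oracle eigendecomposition scores
  blk <- pca$blocks$climate
  xs <- scale(as.matrix(rows[, blk$vars]))
  oracle <- xs %*% eigen(cov(xs), symmetric = TRUE)$vectors
  got <- des$x[, paste0("climate_PC", seq_len(blk$k)), drop = FALSE]
  for (k in seq_len(blk$k)) {
    expect_equal(abs(cor(got[, k], oracle[, k])), 1, tolerance = 1e-8)
  }
  expect_error(assemble_design(rows, pca, "fauna",
                               type_levels = des$type_levels),
               "not seen in training")
  rows_na <- rows; rows_na$c1[3] <- NA
  expect_error(assemble_design(rows_na, pca, "plant"), "missing values")
  expect_error(assemble_design(rows[, -7], pca, "plant"),
               "missing covariate")
})
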