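#' Grid specification for gridded covariates
#'
#' Grids are north-up and row-major with the origin at the upper-left corner.
#' Cell `(row, col)` (1-based) covers the half-open box
#' `[origin_x + (col-1)*cell, origin_x + col*cell)` by
#' `(origin_y - row*cell, origin_y - (row-1)*cell]`.
#'
#' @param origin_x,origin_y Coordinates of the grid's upper-left corner
#'   (degrees for geographic grids, metres/kilometres for projected ones).
#' @param cell_size Cell edge length, same units as the origin; positive.
#' @param n_rows,n_cols Grid dimensions.
#' @param crs_id Free-text identifier of the coordinate reference system.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin_x, origin_y, cell_size, n_rows, n_cols,
                      crs_id = "unspecified") {
  stopifnot(cell_size > 0, n_rows >= 1, n_cols >= 1)
  structure(list(origin_x = origin_x, origin_y = origin_y,
                 cell_size = cell_size, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), crs_id = crs_id),
            class = "grid_spec")
}

grids_equal <- function(a, b, tol = 1e-9) {
  abs(a$origin_x - b$origin_x) < tol && abs(a$origin_y - b$origin_y) < tol &&
    abs(a$cell_size - b$cell_size) < tol && a$n_rows == b$n_rows &&
    a$n_cols == b$n_cols
}

#' Cell-centre coordinates of every grid cell
#'
#' @param grid A [grid_spec()].
#' @return Tibble with columns `row`, `col`, `x`, `y` in row-major order.
#' @export
grid_cell_centers <- function(grid) {
  rc <- expand.grid(col = seq_len(grid$n_cols), row = seq_len(grid$n_rows))
  tibble::tibble(
    row = rc$row, col = rc$col,
    x = grid$origin_x + (rc$col - 0.5) * grid$cell_size,
    y = grid$origin_y - (rc$row - 0.5) * grid$cell_size
  )
}

#' Read a raster from an ESRI ASCII grid file
#'
#' @param path Path to a `.asc` file.
#' @param crs_id CRS identifier to record on the grid (the format itself does
#'   not carry one).
#' @return A list with elements `grid` ([grid_spec()]) and `values` (numeric
#'   matrix, `NA` for nodata).
#' @export
read_ascii_grid <- function(path, crs_id = "unspecified") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^[a-zA-Z]", trimws(lines[i]))) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path)
  }
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ASCII grid data size does not match header in ", path)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  grid <- grid_spec(hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize,
                    hdr$cellsize, hdr$nrows, hdr$ncols, crs_id)
  list(grid = grid, values = m)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' @param values Numeric matrix (rows = grid rows, north first).
#' @param grid A [grid_spec()].
#' @param path Output path.
#' @param nodata Value used to encode `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  stopifnot(nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  hdr <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$origin_x),
    sprintf("yllcorner %.10g", grid$origin_y - grid$n_rows * grid$cell_size),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(values, 1, function(row) {
    row[is.na(row)] <- nodata
    paste(sprintf("%.9g", row), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Assemble aligned covariate rasters into a predictor stack
#'
#' @param paths Named character vector of raster file paths (names become band
#'   names), or an already-read named list of `list(grid, values)` entries.
#' @param block_map Named character vector mapping band names to domain blocks
#'   (`climate`, `soil`, `geology`, `aerosol`, `terrain`, `distance`,
#'   `other`).
#' @param crs_id CRS identifier shared by the rasters.
#' @return A `predictor_stack`: list with `grid`, `bands` (named list of
#'   matrices), `blocks`, and `mask` (logical matrix, `TRUE` where any band is
#'   missing).
#' @export
load_stack <- function(paths, block_map, crs_id = "unspecified") {
  blocks_ok <- c("climate", "soil", "geology", "aerosol", "terrain",
                 "distance", "other")
  if (is.null(names(paths)) || any(names(paths) == "")) {
    stop("paths must be named (band names)")
  }
  rasters <- if (is.character(paths)) {
    lapply(paths, read_ascii_grid, crs_id = crs_id)
  } else paths
  if (anyDuplicated(names(rasters))) stop("duplicate band names")
  missing_blocks <- setdiff(names(rasters), names(block_map))
  if (length(missing_blocks) > 0) {
    stop("no block assigned for band(s): ",
         paste(missing_blocks, collapse = ", "))
  }
  bad <- setdiff(unname(block_map[names(rasters)]), blocks_ok)
  if (length(bad) > 0) stop("unknown block(s): ", paste(bad, collapse = ", "))
  grid <- rasters[[1]]$grid
  for (nm in names(rasters)) {
    if (!grids_equal(grid, rasters[[nm]]$grid)) {
      stop("grid mismatch for band ", nm)
    }
    if (!identical(grid$crs_id, rasters[[nm]]$grid$crs_id)) {
      stop("CRS mismatch for band ", nm)
    }
  }
  bands <- lapply(rasters, `[[`, "values")
  mask <- Reduce(`|`, lapply(bands, is.na))
  structure(list(grid = grid, bands = bands,
                 blocks = block_map[names(bands)], mask = mask),
            class = "predictor_stack")
}

#' Build a predictor stack from in-memory matrices
#'
#' @param grid A [grid_spec()].
#' @param bands Named list of numeric matrices on `grid`.
#' @param block_map Named character vector mapping band names to blocks.
#' @return A `predictor_stack`.
#' @export
predictor_stack <- function(grid, bands, block_map) {
  load_stack(lapply(bands, function(v) list(grid = grid, values = v)),
             block_map, crs_id = grid$crs_id)
}

.cell_index <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row <- floor((grid$origin_y - y) / grid$cell_size) + 1
  # points exactly on the top/left extent boundary belong to the first cell;
  # the bottom/right boundary is outside (half-open convention)
  inside <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  list(row = ifelse(inside, row, NA_integer_),
       col = ifelse(inside, col, NA_integer_), inside = inside)
}

#' Extract covariate values at point locations
#'
#' Nearest-cell (containing-cell) lookup under the half-open grid convention.
#' Points outside the extent or on masked cells yield `NA` rows and a warning.
#'
#' @param stack A `predictor_stack`.
#' @param x,y Point coordinates in the stack's CRS.
#' @return Tibble with `row`, `col`, and one column per band.
#' @export
extract_covariates <- function(stack, x, y) {
  stopifnot(inherits(stack, "predictor_stack"), length(x) == length(y))
  idx <- .cell_index(stack$grid, x, y)
  n <- length(x)
  out <- tibble::tibble(row = as.integer(idx$row), col = as.integer(idx$col))
  flat <- ifelse(idx$inside, (idx$col - 1L) * stack$grid$n_rows + idx$row, NA)
  masked <- !is.na(flat) & stack$mask[cbind(idx$row, idx$col)]
  flat[masked] <- NA
  for (nm in names(stack$bands)) {
    v <- rep(NA_real_, n)
    ok <- !is.na(flat)
    v[ok] <- stack$bands[[nm]][cbind(idx$row[ok], idx$col[ok])]
    out[[nm]] <- v
  }
  n_bad <- sum(!idx$inside | masked)
  if (n_bad > 0) {
    warning(sprintf("%d point(s) outside the extent or on masked cells", n_bad))
  }
  out
}

#' Fit domain-blocked principal component reductions
#'
#' Within each domain block the variables are centred, scaled to unit
#' variance, and eigen-decomposed; the smallest number of leading components
#' whose cumulative explained variance reaches `var_threshold` is retained.
#' Blocks named in `passthrough` (by default the `distance` block, whose
#' variables are interpretable individually) and blocks with fewer than two
#' variables are passed through untransformed. Constant variables are dropped
#' with a warning.
#'
#' @param rows Data frame of covariate values (samples or cells in rows).
#' @param blocks Named character vector mapping column names to blocks.
#' @param var_threshold Retained-variance fraction in `(0, 1]`.
#' @param passthrough Character vector of block names exempt from PCA.
#' @return A `blocked_pca` model.
#' @export
fit_blocked_pca <- function(rows, blocks, var_threshold = 0.8,
                            passthrough = "distance") {
  stopifnot(nrow(rows) >= 2, var_threshold > 0, var_threshold <= 1)
  rows <- as.data.frame(rows)
  vars <- intersect(names(rows), names(blocks))
  if (length(vars) == 0) stop("no covariate columns matched to blocks")
  const <- vars[vapply(vars, function(v) sd(rows[[v]]) == 0, logical(1))]
  if (length(const) > 0) {
    warning("dropping constant variable(s): ", paste(const, collapse = ", "))
    vars <- setdiff(vars, const)
  }
  model <- list(blocks = list(), passthrough_vars = character(),
                var_threshold = var_threshold)
  for (b in unique(unname(blocks[vars]))) {
    bv <- vars[blocks[vars] == b]
    if (b %in% passthrough || length(bv) < 2) {
      model$passthrough_vars <- c(model$passthrough_vars, bv)
      next
    }
    p <- prcomp(rows[, bv, drop = FALSE], center = TRUE, scale. = TRUE)
    ev <- p$sdev^2
    k <- which(cumsum(ev) / sum(ev) >= var_threshold - 1e-12)[1]
    model$blocks[[b]] <- list(
      vars = bv, center = p$center, scale = p$scale,
      rotation = p$rotation, eigenvalues = ev, k = k
    )
  }
  structure(model, class = "blocked_pca")
}

#' Assemble a design matrix of PC scores, passthrough covariates, and
#' sample-type indicators
#'
#' PC scores are computed with the training means and scales stored in the
#' fitted [fit_blocked_pca()] model, so design assembly is deterministic given
#' the model. One-hot indicator columns are created for each sample type in
#' `type_levels`; at prediction time a type outside the training levels is an
#' error.
#'
#' @param rows Data frame of covariate values with no missing entries.
#' @param pca A `blocked_pca` model.
#' @param sample_types Character vector (length 1, recycled, or one per row).
#' @param type_levels Types seen in training. `NULL` (training-time) uses the
#'   sorted unique values of `sample_types`.
#' @return An `sr_design`: list with `x` (numeric matrix), `col_info`
#'   (tibble: name, kind, block), and `type_levels`.
#' @export
assemble_design <- function(rows, pca, sample_types, type_levels = NULL) {
  stopifnot(inherits(pca, "blocked_pca"))
  rows <- as.data.frame(rows)
  sample_types <- rep_len(as.character(sample_types), nrow(rows))
  if (is.null(type_levels)) {
    type_levels <- sort(unique(sample_types))
  } else if (!all(sample_types %in% type_levels)) {
    stop("sample type(s) not seen in training: ",
         paste(setdiff(unique(sample_types), type_levels), collapse = ", "))
  }
  needed <- c(unlist(lapply(pca$blocks, `[[`, "vars")), pca$passthrough_vars)
  missing_cov <- setdiff(needed, names(rows))
  if (length(missing_cov) > 0) {
    stop("missing covariate(s): ", paste(missing_cov, collapse = ", "))
  }
  if (anyNA(rows[, needed, drop = FALSE])) {
    stop("missing values in covariate rows; drop or impute before assembly")
  }
  cols <- list()
  info <- list()
  for (b in names(pca$blocks)) {
    blk <- pca$blocks[[b]]
    xs <- scale(as.matrix(rows[, blk$vars, drop = FALSE]),
                center = blk$center, scale = blk$scale)
    sc <- xs %*% blk$rotation[, seq_len(blk$k), drop = FALSE]
    colnames(sc) <- paste0(b, "_PC", seq_len(blk$k))
    cols[[length(cols) + 1]] <- sc
    info[[length(info) + 1]] <- tibble::tibble(
      name = colnames(sc), kind = "pc", block = b)
  }
  if (length(pca$passthrough_vars) > 0) {
    pt <- as.matrix(rows[, pca$passthrough_vars, drop = FALSE])
    cols[[length(cols) + 1]] <- pt
    info[[length(info) + 1]] <- tibble::tibble(
      name = pca$passthrough_vars, kind = "passthrough",
      block = "passthrough")
  }
  onehot <- vapply(type_levels, function(tl) as.numeric(sample_types == tl),
                   numeric(nrow(rows)))
  if (nrow(rows) == 1L) onehot <- matrix(onehot, nrow = 1)
  colnames(onehot) <- paste0("type_", type_levels)
  cols[[length(cols) + 1]] <- onehot
  info[[length(info) + 1]] <- tibble::tibble(
    name = colnames(onehot), kind = "type", block = "type")
  x <- do.call(cbind, cols)
  rownames(x) <- NULL
  structure(list(x = x, col_info = do.call(rbind, info),
                 type_levels = type_levels),
            class = "sr_design")
}
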