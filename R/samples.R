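#' Sample-set data model
#'
#' A sample set is a tibble with one row per georeferenced
#' \eqn{^{87}Sr/^{86}Sr} measurement and class `sr_samples`. Required columns
#' are `sample_id`, `site`, `lon`, `lat`, `sample_type`, and `ratio`; optional
#' columns are `elevation`, `species`, `rooting_depth`, `se2` (the 2-SE
#' analytical precision), `flags` (semicolon-separated QC flags), `region_tag`,
#' and `source_tag`. `sample_id` must be unique within a set.
#'
#' @name sr_samples
NULL

.sr_flag_levels <- c("fertilizer_contaminated", "nonlocal_human",
                     "out_of_range", "site_outlier")
.sr_sample_types <- c("plant", "water", "human", "fauna", "soil", "rock",
                      "other")
.sr_rooting_depths <- c("shallow", "deep", "unknown")

.sr_optional_cols <- function() {
  list(elevation = NA_real_, species = NA_character_,
       rooting_depth = "unknown", se2 = NA_real_, flags = "",
       region_tag = NA_character_, source_tag = NA_character_)
}

#' Construct and validate a sample set
#'
#' @param data A data frame with the columns described in [sr_samples].
#' @param metadata Optional free-form provenance notes (character).
#' @return A tibble of class `sr_samples`.
#' @export
as_sr_samples <- function(data, metadata = character()) {
  data <- tibble::as_tibble(data)
  required <- c("sample_id", "site", "lon", "lat", "sample_type", "ratio")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(data) == 0) stop("no records")
  for (nm in names(.sr_optional_cols())) {
    if (!nm %in% names(data)) data[[nm]] <- .sr_optional_cols()[[nm]]
  }
  data$sample_id <- as.character(data$sample_id)
  data$flags <- ifelse(is.na(data$flags), "", as.character(data$flags))
  dup <- duplicated(data$sample_id)
  if (any(dup)) {
    stop("duplicate sample_id: ",
         paste(unique(data$sample_id[dup]), collapse = ", "))
  }
  if (any(!is.na(data$ratio) & data$ratio <= 0)) stop("ratio must be > 0")
  if (any(!is.na(data$se2) & data$se2 < 0)) stop("se2 must be >= 0")
  if (any(abs(data$lat) > 90, na.rm = TRUE) ||
      any(abs(data$lon) > 180, na.rm = TRUE)) {
    stop("coordinates outside WGS84 bounds")
  }
  bad_type <- !data$sample_type %in% .sr_sample_types
  if (any(bad_type)) {
    stop("unknown sample_type: ",
         paste(unique(data$sample_type[bad_type]), collapse = ", "))
  }
  all_flags <- unlist(strsplit(data$flags[data$flags != ""], ";"))
  bad_flags <- setdiff(unique(all_flags), .sr_flag_levels)
  if (length(bad_flags) > 0) {
    stop("unknown flag(s): ", paste(bad_flags, collapse = ", "))
  }
  structure(data, metadata = metadata,
            class = c("sr_samples", class(tibble::tibble())))
}

#' Test whether each sample carries a QC flag
#'
#' @param set An `sr_samples` set.
#' @param flag A single flag name.
#' @return Logical vector, one element per sample.
#' @export
has_flag <- function(set, flag) {
  stopifnot(length(flag) == 1L)
  vapply(strsplit(ifelse(is.na(set$flags), "", set$flags), ";"),
         function(f) flag %in% f, logical(1))
}

.add_flag <- function(flags, which, flag) {
  flags[which] <- ifelse(flags[which] == "", flag,
                         paste(flags[which], flag, sep = ";"))
  flags
}

#' Read a sample table from CSV/TSV
#'
#' Coordinates may be supplied either as `lon`/`lat` (WGS84 decimal degrees)
#' or as `utm_e`/`utm_n`/`utm_zone`, which are converted on ingest. Rows whose
#' ratio cannot be parsed as a number are rejected and reported by row index.
#'
#' @param path Path to a delimited text file with a header. Files ending in
#'   `.tsv` are read as tab-separated, all others as comma-separated.
#' @param schema Optional named character vector mapping the canonical column
#'   names (names) to the file's column names (values).
#' @return An `sr_samples` set.
#' @examples
#' plants <- read_sr_samples(
#'   system.file("extdata", "oaxaca_plants.csv", package = "srscape"))
#' nrow(plants)
#' @export
read_sr_samples <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (nrow(raw) == 0) stop("no records")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(raw)) {
        stop("schema column not found in file: ", schema[[canon]])
      }
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  required <- c("sample_id", "site", "ratio")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  ratio <- suppressWarnings(as.numeric(raw$ratio))
  bad <- is.na(ratio) | !is.finite(ratio)
  if (any(bad)) {
    warning(sprintf("rejected %d row(s) with unparseable ratio (rows %s)",
                    sum(bad), paste(which(bad), collapse = ", ")))
    raw <- raw[!bad, , drop = FALSE]
    ratio <- ratio[!bad]
    if (nrow(raw) == 0) stop("no records")
  }
  raw$ratio <- ratio
  has_geo <- all(c("lon", "lat") %in% names(raw))
  has_utm <- all(c("utm_e", "utm_n", "utm_zone") %in% names(raw))
  if (has_geo) {
    raw$lon <- as.numeric(raw$lon)
    raw$lat <- as.numeric(raw$lat)
  } else if (has_utm) {
    ll <- utm_to_geographic(as.numeric(raw$utm_e), as.numeric(raw$utm_n),
                            raw$utm_zone)
    raw$lon <- ll$lon
    raw$lat <- ll$lat
  } else {
    stop("no coordinate columns: need lon/lat or utm_e/utm_n/utm_zone")
  }
  for (nm in c("elevation", "se2")) {
    if (nm %in% names(raw)) raw[[nm]] <- as.numeric(raw[[nm]])
  }
  if (!"sample_type" %in% names(raw)) raw$sample_type <- "plant"
  as_sr_samples(raw, metadata = paste("read from", path))
}

#' Write a sample table to CSV
#'
#' Emits the same dialect that [read_sr_samples()] reads: UTF-8, comma
#' separated, `.` decimal separator, flags joined with `;`.
#'
#' @param set An `sr_samples` set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sr_samples <- function(set, path) {
  readr::write_csv(tibble::as_tibble(set), path, progress = FALSE)
  invisible(path)
}

#' Load the packaged Valley of Oaxaca plant baseline table
#'
#' The 95 modern plant samples from 17 archaeological sites across the Valley
#' of Oaxaca that anchor the regional calibration, with UTM Zone 14N
#' coordinates converted to WGS84 on ingest. Samples judged to be contaminated
#' by modern agricultural fertilizer carry the `fertilizer_contaminated` flag
#' and are excluded from model training by [apply_exclusions()].
#'
#' @return An `sr_samples` set of 95 plant samples.
#' @export
valley_oaxaca_plants <- function() {
  read_sr_samples(system.file("extdata", "oaxaca_plants.csv",
                              package = "srscape", mustWork = TRUE))
}

#' Filter samples to a plausible ratio range
#'
#' Removes samples with ratios outside `[transform$lower, transform$upper]`
#' (bounds inclusive: values exactly on a bound are retained). Removed samples
#' gain the `out_of_range` flag and are attached to the result as the
#' `removed` attribute.
#'
#' @param set An `sr_samples` set.
#' @param transform An [sr_transform()] supplying the bounds.
#' @return The retained `sr_samples` set; `attr(., "removed")` holds the rest.
#' @export
filter_ratio_range <- function(set, transform = sr_transform()) {
  stopifnot(inherits(set, "sr_samples"))
  out <- set$ratio < transform$lower | set$ratio > transform$upper
  out[is.na(out)] <- TRUE
  set$flags <- .add_flag(set$flags, out, "out_of_range")
  kept <- set[!out, , drop = FALSE]
  removed <- set[out, , drop = FALSE]
  if (any(out)) {
    message(sprintf("filter_ratio_range: removed %d of %d sample(s) outside [%g, %g]",
                    sum(out), length(out), transform$lower, transform$upper))
  }
  attr(kept, "removed") <- removed
  kept
}

#' Drop samples carrying excluded QC flags
#'
#' @param set An `sr_samples` set.
#' @param excluded_flags Character vector of flag names; samples carrying any
#'   of them are removed. Row order of the remainder is preserved.
#' @return The retained `sr_samples` set.
#' @export
apply_exclusions <- function(set,
                             excluded_flags = c("fertilizer_contaminated",
                                                "nonlocal_human")) {
  stopifnot(inherits(set, "sr_samples"))
  unknown <- setdiff(excluded_flags, .sr_flag_levels)
  if (length(unknown) > 0) {
    stop("unknown flag(s): ", paste(unknown, collapse = ", "))
  }
  if (length(excluded_flags) == 0) return(set)
  drop <- Reduce(`|`, lapply(excluded_flags, function(f) has_flag(set, f)))
  set[!drop, , drop = FALSE]
}

#' Flag within-site outliers by robust z-score
#'
#' For each site with at least three samples, computes the robust z-score
#' `|ratio - median| / max(1.4826 * MAD, floor)` and flags samples exceeding
#' `threshold` with `site_outlier`. Nothing is removed; combine with
#' [apply_exclusions()] to drop flagged samples. This is a generic screen for
#' implausible site values (such as fertilizer-contaminated plants), not a
#' contaminant-specific forensic test.
#'
#' @param set An `sr_samples` set.
#' @param threshold Robust z cutoff (default 3).
#' @param mad_floor Lower bound on the scaled MAD, guarding sites whose values
#'   are identical.
#' @return The set with `site_outlier` flags added where triggered.
#' @export
screen_site_outliers <- function(set, threshold = 3, mad_floor = 1e-7) {
  stopifnot(inherits(set, "sr_samples"), threshold > 0)
  skipped <- character()
  for (s in unique(set$site)) {
    idx <- which(set$site == s)
    if (length(idx) < 3) {
      skipped <- c(skipped, s)
      next
    }
    r <- set$ratio[idx]
    z <- abs(r - median(r)) / max(mad(r), mad_floor)
    hit <- idx[z > threshold]
    if (length(hit) > 0) {
      set$flags <- .add_flag(set$flags, hit, "site_outlier")
    }
  }
  if (length(skipped) > 0) {
    warning("sites skipped (< 3 samples): ", paste(skipped, collapse = ", "))
  }
  set
}

#' Summary statistics for a site (or the pooled set)
#'
#' Reports n, mean, sample standard deviation (the "1 sigma" convention, n-1
#' denominator), minimum, and maximum of the observed ratios.
#'
#' @param set An `sr_samples` set.
#' @param site Site name, or `"ALL"` for the pooled summary.
#' @return A one-row tibble with columns `site`, `n`, `mean`, `sd`, `min`,
#'   `max`.
#' @examples
#' site_summary(valley_oaxaca_plants(), "ALL")
#' @export
site_summary <- function(set, site = "ALL") {
  stopifnot(inherits(set, "sr_samples"), length(site) == 1L)
  r <- if (identical(site, "ALL")) set$ratio else {
    if (!site %in% set$site) stop("unknown site: ", site)
    set$ratio[set$site == site]
  }
  s <- if (length(r) == 1L) {
    warning("single-sample site: sd reported as 0")
    0
  } else sd(r)
  tibble::tibble(site = site, n = length(r), mean = mean(r), sd = s,
                 min = min(r), max = max(r))
}

#' Countries whose samples define the Mesoamerican evaluation region
#'
#' Helper for region-holdout designs: the country list conventionally used to
#' delimit Mesoamerica when splitting a continental compilation by
#' `region_tag`.
#'
#' @return Character vector of country names.
#' @export
mesoamerica_countries <- function() {
  c("Mexico", "Belize", "Guatemala", "Honduras", "El Salvador", "Nicaragua",
    "Costa Rica")
}
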