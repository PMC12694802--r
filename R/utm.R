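# WGS84 transverse Mercator via the Krueger flattening series (order n^4,
# sub-millimetre for UTM-width zones). Implemented directly because sample
# tables in this field are routinely recorded in UTM from hand-held GPS units.

.tm_constants <- local({
  a <- 6378137
  f <- 1 / 298.257223563
  n <- f / (2 - f)
  list(
    a = a, f = f, n = n, k0 = 0.9996, e = sqrt(f * (2 - f)),
    A = a / (1 + n) * (1 + n^2 / 4 + n^4 / 64),
    alpha = c(n / 2 - 2 * n^2 / 3 + 5 * n^3 / 16 + 41 * n^4 / 180,
              13 * n^2 / 48 - 3 * n^3 / 5 + 557 * n^4 / 1440,
              61 * n^3 / 240 - 103 * n^4 / 140,
              49561 * n^4 / 161280),
    beta = c(n / 2 - 2 * n^2 / 3 + 37 * n^3 / 96 - n^4 / 360,
             n^2 / 48 + n^3 / 15 - 437 * n^4 / 1440,
             17 * n^3 / 480 - 37 * n^4 / 840,
             4397 * n^4 / 161280),
    delta = c(2 * n - 2 * n^2 / 3 - 2 * n^3 + 116 * n^4 / 45,
              7 * n^2 / 3 - 8 * n^3 / 5 - 227 * n^4 / 45,
              56 * n^3 / 15 - 136 * n^4 / 35,
              4279 * n^4 / 630)
  )
})

.parse_utm_zone <- function(zone) {
  m <- regmatches(zone, regexec("^([0-9]{1,2})\\s*([C-HJ-NP-X])$",
                                toupper(trimws(zone))))
  ok <- vapply(m, length, 1L) == 3L
  num <- rep(NA_integer_, length(zone))
  south <- rep(NA, length(zone))
  num[ok] <- as.integer(vapply(m[ok], `[`, "", 2L))
  band <- vapply(m[ok], `[`, "", 3L)
  south[ok] <- band < "N"
  bad <- !ok | is.na(num) | num < 1L | num > 60L
  if (any(bad)) {
    stop(sprintf("invalid UTM zone: %s",
                 paste(unique(zone[bad]), collapse = ", ")))
  }
  list(number = num, south = south)
}

#' Convert UTM coordinates to WGS84 longitude/latitude
#'
#' @param easting,northing Numeric vectors, metres.
#' @param zone UTM zone string(s) such as `"14N"` (zone number plus latitude
#'   band letter; bands C--M are treated as the southern hemisphere).
#' @return A [tibble::tibble] with columns `lon` and `lat` in decimal degrees.
#' @examples
#' utm_to_geographic(737631, 1885941, "14N") # Monte Alban, approx (-96.77, 17.05)
#' @export
utm_to_geographic <- function(easting, northing, zone) {
  stopifnot(is.numeric(easting), is.numeric(northing))
  k <- .tm_constants
  z <- .parse_utm_zone(rep_len(zone, length(easting)))
  if (any(easting < 100000 | easting > 900000, na.rm = TRUE)) {
    stop("easting outside the valid span of a UTM zone (100 km - 900 km)")
  }
  if (any(northing < 0 | northing > 10000000, na.rm = TRUE)) {
    stop("northing outside the valid UTM span (0 - 10,000 km)")
  }
  lam0 <- (-183 + 6 * z$number) * pi / 180
  fn <- ifelse(z$south, 1e7, 0)
  xi <- (northing - fn) / (k$k0 * k$A)
  eta <- (easting - 5e5) / (k$k0 * k$A)
  xi_p <- xi
  eta_p <- eta
  for (j in 1:4) {
    xi_p <- xi_p - k$beta[j] * sin(2 * j * xi) * cosh(2 * j * eta)
    eta_p <- eta_p - k$beta[j] * cos(2 * j * xi) * sinh(2 * j * eta)
  }
  chi <- asin(sin(xi_p) / cosh(eta_p))
  phi <- chi
  for (j in 1:4) phi <- phi + k$delta[j] * sin(2 * j * chi)
  lam <- lam0 + atan2(sinh(eta_p), cos(xi_p))
  tibble::tibble(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

#' Convert WGS84 longitude/latitude to UTM coordinates
#'
#' Inverse of [utm_to_geographic()]; the zone must be supplied (coordinates
#' near zone edges are projected into the requested zone).
#'
#' @param lon,lat Numeric vectors, decimal degrees.
#' @param zone UTM zone string(s) such as `"14N"`.
#' @return A [tibble::tibble] with columns `easting` and `northing` in metres.
#' @export
geographic_to_utm <- function(lon, lat, zone) {
  stopifnot(is.numeric(lon), is.numeric(lat))
  if (any(abs(lat) > 84, na.rm = TRUE)) {
    stop("latitude outside the UTM system's span (84S - 84N)")
  }
  k <- .tm_constants
  z <- .parse_utm_zone(rep_len(zone, length(lon)))
  lam0 <- (-183 + 6 * z$number) * pi / 180
  phi <- lat * pi / 180
  dl <- lon * pi / 180 - lam0
  t <- sinh(atanh(sin(phi)) - k$e * atanh(k$e * sin(phi)))
  xi_p <- atan2(t, cos(dl))
  eta_p <- atanh(sin(dl) / sqrt(1 + t^2))
  xi <- xi_p
  eta <- eta_p
  for (j in 1:4) {
    xi <- xi + k$alpha[j] * sin(2 * j * xi_p) * cosh(2 * j * eta_p)
    eta <- eta + k$alpha[j] * cos(2 * j * xi_p) * sinh(2 * j * eta_p)
  }
  tibble::tibble(
    easting = 5e5 + k$k0 * k$A * eta,
    northing = ifelse(z$south, 1e7, 0) + k$k0 * k$A * xi
  )
}
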