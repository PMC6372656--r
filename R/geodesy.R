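# Normalise angles to [0, 360); guards the floating-point case where
# x %% 360 returns exactly 360 for a tiny negative x.
.norm360 <- function(x) {
  r <- x %% 360
  r[r >= 360] <- 0
  r
}

#' Great-circle distance and initial bearing between two points
#'
#' Spherical geodesy on a sphere of radius 6371.0088 km (errors relative to
#' an ellipsoid are far below one grid cell at the resolutions used here).
#' Distance is the haversine great-circle distance; bearing is the standard
#' forward azimuth, normalised to `[0, 360)`. Coincident points return
#' `c(0, 0)` with attribute `degenerate = TRUE` (a bearing is undefined
#' there).
#'
#' @param from,to Numeric `c(lat, lon)` in degrees (names optional).
#' @return Named numeric `c(distanceKm=, bearingDeg=)`, with a logical
#'   `degenerate` attribute.
#' @examples
#' geodesicDistanceBearing(c(39, -77), c(38, -77))  # due south, ~111 km
#' @export
geodesicDistanceBearing <- function(from, to) {
  .coord <- function(p, what) {
    p <- if (!is.null(names(p)) && all(c("lat", "lon") %in% names(p)))
      c(p[["lat"]], p[["lon"]]) else as.numeric(p[1:2])
    if (any(!is.finite(p)) || abs(p[1]) > 90 || abs(p[2]) > 360)
      stop("invalid ", what, " coordinate")
    p
  }
  from <- .coord(from, "origin"); to <- .coord(to, "destination")
  # geosphere expects (lon, lat)
  p1 <- c(from[2], from[1]); p2 <- c(to[2], to[1])
  if (isTRUE(all.equal(p1, p2, tolerance = 0))) {
    out <- c(distanceKm = 0, bearingDeg = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  d <- geosphere::distHaversine(p1, p2, r = .EARTH_RADIUS_KM)
  b <- .norm360(geosphere::bearing(p1, p2, f = 0))  # f = 0: spherical azimuth
  out <- c(distanceKm = unname(d), bearingDeg = unname(b))
  attr(out, "degenerate") <- FALSE
  out
}

#' Circular mean of bearings
#'
#' Vector-sum azimuth: the arctangent of the mean sines and cosines, so
#' wraparound is handled correctly (e.g. the mean of 350 and 10 degrees is
#' 0, not 180).
#'
#' @param bearingDeg Numeric vector of bearings in degrees.
#' @return Mean bearing in `[0, 360)`; `NA` for an empty input.
#' @export
circularMeanDeg <- function(bearingDeg) {
  if (!length(bearingDeg)) return(NA_real_)
  th <- bearingDeg * pi / 180
  .norm360(atan2(mean(sin(th)), mean(cos(th))) * 180 / pi)
}
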