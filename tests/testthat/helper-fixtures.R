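# Shared fixtures, all built in code.

# Constant-valued grid with sane physical values; individual layers can be
# overridden by name.
testGrid <- function(lat, lon, overrides = list(), mask = NULL) {
  shape <- c(length(lat), length(lon))
  const <- function(v) matrix(v, shape[1], shape[2])
  layers <- c(
    setNames(lapply(climateSeasons(), function(s) const(10)),
             paste0("tmin_", climateSeasons())),
    setNames(lapply(climateSeasons(), function(s) const(18)),
             paste0("tmax_", climateSeasons())),
    setNames(lapply(climateSeasons(), function(s) const(100)),
             paste0("prcp_", climateSeasons())))
  for (nm in names(overrides)) layers[[nm]] <- overrides[[nm]]
  climateGrid(lat, lon, layers, mask = mask)
}

# A flat climate vector matching testGrid's constants.
testVector <- function(tmin = 10, tmax = 18, prcp = 100) {
  seasonalClimateVector(rep(tmin, 4), rep(tmax, 4), rep(prcp, 4))
}

# Complete (or deliberately gappy) monthly station over a year window.
makeStation <- function(id, lat, lon, years = 1960:1990,
                        tmin = 5, tmax = 15, prcp = 80,
                        dropMonths = NULL) {
  rec <- expand.grid(month = 1:12, year = years)[, c("year", "month")]
  rec$tmin <- tmin; rec$tmax <- tmax; rec$prcp <- prcp
  if (!is.null(dropMonths)) rec <- rec[-dropMonths, ]
  stationSeries(id, lat, lon, rec)
}

# Degrees of latitude per km on the reference sphere.
.kmPerDegLat <- pi / 180 * 6371.0088

# A station displaced due north of a point by a given distance in km
# (meridian arcs make haversine distances exact).
stationAtKm <- function(id, center, km, ...) {
  makeStation(id, center[["lat"]] + km / .kmPerDegLat, center[["lon"]], ...)
}

# Identity-like ICV over the 12 variables.
identityICV <- function() icvModel(rep(0, 12), diag(12))

# Hand-written haversine + forward azimuth oracle, independent of
# geosphere.
haversineOracle <- function(from, to, radiusKm = 6371.0088) {
  toRad <- pi / 180
  f1 <- from[1] * toRad; f2 <- to[1] * toRad
  dl <- (to[2] - from[2]) * toRad
  a <- sin((f2 - f1) / 2)^2 + cos(f1) * cos(f2) * sin(dl / 2)^2
  d <- 2 * radiusKm * asin(sqrt(pmin(1, a)))
  th <- atan2(sin(dl) * cos(f2),
              cos(f1) * sin(f2) - sin(f1) * cos(f2) * cos(dl))
  c(distanceKm = unname(d), bearingDeg = unname((th / toRad) %% 360))
}

# Random PSD covariance with unit-scale variances.
randomPSD <- function(n = 12, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  S <- crossprod(A) / n + diag(0.1, n)
  dimnames(S) <- list(climateVariables()[1:n], climateVariables()[1:n])
  S
}
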