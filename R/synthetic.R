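# Synthetic inputs with known structure: smooth climate gradients with
# planted analogs, station series drawn from a known 12 x 12 covariance,
# and square urban polygons. Everything is a pure function of
# (config, seed).

#' Configuration for a synthetic climate grid
#'
#' Defines a spatially smooth climate field: temperatures fall linearly
#' with latitude (a lapse), swing seasonally around the annual mean, and
#' carry a fixed diurnal spread between tmin and tmax; precipitation rises
#' linearly with longitude. Independent Gaussian noise is added per cell
#' and layer (precipitation truncated at zero), and a random fraction of
#' cells can be masked as ocean.
#'
#' @param nLat,nLon Grid shape (>= 2 each).
#' @param bbox Numeric `c(latMin, latMax, lonMin, lonMax)` of the domain.
#' @param baseTmin Annual-mean tmin at latitude 0 (deg C).
#' @param lapse Temperature decrease per degree latitude (deg C / deg).
#' @param diurnalSpread tmax - tmin (deg C, > 0).
#' @param seasonalAmplitude Half-range of the seasonal temperature cycle
#'   (deg C): DJF = mean - amplitude, JJA = mean + amplitude.
#' @param basePrcp Seasonal precipitation at longitude 0 (mm).
#' @param prcpGradient Precipitation change per degree longitude (mm/deg).
#' @param noiseSd Gaussian noise standard deviation (deg C / mm) applied
#'   to every layer.
#' @param oceanFraction Fraction of cells masked at random (default 0).
#' @param seed RNG seed; recorded in the grid metadata.
#' @return A list of class `syntheticGridConfig`.
#' @export
syntheticGridConfig <- function(nLat = 20, nLon = 20,
                                bbox = c(20, 60, -120, -80),
                                baseTmin = 30, lapse = 0.5,
                                diurnalSpread = 8, seasonalAmplitude = 10,
                                basePrcp = 300, prcpGradient = 2,
                                noiseSd = 0, oceanFraction = 0, seed = 1) {
  stopifnot(nLat >= 2, nLon >= 2, diurnalSpread > 0, noiseSd >= 0,
            oceanFraction >= 0, oceanFraction < 1)
  structure(list(nLat = nLat, nLon = nLon, bbox = bbox, baseTmin = baseTmin,
                 lapse = lapse, diurnalSpread = diurnalSpread,
                 seasonalAmplitude = seasonalAmplitude, basePrcp = basePrcp,
                 prcpGradient = prcpGradient, noiseSd = noiseSd,
                 oceanFraction = oceanFraction, seed = seed),
            class = "syntheticGridConfig")
}

# Seasonal phase of the temperature cycle: winter trough, summer peak.
.SEASON_PHASE <- c(DJF = -1, MAM = 0, JJA = 1, SON = 0)

#' Generate a synthetic climate grid
#'
#' @param cfg A [syntheticGridConfig()].
#' @return A [ClimateGrid-class]; bit-identical for identical `cfg`
#'   (including seed).
#' @export
makeGrid <- function(cfg) {
  stopifnot(inherits(cfg, "syntheticGridConfig"))
  withSeed(cfg$seed, {
    latStep <- (cfg$bbox[2] - cfg$bbox[1]) / cfg$nLat
    lonStep <- (cfg$bbox[4] - cfg$bbox[3]) / cfg$nLon
    # cell centers, latitude stored north -> south
    lat <- cfg$bbox[2] - latStep * (seq_len(cfg$nLat) - 0.5)
    lon <- cfg$bbox[3] + lonStep * (seq_len(cfg$nLon) - 0.5)
    latM <- matrix(lat, cfg$nLat, cfg$nLon)
    lonM <- matrix(lon, cfg$nLat, cfg$nLon, byrow = TRUE)
    noise <- function() if (cfg$noiseSd > 0)
      matrix(rnorm(cfg$nLat * cfg$nLon, sd = cfg$noiseSd),
             cfg$nLat, cfg$nLon) else 0
    layers <- list()
    for (s in climateSeasons()) {
      tminClean <- cfg$baseTmin - cfg$lapse * latM +
        cfg$seasonalAmplitude * .SEASON_PHASE[[s]]
      tmin <- tminClean + noise()
      tmax <- tminClean + cfg$diurnalSpread + noise()
      tmax <- pmax(tmax, tmin)   # diurnal spread never inverts
      prcp <- pmax(cfg$basePrcp + cfg$prcpGradient * lonM + noise(), 0)
      layers[[paste0("tmin_", s)]] <- tmin
      layers[[paste0("tmax_", s)]] <- tmax
      layers[[paste0("prcp_", s)]] <- prcp
    }
    mask <- matrix(TRUE, cfg$nLat, cfg$nLon)
    if (cfg$oceanFraction > 0) {
      nDrop <- floor(cfg$oceanFraction * length(mask))
      mask[sample(length(mask), nDrop)] <- FALSE
    }
    climateGrid(lat, lon, layers, mask = mask,
                metadata = list(name = "synthetic", seed = cfg$seed,
                                resolution = c(latStep, lonStep)))
  })
}

#' Plant a future climate at a known grid cell
#'
#' Returns the grid's climate vector at `targetCell` plus `offset`. With a
#' zero offset the pipeline must recover `targetCell` as the best analog
#' at 0 sigma — the basis of the planted-analog recovery tests.
#'
#' @param grid A [ClimateGrid-class].
#' @param targetCell Integer `c(row, col)` into the stored grid.
#' @param offset Numeric offset: length 12 (named or canonical order) or a
#'   scalar applied to all variables.
#' @return Named 12-variable climate vector.
#' @export
plantFuture <- function(grid, targetCell, offset = 0) {
  i <- targetCell[1]; j <- targetCell[2]
  if (!gridMask(grid)[i, j])
    stop("target cell is masked; plant the future at a valid cell")
  base <- vapply(gridLayers(grid), function(m) m[i, j], numeric(1))
  names(base) <- climateVariables()
  if (length(offset) == 1) offset <- rep(offset, 12)
  if (!is.null(names(offset))) offset <- offset[climateVariables()]
  base + as.numeric(offset)
}

#' Generate synthetic station series from a known covariance
#'
#' Draws annual 12-variable vectors from a multivariate normal with the
#' given mean and covariance (the ICV ground truth), disaggregates them to
#' monthly records — each temperature month gets its season's value plus
#' small i.i.d. noise; each precipitation season total is split across its
#' three months by fixed proportions plus noise — and replicates the
#' series across stations with spatial jitter around the center. The
#' annual signal is shared across stations (they observe the same city
#' weather); only the small monthly noise differs per station. December is
#' assigned to the *following* seasonal year, so re-aggregation with the
#' lagged-December rule of [monthlyToSeasonalSeries()] recovers the drawn
#' annual vectors (up to the monthly noise).
#'
#' @param mean Numeric 12-vector (canonical order) of variable means.
#' @param covariance 12 x 12 positive semi-definite covariance.
#' @param nYears Number of seasonal years to generate (>= 2).
#' @param nStations Number of stations.
#' @param center Named `c(lat=, lon=)` of the city centroid.
#' @param jitterKm Station scatter radius around the center (km).
#' @param monthlyNoiseSd Standard deviation of the disaggregation noise.
#' @param startYear First calendar year of the monthly window; the window
#'   spans `nYears + 1` calendar years so that `nYears` seasonal years
#'   survive winter trimming.
#' @param seed RNG seed.
#' @return List of [StationSeries-class] of length `nStations`.
#' @export
makeStationSeries <- function(mean, covariance, nYears, nStations = 5,
                              center = c(lat = 40, lon = -100),
                              jitterKm = 10, monthlyNoiseSd = 0.01,
                              startYear = 1960, seed = 1) {
  stopifnot(nYears >= 2, nStations >= 1)
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("covariance must be positive semi-definite")
  withSeed(seed, {
    years <- startYear:(startYear + nYears)        # calendar window
    ny <- length(years)
    # annual draws indexed by seasonal year; one extra draw feeds the
    # first calendar year's Jan..Nov and the final December
    Z <- MASS::mvrnorm(ny + 1, mu = mean, Sigma = covariance)
    colnames(Z) <- climateVariables()
    prcpSplit <- c(0.30, 0.35, 0.35)               # fixed month shares
    seasonOf <- c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA", "JJA", "JJA",
                  "SON", "SON", "SON", "DJF")
    posOf <- c(2, 3, 1, 2, 3, 1, 2, 3, 1, 2, 3, 1)  # month's slot in season
    monthTab <- expand.grid(month = 1:12, year = years)[, c("year", "month")]
    m <- monthTab$month
    # December belongs to the next seasonal year (lagged-DJF convention)
    zi <- (monthTab$year - startYear + 1L) + (m == 12L)
    clean <- matrix(NA_real_, nrow(monthTab), 3,
                    dimnames = list(NULL, c("tmin", "tmax", "prcp")))
    for (v in c("tmin", "tmax"))
      clean[, v] <- Z[cbind(zi, match(paste(v, seasonOf[m], sep = "_"),
                                      colnames(Z)))]
    clean[, "prcp"] <- Z[cbind(zi, match(paste0("prcp_", seasonOf[m]),
                                         colnames(Z)))] * prcpSplit[posOf[m]]
    kmPerDegLat <- pi / 180 * .EARTH_RADIUS_KM
    lapply(seq_len(nStations), function(k) {
      ang <- runif(1, 0, 2 * pi); rad <- runif(1, 0, jitterKm)
      lat <- center[["lat"]] + rad * cos(ang) / kmPerDegLat
      lon <- center[["lon"]] + rad * sin(ang) /
        (kmPerDegLat * cos(center[["lat"]] * pi / 180))
      rec <- monthTab
      for (v in c("tmin", "tmax", "prcp")) {
        rec[[v]] <- clean[, v] + rnorm(nrow(clean), sd = monthlyNoiseSd)
      }
      rec$prcp <- pmax(rec$prcp, 0)
      stationSeries(sprintf("SYN%03d", k), lat, lon, rec)
    })
  })
}

#' Construct a square urban polygon of a given area
#'
#' @param center Named `c(lat=, lon=)` degrees.
#' @param areaKm2 Positive area; the square has side `sqrt(areaKm2)`.
#' @param name City name.
#' @return An [UrbanArea-class] with centroid equal to `center`.
#' @export
makeUrbanPolygon <- function(center, areaKm2, name = "synthetic-city") {
  stopifnot(areaKm2 > 0)
  halfKm <- sqrt(areaKm2) / 2
  kmPerDegLat <- pi / 180 * .EARTH_RADIUS_KM
  dLat <- halfKm / kmPerDegLat
  dLon <- halfKm / (kmPerDegLat * cos(center[["lat"]] * pi / 180))
  ring <- cbind(
    lat = center[["lat"]] + c(-dLat, -dLat, dLat, dLat, -dLat),
    lon = center[["lon"]] + c(-dLon, dLon, dLon, -dLon, -dLon))
  urbanArea(name, center, areaKm2, polygon = ring)
}
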