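#' Sigma-dissimilarity surface for one city x scenario
#'
#' Computes sigma dissimilarity between the city's future climate vector
#' and every valid cell of the contemporary analog pool, on the pool's own
#' geometry. Masked cells carry no value. Deterministic: the same inputs
#' always give the same surface.
#'
#' @param cityFuture Named 12-variable climate vector (the city's future
#'   climate, typically an ensemble mean).
#' @param pool A [ClimateGrid-class] of contemporary normals (the analog
#'   pool).
#' @param icv The city's [ICVModel-class].
#' @param city,scenario Labels recorded on the surface.
#' @param cap Sigma saturation cap (default 12).
#' @return A [SimilaritySurface-class].
#' @export
similaritySurface <- function(cityFuture, pool, icv, city = "city",
                              scenario = "scenario", cap = 12) {
  mask <- gridMask(pool)
  if (!any(mask)) stop("analog pool has no valid cells")
  cells <- which(mask)
  Y <- vapply(climateVariables(), function(v) gridLayers(pool)[[v]][cells],
              numeric(length(cells)))
  Y <- matrix(Y, ncol = 12, dimnames = list(NULL, climateVariables()))
  D <- mahalanobisDistance(cityFuture, Y, icv)
  cp <- chiPercentile(D, icvDims(icv))
  s <- percentileToSigma(cp$percentile, cp$logSurvival, cap = cap)
  sigma <- matrix(NA_real_, nrow(mask), ncol(mask))
  sigma[cells] <- as.numeric(s)
  new("SimilaritySurface", sigma = sigma, lat = gridLat(pool),
      lon = gridLon(pool), mask = mask, city = city, scenario = scenario)
}

#' Classify analog strength from sigma dissimilarity
#'
#' `sigma <= 2` is a representative analog; `sigma > 4` marks a novel
#' future climate (no contemporary analog in the domain); values between
#' are increasingly poor analogs. Boundaries follow the published
#' convention: exactly 2 is representative, exactly 4 is poor.
#'
#' @param sigma Nonnegative numeric vector.
#' @return Character vector: `"representative"`, `"poor"` or `"novel"`.
#' @export
classifyAnalog <- function(sigma) {
  if (any(sigma < 0)) stop("sigma must be nonnegative")
  ifelse(sigma <= 2, "representative", ifelse(sigma <= 4, "poor", "novel"))
}

#' Best contemporary analog on a similarity surface
#'
#' The valid cell with the smallest sigma dissimilarity; ties are broken
#' by row-major scan order over the stored grid (northernmost row first,
#' west to east within a row) and the number of tied cells is recorded.
#' Geodesic distance and initial bearing run from the city centroid to the
#' winning cell center.
#'
#' @param surface A [SimilaritySurface-class].
#' @param city The [UrbanArea-class] the surface belongs to.
#' @return An [AnalogResult-class].
#' @export
bestAnalog <- function(surface, city) {
  sig <- surface@sigma
  valid <- which(surface@mask)
  if (!length(valid)) stop("all cells of the similarity surface are masked")
  vals <- sig[valid]
  minVal <- min(vals)
  ties <- valid[vals == minVal]
  # column-major linear indices -> row-major scan: order by (row, col)
  rc <- arrayInd(ties, dim(sig))
  best <- ties[order(rc[, 1], rc[, 2])][1]
  bi <- arrayInd(best, dim(sig))
  cellCenter <- c(lat = surface@lat[bi[1]], lon = surface@lon[bi[2]])
  db <- geodesicDistanceBearing(cityCentroid(city), cellCenter)
  new("AnalogResult", city = surface@city, scenario = surface@scenario,
      analogLat = cellCenter[["lat"]], analogLon = cellCenter[["lon"]],
      minSigma = minVal, distanceKm = db[["distanceKm"]],
      bearingDeg = db[["bearingDeg"]], analogClass = classifyAnalog(minVal),
      tieCount = length(ties),
      degenerateBearing = isTRUE(attr(db, "degenerate")))
}

#' Run the analog pipeline for many cities and scenarios
#'
#' For every city, either one result per scenario, or — with ensemble
#' groups — one result per group after averaging the climate *variables*
#' across the group's members ([ensembleMean()]); sigma values are never
#' averaged. A failing city is quarantined (recorded with its error) and
#' the remaining cities proceed. Results are ordered by city then
#' scenario.
#'
#' @param cities List of [UrbanArea-class].
#' @param pool Contemporary [ClimateGrid-class] analog pool.
#' @param icvPerCity Named list of [ICVModel-class], keyed by city name.
#' @param futures Named list (by city name) of named lists (by scenario
#'   id) of 12-variable future climate vectors.
#' @param ensembleGroups `NULL` to score every scenario separately, or a
#'   named list mapping a group label (e.g. `"RCP4.5"`) to the scenario
#'   ids of its members.
#' @param cap Sigma saturation cap.
#' @return A data frame (see [analogTable()]) with attribute `failures`:
#'   a named character vector of per-city error messages.
#' @export
runScenarios <- function(cities, pool, icvPerCity, futures,
                         ensembleGroups = NULL, cap = 12) {
  results <- list()
  failures <- character()
  for (city in cities[order(vapply(cities, cityName, character(1)))]) {
    nm <- cityName(city)
    res <- tryCatch({
      icv <- icvPerCity[[nm]]
      fut <- futures[[nm]]
      if (is.null(icv) || is.null(fut))
        stop(sprintf("city '%s': missing ICV model or future climate", nm))
      runs <- if (is.null(ensembleGroups)) {
        fut[order(names(fut))]
      } else {
        lapply(ensembleGroups, function(members) {
          if (!all(members %in% names(fut)))
            stop(sprintf("city '%s': missing ensemble member(s) %s", nm,
                         paste(setdiff(members, names(fut)), collapse = ", ")))
          ensembleMean(fut[members])
        })
      }
      lapply(names(runs), function(sc)
        bestAnalog(similaritySurface(runs[[sc]], pool, icv, city = nm,
                                     scenario = sc, cap = cap), city))
    }, error = function(e) e)
    if (inherits(res, "error")) failures[nm] <- conditionMessage(res)
    else results <- c(results, res)
  }
  if (!length(results) && length(failures))
    warning("all cities failed; see the failures attribute")
  out <- analogTable(results)
  attr(out, "failures") <- failures
  out
}

#' Cohort summary of analog results
#'
#' Per scenario (and optionally per region): arithmetic mean analog
#' distance, circular mean bearing (degenerate bearings from coincident
#' points are excluded and counted), and the fractions of cities with a
#' representative analog (sigma <= 2) and with a novel future climate
#' (sigma > 4).
#'
#' @param results Data frame from [runScenarios()]/[analogTable()], or a
#'   list of [AnalogResult-class].
#' @param regionTags Optional character vector (or named vector keyed by
#'   city) tagging each result's region for per-region breakdowns.
#' @return Data frame with one row per scenario (x region), columns `n`,
#'   `meanDistanceKm`, `meanBearingDeg`, `fracRepresentative`,
#'   `fracNovel`, `nBearingExcluded`.
#' @export
summarizeAnalogs <- function(results, regionTags = NULL) {
  if (!is.data.frame(results)) results <- analogTable(results)
  if (!nrow(results)) stop("no results to summarize")
  regions <- if (is.null(regionTags)) rep(NA_character_, nrow(results))
             else if (!is.null(names(regionTags))) unname(regionTags[results$city])
             else as.character(regionTags)
  key <- paste(results$scenario, regions)
  out <- lapply(unname(split(seq_len(nrow(results)), key)), function(ix) {
    d <- results[ix, ]
    ok <- !d$degenerateBearing
    data.frame(
      scenario = d$scenario[1],
      region = regions[ix[1]],
      n = nrow(d),
      meanDistanceKm = mean(d$distanceKm),
      meanBearingDeg = circularMeanDeg(d$bearingDeg[ok]),
      fracRepresentative = mean(d$minSigma <= 2),
      fracNovel = mean(d$minSigma > 4),
      nBearingExcluded = sum(!ok),
      stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, out)
  out[order(out$scenario, out$region), , drop = FALSE]
}

#' Filter urban areas by analysis prerequisites
#'
#' Keeps cities with area above the minimum, passing an optional station
#' availability check, and (optionally) intersecting at least
#' `minPoolCells` distinct valid cells of the analog pool — a proxy for
#' sufficient spatial heterogeneity in climate within the city. Exclusion
#' is the mechanism, not an error: every excluded city carries a
#' machine-readable reason (`"area"`, `"stations"`, `"pool"`).
#'
#' @param cities List of [UrbanArea-class].
#' @param minAreaKm2 Minimum area (default 50 km^2; kept cities must
#'   exceed it).
#' @param stationCheck Optional function(city) returning `TRUE` when the
#'   city has sufficient station records (e.g. a wrapper over
#'   [selectStations()]).
#' @param pool Optional [ClimateGrid-class]; when given, cities must
#'   intersect `minPoolCells` valid cells.
#' @param minPoolCells Minimum intersected valid pool cells (default 2).
#' @return List with `kept` (list of [UrbanArea-class]) and `excluded`
#'   (data frame `city`, `reason`).
#' @export
filterUrbanAreas <- function(cities, minAreaKm2 = 50, stationCheck = NULL,
                             pool = NULL, minPoolCells = 2) {
  kept <- list()
  excluded <- data.frame(city = character(), reason = character(),
                         stringsAsFactors = FALSE)
  drop <- function(city, why) {
    excluded[nrow(excluded) + 1L, ] <<- list(cityName(city), why)
  }
  for (city in cities) {
    if (cityArea(city) <= minAreaKm2) { drop(city, "area"); next }
    if (!is.null(stationCheck) &&
        !isTRUE(tryCatch(stationCheck(city), error = function(e) FALSE))) {
      drop(city, "stations"); next
    }
    if (!is.null(pool)) {
      n <- tryCatch({
        poly <- cityPolygon(city)
        if (nrow(poly) == 0) stop("no polygon")
        lat <- gridLat(pool); lon <- gridLon(pool)
        cl <- matrix(lat, length(lat), length(lon))
        cn <- matrix(lon, length(lat), length(lon), byrow = TRUE)
        sum(matrix(.pointInPolygon(as.vector(cl), as.vector(cn), poly),
                   length(lat), length(lon)) & gridMask(pool))
      }, error = function(e) 0L)
      if (n < minPoolCells) { drop(city, "pool"); next }
    }
    kept <- c(kept, city)
  }
  list(kept = kept, excluded = excluded)
}
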