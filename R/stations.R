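#' Read long-format monthly station records
#'
#' Reads a CSV with columns `station_id`, `lat`, `lon`, `year`, `month`,
#' `tmin`, `tmax`, `prcp` (one row per station-month, GHCN-style monthly
#' export) into a list of [StationSeries-class] objects. Values equal to
#' the missing-value sentinel become `NA`.
#'
#' @param path CSV path.
#' @param sentinel Missing-value sentinel (default -9999).
#' @return Named list of [StationSeries-class], keyed by station id.
#' @export
readStations <- function(path, sentinel = -9999) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "lat", "lon", "year", "month", "tmin", "tmax", "prcp")
  if (!all(need %in% names(df)))
    stop("station CSV must have columns: ", paste(need, collapse = ", "))
  for (v in c("tmin", "tmax", "prcp")) df[[v]][df[[v]] == sentinel] <- NA_real_
  out <- lapply(split(df, df$station_id), function(d) {
    stationSeries(d$station_id[1], d$lat[1], d$lon[1],
                  d[c("year", "month", "tmin", "tmax", "prcp")])
  })
  out[order(names(out))]
}

#' Is a station series complete over a year window?
#'
#' Complete means every month of every year in the window has finite
#' `tmin`, `tmax` and `prcp`.
#'
#' @param station A [StationSeries-class].
#' @param years Integer vector of required calendar years.
#' @return Logical.
#' @export
isComplete <- function(station, years = 1960:1990) {
  rec <- stationRecords(station)
  rec <- rec[rec$year %in% years, ]
  if (nrow(rec) < 12 * length(years)) return(FALSE)
  key <- paste(rec$year, rec$month)
  if (anyDuplicated(key)) rec <- rec[!duplicated(key), ]
  nrow(rec) == 12 * length(years) &&
    all(is.finite(rec$tmin) & is.finite(rec$tmax) & is.finite(rec$prcp))
}

#' Select weather stations for a city
#'
#' Returns all complete stations inside the city polygon if there are at
#' least `minN`; otherwise the in-polygon stations are supplemented with
#' the nearest complete stations outside the polygon, by distance from the
#' city centroid, until `minN` is reached — but never beyond
#' `maxRadiusKm`. Ordering is deterministic: distance from the centroid,
#' ties broken by station id.
#'
#' @param stations List of [StationSeries-class].
#' @param city An [UrbanArea-class] with polygon and centroid.
#' @param minN Minimum number of stations (default 5).
#' @param maxRadiusKm Search radius around the centroid (default 50 km).
#' @param years Completeness window (default 1960:1990).
#' @return List of selected [StationSeries-class]; errors with class
#'   `insufficientStations` when fewer than `minN` complete stations lie
#'   within `maxRadiusKm` (such a city is excluded from analysis).
#' @export
selectStations <- function(stations, city, minN = 5, maxRadiusKm = 50,
                           years = 1960:1990) {
  complete <- Filter(function(s) isComplete(s, years), stations)
  if (length(complete)) {
    ct <- cityCentroid(city)
    dist <- vapply(complete, function(s)
      geodesicDistanceBearing(ct, stationLocation(s))[["distanceKm"]],
      numeric(1))
    ids <- vapply(complete, stationId, character(1))
    ord <- order(dist, ids)
    complete <- complete[ord]; dist <- dist[ord]
    poly <- cityPolygon(city)
    inside <- if (nrow(poly)) vapply(complete, function(s) {
      loc <- stationLocation(s)
      .pointInPolygon(loc[["lat"]], loc[["lon"]], poly)
    }, logical(1)) else rep(FALSE, length(complete))
    if (sum(inside) >= minN) return(complete[inside])
    chosen <- inside
    for (k in seq_along(complete)) {
      if (sum(chosen) >= minN) break
      if (!chosen[k] && dist[k] <= maxRadiusKm) chosen[k] <- TRUE
    }
    if (sum(chosen) >= minN) return(complete[chosen])
  }
  cond <- simpleError(sprintf(
    "city '%s': only %d complete station(s) within %g km (need %d)",
    cityName(city), length(complete), maxRadiusKm, minN))
  class(cond) <- c("insufficientStations", class(cond))
  stop(cond)
}

#' Combine station records by inverse distance weighting
#'
#' Produces one monthly series located at the city centroid: for every
#' year, month and variable, the weighted mean across stations with
#' weights `1 / d^power`, `d` the great-circle distance from station to
#' centroid. A station closer than 1 m is given a 1 m floor distance so a
#' station at the exact centroid cannot produce an infinite weight.
#'
#' @param stations Non-empty list of [StationSeries-class] complete over a
#'   common window.
#' @param centroid Named numeric `c(lat=, lon=)`.
#' @param power IDW exponent (default 1, plain inverse distance).
#' @return A [StationSeries-class] at the centroid with id `"IDW"`.
#' @export
idwCombine <- function(stations, centroid, power = 1) {
  if (!length(stations)) stop("idwCombine needs at least one station")
  d <- vapply(stations, function(s)
    geodesicDistanceBearing(centroid, stationLocation(s))[["distanceKm"]],
    numeric(1))
  w <- 1 / pmax(d, 0.001)^power   # 1 m floor
  w <- w / sum(w)
  recs <- lapply(stations, function(s) {
    r <- stationRecords(s)
    r[order(r$year, r$month), ]
  })
  key <- paste(recs[[1]]$year, recs[[1]]$month)
  for (r in recs[-1]) {
    if (!identical(paste(r$year, r$month), key))
      stop("stations do not share a common year-month window")
  }
  out <- recs[[1]]
  for (v in c("tmin", "tmax", "prcp")) {
    acc <- 0
    for (k in seq_along(recs)) acc <- acc + w[k] * recs[[k]][[v]]
    out[[v]] <- acc
  }
  stationSeries("IDW", centroid[["lat"]], centroid[["lon"]], out)
}

#' Aggregate a monthly station series to seasonal annual values
#'
#' Seasonal temperature is the 3-month mean and seasonal precipitation the
#' 3-month total, matching the climate normals. Winter (DJF) for year Y
#' uses December of year Y-1 with January and February of year Y (the
#' lagged-December climatological convention), so the first calendar year
#' of the window is dropped and a 31-year window (e.g. 1960-1990) yields
#' 30 complete seasonal years.
#'
#' @param series A complete [StationSeries-class].
#' @return A [SeasonalSeries-class].
#' @export
monthlyToSeasonalSeries <- function(series) {
  rec <- stationRecords(series)
  if (any(!is.finite(rec$tmin) | !is.finite(rec$tmax) | !is.finite(rec$prcp)))
    stop("series has missing months; aggregate complete series only")
  years <- sort(unique(rec$year))
  if (!identical(as.integer(years), seq(min(years), max(years))))
    stop("series years are not contiguous")
  ny <- length(years)
  outYears <- years[-1]                     # first year lost to lagged DJF
  if (length(outYears) < 3)
    stop("fewer than 3 usable years after winter trimming")
  idx <- cbind(match(rec$year, years), rec$month)
  rows <- 2:ny
  vals <- matrix(NA_real_, length(outYears), 12,
                 dimnames = list(outYears, climateVariables()))
  for (v in c("tmin", "tmax", "prcp")) {
    m <- matrix(NA_real_, ny, 12)
    m[idx] <- rec[[v]]
    if (any(!is.finite(m))) stop("series has missing months")
    agg <- if (v == "prcp") rowSums else rowMeans
    for (s in climateSeasons()) {
      mon <- .SEASON_MONTHS[[s]]
      block <- if (s == "DJF") cbind(m[rows - 1, 12], m[rows, 1:2])
               else m[rows, mon, drop = FALSE]
      vals[, paste(v, s, sep = "_")] <- agg(block)
    }
  }
  seasonalSeries(vals)
}
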