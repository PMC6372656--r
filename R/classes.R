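#' ClimateGrid: a regular lat-lon grid of 12 seasonal climate layers
#'
#' Holds the 12 seasonal climate variables (see [climateVariables()]) on a
#' regular latitude/longitude grid of cell centers, plus a validity mask
#' (`TRUE` = usable land cell). Latitudes are stored north-to-south but both
#' coordinate vectors are exposed explicitly, so orientation never matters
#' to callers. Masked cells carry `NA` in every layer.
#'
#' @slot lat Numeric vector of cell-center latitudes (degrees), strictly
#'   monotone, constant spacing.
#' @slot lon Numeric vector of cell-center longitudes (degrees), strictly
#'   monotone, constant spacing.
#' @slot layers Named list of 12 numeric matrices (`length(lat)` x
#'   `length(lon)`), names as in [climateVariables()]. Temperatures in deg C,
#'   precipitation in mm per season.
#' @slot mask Logical matrix, same shape; `TRUE` marks a valid cell.
#' @slot metadata List of free-form provenance fields (name, resolution,
#'   epoch, seed, ...).
#' @export
setClass("ClimateGrid",
  representation(lat = "numeric", lon = "numeric", layers = "list",
                 mask = "matrix", metadata = "list"))

.checkRegular <- function(x, what) {
  if (length(x) < 1) return(sprintf("%s coordinate vector is empty", what))
  if (length(x) > 1) {
    d <- diff(x)
    if (any(d == 0) || length(unique(sign(d))) != 1)
      return(sprintf("%s coordinates are not strictly monotone", what))
    if (max(abs(abs(d) - abs(d[1]))) > 1e-6 * abs(d[1]))
      return(sprintf("%s spacing is not constant", what))
  }
  NULL
}

setValidity("ClimateGrid", function(object) {
  msgs <- c(.checkRegular(object@lat, "lat"), .checkRegular(object@lon, "lon"))
  vars <- climateVariables()
  if (!setequal(names(object@layers), vars))
    msgs <- c(msgs, "layers must be named exactly by the 12 climate variables")
  dims <- c(length(object@lat), length(object@lon))
  for (v in names(object@layers)) {
    if (!identical(dim(object@layers[[v]]), as.integer(dims)))
      msgs <- c(msgs, sprintf("layer '%s' does not match grid shape", v))
  }
  if (!identical(dim(object@mask), as.integer(dims)))
    msgs <- c(msgs, "mask does not match grid shape")
  else if (!is.logical(object@mask))
    msgs <- c(msgs, "mask must be logical")
  else {
    for (v in names(object@layers)) {
      bad <- is.finite(object@layers[[v]]) & !object@mask
      if (any(bad))
        msgs <- c(msgs, sprintf("layer '%s' has finite values in masked cells", v))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ClimateGrid
#'
#' @param lat,lon Cell-center coordinate vectors (degrees); must be strictly
#'   monotone with constant spacing.
#' @param layers Named list of 12 matrices keyed by [climateVariables()].
#' @param mask Logical validity matrix (`TRUE` = usable cell); defaults to
#'   cells finite in all layers. Masked cells are forced to `NA` everywhere.
#' @param metadata List of provenance fields.
#' @return A [ClimateGrid-class] object.
#' @export
climateGrid <- function(lat, lon, layers, mask = NULL, metadata = list()) {
  layers <- layers[climateVariables()]
  if (is.null(mask)) {
    mask <- Reduce(`&`, lapply(layers, is.finite))
  }
  layers <- lapply(layers, function(m) { m[!mask] <- NA_real_; m })
  new("ClimateGrid", lat = as.numeric(lat), lon = as.numeric(lon),
      layers = layers, mask = mask, metadata = metadata)
}

#' @describeIn climateGrid Cell-center latitudes.
#' @param x A `ClimateGrid`.
#' @export
gridLat <- function(x) x@lat

#' @describeIn climateGrid Cell-center longitudes.
#' @export
gridLon <- function(x) x@lon

#' @describeIn climateGrid Named list of the 12 layer matrices.
#' @export
gridLayers <- function(x) x@layers

#' @describeIn climateGrid Logical validity mask (`TRUE` = usable cell).
#' @export
gridMask <- function(x) x@mask

#' @describeIn climateGrid Metadata list.
#' @export
gridMetadata <- function(x) x@metadata

#' @describeIn climateGrid Grid cell size in degrees (lat, lon).
#' @export
cellSize <- function(x) {
  c(lat = if (length(x@lat) > 1) abs(diff(x@lat[1:2])) else NA_real_,
    lon = if (length(x@lon) > 1) abs(diff(x@lon[1:2])) else NA_real_)
}

setMethod("show", "ClimateGrid", function(object) {
  cat(sprintf("ClimateGrid: %d x %d cells, %d valid\n",
              length(object@lat), length(object@lon), sum(object@mask)))
  cat(sprintf("  lat [%.3f, %.3f], lon [%.3f, %.3f], cell %.4f deg\n",
              min(object@lat), max(object@lat), min(object@lon),
              max(object@lon), cellSize(object)[["lat"]]))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

#' UrbanArea: a named city polygon with centroid and area
#'
#' @slot name City name.
#' @slot polygon Numeric matrix with columns `lat`, `lon` describing a
#'   closed ring (first row repeated last is optional), or a 0-row matrix
#'   when no polygon is available.
#' @slot centroid Named numeric `c(lat=, lon=)` in degrees.
#' @slot areaKm2 Area in square kilometres.
#' @export
setClass("UrbanArea",
  representation(name = "character", polygon = "matrix",
                 centroid = "numeric", areaKm2 = "numeric"))

setValidity("UrbanArea", function(object) {
  msgs <- character()
  if (object@areaKm2 <= 0) msgs <- c(msgs, "areaKm2 must be positive")
  if (!all(c("lat", "lon") %in% names(object@centroid)))
    msgs <- c(msgs, "centroid must be named c(lat=, lon=)")
  if (nrow(object@polygon) > 0) {
    if (!all(c("lat", "lon") %in% colnames(object@polygon)))
      msgs <- c(msgs, "polygon must have lat/lon columns")
    else {
      ct <- object@centroid
      if (ct[["lat"]] < min(object@polygon[, "lat"]) ||
          ct[["lat"]] > max(object@polygon[, "lat"]) ||
          ct[["lon"]] < min(object@polygon[, "lon"]) ||
          ct[["lon"]] > max(object@polygon[, "lon"]))
        msgs <- c(msgs, "centroid lies outside the polygon bounding box")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an UrbanArea
#'
#' @param name City name.
#' @param centroid Named numeric `c(lat=, lon=)` degrees.
#' @param areaKm2 Positive area in km^2.
#' @param polygon Optional matrix with `lat`, `lon` columns (ring of
#'   vertices).
#' @return An [UrbanArea-class] object.
#' @export
urbanArea <- function(name, centroid, areaKm2, polygon = NULL) {
  if (is.null(polygon))
    polygon <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("lat", "lon")))
  new("UrbanArea", name = name, polygon = polygon,
      centroid = c(lat = unname(centroid[["lat"]]),
                   lon = unname(centroid[["lon"]])),
      areaKm2 = areaKm2)
}

#' @describeIn urbanArea City name.
#' @param x An `UrbanArea`.
#' @export
cityName <- function(x) x@name

#' @describeIn urbanArea Centroid `c(lat=, lon=)`.
#' @export
cityCentroid <- function(x) x@centroid

#' @describeIn urbanArea Area in km^2.
#' @export
cityArea <- function(x) x@areaKm2

#' @describeIn urbanArea Polygon vertex matrix (`lat`, `lon` columns).
#' @export
cityPolygon <- function(x) x@polygon

setMethod("show", "UrbanArea", function(object) {
  cat(sprintf("UrbanArea '%s': centroid (%.3f, %.3f), %.1f km2, %s\n",
              object@name, object@centroid[["lat"]], object@centroid[["lon"]],
              object@areaKm2,
              if (nrow(object@polygon)) sprintf("%d-vertex polygon",
                                                nrow(object@polygon))
              else "no polygon"))
})

#' StationSeries: monthly weather-station records
#'
#' Monthly minimum/maximum temperature (deg C) and total precipitation
#' (mm/month) for one station over a window of calendar years.
#'
#' @slot stationId Station identifier.
#' @slot lat,lon Station location (degrees).
#' @slot records Data frame with columns `year`, `month`, `tmin`, `tmax`,
#'   `prcp`; missing months are absent rows or `NA` values.
#' @export
setClass("StationSeries",
  representation(stationId = "character", lat = "numeric", lon = "numeric",
                 records = "data.frame"))

setValidity("StationSeries", function(object) {
  need <- c("year", "month", "tmin", "tmax", "prcp")
  if (!all(need %in% names(object@records)))
    return("records must have columns year, month, tmin, tmax, prcp")
  if (nrow(object@records) &&
      any(object@records$month < 1 | object@records$month > 12))
    return("month must be in 1..12")
  TRUE
})

#' Construct a StationSeries
#'
#' @param stationId Identifier.
#' @param lat,lon Location in degrees.
#' @param records Data frame with columns `year`, `month`, `tmin`, `tmax`,
#'   `prcp`.
#' @return A [StationSeries-class] object.
#' @export
stationSeries <- function(stationId, lat, lon, records) {
  new("StationSeries", stationId = as.character(stationId), lat = lat,
      lon = lon, records = as.data.frame(records))
}

#' @describeIn stationSeries Station identifier.
#' @param x A `StationSeries`.
#' @export
stationId <- function(x) x@stationId

#' @describeIn stationSeries Location `c(lat=, lon=)`.
#' @export
stationLocation <- function(x) c(lat = x@lat, lon = x@lon)

#' @describeIn stationSeries Monthly records data frame.
#' @export
stationRecords <- function(x) x@records

setMethod("show", "StationSeries", function(object) {
  yrs <- range(object@records$year)
  cat(sprintf("StationSeries '%s' at (%.3f, %.3f): %d monthly rows, %d-%d\n",
              object@stationId, object@lat, object@lon,
              nrow(object@records), yrs[1], yrs[2]))
})

#' SeasonalSeries: annual series of the 12 seasonal climate variables
#'
#' One row per (seasonal) year; columns are the 12 variables of
#' [climateVariables()]. Produced by [monthlyToSeasonalSeries()] and
#' consumed by [icvCovariance()].
#'
#' @slot values Numeric matrix, `nYears` x 12, rownames = years.
#' @export
setClass("SeasonalSeries", representation(values = "matrix"))

setValidity("SeasonalSeries", function(object) {
  if (!identical(colnames(object@values), climateVariables()))
    return("columns must be the 12 climate variables in canonical order")
  if (nrow(object@values) < 2) return("at least 2 years are required")
  if (any(!is.finite(object@values))) return("no missing entries are allowed")
  TRUE
})

#' Construct a SeasonalSeries
#'
#' @param values Numeric matrix (years x 12 variables); column names must
#'   equal [climateVariables()] and rownames give the years.
#' @return A [SeasonalSeries-class] object.
#' @export
seasonalSeries <- function(values) new("SeasonalSeries", values = values)

#' @describeIn seasonalSeries The year x variable matrix.
#' @param x A `SeasonalSeries`.
#' @export
seasonalValues <- function(x) x@values

#' @describeIn seasonalSeries Number of complete years.
#' @export
nYears <- function(x) nrow(x@values)

setMethod("show", "SeasonalSeries", function(object) {
  cat(sprintf("SeasonalSeries: %d years (%s-%s), 12 variables\n",
              nrow(object@values), rownames(object@values)[1],
              rownames(object@values)[nrow(object@values)]))
})

#' ICVModel: interannual climatic variability covariance model
#'
#' The covariance of a city's year-to-year seasonal climate, used to scale
#' Mahalanobis distances. Optionally truncated to leading principal axes,
#' in which case `basis` holds the retained orthonormal axes and
#' `covariance` is expressed in that basis (diagonal).
#'
#' @slot mean Numeric 12-vector of variable means.
#' @slot covariance Symmetric positive semi-definite matrix; 12 x 12 when
#'   untruncated, `nDims` x `nDims` in the retained basis when truncated.
#' @slot basis 12 x `nDims` orthonormal matrix of retained principal axes,
#'   or a 0 x 0 matrix when no truncation was applied.
#' @slot nDims Integer in 1..12: the dimensionality used as the
#'   chi-distribution degrees of freedom.
#' @slot detrended Logical; was the series linearly detrended first?
#' @export
setClass("ICVModel",
  representation(mean = "numeric", covariance = "matrix", basis = "matrix",
                 nDims = "integer", detrended = "logical"))

setValidity("ICVModel", function(object) {
  msgs <- character()
  S <- object@covariance
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    msgs <- c(msgs, "covariance must be symmetric")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(1, max(abs(ev))))
    msgs <- c(msgs, "covariance must be positive semi-definite")
  if (object@nDims < 1L || object@nDims > 12L)
    msgs <- c(msgs, "nDims must be in 1..12")
  if (prod(dim(object@basis)) > 0) {
    B <- object@basis
    if (ncol(B) != object@nDims)
      msgs <- c(msgs, "basis must have nDims columns")
    if (max(abs(crossprod(B) - diag(ncol(B)))) > 1e-8)
      msgs <- c(msgs, "basis columns must be orthonormal")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an ICVModel
#'
#' Usually produced by [icvCovariance()]; the constructor is exported for
#' synthetic and testing use.
#'
#' @param mean Numeric 12-vector.
#' @param covariance Covariance matrix (12 x 12, or `nDims` x `nDims` in the
#'   retained basis).
#' @param basis Optional 12 x `nDims` orthonormal matrix.
#' @param nDims Retained dimensionality (chi degrees of freedom); default
#'   `ncol(covariance)`.
#' @param detrended Logical flag.
#' @return An [ICVModel-class] object.
#' @export
icvModel <- function(mean, covariance, basis = NULL,
                     nDims = ncol(covariance), detrended = FALSE) {
  if (is.null(basis)) basis <- matrix(numeric(0), 0, 0)
  new("ICVModel", mean = mean, covariance = covariance, basis = basis,
      nDims = as.integer(nDims), detrended = detrended)
}

#' @describeIn icvModel Mean 12-vector.
#' @param x An `ICVModel`.
#' @export
icvMean <- function(x) x@mean

#' @describeIn icvModel Covariance matrix (in the retained basis when
#'   truncated).
#' @export
icvCov <- function(x) x@covariance

#' @describeIn icvModel Retained orthonormal basis (0 x 0 when untruncated).
#' @export
icvBasis <- function(x) x@basis

#' @describeIn icvModel Retained dimensionality (the chi degrees of
#'   freedom).
#' @export
icvDims <- function(x) x@nDims

setMethod("show", "ICVModel", function(object) {
  cat(sprintf("ICVModel: %d retained dimension(s)%s%s\n", object@nDims,
              if (prod(dim(object@basis)) > 0) ", PCA-truncated" else "",
              if (object@detrended) ", detrended" else ""))
})

#' Dissimilarity: one sigma-dissimilarity evaluation
#'
#' @slot D Mahalanobis distance (unitless, ICV-standardised).
#' @slot n Chi degrees of freedom (retained climate dimensions).
#' @slot percentile Chi-CDF of `D` with `n` dof, in `[0, 1]`.
#' @slot logSurvival Natural log of the chi survival function at `D`
#'   (kept so extreme distances remain informative past the limits of
#'   double-precision percentiles).
#' @slot sigma The dissimilarity in sigma units: the 1-dof chi quantile of
#'   `percentile`, capped when saturated.
#' @slot saturated `TRUE` when `sigma` was clipped at the configured cap.
#' @export
setClass("Dissimilarity",
  representation(D = "numeric", n = "integer", percentile = "numeric",
                 logSurvival = "numeric", sigma = "numeric",
                 saturated = "logical"))

setValidity("Dissimilarity", function(object) {
  msgs <- character()
  if (object@D < 0) msgs <- c(msgs, "D must be nonnegative")
  if (object@sigma < 0) msgs <- c(msgs, "sigma must be nonnegative")
  if (!object@saturated &&
      abs(object@percentile - pchisq(object@D^2, object@n)) > 1e-8)
    msgs <- c(msgs, "percentile does not match the chi CDF of D")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "Dissimilarity", function(object) {
  cat(sprintf("Dissimilarity: D = %.4f (n = %d) -> %.4f sigma%s\n",
              object@D, object@n, object@sigma,
              if (object@saturated) " [saturated]" else ""))
})

#' SimilaritySurface: sigma dissimilarity over the analog pool
#'
#' Sigma values on the contemporary (analog-pool) grid geometry for one
#' city x scenario; masked cells are `NA`.
#'
#' @slot sigma Numeric matrix of sigma values (`NA` where masked).
#' @slot lat,lon Cell-center coordinates inherited from the pool grid.
#' @slot mask Logical validity mask inherited from the pool grid.
#' @slot city City name.
#' @slot scenario Scenario identifier.
#' @export
setClass("SimilaritySurface",
  representation(sigma = "matrix", lat = "numeric", lon = "numeric",
                 mask = "matrix", city = "character", scenario = "character"))

setValidity("SimilaritySurface", function(object) {
  dims <- c(length(object@lat), length(object@lon))
  if (!identical(dim(object@sigma), as.integer(dims)))
    return("sigma matrix does not match grid shape")
  if (!identical(dim(object@mask), as.integer(dims)))
    return("mask does not match grid shape")
  v <- object@sigma[object@mask]
  if (any(!is.finite(v)) || any(v < 0))
    return("sigma must be finite and nonnegative on all valid cells")
  TRUE
})

#' Sigma matrix of a similarity surface
#'
#' @param x A [SimilaritySurface-class].
#' @return Numeric matrix of sigma values, `NA` where masked.
#' @export
surfaceSigma <- function(x) x@sigma

setMethod("show", "SimilaritySurface", function(object) {
  v <- object@sigma[object@mask]
  cat(sprintf("SimilaritySurface '%s' x '%s': %d valid cells, sigma [%.3f, %.3f]\n",
              object@city, object@scenario, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

#' AnalogResult: the best contemporary analog for one city x scenario
#'
#' @slot city City name.
#' @slot scenario Scenario identifier.
#' @slot analogLat,analogLon Cell-center coordinates of the best-analog
#'   cell (degrees).
#' @slot minSigma Sigma dissimilarity at the best cell.
#' @slot distanceKm Great-circle distance from the city centroid to the
#'   best-analog cell center.
#' @slot bearingDeg Initial bearing (forward azimuth) in `[0, 360)`.
#' @slot analogClass One of `"representative"` (sigma <= 2), `"poor"`
#'   (2 < sigma <= 4), `"novel"` (sigma > 4).
#' @slot tieCount Number of cells sharing the minimum sigma.
#' @slot degenerateBearing `TRUE` when the analog coincides with the
#'   centroid (bearing reported as 0 by convention).
#' @export
setClass("AnalogResult",
  representation(city = "character", scenario = "character",
                 analogLat = "numeric", analogLon = "numeric",
                 minSigma = "numeric", distanceKm = "numeric",
                 bearingDeg = "numeric", analogClass = "character",
                 tieCount = "integer", degenerateBearing = "logical"))

setValidity("AnalogResult", function(object) {
  msgs <- character()
  if (object@distanceKm < 0) msgs <- c(msgs, "distanceKm must be nonnegative")
  if (object@bearingDeg < 0 || object@bearingDeg >= 360)
    msgs <- c(msgs, "bearingDeg must be in [0, 360)")
  if (!object@analogClass %in% c("representative", "poor", "novel"))
    msgs <- c(msgs, "analogClass must be representative/poor/novel")
  if (object@analogClass != classifyAnalog(object@minSigma))
    msgs <- c(msgs, "analogClass inconsistent with minSigma thresholds")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "AnalogResult", function(object) {
  cat(sprintf(
    "AnalogResult '%s' x '%s': best cell (%.3f, %.3f), %.3f sigma (%s)\n",
    object@city, object@scenario, object@analogLat, object@analogLon,
    object@minSigma, object@analogClass))
  cat(sprintf("  %.1f km at bearing %.1f deg%s, %d tied cell(s)\n",
              object@distanceKm, object@bearingDeg,
              if (object@degenerateBearing) " (degenerate)" else "",
              object@tieCount))
})

#' Convert analog results to a data frame
#'
#' @param results An [AnalogResult-class] object or a list of them.
#' @return A data frame with one row per result (city, scenario, analog
#'   coordinates, minSigma, distanceKm, bearingDeg, analogClass, tieCount,
#'   degenerateBearing).
#' @export
analogTable <- function(results) {
  if (is(results, "AnalogResult")) results <- list(results)
  if (!length(results))
    return(data.frame(city = character(), scenario = character(),
                      analogLat = numeric(), analogLon = numeric(),
                      minSigma = numeric(), distanceKm = numeric(),
                      bearingDeg = numeric(), analogClass = character(),
                      tieCount = integer(), degenerateBearing = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(results, function(r) {
    data.frame(city = r@city, scenario = r@scenario,
               analogLat = r@analogLat, analogLon = r@analogLon,
               minSigma = r@minSigma, distanceKm = r@distanceKm,
               bearingDeg = r@bearingDeg, analogClass = r@analogClass,
               tieCount = r@tieCount, degenerateBearing = r@degenerateBearing,
               stringsAsFactors = FALSE)
  }))
}
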