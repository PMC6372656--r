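#' Write analog results to CSV
#'
#' One row per city x scenario with all analog fields (see
#' [analogTable()]).
#'
#' @param results Data frame from [runScenarios()] or list of
#'   [AnalogResult-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeAnalogCSV <- function(results, path) {
  if (!is.data.frame(results)) results <- analogTable(results)
  write.csv(results, path, row.names = FALSE)
  invisible(path)
}

#' Write a similarity surface as an ASCII grid raster
#'
#' One-band plain-text raster (sigma values, nodata at masked cells),
#' readable by standard GIS tools.
#'
#' @param surface A [SimilaritySurface-class].
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
writeSurfaceGrid <- function(surface, path) {
  writeAsciiGrid(surface@sigma, surface@lat, surface@lon, path)
  invisible(path)
}

#' Export analog results as GeoJSON web layers
#'
#' For each result: the city centroid as a Point, the best-analog cell
#' center as a Point, and the city-to-analog LineString, each carrying
#' `city`, `scenario`, `sigma`, `class`, `distance_km` and `bearing_deg`
#' properties. Coordinates are GeoJSON order (lon, lat).
#'
#' @param results Data frame from [runScenarios()] (needs the city
#'   centroids supplied via `cities`).
#' @param cities List of [UrbanArea-class] covering every city in
#'   `results`.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
exportAnalogGeoJSON <- function(results, cities, path) {
  if (!is.data.frame(results)) results <- analogTable(results)
  centroids <- lapply(cities, cityCentroid)
  names(centroids) <- vapply(cities, cityName, character(1))
  features <- list()
  for (i in seq_len(nrow(results))) {
    r <- results[i, ]
    ct <- centroids[[r$city]]
    if (is.null(ct)) stop("no UrbanArea supplied for city '", r$city, "'")
    props <- list(city = r$city, scenario = r$scenario, sigma = r$minSigma,
                  class = r$analogClass, distance_km = r$distanceKm,
                  bearing_deg = r$bearingDeg)
    cityPt <- c(ct[["lon"]], ct[["lat"]])
    analogPt <- c(r$analogLon, r$analogLat)
    features <- c(features, list(
      list(type = "Feature",
           geometry = list(type = "Point", coordinates = cityPt),
           properties = c(props, role = "city")),
      list(type = "Feature",
           geometry = list(type = "Point", coordinates = analogPt),
           properties = c(props, role = "analog")),
      list(type = "Feature",
           geometry = list(type = "LineString",
                           coordinates = list(cityPt, analogPt)),
           properties = c(props, role = "link"))))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read urban-area polygons from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon (or MultiPolygon; outer ring of
#' the first polygon is used) features. The name property field is
#' configurable; area is taken from an `area_km2` property when present,
#' otherwise approximated from the ring on the sphere.
#'
#' @param path GeoJSON path.
#' @param nameField Property holding the city name (default `"name"`).
#' @return List of [UrbanArea-class].
#' @export
readUrbanAreasGeoJSON <- function(path, nameField = "name") {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  lapply(gj$features, function(f) {
    geom <- f$geometry
    ring <- switch(geom$type,
      Polygon = geom$coordinates[[1]],
      MultiPolygon = geom$coordinates[[1]][[1]],
      stop("unsupported geometry type: ", geom$type))
    m <- do.call(rbind, lapply(ring, function(p)
      c(lat = p[[2]], lon = p[[1]])))
    nm <- f$properties[[nameField]]
    if (is.null(nm)) stop("feature lacks a '", nameField, "' property")
    centroid <- c(lat = mean(range(m[, "lat"])),
                  lon = mean(range(m[, "lon"])))
    area <- f$properties[["area_km2"]]
    if (is.null(area)) {
      kmLat <- pi / 180 * .EARTH_RADIUS_KM
      area <- diff(range(m[, "lat"])) * kmLat *
        diff(range(m[, "lon"])) * kmLat * cos(centroid[["lat"]] * pi / 180)
    }
    urbanArea(nm, centroid, area, polygon = m)
  })
}

#' Write urban areas as GeoJSON
#'
#' @param cities List of [UrbanArea-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeUrbanAreasGeoJSON <- function(cities, path) {
  features <- lapply(cities, function(city) {
    poly <- cityPolygon(city)
    ring <- lapply(seq_len(nrow(poly)), function(i)
      c(poly[i, "lon"], poly[i, "lat"]))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(name = cityName(city),
                           area_km2 = cityArea(city)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
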