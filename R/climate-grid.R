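#' Read gridded climate normals into a ClimateGrid
#'
#' Reads one single-layer ASCII-grid raster per seasonal variable, applies
#' any declared packed-integer scale/offset (e.g. temperatures stored as
#' tenths of a degree need `scale = 0.1`), and combines them into a
#' [ClimateGrid-class]. The validity mask is the union of the per-layer
#' nodata masks: a cell missing in any layer is masked in all.
#'
#' @param paths Character vector of raster file paths.
#' @param variableMap Data frame with one row per file, columns `file`
#'   (basename or full path, matched against `paths`), `variable`
#'   (`"tmin"`, `"tmax"`, `"prcp"`), `season` (`"DJF"`, ...), and optional
#'   `scale` (default 1) and `offset` (default 0); stored value maps to
#'   physical units as `value * scale + offset`. Must cover each of the 12
#'   variables exactly once.
#' @param metadata Optional metadata list attached to the grid.
#' @return A [ClimateGrid-class] in physical units (deg C, mm).
#' @export
readNormals <- function(paths, variableMap, metadata = list()) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing input file(s): ",
                            paste(missing, collapse = ", "))
  vm <- as.data.frame(variableMap)
  if (is.null(vm$scale)) vm$scale <- 1
  if (is.null(vm$offset)) vm$offset <- 0
  vm$scale[is.na(vm$scale)] <- 1
  vm$offset[is.na(vm$offset)] <- 0
  vm$key <- paste(vm$variable, vm$season, sep = "_")
  if (!setequal(vm$key, climateVariables()) || anyDuplicated(vm$key))
    stop("variableMap must cover all 12 variables exactly once; got: ",
         paste(sort(vm$key), collapse = ", "))

  ref <- NULL
  layers <- vector("list", 12)
  names(layers) <- climateVariables()
  for (k in seq_len(nrow(vm))) {
    p <- paths[basename(paths) == basename(vm$file[k])]
    if (length(p) != 1)
      stop("variableMap entry '", vm$file[k],
           "' does not match exactly one input path")
    g <- readAsciiGrid(p)
    if (is.null(ref)) ref <- g
    else if (length(g$lat) != length(ref$lat) ||
             length(g$lon) != length(ref$lon) ||
             max(abs(g$lat - ref$lat)) > 1e-8 ||
             max(abs(g$lon - ref$lon)) > 1e-8)
      stop("grid geometry of '", vm$file[k],
           "' does not match the first layer")
    layers[[vm$key[k]]] <- g$values * vm$scale[k] + vm$offset[k]
  }
  mask <- Reduce(`&`, lapply(layers, function(m) is.finite(m)))
  climateGrid(ref$lat, ref$lon, layers, mask = mask, metadata = metadata)
}

#' Write a ClimateGrid as one ASCII grid per layer
#'
#' Writes 12 files `<prefix><variable>.asc` plus `<prefix>metadata.json`.
#' Finite cells round-trip bit-for-bit through [readClimateGrid()].
#'
#' @param grid A [ClimateGrid-class].
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Named character vector of the layer file paths, invisibly.
#' @export
writeClimateGrid <- function(grid, dir, prefix = "") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(climateVariables(), function(v) {
    p <- file.path(dir, paste0(prefix, v, ".asc"))
    writeAsciiGrid(gridLayers(grid)[[v]], gridLat(grid), gridLon(grid), p)
    p
  }, character(1))
  meta <- gridMetadata(grid)
  if (length(meta))
    jsonlite::write_json(meta, file.path(dir, paste0(prefix, "metadata.json")),
                         auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a ClimateGrid written by writeClimateGrid
#'
#' @param dir Directory holding `<prefix><variable>.asc` files.
#' @param prefix Filename prefix used when writing.
#' @return A [ClimateGrid-class].
#' @export
readClimateGrid <- function(dir, prefix = "") {
  paths <- file.path(dir, paste0(prefix, climateVariables(), ".asc"))
  vm <- data.frame(file = basename(paths),
                   variable = rep(c("tmin", "tmax", "prcp"), each = 4),
                   season = rep(climateSeasons(), 3))
  metaPath <- file.path(dir, paste0(prefix, "metadata.json"))
  meta <- if (file.exists(metaPath)) jsonlite::read_json(metaPath) else list()
  readNormals(paths, vm, metadata = meta)
}

#' Crop a ClimateGrid to a lat-lon bounding box
#'
#' Keeps exactly the cells whose centers fall inside the (closed) bounds;
#' layers and mask subset consistently. The canonical study domain of the
#' analysis this package supports runs from the equator to 80 deg N and
#' 170 to 30 deg W.
#'
#' @param grid A [ClimateGrid-class].
#' @param latMin,latMax,lonMin,lonMax Bounds in degrees.
#' @return The cropped [ClimateGrid-class].
#' @export
cropDomain <- function(grid, latMin, latMax, lonMin, lonMax) {
  ri <- which(gridLat(grid) >= latMin & gridLat(grid) <= latMax)
  ci <- which(gridLon(grid) >= lonMin & gridLon(grid) <= lonMax)
  if (!length(ri) || !length(ci))
    stop("crop bounds do not intersect the grid domain")
  climateGrid(gridLat(grid)[ri], gridLon(grid)[ci],
              lapply(gridLayers(grid), function(m) m[ri, ci, drop = FALSE]),
              mask = gridMask(grid)[ri, ci, drop = FALSE],
              metadata = gridMetadata(grid))
}

#' Ensemble mean across climate scenarios
#'
#' Averages climate *variables* across ensemble members, cell by cell
#' (grids) or element by element (city climate vectors). This is the
#' ensemble path of the pipeline: sigma dissimilarity is computed once
#' against the ensemble-mean climate, never averaged across members.
#' For grids, a cell masked in any member is masked in the mean.
#'
#' @param members List of [ClimateGrid-class] objects with identical
#'   geometry, or list of 12-variable climate vectors.
#' @return The same type as the members.
#' @export
ensembleMean <- function(members) {
  if (!length(members)) stop("ensemble needs at least one member")
  if (is(members[[1]], "ClimateGrid")) {
    ref <- members[[1]]
    for (m in members[-1]) {
      if (length(gridLat(m)) != length(gridLat(ref)) ||
          length(gridLon(m)) != length(gridLon(ref)) ||
          max(abs(gridLat(m) - gridLat(ref))) > 1e-8 ||
          max(abs(gridLon(m) - gridLon(ref))) > 1e-8)
        stop("ensemble members have mismatched grid geometry")
    }
    mask <- Reduce(`&`, lapply(members, gridMask))
    layers <- lapply(climateVariables(), function(v)
      Reduce(`+`, lapply(members, function(m) gridLayers(m)[[v]])) /
        length(members))
    names(layers) <- climateVariables()
    climateGrid(gridLat(ref), gridLon(ref), layers, mask = mask,
                metadata = gridMetadata(ref))
  } else {
    vecs <- lapply(members, function(v) {
      if (!all(climateVariables() %in% names(v)))
        stop("ensemble member is not a 12-variable climate vector")
      v[climateVariables()]
    })
    out <- Reduce(`+`, vecs) / length(vecs)
    names(out) <- climateVariables()
    out
  }
}

# Even-odd (ray casting) point-in-polygon test on lon/lat treated as
# planar; adequate for city-scale polygons away from the dateline.
.pointInPolygon <- function(lat, lon, polygon) {
  py <- polygon[, "lat"]; px <- polygon[, "lon"]
  n <- length(px)
  j <- n
  inside <- rep(FALSE, length(lat))
  for (i in seq_len(n)) {
    cross <- ((py[i] > lat) != (py[j] > lat)) &
      (lon < (px[j] - px[i]) * (lat - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Extract a city's climate vector from a grid
#'
#' Either the unweighted mean over the valid cells whose centers fall
#' inside the city polygon (`"polygon_mean"`, the default used for city
#' future climates) or the value at the single cell containing the
#' centroid (`"centroid"`, for sensitivity checks).
#'
#' @param grid A [ClimateGrid-class].
#' @param city An [UrbanArea-class].
#' @param mode `"polygon_mean"` or `"centroid"`.
#' @return Named 12-variable climate vector.
#' @export
extractCityClimate <- function(grid, city,
                               mode = c("polygon_mean", "centroid")) {
  mode <- match.arg(mode)
  lat <- gridLat(grid); lon <- gridLon(grid)
  if (mode == "centroid" || nrow(cityPolygon(city)) == 0) {
    ct <- cityCentroid(city)
    ri <- which.min(abs(lat - ct[["lat"]]))
    ci <- which.min(abs(lon - ct[["lon"]]))
    half <- cellSize(grid) / 2
    if (abs(lat[ri] - ct[["lat"]]) > half[["lat"]] + 1e-9 ||
        abs(lon[ci] - ct[["lon"]]) > half[["lon"]] + 1e-9 ||
        !gridMask(grid)[ri, ci])
      stop(sprintf("city '%s': centroid does not fall in a valid grid cell",
                   cityName(city)))
    out <- vapply(gridLayers(grid), function(m) m[ri, ci], numeric(1))
  } else {
    cellLat <- matrix(lat, length(lat), length(lon))
    cellLon <- matrix(lon, length(lat), length(lon), byrow = TRUE)
    inside <- matrix(.pointInPolygon(as.vector(cellLat), as.vector(cellLon),
                                     cityPolygon(city)),
                     length(lat), length(lon))
    keep <- inside & gridMask(grid)
    if (!any(keep))
      stop(sprintf("city '%s': polygon intersects no valid grid cell",
                   cityName(city)))
    out <- vapply(gridLayers(grid), function(m) mean(m[keep]), numeric(1))
  }
  names(out) <- climateVariables()
  out
}
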