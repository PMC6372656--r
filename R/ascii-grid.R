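# ESRI ASCII grid (.asc) reader/writer. Plain-text raster interchange:
# a 6-line header (ncols, nrows, xllcorner/xllcenter, yllcorner/yllcenter,
# cellsize, NODATA_value) followed by nrows lines of ncols values, first
# data row = northernmost. Values are written at full double precision so
# write -> read round-trips finite cells bit-for-bit.

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file.
#' @return List with `values` (numeric matrix, rows north to south, nodata
#'   as `NA`), `lat`, `lon` (cell-center coordinate vectors, lat descending)
#'   and `cellsize` (degrees).
#' @export
readAsciiGrid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^[a-zA-Z]", trimws(lines[i]))) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  if (!all(c("ncols", "nrows") %in% names(hdr)) ||
      !("cellsize" %in% names(hdr) || all(c("dx", "dy") %in% names(hdr))))
    stop("malformed ASCII grid header in ", path)
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nrows * ncols)
    stop(sprintf("expected %d values, found %d in %s", nrows * ncols,
                 length(vals), path))
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  dx <- if (!is.null(hdr$dx)) hdr$dx else hdr$cellsize
  dy <- if (!is.null(hdr$dy)) hdr$dy else hdr$cellsize
  # corner vs center registration
  x0 <- if (!is.null(hdr$xllcenter)) hdr$xllcenter else hdr$xllcorner + dx / 2
  y0 <- if (!is.null(hdr$yllcenter)) hdr$yllcenter else hdr$yllcorner + dy / 2
  lon <- x0 + dx * (seq_len(ncols) - 1)
  lat <- y0 + dy * (nrows - seq_len(nrows))   # row 1 = northernmost
  list(values = m, lat = lat, lon = lon, cellsize = c(dy, dx))
}

#' Write an ESRI ASCII grid
#'
#' @param values Numeric matrix, rows ordered north to south (`NA` =
#'   nodata).
#' @param lat,lon Cell-center coordinate vectors matching `values`.
#' @param path Output path.
#' @param nodata Nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(values, lat, lon, path, nodata = -9999) {
  stopifnot(nrow(values) == length(lat), ncol(values) == length(lon))
  if (length(lat) > 1 && lat[1] < lat[2]) {   # ensure north-first storage
    values <- values[rev(seq_along(lat)), , drop = FALSE]
    lat <- rev(lat)
  }
  dx <- if (length(lon) > 1) abs(lon[2] - lon[1]) else 1
  dy <- if (length(lat) > 1) abs(lat[1] - lat[2]) else dx
  hdr <- c(sprintf("ncols %d", ncol(values)),
           sprintf("nrows %d", nrow(values)),
           sprintf("xllcenter %.10f", min(lon)),
           sprintf("yllcenter %.10f", min(lat)),
           # square cells use the classic single-cellsize header;
           # rectangular cells use the GDAL AAIGrid dx/dy extension
           if (abs(dx - dy) < 1e-9) sprintf("cellsize %.10f", dx)
           else c(sprintf("dx %.10f", dx), sprintf("dy %.10f", dy)),
           sprintf("NODATA_value %d", as.integer(nodata)))
  v <- values
  v[is.na(v)] <- nodata
  rows <- apply(v, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
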