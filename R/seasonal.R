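#' Build a 12-variable seasonal climate vector
#'
#' @param tmin,tmax,prcp Numeric length-4 vectors ordered DJF, MAM, JJA,
#'   SON (or named by season). Temperatures in deg C, precipitation in mm
#'   per season.
#' @return Named numeric vector of length 12 in the canonical
#'   [climateVariables()] order.
#' @examples
#' v <- seasonalClimateVector(tmin = c(-5, 5, 15, 6),
#'                            tmax = c(3, 14, 27, 15),
#'                            prcp = c(200, 250, 300, 240))
#' @export
seasonalClimateVector <- function(tmin, tmax, prcp) {
  pick <- function(x) {
    if (!is.null(names(x))) x <- x[climateSeasons()]
    stopifnot(length(x) == 4)
    as.numeric(x)
  }
  out <- c(pick(tmin), pick(tmax), pick(prcp))
  names(out) <- climateVariables()
  validateClimateVector(out)
  out
}

#' Validate a seasonal climate vector
#'
#' Checks the 12-vector invariants: all values finite, `tmax >= tmin` in
#' every season, precipitation nonnegative.
#'
#' @param x Named numeric vector with the 12 [climateVariables()] entries.
#' @return `x`, invisibly; errors on violation.
#' @export
validateClimateVector <- function(x) {
  if (!all(climateVariables() %in% names(x)))
    stop("climate vector must carry all 12 variables: ",
         paste(setdiff(climateVariables(), names(x)), collapse = ", "))
  x <- x[climateVariables()]
  if (any(!is.finite(x))) stop("climate vector has non-finite values")
  for (s in climateSeasons()) {
    if (x[paste0("tmax_", s)] < x[paste0("tmin_", s)])
      stop(sprintf("tmax < tmin in season %s", s))
    if (x[paste0("prcp_", s)] < 0)
      stop(sprintf("negative precipitation in season %s", s))
  }
  invisible(x)
}

.asMonthlyList <- function(monthly) {
  if (is.numeric(monthly) && length(monthly) == 12)
    monthly <- as.list(monthly)
  if (!is.list(monthly) || length(monthly) != 12)
    stop("expected 12 monthly layers (got ", length(monthly), ")")
  if (!is.null(names(monthly))) {
    idx <- match(sprintf("%02d", 1:12), names(monthly))
    if (any(is.na(idx))) idx <- match(month.abb, names(monthly))
    if (any(is.na(idx))) idx <- match(as.character(1:12), names(monthly))
    if (any(is.na(idx)))
      stop("monthly layers must be named by month number (1..12, '01'..'12') ",
           "or month abbreviation")
    monthly <- monthly[idx]
  }
  monthly
}

#' Aggregate 12 monthly layers to the four climatological seasons
#'
#' Temperatures use the arithmetic mean of the season's three months;
#' precipitation uses the seasonal total. DJF combines December, January
#' and February of the same calendar slot, the convention for
#' climatological normals (time series use the lagged-December rule of
#' [monthlyToSeasonalSeries()] instead).
#'
#' @param monthly List of 12 monthly layers (matrices or scalars), ordered
#'   Jan..Dec or named by month, or a numeric vector of length 12.
#' @param statistic `"mean"` for temperature, `"sum"` for precipitation.
#' @return Named list `DJF`, `MAM`, `JJA`, `SON` of the same layer type
#'   (matrices stay matrices; scalar input yields a named numeric vector).
#' @examples
#' monthlyToSeasonal(rep(5, 12), "mean")           # 5 deg C all seasons
#' monthlyToSeasonal(rep(100, 12), "sum")[["JJA"]] # 300 mm
#' @export
monthlyToSeasonal <- function(monthly, statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  monthly <- .asMonthlyList(monthly)
  scalarIn <- all(vapply(monthly, function(m) length(m) == 1, logical(1)))
  out <- lapply(.SEASON_MONTHS, function(months) {
    acc <- Reduce(`+`, monthly[months])
    if (statistic == "mean") acc / 3 else acc
  })
  if (scalarIn) unlist(out) else out
}
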