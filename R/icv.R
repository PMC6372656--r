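#' Estimate the interannual climatic variability (ICV) model
#'
#' Fits the 12 x 12 sample covariance (divisor `nYears - 1`) of a city's
#' annual seasonal climate vectors, optionally after removing a per-variable
#' linear trend in year (the trend is removed, the mean retained). With
#' `truncation`, the covariance is diagonalised and only principal axes
#' whose standard deviation exceeds the threshold are retained (always at
#' least one); the returned covariance is then diagonal in the retained
#' orthonormal basis and the retained count becomes the chi
#' degrees of freedom used downstream.
#'
#' A full-rank 12 x 12 estimate needs `nYears >= 13`; shorter series are
#' permitted with truncation.
#'
#' @param series A [SeasonalSeries-class].
#' @param detrend Remove a linear year trend per variable first?
#' @param truncation `NULL` for none, or a positive number `t`: retain
#'   principal axes with standard deviation > `t` (in the variables'
#'   physical units).
#' @return An [ICVModel-class].
#' @export
icvCovariance <- function(series, detrend = FALSE, truncation = NULL) {
  X <- seasonalValues(series)
  mu <- colMeans(X)
  if (detrend) {
    yr <- as.numeric(rownames(X))
    X <- apply(X, 2, function(col) residuals(lm(col ~ yr))) +
      matrix(mu, nrow(X), 12, byrow = TRUE)
  }
  S <- cov(X)
  vars <- diag(S)
  if (is.null(truncation)) {
    zero <- names(vars)[vars <= .Machine$double.eps * max(vars, 1)]
    if (length(zero))
      stop("zero-variance variable(s) ", paste(zero, collapse = ", "),
           ": use PCA truncation or add jitter")
    icvModel(mu, S, detrended = detrend)
  } else {
    eg <- eigen(S, symmetric = TRUE)
    sdev <- sqrt(pmax(eg$values, 0))
    keep <- max(1L, sum(sdev > truncation))
    icvModel(mu, diag(eg$values[seq_len(keep)], keep, keep),
             basis = eg$vectors[, seq_len(keep), drop = FALSE],
             nDims = keep, detrended = detrend)
  }
}
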