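#' ICV-scaled Mahalanobis distance
#'
#' Computes `D = sqrt((x - y)' Sigma^-1 (x - y))` with `Sigma` the ICV
#' covariance, via a Cholesky factorisation and triangular solve (no
#' explicit matrix inverse). When the ICV model carries a truncated
#' principal-axis basis, the difference vector is first projected onto the
#' retained axes and the (diagonal) covariance applied there. `y` may be a
#' matrix with one row per candidate location, in which case a distance is
#' returned per row — this is the vectorised path used for whole-grid
#' similarity surfaces.
#'
#' @param x Named 12-variable climate vector.
#' @param y Named 12-variable climate vector, or a matrix with the 12
#'   variables as columns.
#' @param icv An [ICVModel-class]; its covariance must be full rank in the
#'   retained basis.
#' @param ridge Optional nonnegative jitter added to the covariance
#'   diagonal (default 0, i.e. off) for near-singular covariances.
#' @return Nonnegative numeric vector of distances.
#' @export
mahalanobisDistance <- function(x, y, icv, ridge = 0) {
  x <- x[climateVariables()]
  if (is.matrix(y)) y <- y[, climateVariables(), drop = FALSE]
  else y <- matrix(y[climateVariables()], 1, 12,
                   dimnames = list(NULL, climateVariables()))
  d <- sweep(y, 2, x)                # rows: y_i - x
  B <- icvBasis(icv)
  if (prod(dim(B)) > 0) d <- d %*% B # project onto retained axes
  S <- icvCov(icv)
  if (ridge > 0) S <- S + diag(ridge, nrow(S))
  R <- tryCatch(chol(S), error = function(e) {
    C <- stats::cov2cor(S)
    diag(C) <- 0
    ij <- which(abs(C) == max(abs(C)), arr.ind = TRUE)[1, ]
    nm <- colnames(S)
    if (is.null(nm)) nm <- paste0("dim", seq_len(ncol(S)))
    stop(sprintf(
      "ICV covariance is singular or near-singular (worst pair: %s ~ %s, r = %.6f); use truncation or ridge",
      nm[ij[1]], nm[ij[2]], C[ij[1], ij[2]]))
  })
  z <- backsolve(R, t(d), transpose = TRUE)
  sqrt(colSums(z^2))
}

#' Chi-distribution percentile of a Mahalanobis distance
#'
#' Under multivariate normality, the Mahalanobis distance of an
#' observation from its distribution follows a chi distribution (the
#' square root of a chi-squared) with `n` degrees of freedom, `n` being
#' the number of retained climate dimensions. Returns the CDF at `D`
#' together with the log survival function computed directly in log space,
#' so extreme distances stay informative where the percentile itself
#' rounds to 1.
#'
#' @param D Nonnegative numeric vector of distances.
#' @param n Degrees of freedom (>= 1).
#' @return List with `percentile` (chi CDF values in `[0, 1]`) and
#'   `logSurvival` (natural log of the survival function).
#' @examples
#' round(100 * chiPercentile(2, 1)$percentile)      # 95
#' round(100 * chiPercentile(4, 1)$percentile, 3)   # 99.994
#' @export
chiPercentile <- function(D, n) {
  stopifnot(all(D >= 0), n >= 1)
  list(percentile = pchisq(D^2, df = n),
       logSurvival = pchisq(D^2, df = n, lower.tail = FALSE, log.p = TRUE))
}

#' Convert a chi percentile to sigma dissimilarity
#'
#' Sigma dissimilarity is the multivariate z-score: the quantile of a chi
#' distribution with one degree of freedom at the given percentile, so
#' that a percentile of 0.9545 maps to 2 sigma regardless of the original
#' dimensionality. When the log survival companion is supplied the
#' inversion runs entirely in log space, which stays exact far beyond the
#' point where the percentile itself saturates at 1 in double precision.
#' Values beyond `cap` are clipped and flagged: past the cap the exact
#' magnitude carries no additional information.
#'
#' @param percentile Numeric vector of percentiles in `[0, 1]` (may be
#'   `NULL` when `logSurvival` is given).
#' @param logSurvival Optional log survival values; preferred when
#'   available.
#' @param cap Saturation cap in sigma units (default 12).
#' @return Numeric vector of sigma values with a logical attribute
#'   `saturated` marking clipped entries.
#' @export
percentileToSigma <- function(percentile = NULL, logSurvival = NULL,
                              cap = 12) {
  if (is.null(percentile) && is.null(logSurvival))
    stop("supply a percentile or its log survival")
  sigma <- if (!is.null(logSurvival)) {
    stopifnot(all(logSurvival <= 0))
    sqrt(qchisq(logSurvival, df = 1, lower.tail = FALSE, log.p = TRUE))
  } else {
    stopifnot(all(percentile >= 0 & percentile <= 1))
    sqrt(qchisq(percentile, df = 1))
  }
  saturated <- !is.finite(sigma) | sigma > cap
  sigma[saturated] <- cap
  attr(sigma, "saturated") <- saturated
  sigma
}

#' Sigma dissimilarity between two climates
#'
#' The composed statistic: Mahalanobis distance under the city's ICV
#' model, its percentile within the chi distribution with `n` retained
#' dimensions, and the 1-dof chi quantile of that percentile. Identical
#' climates give 0 sigma (a perfect analog); for `n = 1` sigma equals the
#' distance itself.
#'
#' @param x,y Named 12-variable climate vectors.
#' @param icv An [ICVModel-class].
#' @param cap Saturation cap in sigma units (default 12).
#' @return A [Dissimilarity-class] object.
#' @export
sigmaDissimilarity <- function(x, y, icv, cap = 12) {
  D <- mahalanobisDistance(x, y, icv)
  n <- icvDims(icv)
  cp <- chiPercentile(D, n)
  s <- percentileToSigma(cp$percentile, cp$logSurvival, cap = cap)
  new("Dissimilarity", D = D, n = as.integer(n),
      percentile = cp$percentile, logSurvival = cp$logSurvival,
      sigma = as.numeric(s), saturated = attr(s, "saturated"))
}
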