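---
title: "Climate-analog mapping with sigma dissimilarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Climate-analog mapping with sigma dissimilarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climAnalogs)
```

## The question and the statistic

Climate-analog mapping answers a simple question with a careful statistic:
*which place today has the climate my city is projected to have in the
future?* The climate state of a place is summarised as a 12-vector —
minimum temperature, maximum temperature (°C) and total precipitation (mm)
for each climatological season (DJF, MAM, JJA, SON). For a city with
projected future climate $x$ and a candidate grid cell with contemporary
climate $y$, dissimilarity is measured in three steps:

1. **Mahalanobis distance scaled by interannual climatic variability
   (ICV).** $D = \sqrt{(x - y)^{\top} \Sigma^{-1} (x - y)}$, where
   $\Sigma$ is the covariance of the city's *year-to-year* seasonal
   climate. Scaling by ICV makes a 1 °C shift count for more in a place
   with stable summers than in one with volatile ones, makes the measure
   independent of each variable's units, and discounts the double-counting
   that correlated variables (e.g. tmin and tmax) would otherwise cause.

2. **Chi percentile.** Under multivariate normality, $D$ for draws from
   the city's own climate follows a chi distribution (the square root of a
   chi-squared) with $n$ degrees of freedom, $n$ being the number of
   climate dimensions retained in $\Sigma$. `chiPercentile()` evaluates
   $p = P(\chi_n \le D)$.

3. **Sigma dissimilarity.** $\sigma = F^{-1}_{\chi_1}(p)$, the 1-dof chi
   quantile of that percentile. This re-expresses any multidimensional
   distance as a familiar z-score: $2\sigma$ is the 95th percentile of the
   chi distribution, $4\sigma$ the 99.994th. $0\sigma$ is a perfect
   analog; values $\le 2\sigma$ are *representative* analogs; values
   $> 4\sigma$ indicate a *novel* climate with no meaningful analog in the
   search domain.

The best contemporary analog of a city × scenario is the grid cell
minimising $\sigma$ over the analog pool (`similaritySurface()` then
`bestAnalog()`), reported with the great-circle distance and initial
bearing from the city centroid to that cell.

```{r}
# the anchors that define the sigma scale
round(100 * chiPercentile(2, 1)$percentile)     # 2 sigma = 95th percentile
round(100 * chiPercentile(4, 1)$percentile, 3)  # 4 sigma = 99.994th
```

## Model assumptions

The chi-percentile step assumes the ICV of seasonal climate is
approximately multivariate normal. Seasonal temperature means are close to
normal; seasonal precipitation totals are right-skewed, so the percentile
conversion is an approximation whose quality degrades in strongly arid or
monsoonal regimes. The statistic also assumes the future projection and
the contemporary normals are expressed on a common baseline (the
change-factor downscaling that produces such projections is upstream of
this package and out of its scope), and it deliberately ignores urban heat
islands, extremes, and within-season timing.

## The pipeline and its tunable parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| seasons/variables | everywhere | 12 (3 × 4) | tmin, tmax, prcp per season |
| analog classes | `classifyAnalog()` | ≤2σ, >4σ | representative / poor / novel; boundaries inclusive at 2 and exclusive at 4 |
| station rule | `selectStations()` | ≥5 within 50 km | in-polygon stations first, then nearest outside, by centroid distance |
| IDW power | `idwCombine()` | 1 | plain inverse distance; the combination rule is stated only as "inverse distance weighting" upstream, so the exponent is exposed |
| IDW distance floor | `idwCombine()` | 1 m | a station at the exact centroid must not get infinite weight |
| detrend | `icvCovariance()` | off | detrending the 1960–1990 series is defensible but not part of the canonical recipe; exposed as a switch |
| PCA truncation | `icvCovariance()` | off | for short series or degenerate variables: retain axes with SD above a threshold; the retained count becomes the chi dof |
| sigma cap | `percentileToSigma()` | 12σ | beyond this the exact magnitude is numerically meaningless; capped values are flagged `saturated`, never silent |
| sphere radius | geodesy | 6371.0088 km | mean Earth radius; spherical vs ellipsoidal error is far below one grid cell |
| city future climate | `extractCityClimate()` | `polygon_mean` | unweighted mean over valid cells whose centers fall in the polygon; `centroid` mode for sensitivity checks |

Three of these deserve the reasoning spelled out, because the design was
genuinely open:

**Ensembles average variables, never sigmas.** With 27 earth-system models
per emission pathway, `runScenarios(..., ensembleGroups =)` averages the
12 climate variables across members first and computes sigma once against
the ensemble mean. Averaging per-member sigma values is a different (and
inflated) statistic; the pipeline deliberately provides no path to it, and
a constructed counterexample in the test suite (members whose individual
best analogs both differ from the ensemble's) pins the behaviour down.

**Winter belongs to the year it ends in.** For annual ICV series, DJF of
year $Y$ combines December of $Y-1$ with January–February of $Y$ — the
standard climatological convention. The first calendar year of a station
window is therefore dropped: a 1960–1990 window yields 30 seasonal years.
For 30-year *normals* no lag applies (December is climatological, not
dated).

**DJF at 2σ, tie-breaks and boundaries are conventions, stated once.**
Argmin ties on a similarity surface are broken by row-major scan order
(northernmost row, then west to east) with the tie count surfaced in the
result — deterministic and auditable. Exactly 2σ classifies as
representative and exactly 4σ as poor, matching the ≤2σ / >4σ phrasing of
the thresholds.

## Numerical choices

* Mahalanobis distances use a Cholesky factorisation and triangular solve,
  never an explicit inverse; near-singular covariances raise an error
  naming the most collinear variable pair, with optional ridge jitter and
  PCA truncation as remedies.
* The percentile→sigma inversion runs in log-survival space
  (`qchisq(log.p = TRUE)`): at large $D$ the percentile is
  indistinguishable from 1 in double precision, but the log survival
  function remains exact, so surfaces stay strictly monotone out to the
  12σ cap.
* Bearings are normalised to $[0, 360)$ with a guard for the
  floating-point case where a tiny negative angle modulo 360 returns 360.
  "Average direction" across cities is a circular (vector-sum) mean —
  arithmetic averaging of angles is wrong under wraparound — and
  degenerate bearings (analog coincides with the centroid) are excluded
  and counted.
* Raster I/O uses the plain-text ESRI ASCII grid format (with the GDAL
  `dx`/`dy` extension for non-square cells), written at full double
  precision so grids round-trip bit-for-bit; polygons and web layers are
  GeoJSON.

## What the synthetic generator emulates — and what it does not

`makeGrid()` builds spatially smooth fields: temperature falls linearly
with latitude, swings seasonally, and keeps a fixed diurnal spread;
precipitation rises linearly with longitude; independent Gaussian noise is
added per cell (precipitation truncated at 0) and a configurable fraction
of cells is masked as ocean. `plantFuture()` copies a chosen cell's
climate (plus a known offset) as a city's "projection", so the correct
best analog is known by construction. `makeStationSeries()` draws annual
12-vectors from a known covariance and disaggregates them to months with
small noise, sharing the annual signal across stations.

This supports exact parameter-recovery tests: planted analogs must be
found cell-exactly; a planted cross-correlation of 0.8 must be recovered
through the full station → IDW → seasonal-aggregation → covariance path;
offsets scaled to the 2σ distance must flip the analog class at the
boundary. What passing these tests does *not* show: real climate fields
have orography, coastlines and spatially correlated noise; real
precipitation is heavy-tailed; real station records have inhomogeneities.
The generator makes no attempt to mimic North American climatology or
model spread — it is a controlled truth, not a realistic one.

Problem sizes in the shipped tests are chosen to make the statistics
sharp but cheap: calibration uses $10^5$ Monte-Carlo draws per
dimensionality (standard error ≈ 0.0007 on the 0.9545 coverage), planted
analogs use 20 seeds on 20 × 20 grids, and ICV recovery uses a
10,000-year synthetic series (correlation standard error ≈ 0.004).

## Known limitations

* Multivariate normality of ICV is assumed, as discussed above.
* Point-in-polygon tests treat longitude/latitude as planar — adequate for
  city-scale polygons away from the antimeridian, not for polygons
  spanning it.
* The "spatial heterogeneity in climate" exclusion applied to urban areas
  in published analyses is not quantified anywhere; `filterUrbanAreas()`
  offers a configurable proxy (a minimum number of intersected pool
  cells), off by default.
* The analog pool is scanned exhaustively; for continental 5-arc-minute
  domains this is an O(cells) vectorised pass per city × scenario, which
  is fast in practice, but no spatial indexing is attempted.
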