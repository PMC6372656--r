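test_that("makeGrid builds the configured gradients deterministically", {
  cfg <- syntheticGridConfig(nLat = 8, nLon = 8, noiseSd = 0, lapse = 0.5,
                             diurnalSpread = 8, seed = 1)
  g <- makeGrid(cfg)
  # two cells 10 degrees apart in latitude: the southern one is 5 deg C
  # warmer in every temperature layer
  lat <- gridLat(g)
  i2 <- which.min(abs(lat - (lat[1] - 10)))
  expect_equal(lat[1] - lat[i2], 10)
  for (v in grep("^t", climateVariables(), value = TRUE))
    expect_equal(gridLayers(g)[[v]][i2, 1] - gridLayers(g)[[v]][1, 1],
                 0.5 * 10)
  # diurnal spread holds everywhere without noise
  for (s in climateSeasons())
    expect_equal(gridLayers(g)[[paste0("tmax_", s)]] -
                   gridLayers(g)[[paste0("tmin_", s)]],
                 matrix(8, 8, 8))
  # same seed -> bit-identical; different seed -> different noise
  gN <- makeGrid(syntheticGridConfig(nLat = 10, nLon = 8, noiseSd = 1,
                                     seed = 5))
  expect_identical(gridLayers(makeGrid(syntheticGridConfig(nLat = 10,
                                                           nLon = 8,
                                                           noiseSd = 1,
                                                           seed = 5))),
                   gridLayers(gN))
  gM <- makeGrid(syntheticGridConfig(nLat = 10, nLon = 8, noiseSd = 1,
                                     seed = 6))
  expect_false(identical(gridLayers(gM), gridLayers(gN)))
  expect_equal(gridMetadata(gN)$seed, 5)
  expect_error(syntheticGridConfig(nLat = 1), "nLat")
})

test_that("plantFuture returns the target cell's climate plus the offset", {
  g <- makeGrid(syntheticGridConfig(nLat = 10, nLon = 10, noiseSd = 0.5,
                                    oceanFraction = 0.3, seed = 9))
  valid <- which(gridMask(g), arr.ind = TRUE)
  cell <- valid[1, ]
  v <- plantFuture(g, cell)
  expect_equal(unname(v),
               vapply(gridLayers(g), function(m) m[cell[1], cell[2]],
                      numeric(1)), ignore_attr = TRUE)
  v2 <- plantFuture(g, cell, offset = 2)
  expect_equal(v2, v + 2)
  masked <- which(!gridMask(g), arr.ind = TRUE)[1, ]
  expect_error(plantFuture(g, masked), "masked")
})

test_that("a uniform warming offset shifts the best analog equatorward", {
  g <- makeGrid(syntheticGridConfig(nLat = 21, nLon = 5, noiseSd = 0,
                                    seed = 1))
  cell <- c(10, 3)
  off <- rep(0, 12)
  names(off) <- climateVariables()
  off[grep("^t", names(off))] <- 2         # +2 deg C in all temperatures
  fut <- plantFuture(g, cell, off)
  res <- bestAnalog(similaritySurface(fut, g, identityICV()),
                    makeUrbanPolygon(c(lat = gridLat(g)[cell[1]],
                                       lon = gridLon(g)[cell[2]]),
                                     100, "warm"))
  # warmer future matches contemporary climate at lower latitude
  expect_lt(res@analogLat, gridLat(g)[cell[1]])
})

test_that("makeStationSeries is reproducible and respects its covariance", {
  mu <- rep(c(5, 15, 300), each = 4)
  S <- diag(c(rep(1, 8), rep(25, 4)))
  a <- makeStationSeries(mu, S, nYears = 30, nStations = 3, seed = 12)
  b <- makeStationSeries(mu, S, nYears = 30, nStations = 3, seed = 12)
  expect_identical(lapply(a, stationRecords), lapply(b, stationRecords))
  expect_length(a, 3)
  expect_error(makeStationSeries(mu, diag(12) - 0.5 * matrix(1, 12, 12),
                                 nYears = 10),
               "positive semi-definite")
  # single station end-to-end: idwCombine is the identity path
  one <- makeStationSeries(mu, S, nYears = 30, nStations = 1, seed = 4)
  comb <- idwCombine(one, c(lat = 40, lon = -100))
  expect_equal(stationRecords(comb)[c("tmin", "tmax", "prcp")],
               stationRecords(one[[1]])[c("tmin", "tmax", "prcp")])
})

test_that("station generation + aggregation recovers the drawn annual vectors", {
  mu <- rep(c(5, 15, 300), each = 4)
  S <- randomPSD(seed = 2)
  st <- makeStationSeries(mu, S, nYears = 500, nStations = 4,
                          monthlyNoiseSd = 0.005, seed = 3)
  ss <- monthlyToSeasonalSeries(idwCombine(st, c(lat = 40, lon = -100)))
  expect_equal(nYears(ss), 500)
  m <- icvCovariance(ss)
  # estimator consistency: at n = 500 the covariance is within sampling
  # error of the truth (elements have SE ~ sqrt(2/n) on unit scales)
  expect_lt(max(abs(icvCov(m) - S) / (abs(S) + 1)), 0.3)
  expect_equal(unname(icvMean(m)), mu, tolerance = 0.2)
})

test_that("makeUrbanPolygon builds squares of the requested area", {
  city <- makeUrbanPolygon(c(lat = 40, lon = -100), 100, "sq")
  expect_equal(unname(cityCentroid(city)), c(40, -100))
  poly <- cityPolygon(city)
  # side ~ 10 km: measure the southern edge geodesically
  edge <- geodesicDistanceBearing(poly[1, ], poly[2, ])
  expect_equal(edge[["distanceKm"]], 10, tolerance = 0.01)
  # deterministic: same parameters, identical polygon
  expect_identical(cityPolygon(makeUrbanPolygon(c(lat = 40, lon = -100),
                                                100, "sq")), poly)
  expect_error(makeUrbanPolygon(c(lat = 40, lon = -100), -5), "areaKm2 > 0")
})

test_that("the full synthetic pipeline recovers every planted city", {
  g <- makeGrid(syntheticGridConfig(nLat = 20, nLon = 20, noiseSd = 0,
                                    oceanFraction = 0.1, seed = 17))
  valid <- which(gridMask(g), arr.ind = TRUE)
  set.seed(17)
  cells <- valid[sample(nrow(valid), 4), , drop = FALSE]
  mu <- rep(c(5, 15, 300), each = 4)
  S <- diag(c(rep(1, 8), rep(100, 4)))
  cities <- list(); icvs <- list(); futures <- list()
  for (k in seq_len(nrow(cells))) {
    nm <- sprintf("city%d", k)
    center <- c(lat = gridLat(g)[cells[k, 1]], lon = gridLon(g)[cells[k, 2]])
    cities[[k]] <- makeUrbanPolygon(center, 100, nm)
    st <- makeStationSeries(mu, S, nYears = 40, nStations = 5,
                            center = center, seed = 100 + k)
    icvs[[nm]] <- icvCovariance(monthlyToSeasonalSeries(
      idwCombine(selectStations(st, cities[[k]], years = 1961:1990),
                 center)))
    futures[[nm]] <- list(base = plantFuture(g, cells[k, ]))
  }
  res <- runScenarios(cities, g, icvs, futures)
  expect_equal(nrow(res), 4)
  expect_true(all(res$minSigma < 0.05))
  for (k in seq_len(nrow(cells))) {
    row <- res[res$city == sprintf("city%d", k), ]
    expect_equal(row$analogLat, gridLat(g)[cells[k, 1]])
    expect_equal(row$analogLon, gridLon(g)[cells[k, 2]])
  }
})

test_that("class boundaries flip at offsets scaled to the 2-sigma distance", {
  # an offset with Mahalanobis length at the chi(n) 95.45th percentile
  # sits exactly on the representative/poor boundary
  g <- makeGrid(syntheticGridConfig(nLat = 12, nLon = 12, noiseSd = 0,
                                    lapse = 2, prcpGradient = 10, seed = 23))
  cell <- c(6, 6)
  icv <- identityICV()
  Dstar <- sqrt(qchisq(pchisq(4, 1), 12))  # D with sigma = 2 at n = 12
  unit <- rep(1 / sqrt(12), 12)
  city <- makeUrbanPolygon(c(lat = gridLat(g)[cell[1]],
                             lon = gridLon(g)[cell[2]]), 100, "edge")
  below <- bestAnalog(similaritySurface(
    plantFuture(g, cell, unit * (Dstar * 0.99)), g, icv), city)
  above <- bestAnalog(similaritySurface(
    plantFuture(g, cell, unit * (Dstar * 1.01)), g, icv), city)
  # the planted cell is still the argmin in both cases ...
  expect_equal(below@analogLat, gridLat(g)[cell[1]])
  # ... but the class flips across the boundary
  expect_equal(below@analogClass, "representative")
  expect_equal(above@analogClass, "poor")
  expect_equal(below@minSigma, 2, tolerance = 0.05)
  expect_equal(above@minSigma, 2, tolerance = 0.05)
})
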