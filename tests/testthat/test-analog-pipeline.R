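plantedSetup <- function(seed = 1, noiseSd = 0.3, cell = c(8, 9),
                         nLat = 15, nLon = 15) {
  g <- makeGrid(syntheticGridConfig(nLat = nLat, nLon = nLon,
                                    noiseSd = noiseSd, seed = seed))
  city <- makeUrbanPolygon(c(lat = gridLat(g)[cell[1]],
                             lon = gridLon(g)[cell[2]]), 100, "planted")
  list(grid = g, city = city, future = plantFuture(g, cell),
       cell = cell)
}

test_that("similaritySurface is zero on a perfect-analog field and scale-invariant", {
  lat <- c(41.5, 40.5); lon <- c(-100.5, -99.5)
  g <- testGrid(lat, lon)
  v <- testVector()
  surf <- similaritySurface(v, g, identityICV())
  expect_equal(unname(surfaceSigma(surf)), matrix(0, 2, 2))
  # doubling precipitation units in values and covariance changes nothing
  sc <- setNames(rep(1, 12), climateVariables()); sc[9:12] <- 2
  g2 <- climateGrid(lat, lon, Map(function(m, k) m * k,
                                  gridLayers(g)[climateVariables()],
                                  as.list(sc)))
  S <- diag(sc^2); dimnames(S) <- list(climateVariables(), climateVariables())
  surf2 <- similaritySurface(v * sc, g2, icvModel(rep(0, 12), S))
  expect_equal(surfaceSigma(surf2), surfaceSigma(surf), tolerance = 1e-9)
  # masked cells carry no value
  gm <- testGrid(lat, lon, mask = matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2))
  expect_true(is.na(surfaceSigma(similaritySurface(v, gm,
                                                   identityICV()))[2, 1]))
})

test_that("bestAnalog recovers a planted analog cell exactly", {
  s <- plantedSetup(seed = 42)
  surf <- similaritySurface(s$future, s$grid, identityICV(), city = "planted")
  res <- bestAnalog(surf, s$city)
  expect_equal(c(res@analogLat, res@analogLon),
               c(gridLat(s$grid)[s$cell[1]], gridLon(s$grid)[s$cell[2]]))
  expect_equal(res@minSigma, 0)
  expect_equal(res@analogClass, "representative")
  expect_equal(res@tieCount, 1L)
  expect_true(res@degenerateBearing)       # analog is the city itself
})

test_that("bestAnalog breaks ties by scan order and counts them", {
  lat <- c(41.5, 40.5); lon <- c(-100.5, -99.5)
  g <- testGrid(lat, lon)
  surf <- similaritySurface(testVector(), g, identityICV())
  city <- urbanArea("flat", c(lat = 40.5, lon = -99.5), 60)
  res <- bestAnalog(surf, city)
  expect_equal(res@tieCount, 4L)
  # first valid cell in scan order: northernmost row, westernmost column
  expect_equal(c(res@analogLat, res@analogLon), c(41.5, -100.5))
  # all-masked surface is a domain error
  expect_error(similaritySurface(testVector(),
                                 testGrid(lat, lon,
                                          mask = matrix(FALSE, 2, 2)),
                                 identityICV()),
               "no valid cells")
})

test_that("classifyAnalog applies the published thresholds and boundaries", {
  expect_equal(classifyAnalog(0.57), "representative")  # D.C. under RCP4.5
  expect_equal(classifyAnalog(2.89), "poor")            # D.C. under RCP8.5
  expect_equal(classifyAnalog(c(2, 2.0001, 4, 4.0001, 7)),
               c("representative", "poor", "poor", "novel", "novel"))
  expect_error(classifyAnalog(-0.1), "nonnegative")
})

test_that("geodesicDistanceBearing matches the haversine oracle", {
  cases <- list(list(c(39, -77), c(38, -77)),       # due south
                list(c(0, 0), c(0, 1)),             # equatorial arc
                list(c(45, -100), c(52, -80)),
                list(c(10, -170), c(-5, -140)))
  for (cs in cases) {
    got <- geodesicDistanceBearing(cs[[1]], cs[[2]])
    want <- haversineOracle(cs[[1]], cs[[2]])
    expect_equal(got[["distanceKm"]], want[["distanceKm"]], tolerance = 1e-6)
    expect_equal(got[["bearingDeg"]], want[["bearingDeg"]], tolerance = 1e-6)
  }
  expect_equal(geodesicDistanceBearing(c(39, -77), c(38, -77))[["bearingDeg"]],
               180)
  expect_equal(geodesicDistanceBearing(c(0, 0), c(0, 1))[["distanceKm"]],
               111.19, tolerance = 0.1)
  same <- geodesicDistanceBearing(c(40, -100), c(40, -100))
  expect_equal(as.numeric(same), c(0, 0))
  expect_true(attr(same, "degenerate"))
  expect_error(geodesicDistanceBearing(c(95, 0), c(0, 0)), "invalid")
})

test_that("translating the planted cell moves distance/bearing per the oracle", {
  s <- plantedSetup(seed = 5, cell = c(4, 4))
  for (shift in list(c(4, 0), c(0, 5), c(6, 8))) {
    target <- s$cell + shift
    surf <- similaritySurface(plantFuture(s$grid, target), s$grid,
                              identityICV())
    res <- bestAnalog(surf, s$city)
    want <- haversineOracle(cityCentroid(s$city),
                            c(gridLat(s$grid)[target[1]],
                              gridLon(s$grid)[target[2]]))
    expect_equal(res@distanceKm, want[["distanceKm"]], tolerance = 1e-6)
    expect_equal(res@bearingDeg, want[["bearingDeg"]], tolerance = 1e-6)
  }
})

test_that("runScenarios yields one result per city x scenario, ensembles variables first", {
  s1 <- plantedSetup(seed = 1, cell = c(3, 3))
  s2cell <- c(11, 12)
  fut2 <- plantFuture(s1$grid, s2cell)
  city2 <- makeUrbanPolygon(c(lat = gridLat(s1$grid)[s2cell[1]],
                              lon = gridLon(s1$grid)[s2cell[2]]), 100, "B")
  cities <- list(s1$city, city2)
  icvs <- list(planted = identityICV(), B = identityICV())
  futures <- list(planted = list(sc1 = s1$future, sc2 = s1$future + 0.5,
                                 sc3 = s1$future + 1),
                  B = list(sc1 = fut2, sc2 = fut2 + 0.5, sc3 = fut2 + 1))
  res <- runScenarios(cities, s1$grid, icvs, futures)
  expect_equal(nrow(res), 6)                       # 2 cities x 3 scenarios
  expect_length(attr(res, "failures"), 0)

  # identical members: the ensemble equals any single member
  futSame <- list(planted = setNames(rep(list(s1$future), 27),
                                     paste0("esm", 1:27)))
  one <- runScenarios(cities[1], s1$grid, icvs["planted"], futSame,
                      ensembleGroups = list(RCP = paste0("esm", 1:27)))
  single <- runScenarios(cities[1], s1$grid, icvs["planted"],
                         list(planted = futSame$planted["esm1"]))
  expect_equal(one$minSigma, single$minSigma)
  expect_equal(one[c("analogLat", "analogLon")],
               single[c("analogLat", "analogLon")])
})

test_that("the ensemble averages climate variables, never sigma values", {
  # noise-free lapse grid: climate is linear in latitude, so the mean of
  # the climates at rows 4 and 8 is exactly the climate at row 6 --
  # a planted analog that belongs to neither member.
  g <- makeGrid(syntheticGridConfig(nLat = 11, nLon = 5, noiseSd = 0,
                                    seed = 2))
  mA <- plantFuture(g, c(4, 3))
  mB <- plantFuture(g, c(8, 3))
  city <- makeUrbanPolygon(c(lat = gridLat(g)[6], lon = gridLon(g)[3]),
                           100, "mid")
  icvs <- list(mid = identityICV())
  futures <- list(mid = list(a = mA, b = mB))
  memberRes <- runScenarios(list(city), g, icvs, futures)
  ensRes <- runScenarios(list(city), g, icvs, futures,
                         ensembleGroups = list(ens = c("a", "b")))
  expect_equal(ensRes$analogLat, gridLat(g)[6])
  expect_equal(ensRes$minSigma, 0)
  expect_false(ensRes$analogLat %in% memberRes$analogLat)
})

test_that("per-city failures quarantine the city and others proceed", {
  s <- plantedSetup(seed = 3)
  cityBad <- makeUrbanPolygon(c(lat = 40, lon = -100), 100, "no-icv")
  res <- runScenarios(list(s$city, cityBad), s$grid,
                      list(planted = identityICV()),
                      list(planted = list(sc = s$future),
                           `no-icv` = list(sc = s$future)))
  expect_equal(nrow(res), 1)
  expect_match(attr(res, "failures")[["no-icv"]], "missing ICV")
})

test_that("summaries average distances, bearings circularly, and count classes", {
  mk <- function(city, sigma, dist, bearing, scen = "s") {
    new("AnalogResult", city = city, scenario = scen, analogLat = 0,
        analogLon = 0, minSigma = sigma, distanceKm = dist,
        bearingDeg = bearing, analogClass = classifyAnalog(sigma),
        tieCount = 1L, degenerateBearing = FALSE)
  }
  res <- list(mk("a", 1.0, 100, 190), mk("b", 5.0, 300, 210),
              mk("c", 4.5, 200, 350), mk("d", 3.0, 400, 10))
  sm <- summarizeAnalogs(res)
  expect_equal(sm$meanDistanceKm, 250)
  expect_equal(sm$fracRepresentative, 0.25)
  expect_equal(sm$fracNovel, 0.5)
  # wraparound pairs: mean of {350, 10} is 0 and of {190, 210} is 200
  expect_equal(circularMeanDeg(c(350, 10)), 0)
  expect_equal(circularMeanDeg(c(190, 210)), 200)
  # ordering invariance
  sm2 <- summarizeAnalogs(res[c(3, 1, 4, 2)])
  expect_equal(sm2, sm)
  # degenerate bearings are excluded from the circular mean and counted
  deg <- mk("e", 0, 0, 0)
  deg@degenerateBearing <- TRUE
  sm3 <- summarizeAnalogs(c(res[1:2], list(deg)))
  expect_equal(sm3$nBearingExcluded, 1)
  expect_equal(sm3$meanBearingDeg, circularMeanDeg(c(190, 210)))
  # per-region breakdowns via named tags
  tags <- c(a = "west", b = "east", c = "east", d = "west")
  smr <- summarizeAnalogs(res, regionTags = tags)
  expect_equal(nrow(smr), 2)
  expect_equal(smr$fracRepresentative[smr$region == "west"], 0.5)
  expect_error(summarizeAnalogs(analogTable(list())[0, ]), "no results")
})

test_that("filterUrbanAreas excludes with machine-readable reasons", {
  g <- makeGrid(syntheticGridConfig(nLat = 40, nLon = 40, seed = 4))
  small <- makeUrbanPolygon(c(lat = 40, lon = -100), 49, "too-small")
  noStations <- makeUrbanPolygon(c(lat = 42, lon = -101), 400, "no-stations")
  good <- makeUrbanPolygon(c(lat = 45, lon = -99), 40000, "good")
  check <- function(city) cityName(city) == "good"
  out <- filterUrbanAreas(list(small, noStations, good),
                          stationCheck = check, pool = g)
  expect_equal(vapply(out$kept, cityName, character(1)), "good")
  expect_equal(out$excluded$reason[out$excluded$city == "too-small"], "area")
  expect_equal(out$excluded$reason[out$excluded$city == "no-stations"],
               "stations")
  # a polygon too small to contain two pool cell centers fails the
  # heterogeneity proxy
  tiny <- makeUrbanPolygon(c(lat = 44, lon = -98), 60, "tiny-footprint")
  out2 <- filterUrbanAreas(list(tiny), pool = g)
  expect_equal(out2$excluded$reason, "pool")
})

test_that("exports round-trip results and surfaces as text layers", {
  dir <- withr::local_tempdir()
  s <- plantedSetup(seed = 8)
  surf <- similaritySurface(s$future, s$grid, identityICV(),
                            city = "planted", scenario = "sc")
  res <- bestAnalog(surf, s$city)
  csv <- file.path(dir, "results.csv")
  writeAnalogCSV(list(res), csv)
  back <- read.csv(csv)
  expect_equal(back$minSigma, res@minSigma)
  asc <- file.path(dir, "surface.asc")
  writeSurfaceGrid(surf, asc)
  rt <- readAsciiGrid(asc)
  expect_equal(rt$values, surfaceSigma(surf))
  gj <- file.path(dir, "layers.geojson")
  exportAnalogGeoJSON(list(res), list(s$city), gj)
  fc <- jsonlite::read_json(gj)
  expect_equal(fc$type, "FeatureCollection")
  expect_equal(length(fc$features), 3)     # city, analog, link
  roles <- vapply(fc$features, function(f) f$properties$role, character(1))
  expect_setequal(roles, c("city", "analog", "link"))
})

test_that("urban-area GeoJSON round-trips polygons, names and areas", {
  dir <- withr::local_tempdir()
  cities <- list(makeUrbanPolygon(c(lat = 40, lon = -100), 120, "A"),
                 makeUrbanPolygon(c(lat = 45, lon = -90), 75, "B"))
  path <- file.path(dir, "cities.geojson")
  writeUrbanAreasGeoJSON(cities, path)
  back <- readUrbanAreasGeoJSON(path)
  expect_equal(vapply(back, cityName, character(1)), c("A", "B"))
  expect_equal(vapply(back, cityArea, numeric(1)), c(120, 75))
  expect_equal(cityCentroid(back[[1]]), cityCentroid(cities[[1]]),
               tolerance = 1e-9)
})
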