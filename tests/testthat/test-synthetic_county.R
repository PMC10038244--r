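# Synthetic-county generator and the rasterized reference oracle.

test_that("the generator is fully determined by its seed", {
  a <- generateCounty(desk_params(11))
  b <- generateCounty(desk_params(11))
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c <- generateCounty(desk_params(12))
  expect_false(identical(serialize(a, NULL), serialize(c, NULL)))
  # generation does not disturb the caller's RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(generateCounty(desk_params(11))); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("generated bundles have the protocol's layer inventory", {
  L <- generateCounty(desk_params(3))
  expect_setequal(names(L), c("counties", "heritage", "streams",
                              "waterbodies", "wetlands", "addresses",
                              "blocks"))
  expect_equal(layerKind(L$streams), "line")
  expect_equal(layerKind(L$addresses), "point")
  expect_true(all(c("GAP_STATUS", "OWNER_TYPE") %in%
                  names(attrTable(L$heritage))))
  expect_true(all(attrTable(L$blocks)$POPULATION >= 10 &
                  attrTable(L$blocks)$POPULATION <= 1000))
  # wetland coverage of the county hits the target within 2 percent
  county <- layerGeoms(L$counties)[[1]]
  wetUnion <- treatzones:::geomUnionAll(layerGeoms(L$wetlands))
  cover <- treatzones:::geomArea(
    treatzones:::geomIntersection(wetUnion, county))
  target <- 0.35 * (4 * 5280)^2
  expect_lt(abs(cover - target), 0.02 * target)
  # all addresses inside the county
  pts <- coordsOf(L$addresses)
  bb <- treatzones:::geomBBox(county)
  expect_true(all(pts[, 1] >= bb[1] & pts[, 1] <= bb[3] &
                  pts[, 2] >= bb[2] & pts[, 2] <= bb[4]))
})

test_that("generator edge cases propagate through the pipeline", {
  # no wetlands -> zero Approved area
  L0 <- generateCounty(desk_params(5, wetlandFraction = 0))
  expect_equal(nFeatures(L0$wetlands), 0L)
  res <- runPipeline(L0, pipelineConfig())
  expect_equal(summaryTable(res$summary)$area_mi2[1], 0)
  # no addresses -> bundle valid, pipeline fails at the fishnet step
  LA <- generateCounty(desk_params(5, nAddresses = 0))
  expect_equal(nFeatures(LA$addresses), 0L)
  expect_error(runPipeline(LA, pipelineConfig()), "Step 8")
  # infeasible parameters are rejected up front
  expect_error(countyParams(wetlandFraction = 2), "wetlandFraction")
})

test_that("the hand-built fixture classifies exactly as derived", {
  sc <- expectedSimpleCase()
  res <- runPipeline(sc$layers, sc$config)
  got <- gridCells(res$grid)[, c("row", "col", "type")]
  expect_equal(got, sc$expected, ignore_attr = TRUE)
  # partition invariant: every post-erase cell got exactly one class
  expect_false(any(is.na(gridCells(res$grid)$type)))
  # removing the preserve removes the sensitive area and all Warning cells
  sc2 <- expectedSimpleCase(withPreserve = FALSE)
  res2 <- runPipeline(sc2$layers, sc2$config)
  expect_false("Warning" %in% gridCells(res2$grid)$type)
  expect_equal(nCells(res2$grid), 25L)
})

test_that("oracle: an all-wetland county with no sensitive features is all Approved", {
  sc <- expectedSimpleCase(withPreserve = FALSE)
  sc$layers$wetlands <- vectorLayer(list(sq(-100, -100, 5 * 5280 + 200)),
                                    data.frame(WETLAND_TYPE = "swamp"),
                                    crs = 2264)
  ref <- referenceAreas(rasterOracle(sc$layers, sc$config, 20))
  gridArea <- 25 * 5280^2
  expect_lt(abs(ref[["Approved"]] - gridArea) / gridArea, 0.01)
  expect_equal(ref[["Warning"]], 0)
  # matching vector result
  res <- runPipeline(sc$layers, sc$config)
  expect_equal(summaryTable(res$summary)$area_ft2[1], gridArea)
})

test_that("oracle converges toward the vector areas as resolution shrinks", {
  L <- generateCounty(desk_params(7))
  cfg <- pipelineConfig()
  v <- areas_by_class(runPipeline(L, cfg)$summary)
  disc <- vapply(c(40, 20, 10), function(res) {
    r <- referenceAreas(rasterOracle(L, cfg, res))
    sum(abs(v[names(r)] - r))
  }, 0)
  # halving the resolution must not inflate the discrepancy by more than 2x
  expect_lt(disc[2], 2 * disc[1] + 1)
  expect_lt(disc[3], 2 * disc[2] + 1)
  # and the finest level agrees within 1 percent of the total
  expect_lt(disc[3] / sum(v), 0.01)
})

test_that("raising the wetland fraction never lowers oracle Approved area", {
  cfg <- pipelineConfig()
  a <- vapply(c(0.15, 0.35), function(f) {
    L <- generateCounty(desk_params(9, wetlandFraction = f))
    referenceAreas(rasterOracle(L, cfg, 20))[["Approved"]]
  }, 0)
  expect_gte(a[2], a[1])
})

test_that("a too-coarse oracle resolution is rejected", {
  sc <- expectedSimpleCase()
  expect_error(rasterOracle(sc$layers, sc$config, 100), "resolution")
})
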