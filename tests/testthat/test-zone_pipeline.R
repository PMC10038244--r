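# Stage-by-stage behaviour of the 18-step protocol operations.

test_that("county selection matches case-insensitively and dissolves parts", {
  counties <- vectorLayer(list(sq(0, 0, 10), sq(100, 0, 10)),
                          data.frame(County = c("Brunswick", "Columbus"),
                                     stringsAsFactors = FALSE), crs = 2264)
  one <- selectCounty(counties, "  brunswick ")
  expect_equal(nFeatures(one), 1L)
  expect_equal(attrTable(one)$County, "Brunswick")
  expect_error(selectCounty(counties, "Wake"), "Brunswick.*Columbus")
  # two rows with the same name dissolve into one multi-part feature
  onslow <- vectorLayer(list(sq(0, 0, 10), sq(100, 0, 20)),
                        data.frame(County = c("Onslow", "Onslow"),
                                   stringsAsFactors = FALSE), crs = 2264)
  d <- selectCounty(onslow, "Onslow")
  expect_equal(nFeatures(d), 1L)
  expect_equal(layerArea(d), 100 + 400)
})

test_that("heritage filter keeps GAP 1/2 codes and federal owners", {
  h <- vectorLayer(list(sq(0, 0, 1), sq(2, 0, 1), sq(4, 0, 1), sq(6, 0, 1)),
    data.frame(
      GAP_STATUS = c(
        "1: Managed for biodiversity; disturbance events proceed or mimicked",
        "3", "3", "2: Managed for biodiversity; disturbance events suppressed"),
      OWNER_TYPE = c("state", "private", "Federal Land", "Local Government"),
      stringsAsFactors = FALSE), crs = 2264)
  kept <- filterHeritage(h, pipelineConfig())
  expect_equal(nFeatures(kept), 3L)
  expect_setequal(attrTable(kept)$OWNER_TYPE,
                  c("state", "Federal Land", "Local Government"))
  # the GAP=3 / private feature is the one dropped
  expect_false("private" %in% attrTable(kept)$OWNER_TYPE)
  expect_error(filterHeritage(squareLayer(0, 0, 1), pipelineConfig()),
               "GAP_STATUS")
})

test_that("hydro line buffer matches the analytic round-cap area", {
  ln <- lineLayer(cbind(c(0, 1000), c(0, 0)))
  buf <- bufferHydroLines(ln, 50)
  expect_equal(layerKind(buf), "polygon")
  target <- 2 * 50 * 1000 + pi * 50^2
  expect_lt(abs(layerArea(buf) - target) / target, 1e-3)
  # zero-length line dropped with a warning
  zl <- lineLayer(cbind(c(5, 5), c(7, 7)))
  expect_warning(out <- bufferHydroLines(zl, 50), "degenerate")
  expect_equal(nFeatures(out), 0L)
  expect_error(bufferHydroLines(squareLayer(0, 0, 1), 50), "line layer")
})

test_that("right-angle polyline buffer agrees with a 1-ft raster oracle", {
  bend <- lineLayer(cbind(c(0, 500, 500), c(0, 0, 500)))
  buf <- bufferHydroLines(bend, 50)
  # oracle: count 1-ft pixels whose center is within 50 ft of the polyline
  nx <- 700L; ny <- 700L; x0 <- -75; y0 <- -75
  band <- treatzones:::rcpp_seg_band(
    list(list(x = c(0, 500, 500), y = c(0, 0, 500))),
    nx, ny, x0, y0, 1, 50)
  oracle <- sum(band) * 1
  expect_lt(abs(layerArea(buf) - oracle) / oracle, 0.005)
})

test_that("merge concatenates features without dissolving", {
  a <- squareLayer(0, 0, 1); b <- squareLayer(2, 0, 1)
  m <- mergeLayers(list(lakes = a, heritage = b))
  expect_equal(nFeatures(m), 2L)
  expect_equal(layerArea(m), 2)
  expect_equal(attrTable(m)$src_layer, c("lakes", "heritage"))
  # overlap untouched
  ov <- mergeLayers(list(a = squareLayer(0, 0, 2), b = squareLayer(1, 0, 2)))
  expect_equal(nFeatures(ov), 2L)
  expect_equal(layerArea(ov), 8)           # summed, not dissolved
  # empty layers ignored
  e <- vectorLayer(list(), crs = 2264, geomKind = "polygon")
  expect_equal(nFeatures(mergeLayers(list(a, e, b))), 2L)
})

test_that("clip behaves as a cookie cutter", {
  boundary <- squareLayer(0, 0, 10)
  half <- squareLayer(-5, 0, 10)     # half inside
  out <- clipLayer(half, boundary)
  expect_equal(layerArea(out), 50, tolerance = 1e-9)
  expect_equal(nFeatures(clipLayer(squareLayer(100, 100, 1), boundary)), 0L)
  inside <- squareLayer(2, 2, 3)
  kept <- clipLayer(inside, boundary)
  expect_equal(coordsOf(kept), coordsOf(inside))
  expect_error(clipLayer(half, vectorLayer(list(), crs = 2264,
                                           geomKind = "polygon")),
               "single polygon")
})

test_that("sensitive buffer+dissolve matches the rounded-rectangle area", {
  sqr <- squareLayer(0, 0, 100)
  s <- bufferDissolveSensitive(sqr, 100)
  target <- 100^2 + 4 * 100 * 100 + pi * 100^2
  expect_lt(abs(s@area - target) / target, 1e-3)
  expect_equal(s@componentCount, 1L)
  # two squares 150 ft apart dissolve when buffered by 100 ft each
  two <- vectorLayer(list(sq(0, 0, 100), sq(250, 0, 100)), crs = 2264)
  expect_equal(bufferDissolveSensitive(two, 100)@componentCount, 1L)
  # and stay separate with a small buffer
  expect_equal(bufferDissolveSensitive(two, 10)@componentCount, 2L)
  # zero buffer dissolves only
  ovl <- vectorLayer(list(sq(0, 0, 2), sq(1, 0, 2)), crs = 2264)
  s0 <- bufferDissolveSensitive(ovl, 0)
  expect_equal(s0@area, 6, tolerance = 1e-9)
})

test_that("fishnet snaps its origin and retains address-bearing cells", {
  cfg <- pipelineConfig()
  g <- buildFishnet(pointLayer(cbind(c(100, 6000), c(100, 6000))), cfg)
  expect_equal(nCells(g), 2L)
  expect_equal(gridCells(g)[, c("row", "col")],
               data.frame(row = c(0L, 1L), col = c(0L, 1L)))
  expect_equal(gridCells(g)$area, c(5280^2, 5280^2))
  # all addresses in one cell
  g1 <- buildFishnet(pointLayer(cbind(c(10, 20, 30), c(10, 20, 30))), cfg)
  expect_equal(nCells(g1), 1L)
  expect_equal(gridCells(g1)$area, 27878400)
  # keep_empty_cells retains the full 2x2 bounding block
  cfgE <- pipelineConfig(keepEmptyCells = TRUE)
  expect_equal(nCells(buildFishnet(
    pointLayer(cbind(c(100, 6000), c(100, 6000))), cfgE)), 4L)
  expect_error(buildFishnet(vectorLayer(list(), crs = 2264,
                                        geomKind = "point"), cfg),
               "empty address layer")
})

test_that("erase removes covered cells and clips partially covered ones", {
  cell <- sq(0, 0, 5280)
  grid <- gridOfSquares(list(cell), cbind(0L, 0L))
  # fully covered -> dropped
  full <- sensitiveFrom(sq(-10, -10, 5300))
  expect_equal(nCells(eraseSensitive(grid, full)), 0L)
  # left half covered -> half the area remains
  halfc <- sensitiveFrom(treatzones:::mkGeom("Polygon", list(matrix(
    c(-100, -100, 2640, -100, 2640, 5380, -100, 5380), ncol = 2,
    byrow = TRUE))))
  e <- eraseSensitive(gridOfSquares(list(cell), cbind(0L, 0L)), halfc)
  expect_equal(gridCells(e)$area, 5280^2 / 2, tolerance = 1e-9)
  # untouched cell keeps its geometry
  far <- sensitiveFrom(sq(1e6, 1e6, 10))
  u <- eraseSensitive(gridOfSquares(list(cell), cbind(0L, 0L)), far)
  expect_equal(gridGeoms(u)[[1]], cell)
})

test_that("warning classification uses an inclusive distance threshold", {
  s <- sensitiveFrom(sq(0, 0, 100))
  mkcell <- function(x) gridOfSquares(list(sq(x, 0, 100)), cbind(0L, 0L))
  # abutting (distance 0)
  r0 <- classifyWarning(mkcell(100), s, 100)
  expect_equal(nCells(r0$warning), 1L)
  expect_equal(gridCells(r0$warning)$type, "Warning")
  # exactly at the threshold: inclusive
  r100 <- classifyWarning(mkcell(200), s, 100)
  expect_equal(nCells(r100$warning), 1L)
  # beyond
  r200 <- classifyWarning(mkcell(300), s, 100)
  expect_equal(nCells(r200$warning), 0L)
  expect_equal(nCells(r200$rest), 1L)
  expect_true(all(is.na(gridCells(r200$rest)$type)))
  # warning + rest partition the input
  expect_equal(nCells(r100$warning) + nCells(r100$rest), 1L)
})

test_that("remainder classification tests wetland intersection incl. touches", {
  wl <- function(...) vectorLayer(list(...), crs = 2264)
  cellg <- gridOfSquares(list(sq(0, 0, 100)), cbind(0L, 0L))
  over <- classifyRemainder(cellg, wl(sq(50, 50, 100)))
  expect_equal(gridCells(over$approved)$type, "Approved")
  none <- classifyRemainder(cellg, wl(sq(500, 500, 10)))
  expect_equal(gridCells(none$notSignificant)$type, "Not Significant")
  # shared edge only: touch counts as intersects
  touch <- classifyRemainder(cellg, wl(sq(100, 0, 100)))
  expect_equal(nCells(touch$approved), 1L)
})

test_that("classified merge conserves counts and rejects duplicate ids", {
  s <- sensitiveFrom(sq(-1000, -1000, 100))
  mk <- function(n, off, type) {
    g <- gridOfSquares(lapply(seq_len(n), function(i)
      sq(off + i * 200, 0, 100)), cbind(rep(0L, n), off + seq_len(n)))
    g@cells$type <- type
    g
  }
  w <- mk(3, 0L, "Warning"); a <- mk(2, 10L, "Approved")
  ns <- mk(1, 20L, "Not Significant")
  grid <- mergeClassified(w, a, ns, pipelineConfig())
  expect_equal(nCells(grid), 6L)
  expect_setequal(unique(gridCells(grid)$type),
                  c("Warning", "Approved", "Not Significant"))
  # empty Not Significant is fine (wetland-rich counties)
  e <- mk(0, 30L, character(0))
  expect_equal(nCells(mergeClassified(w, a, e, pipelineConfig())), 5L)
  # duplicate id across classes is an internal error
  expect_error(mergeClassified(w, mk(3, 0L, "Approved"), e, pipelineConfig()),
               "duplicate cell id")
})

test_that("area-weighted apportionment splits people by overlap", {
  cfg <- pipelineConfig()
  mkgrid <- function(squares, rc) {
    g <- gridOfSquares(squares, rc)
    g@cells$type <- "Approved"
    new("ClassifiedGrid", cells = g@cells, geoms = g@geoms, crs = g@crs,
        config = cfg)
  }
  # one block of 100 exactly covering two half-cells -> 50/50
  grid <- mkgrid(list(sq(0, 0, 100), sq(100, 0, 100)),
                 cbind(c(0L, 0L), c(0L, 1L)))
  blocks <- vectorLayer(list(sq(50, 0, 100)),
                        data.frame(POPULATION = 100), crs = 2264)
  out <- attachPopulation(grid, blocks)
  expect_equal(gridCells(out)$population, c(50, 50))
  expect_equal(gridCells(out)$density, c(50, 50) / 100^2)
  # block half inside the grid contributes half its people in total
  gr2 <- mkgrid(list(sq(0, 0, 100)), cbind(0L, 0L))
  b2 <- vectorLayer(list(sq(50, 0, 100)), data.frame(POPULATION = 100),
                    crs = 2264)
  expect_equal(sum(gridCells(attachPopulation(gr2, b2))$population), 50)
  # disjoint -> zero
  b3 <- vectorLayer(list(sq(1000, 1000, 10)), data.frame(POPULATION = 100),
                    crs = 2264)
  expect_equal(gridCells(attachPopulation(gr2, b3))$population, 0)
  # block_copy copies full populations (documented over-counting)
  out2 <- attachPopulation(grid, blocks, mode = "block_copy")
  expect_equal(gridCells(out2)$population, c(100, 100))
  # negative population rejected
  bneg <- vectorLayer(list(sq(0, 0, 10)), data.frame(POPULATION = -1),
                      crs = 2264)
  expect_error(attachPopulation(gr2, bneg), "negative")
})

test_that("zone summary reports 2-dp square miles and exact acre conversion", {
  sc <- expectedSimpleCase()
  res <- runPipeline(sc$layers, sc$config)
  tab <- summaryTable(res$summary)
  expect_equal(tab$type, c("Approved", "Warning", "Not Significant", "Total"))
  expect_equal(tab$area_mi2, round(tab$area_mi2, 2))
  expect_equal(tab$area_acres, tab$area_mi2 * 640)
  expect_equal(tab$area_ft2[4], sum(tab$area_ft2[1:3]))
  # a grid with no Approved cells still reports an explicit zero row
  sc0 <- expectedSimpleCase()
  sc0$layers$wetlands <- vectorLayer(list(), crs = 2264,
                                     geomKind = "polygon")
  tab0 <- summaryTable(runPipeline(sc0$layers, sc0$config)$summary)
  expect_equal(tab0$area_mi2[tab0$type == "Approved"], 0)
  expect_equal(tab0$cell_count[tab0$type == "Approved"], 0L)
})

test_that("cost projection scales vetted acres by the configured rates", {
  sc <- expectedSimpleCase()
  summ <- runPipeline(sc$layers, sc$config)$summary
  tab <- summaryTable(summ)
  acres <- sum(tab$area_acres[tab$type %in% c("Approved", "Warning")])
  rep <- estimateTreatmentCost(summ, costPerAcre = 1.5, productRate = 0.02)
  expect_equal(rep$treatable_acres, acres)
  expect_equal(rep$cost, acres * 1.5)
  expect_equal(rep$product, acres * 0.02)
  # 582.02 mi^2 of treatable area converts to 372492.8 acres
  expect_equal(582.02 * 640, 372492.8)
  expect_error(estimateTreatmentCost(summ, -1, 0), "rates")
})

test_that("pipeline degenerate cases behave as specified", {
  # no wetlands -> no Approved cells
  sc <- expectedSimpleCase()
  sc$layers$wetlands <- vectorLayer(list(), crs = 2264, geomKind = "polygon")
  res <- runPipeline(sc$layers, sc$config)
  expect_false("Approved" %in% gridCells(res$grid)$type)
  # sensitive covering everything -> empty grid, zero summary, warning
  sc2 <- expectedSimpleCase()
  sc2$layers$heritage <- vectorLayer(
    list(sq(-200, -200, 5 * 5280 + 400)),
    data.frame(GAP_STATUS = "1: Managed for biodiversity",
               OWNER_TYPE = "Federal Land", stringsAsFactors = FALSE),
    crs = 2264)
  expect_warning(res2 <- runPipeline(sc2$layers, sc2$config), "empty")
  expect_equal(nCells(res2$grid), 0L)
  expect_equal(summaryTable(res2$summary)$area_mi2, rep(0, 4))
  # errors carry their step number
  sc3 <- expectedSimpleCase()
  sc3$layers$addresses <- vectorLayer(list(), crs = 2264, geomKind = "point")
  expect_error(runPipeline(sc3$layers, sc3$config), "Step 8")
  # geographic working CRS is rejected
  expect_error(runPipeline(sc$layers,
                           pipelineConfig(countyName = "Simplecase",
                                          workingCRS = 4326)),
               "projected")
  # layers not in the working CRS are rejected before geometry work
  sc4 <- expectedSimpleCase()
  sc4$layers$blocks@crs <- 32119L
  expect_error(runPipeline(sc4$layers, sc4$config), "blocks")
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(pipelineConfig(cellArea = -1), "cellArea")
  expect_error(pipelineConfig(countyName = "  "), "countyName")
  expect_error(pipelineConfig(hydroHalfWidth = 0), "hydroHalfWidth")
  expect_silent(pipelineConfig(sensitiveBuffer = 0))
})
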