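# Layer I/O: format round trips, schema validation, reprojection, repair.

test_that("a GeoJSON unit square reads as one polygon feature", {
  f <- tempfile(fileext = ".geojson")
  writeLines(paste0('{"type":"FeatureCollection","features":[',
                    '{"type":"Feature","properties":{"name":"sq"},',
                    '"geometry":{"type":"Polygon","coordinates":',
                    '[[[0,0],[1,0],[1,1],[0,1],[0,0]]]}}]}'), f)
  l <- readLayer(f)
  expect_equal(nFeatures(l), 1L)
  expect_equal(layerKind(l), "polygon")
  expect_equal(layerCRS(l), 4326L)  # RFC 7946 default
  expect_equal(layerArea(l), 1)
  expect_equal(attrTable(l)$name, "sq")
})

test_that("write/read round-trips geometry, attributes and CRS in all formats", {
  multi <- treatzones:::mkGeom("MultiPolygon", list(
    list(matrix(c(0, 0, 10, 0, 10, 10, 0, 10), ncol = 2, byrow = TRUE)),
    list(matrix(c(100, 100, 120, 100, 120, 130, 100, 130), ncol = 2,
                byrow = TRUE),
         matrix(c(105, 105, 115, 105, 115, 115, 105, 115), ncol = 2,
                byrow = TRUE))))
  orig <- vectorLayer(list(sq(2150000.123456789, 60000.987654321, 5280),
                           multi),
                      data.frame(NAME = c("a", "b"), VAL = c(1.5, -2.25),
                                 N = c(3L, 4L), stringsAsFactors = FALSE),
                      crs = 2264)
  for (ext in c("geojson", "shp", "gpkg")) {
    f <- file.path(tempdir(), paste0("rt.", ext))
    writeLayer(orig, f)
    back <- readLayer(f)
    expect_equal(nFeatures(back), 2L, info = ext)
    expect_equal(layerCRS(back), 2264L, info = ext)
    expect_equal(back@geoms[[2]]$type, "MultiPolygon", info = ext)
    expect_length(back@geoms[[2]]$coords, 2)               # part count
    expect_length(back@geoms[[2]]$coords[[2]], 2)          # hole preserved
    expect_lt(max(abs(coordsOf(back) - coordsOf(orig))), 1e-9)
    expect_equal(as.character(attrTable(back)$NAME), c("a", "b"), info = ext)
    expect_equal(attrTable(back)$VAL, c(1.5, -2.25), info = ext)
  }
})

test_that("an empty layer is written as a valid empty collection", {
  empty <- vectorLayer(list(), crs = 2264, geomKind = "polygon")
  for (ext in c("geojson", "shp", "gpkg")) {
    f <- file.path(tempdir(), paste0("empty.", ext))
    writeLayer(empty, f)
    expect_equal(nFeatures(readLayer(f)), 0L, info = ext)
  }
})

test_that("points and lines round-trip through shapefile and geojson", {
  pts <- pointLayer(cbind(c(100.5, 6000.25), c(100.5, 6000.75)))
  ln <- lineLayer(cbind(c(0, 500, 1000), c(0, 250, 0)))
  for (ext in c("geojson", "shp")) {
    f1 <- file.path(tempdir(), paste0("p.", ext))
    writeLayer(pts, f1)
    expect_lt(max(abs(coordsOf(readLayer(f1)) - coordsOf(pts))), 1e-9)
    f2 <- file.path(tempdir(), paste0("l.", ext))
    writeLayer(ln, f2)
    expect_lt(max(abs(coordsOf(readLayer(f2)) - coordsOf(ln))), 1e-9)
  }
})

test_that("schema validation names the missing attribute", {
  heritageSchema <- layerSchema(c(GAP_STATUS = "any", OWNER_TYPE = "any"),
                                "polygon")
  f <- tempfile(fileext = ".geojson")
  writeLayer(squareLayer(0, 0, 1, attrs = data.frame(OWNER_TYPE = "state")),
             f)
  expect_error(readLayer(f, schema = heritageSchema), "GAP_STATUS")
  # case-insensitive match passes
  f2 <- tempfile(fileext = ".geojson")
  writeLayer(squareLayer(0, 0, 1, attrs = data.frame(gap_status = "1",
                                                     Owner_Type = "x")), f2)
  expect_s4_class(readLayer(f2, schema = heritageSchema), "VectorLayer")
})

test_that("reprojection: identity is exact, round trip preserves area", {
  l <- squareLayer(2150000, 60000, 5280)
  same <- reprojectLayer(l, 2264)
  expect_identical(coordsOf(same), coordsOf(l))
  deg <- reprojectLayer(l, 4326)
  expect_true(all(abs(coordsOf(deg)[, 1] + 78) < 2))   # degrees, near NC
  back <- reprojectLayer(deg, 2264)
  expect_lt(abs(layerArea(back) - layerArea(l)) / layerArea(l), 1e-6)
  # projected <-> projected via metres zone
  m <- reprojectLayer(l, 32119)
  expect_lt(abs(layerArea(m) * (1200 / 3937)^-2 / layerArea(l) - 1), 1e-6)
  expect_error(reprojectLayer(l, 999999), "EPSG")
})

test_that("geometry repair: bow-tie resolves to the sum of its lobes", {
  bow <- vectorLayer(list(treatzones:::mkGeom("Polygon", list(matrix(
    c(0, 0, 1, 1, 1, 0, 0, 1), ncol = 2, byrow = TRUE)))), crs = 2264)
  fixed <- suppressWarnings(makeValidLayer(bow))
  # shoelace on each triangular lobe: 2 * (1/2 * 1/2 * 1/2) = 0.25 + 0.25
  expect_equal(layerArea(fixed), 0.5, tolerance = 1e-9)
  # valid input unchanged, and repair is idempotent
  v <- squareLayer(0, 0, 7)
  expect_equal(layerArea(makeValidLayer(v)), 49)
  again <- makeValidLayer(fixed)
  expect_equal(layerArea(again), layerArea(fixed), tolerance = 1e-12)
  # degenerate zero-area polygon dropped and counted
  degen <- vectorLayer(list(treatzones:::mkGeom("Polygon", list(matrix(
    c(0, 0, 1, 1, 2, 2), ncol = 2, byrow = TRUE)))), crs = 2264)
  expect_warning(out <- makeValidLayer(degen), "dropped")
  expect_equal(nFeatures(out), 0L)
  expect_equal(attr(out, "dropped"), 1L)
})

test_that("mixed-CRS inputs are rejected before any geometry work", {
  a <- squareLayer(0, 0, 1, crs = 2264)
  b <- squareLayer(0, 0, 1, crs = 32119)
  expect_error(mergeLayers(list(a, b)), "mixed CRS")
  expect_error(clipLayer(a, b), "mixed CRS")
})

test_that("unknown formats and missing files fail cleanly", {
  expect_error(readLayer("/nonexistent/file.geojson"), "not found")
  f <- tempfile(fileext = ".xyz")
  file.create(f)
  expect_error(readLayer(f), "format")
  expect_error(writeLayer(squareLayer(0, 0, 1),
                          "/nonexistent/dir/out.geojson"), "directory")
})
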