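# Shared builders for small in-code fixtures.

sq <- function(x0, y0, side) {
  treatzones:::squareGeom(x0, y0, side)
}

squareLayer <- function(x0, y0, side, crs = 2264, attrs = NULL) {
  vectorLayer(list(sq(x0, y0, side)), attrs, crs = crs)
}

lineLayer <- function(coords, crs = 2264) {
  vectorLayer(list(treatzones:::mkGeom("LineString", coords)),
              crs = crs, geomKind = "line")
}

pointLayer <- function(xy, crs = 2264) {
  vectorLayer(lapply(seq_len(nrow(xy)), function(i)
    treatzones:::mkGeom("Point", xy[i, ])), crs = crs, geomKind = "point")
}

coordsOf <- function(layer) {
  do.call(rbind, lapply(layerGeoms(layer), treatzones:::geomCoordMat))
}

# a SensitiveArea from plain polygon squares (buffer 0 keeps them as-is)
sensitiveFrom <- function(..., crs = 2264) {
  geoms <- list(...)
  bufferDissolveSensitive(vectorLayer(geoms, crs = crs), 0)
}

# untyped grid whose cells are the given squares
gridOfSquares <- function(squares, rowcol, crs = 2264) {
  n <- length(squares)
  rowcol <- matrix(as.integer(rowcol), ncol = 2)
  cells <- data.frame(row = rowcol[seq_len(n), 1],
                      col = rowcol[seq_len(n), 2],
                      type = rep(NA_character_, n),
                      area = vapply(squares, treatzones:::geomArea, 0),
                      population = numeric(n), density = numeric(n))
  treatzones:::zoneGrid(cells, squares, crs)
}

# small, fast generator settings used by the property tests
desk_params <- function(seed, ...) {
  args <- list(side = 4 * 5280, nRivers = 2, nLakes = 2,
               wetlandFraction = 0.35, nPreserves = 4, nAddresses = 250,
               blockGrid = 4, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(countyParams, args)
}

areas_by_class <- function(summary) {
  tab <- summaryTable(summary)
  stats::setNames(tab$area_ft2[1:3], tab$type[1:3])
}
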