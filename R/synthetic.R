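# Seeded synthetic county bundles. The generator emulates the layer
# inventory the protocol consumes — a county polygon containing river
# centerlines, lakes, wetland blobs, protected preserves, clustered address
# points and a census-block tiling with populations — with fully
# reproducible output under a fixed seed.

# GAP status / owner-type vocabulary used by the generator; the first two
# GAP values and the federal owner are the ones the protocol keeps.
.GAP_VOCAB <- c(
  "1: Managed for biodiversity; disturbance events proceed or mimicked",
  "2: Managed for biodiversity; disturbance events suppressed",
  "3: Managed for multiple uses",
  "4: No known mandate for protection")
.OWNER_VOCAB <- c("Federal Land", "State", "Local Government", "Private")

# run expr with a locally seeded RNG, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(list = ".Random.seed", envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# random star-shaped blob polygon around (cx, cy) with mean radius r0
.blobPolygon <- function(cx, cy, r0, nv = 48) {
  amp <- stats::runif(3, 0.05, 0.22)
  ph <- stats::runif(3, 0, 2 * pi)
  th <- seq(0, 2 * pi, length.out = nv + 1)[-(nv + 1)]
  r <- r0 * (1 + amp[1] * sin(th + ph[1]) + amp[2] * sin(2 * th + ph[2]) +
             amp[3] * sin(3 * th + ph[3]))
  mkGeom("Polygon", list(cbind(cx + r * cos(th), cy + r * sin(th))))
}

# Chaikin corner cutting (one pass) on an open polyline matrix
.chaikin <- function(m) {
  n <- nrow(m)
  if (n < 3) return(m)
  out <- matrix(0, 2 * (n - 1), 2)
  for (i in seq_len(n - 1)) {
    out[2 * i - 1, ] <- 0.75 * m[i, ] + 0.25 * m[i + 1, ]
    out[2 * i, ] <- 0.25 * m[i, ] + 0.75 * m[i + 1, ]
  }
  rbind(m[1, ], out, m[n, ])
}

#' Generate a synthetic county layer bundle
#'
#' Builds a complete, internally consistent set of input layers for the
#' pipeline: a square county, smoothed random-walk river centerlines crossing
#' it, lake and wetland blob polygons (wetland coverage iteratively scaled to
#' the target fraction within 2 percent), protected-land rectangles carrying
#' GAP/owner attributes drawn from the protocol vocabulary, uniform or
#' clustered address points, and an n x n census-block tiling with log-uniform
#' block populations in [10, 1000]. The seed fully determines the bundle.
#'
#' @param params a \code{CountyParams}
#' @param crs working CRS for the bundle (projected EPSG)
#' @return named list of \code{VectorLayer}s: counties, heritage, streams,
#'   waterbodies, wetlands, addresses, blocks
#' @export
generateCounty <- function(params, crs = 2264) {
  stopifnot(is(params, "CountyParams"))
  validObject(params)
  .withSeed(params@seed, .generateCountyImpl(params, as.integer(crs)))
}

.generateCountyImpl <- function(params, crs) {
  s <- params@side
  # a plausible corner in NC State Plane feet (south-eastern coastal plain)
  x0 <- 2150000; y0 <- 60000
  countyGeom <- squareGeom(x0, y0, s)
  counties <- vectorLayer(list(countyGeom),
                          data.frame(County = "Synthetic",
                                     stringsAsFactors = FALSE), crs = crs)

  # rivers: smoothed random walks crossing west -> east
  streams <- list()
  if (params@nRivers > 0) for (k in seq_len(params@nRivers)) {
    nseg <- 24
    xs <- seq(x0 - 0.05 * s, x0 + 1.05 * s, length.out = nseg)
    ys <- y0 + s * stats::runif(1, 0.15, 0.85) +
      cumsum(stats::rnorm(nseg, 0, s / 40))
    ys <- pmin(pmax(ys, y0 - 0.04 * s), y0 + 1.04 * s)
    m <- .chaikin(.chaikin(cbind(xs, ys)))
    streams <- c(streams, list(mkGeom("LineString", m)))
  }
  streamsL <- vectorLayer(streams,
                          data.frame(NAME = if (length(streams))
                            paste0("River ", seq_along(streams))
                            else character(0), stringsAsFactors = FALSE),
                          crs = crs, geomKind = "line")
  streamsL <- clipLayer(streamsL, counties)

  # lakes
  lakes <- list()
  if (params@nLakes > 0) for (k in seq_len(params@nLakes)) {
    r0 <- stats::runif(1, 0.02, 0.06) * s
    cx <- stats::runif(1, x0 + r0 * 1.5, x0 + s - r0 * 1.5)
    cy <- stats::runif(1, y0 + r0 * 1.5, y0 + s - r0 * 1.5)
    lakes <- c(lakes, list(.blobPolygon(cx, cy, r0)))
  }
  lakesL <- vectorLayer(lakes,
                        data.frame(NAME = if (length(lakes))
                          paste0("Lake ", seq_along(lakes))
                          else character(0), stringsAsFactors = FALSE),
                        crs = crs, geomKind = "polygon")

  # wetlands: blobs scaled iteratively to hit the target county fraction
  wetlands <- list()
  if (params@wetlandFraction > 0) {
    nblob <- max(4L, as.integer(round(6 * s / 52800)))
    ctr <- cbind(stats::runif(nblob, x0, x0 + s),
                 stats::runif(nblob, y0, y0 + s))
    shapes <- lapply(seq_len(nblob), function(k)
      .blobPolygon(ctr[k, 1], ctr[k, 2],
                   stats::runif(1, 0.08, 0.2) * s))
    target <- params@wetlandFraction * s^2
    scale <- 1
    ok <- FALSE
    for (it in 1:25) {
      scaled <- lapply(seq_len(nblob), function(k)
        geomMapCoords(shapes[[k]], function(m)
          cbind(ctr[k, 1] + (m[, 1] - ctr[k, 1]) * scale,
                ctr[k, 2] + (m[, 2] - ctr[k, 2]) * scale)))
      u <- geomUnionAll(scaled)
      a <- geomArea(geomIntersection(u, countyGeom))
      if (abs(a - target) <= 0.02 * target) { ok <- TRUE; break }
      scale <- scale * sqrt(target / max(a, 1e-9))
      if (scale > 50) break
    }
    if (!ok) stop("generation error: cannot reach wetland fraction ",
                  params@wetlandFraction, " within tolerance")
    wetlands <- scaled
  }
  wetlandsL <- vectorLayer(wetlands,
                           data.frame(WETLAND_TYPE = if (length(wetlands))
                             sample(c("bottomland swamp", "tidal salt marsh",
                                      "cedar forest"), length(wetlands),
                                    replace = TRUE) else character(0),
                             stringsAsFactors = FALSE),
                           crs = crs, geomKind = "polygon")

  # preserves (heritage): random rectangles, mixed keep/drop attributes
  pres <- list(); gapv <- character(); ownv <- character()
  if (params@nPreserves > 0) for (k in seq_len(params@nPreserves)) {
    w <- stats::runif(1, 0.05, 0.18) * s
    h <- stats::runif(1, 0.05, 0.18) * s
    px <- stats::runif(1, x0, x0 + s - w)
    py <- stats::runif(1, y0, y0 + s - h)
    pres <- c(pres, list(mkGeom("Polygon", list(matrix(
      c(px, py, px + w, py, px + w, py + h, px, py + h),
      ncol = 2, byrow = TRUE)))))
    gapv <- c(gapv, sample(.GAP_VOCAB, 1))
    ownv <- c(ownv, sample(.OWNER_VOCAB, 1))
  }
  heritageL <- vectorLayer(pres,
                           data.frame(GAP_STATUS = gapv, OWNER_TYPE = ownv,
                                      stringsAsFactors = FALSE),
                           crs = crs, geomKind = "polygon")

  # addresses
  n <- params@nAddresses
  if (n > 0) {
    if (params@addressClustering == "uniform") {
      ax <- stats::runif(n, x0, x0 + s); ay <- stats::runif(n, y0, y0 + s)
    } else {
      k <- max(3L, as.integer(n / 300))
      cx <- stats::runif(k, x0 + 0.1 * s, x0 + 0.9 * s)
      cy <- stats::runif(k, y0 + 0.1 * s, y0 + 0.9 * s)
      pick <- sample.int(k, n, replace = TRUE)
      ax <- stats::rnorm(n, cx[pick], 0.07 * s)
      ay <- stats::rnorm(n, cy[pick], 0.07 * s)
      out <- ax < x0 | ax > x0 + s | ay < y0 | ay > y0 + s
      ax[out] <- stats::runif(sum(out), x0, x0 + s)
      ay[out] <- stats::runif(sum(out), y0, y0 + s)
    }
    addrG <- lapply(seq_len(n), function(i) mkGeom("Point", c(ax[i], ay[i])))
  } else addrG <- list()
  addressesL <- vectorLayer(addrG, data.frame(ADDR_ID = seq_along(addrG)),
                            crs = crs, geomKind = "point")

  # census blocks: n x n tiling with log-uniform populations
  nb <- params@blockGrid
  bs <- s / nb
  blocks <- list(); bpop <- numeric()
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    blocks <- c(blocks, list(squareGeom(x0 + (j - 1) * bs,
                                        y0 + (i - 1) * bs, bs)))
    bpop <- c(bpop, round(exp(stats::runif(1, log(10), log(1000)))))
  }
  blocksL <- vectorLayer(blocks,
                         data.frame(GEOID = sprintf("B%03d", seq_along(blocks)),
                                    POPULATION = bpop,
                                    stringsAsFactors = FALSE),
                         crs = crs, geomKind = "polygon")

  list(counties = counties, heritage = heritageL, streams = streamsL,
       waterbodies = lakesL, wetlands = wetlandsL, addresses = addressesL,
       blocks = blocksL)
}

#' Hand-constructed fixture with exactly derivable classes
#'
#' A 5x5-cell county (cells of 1 mi^2) with: a protected preserve exactly
#' covering the center cell, a wetland strip along the west column, one
#' address at the center of every cell, and a census block per cell with 100
#' people. With default parameters the expected classification is exactly
#' derivable by hand: the center cell is fully erased (it lies inside the
#' buffered sensitive area); its 8 neighbours touch the buffered area, so
#' distance 0 gives Warning; the 5 west-column cells intersect the wetland
#' strip and are Approved; the remaining 11 cells are Not Significant.
#'
#' @param withPreserve include the preserve? (without it there is no
#'   sensitive area and hence no Warning cells)
#' @param crs working CRS
#' @return list(layers = named \code{VectorLayer}s, expected = data.frame
#'   (row, col, type) of the hand-derived classification, config =
#'   the matching \code{PipelineConfig})
#' @export
expectedSimpleCase <- function(withPreserve = TRUE, crs = 2264) {
  side <- 5280
  n <- 5L
  county <- vectorLayer(list(squareGeom(0, 0, n * side)),
                        data.frame(County = "Simplecase",
                                   stringsAsFactors = FALSE), crs = crs)
  pres <- if (withPreserve) list(squareGeom(2 * side, 2 * side, side))
          else list()
  heritage <- vectorLayer(pres,
    data.frame(GAP_STATUS = if (withPreserve)
                 "1: Managed for biodiversity; disturbance events proceed or mimicked"
               else character(0),
               OWNER_TYPE = if (withPreserve) "State" else character(0),
               stringsAsFactors = FALSE),
    crs = crs, geomKind = "polygon")
  # wetland strip along the west column; 100 ft short of the column's east
  # edge so that column-1 cells do not even touch it
  strip <- mkGeom("Polygon", list(matrix(
    c(0, 0, side - 100, 0, side - 100, n * side, 0, n * side),
    ncol = 2, byrow = TRUE)))
  wetlands <- vectorLayer(list(strip),
                          data.frame(WETLAND_TYPE = "bottomland swamp",
                                     stringsAsFactors = FALSE),
                          crs = crs, geomKind = "polygon")
  addr <- list(); rows <- integer(); cols <- integer()
  for (r in 0:(n - 1)) for (cc in 0:(n - 1)) {
    addr <- c(addr, list(mkGeom("Point", c((cc + 0.5) * side,
                                           (r + 0.5) * side))))
    rows <- c(rows, r); cols <- c(cols, cc)
  }
  addresses <- vectorLayer(addr, data.frame(ADDR_ID = seq_along(addr)),
                           crs = crs, geomKind = "point")
  blocks <- list()
  for (r in 0:(n - 1)) for (cc in 0:(n - 1))
    blocks <- c(blocks, list(squareGeom(cc * side, r * side, side)))
  blocksL <- vectorLayer(blocks,
                         data.frame(GEOID = sprintf("B%02d", seq_along(blocks)),
                                    POPULATION = rep(100, length(blocks)),
                                    stringsAsFactors = FALSE),
                         crs = crs, geomKind = "polygon")
  emptyPoly <- vectorLayer(list(), data.frame(),
                           crs = crs, geomKind = "polygon")
  emptyLine <- vectorLayer(list(),
                           data.frame(NAME = character(0),
                                      stringsAsFactors = FALSE),
                           crs = crs, geomKind = "line")
  expected <- data.frame(row = rows, col = cols, type = "Not Significant",
                         stringsAsFactors = FALSE)
  expected$type[expected$col == 0] <- "Approved"
  if (withPreserve) {
    ring <- abs(expected$row - 2) <= 1 & abs(expected$col - 2) <= 1
    expected$type[ring] <- "Warning"
    expected <- expected[!(expected$row == 2 & expected$col == 2), ]
  }
  config <- pipelineConfig(countyName = "Simplecase", workingCRS = crs)
  list(layers = list(counties = county, heritage = heritage,
                     streams = emptyLine, waterbodies = emptyPoly,
                     wetlands = wetlands, addresses = addresses,
                     blocks = blocksL),
       expected = expected[order(expected$row, expected$col), ] |>
         `rownames<-`(NULL),
       config = config)
}
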