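# Geometry core: a GeoJSON-shaped internal representation plus thin wrappers
# around the Clipper engine (package 'polyclip') for all boolean overlay and
# offset (buffer) work.
#
# A geometry is list(type = <GeoJSON type>, coords = ...):
#   Point            numeric length-2
#   MultiPoint       n x 2 matrix
#   LineString       n x 2 matrix
#   MultiLineString  list of n x 2 matrices
#   Polygon          list of rings (n x 2 matrices); ring 1 exterior (CCW),
#                    subsequent rings holes (CW); rings are NOT closed
#                    (first vertex not repeated)
#   MultiPolygon     list of Polygon coordinate lists
#
# All coordinates are planar, in the linear unit of the layer CRS.

# Clipper snapping tolerance (absolute, in CRS units). Verified stable for
# State Plane magnitudes (~3e6 ft); keeps overlay error far below the 1e-9
# coordinate tolerances used in the I/O contracts.
.TZ_EPS <- 1e-10

.SQFT_PER_SQMI <- 27878400  # 5280^2
.ACRES_PER_SQMI <- 640

#' @noRd
geomKindOf <- function(type) {
  switch(type,
    Point = , MultiPoint = "point",
    LineString = , MultiLineString = "line",
    Polygon = , MultiPolygon = "polygon",
    stop("unknown geometry type: ", type))
}

#' @noRd
mkGeom <- function(type, coords) list(type = type, coords = coords)

.closeMat <- function(m) {
  if (!is.matrix(m)) m <- matrix(m, ncol = 2, byrow = TRUE)
  storage.mode(m) <- "double"
  m
}

# signed area of one ring (n x 2 matrix, unclosed); CCW positive
.ringSignedArea <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# normalize a list of rings so ring 1 is CCW and holes CW
.normalizePolyRings <- function(rings) {
  if (!length(rings)) return(rings)
  lapply(seq_along(rings), function(i) {
    m <- .closeMat(rings[[i]])
    a <- .ringSignedArea(m)
    want_ccw <- (i == 1L)
    if ((a < 0) == want_ccw) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    m
  })
}

#' @noRd
normalizeGeom <- function(g) {
  if (g$type == "Polygon") {
    g$coords <- .normalizePolyRings(g$coords)
  } else if (g$type == "MultiPolygon") {
    g$coords <- lapply(g$coords, .normalizePolyRings)
  } else if (g$type %in% c("LineString", "MultiPoint")) {
    g$coords <- .closeMat(g$coords)
  } else if (g$type == "MultiLineString") {
    g$coords <- lapply(g$coords, .closeMat)
  } else if (g$type == "Point") {
    g$coords <- as.numeric(g$coords)
  }
  g
}

# ---- area / bbox -----------------------------------------------------------

#' Planar area of a geometry
#'
#' Shoelace area of a polygon or multi-polygon (holes subtracted), in squared
#' CRS units. Zero for points and lines.
#'
#' @param g an internal geometry (as stored in a \code{VectorLayer})
#' @return numeric scalar
#' @noRd
geomArea <- function(g) {
  if (g$type == "Polygon") {
    rings <- .normalizePolyRings(g$coords)
    sum(vapply(rings, .ringSignedArea, 0))
  } else if (g$type == "MultiPolygon") {
    sum(vapply(g$coords, function(rings) {
      rings <- .normalizePolyRings(rings)
      sum(vapply(rings, .ringSignedArea, 0))
    }, 0))
  } else 0
}

#' @noRd
geomBBox <- function(g) {
  cm <- geomCoordMat(g)
  if (!nrow(cm)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
  c(min(cm[, 1]), min(cm[, 2]), max(cm[, 1]), max(cm[, 2]))
}

# all coordinates of a geometry as one matrix
#' @noRd
geomCoordMat <- function(g) {
  switch(g$type,
    Point = matrix(g$coords, ncol = 2),
    MultiPoint = , LineString = g$coords,
    MultiLineString = do.call(rbind, g$coords),
    Polygon = do.call(rbind, g$coords),
    MultiPolygon = do.call(rbind, lapply(g$coords, function(p) do.call(rbind, p))))
}

# apply f(matrix)->matrix to every coordinate block, preserving structure
#' @noRd
geomMapCoords <- function(g, f) {
  switch(g$type,
    Point = { g$coords <- as.numeric(f(matrix(g$coords, ncol = 2))); g },
    MultiPoint = , LineString = { g$coords <- f(g$coords); g },
    MultiLineString = { g$coords <- lapply(g$coords, f); g },
    Polygon = { g$coords <- lapply(g$coords, f); g },
    MultiPolygon = {
      g$coords <- lapply(g$coords, function(p) lapply(p, f)); g
    })
}

# ---- conversion to/from polyclip paths -------------------------------------

# polygon geometry -> flat list of list(x=, y=) rings (orientation preserved)
#' @noRd
geomToRings <- function(g) {
  if (is.null(g)) return(list())
  if (g$type == "Polygon") {
    lapply(g$coords, function(m) list(x = m[, 1], y = m[, 2]))
  } else if (g$type == "MultiPolygon") {
    out <- list()
    for (p in g$coords)
      out <- c(out, lapply(p, function(m) list(x = m[, 1], y = m[, 2])))
    out
  } else stop("geomToRings: not a polygon geometry")
}

# line geometry -> list of open paths
#' @noRd
geomToPaths <- function(g) {
  if (g$type == "LineString") {
    list(list(x = g$coords[, 1], y = g$coords[, 2]))
  } else if (g$type == "MultiLineString") {
    lapply(g$coords, function(m) list(x = m[, 1], y = m[, 2]))
  } else stop("geomToPaths: not a line geometry")
}

# boundary paths of any polygon geometry (for distance computations)
#' @noRd
geomBoundaryPaths <- function(g) geomToRings(g)

# flat ring list (from Clipper) -> Polygon / MultiPolygon geometry, assigning
# holes to the smallest enclosing exterior. Returns NULL for an empty set.
#' @noRd
ringsToGeom <- function(rings, sliver = 0) {
  if (!length(rings)) return(NULL)
  mats <- lapply(rings, function(r) cbind(r$x, r$y))
  areas <- vapply(mats, .ringSignedArea, 0)
  keep <- abs(areas) > sliver
  mats <- mats[keep]; areas <- areas[keep]
  if (!length(mats)) return(NULL)
  ext <- which(areas > 0); hol <- which(areas < 0)
  if (!length(ext)) return(NULL)
  parts <- lapply(ext, function(i) list(mats[[i]]))
  if (length(hol)) {
    for (h in hol) {
      px <- mats[[h]][1, 1]; py <- mats[[h]][1, 2]
      inside <- which(vapply(ext, function(i) {
        sp::point.in.polygon(px, py, mats[[i]][, 1], mats[[i]][, 2]) > 0
      }, NA))
      if (!length(inside)) next  # orphan hole: numeric noise, drop
      # smallest containing exterior
      j <- inside[which.min(areas[ext][inside])]
      parts[[j]] <- c(parts[[j]], list(mats[[h]]))
    }
  }
  parts <- lapply(parts, .normalizePolyRings)
  if (length(parts) == 1L) mkGeom("Polygon", parts[[1]])
  else mkGeom("MultiPolygon", parts)
}

# ---- Clipper wrappers ------------------------------------------------------

#' @noRd
pcUnionRings <- function(rings) {
  if (!length(rings)) return(list())
  polyclip::polyclip(rings, rings, op = "union",
                     fillA = "nonzero", fillB = "nonzero", eps = .TZ_EPS)
}

#' @noRd
pcOp <- function(a, b, op) {
  if (!length(a)) return(list())
  if (!length(b)) {
    if (op %in% c("minus", "union")) return(if (op == "minus") a else pcUnionRings(a))
    return(list())
  }
  polyclip::polyclip(a, b, op = op,
                     fillA = "nonzero", fillB = "nonzero", eps = .TZ_EPS)
}

# union of many polygon geometries -> single geometry (or NULL)
#' @noRd
geomUnionAll <- function(geoms) {
  rings <- list()
  for (g in geoms) if (!is.null(g)) rings <- c(rings, geomToRings(g))
  ringsToGeom(pcUnionRings(rings))
}

#' @noRd
geomIntersection <- function(a, b, sliver = 0) {
  if (is.null(a) || is.null(b)) return(NULL)
  ringsToGeom(pcOp(geomToRings(a), geomToRings(b), "intersection"), sliver)
}

#' @noRd
geomDifference <- function(a, b, sliver = 0) {
  if (is.null(a)) return(NULL)
  if (is.null(b)) return(a)
  ringsToGeom(pcOp(geomToRings(a), geomToRings(b), "minus"), sliver)
}

# arc tolerance giving >= 64 segments per quarter circle
.arcTol <- function(dist) max(abs(dist) * 5e-5, .TZ_EPS)

# outward offset (round joins) of a polygon geometry, then dissolve
#' @noRd
geomBufferPoly <- function(g, dist) {
  rings <- pcUnionRings(geomToRings(g))
  if (!length(rings)) return(NULL)
  if (dist == 0) return(ringsToGeom(rings))
  out <- polyclip::polyoffset(rings, dist, jointype = "round",
                              arctol = .arcTol(dist))
  ringsToGeom(pcUnionRings(out))
}

# round-capped, round-joined buffer of one line geometry -> polygon geometry
#' @noRd
geomBufferLine <- function(g, halfwidth) {
  paths <- geomToPaths(g)
  paths <- Filter(function(p) {
    length(p$x) >= 2 && any(diff(p$x) != 0 | diff(p$y) != 0)
  }, paths)
  if (!length(paths)) return(NULL)
  out <- polyclip::polylineoffset(paths, halfwidth, jointype = "round",
                                  endtype = "openround",
                                  arctol = .arcTol(halfwidth))
  ringsToGeom(pcUnionRings(out))
}

# minimum distance between boundaries of two geometries, capped: returns Inf
# when the true distance exceeds 'cap'
#' @noRd
geomMinDistance <- function(a, b, cap = Inf) {
  pa <- if (geomKindOf(a$type) == "polygon") geomToRings(a) else geomToPaths(a)
  pb <- if (geomKindOf(b$type) == "polygon") geomToRings(b) else geomToPaths(b)
  closedA <- geomKindOf(a$type) == "polygon"
  closedB <- geomKindOf(b$type) == "polygon"
  rcpp_min_dist_paths(pa, pb, closedA, closedB, cap)
}

# DE-9IM style "intersects" between two polygon geometries: positive overlap
# area OR boundary contact (distance zero within tolerance)
#' @noRd
geomIntersects <- function(a, b, tol = 1e-9) {
  if (is.null(a) || is.null(b)) return(FALSE)
  ba <- geomBBox(a); bb <- geomBBox(b)
  if (ba[1] > bb[3] + tol || bb[1] > ba[3] + tol ||
      ba[2] > bb[4] + tol || bb[2] > ba[4] + tol) return(FALSE)
  inter <- geomIntersection(a, b)
  if (!is.null(inter) && geomArea(inter) > 0) return(TRUE)
  geomMinDistance(a, b, cap = max(tol * 10, 1e-6)) <= tol
}

# component (exterior ring) count of a polygon geometry
#' @noRd
geomComponentCount <- function(g) {
  if (is.null(g)) return(0L)
  if (g$type == "Polygon") 1L else length(g$coords)
}

# an axis-aligned square polygon geometry
#' @noRd
squareGeom <- function(x0, y0, side) {
  mkGeom("Polygon", list(matrix(c(x0, y0, x0 + side, y0,
                                  x0 + side, y0 + side, x0, y0 + side),
                                ncol = 2, byrow = TRUE)))
}
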