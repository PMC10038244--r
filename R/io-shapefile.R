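# ESRI Shapefile reader/writer (.shp/.shx binary geometry, .dbf attribute
# table via foreign::read.dbf/write.dbf, .prj WKT from the CRS registry).
# Supported shape types: Point (1), PolyLine (3), Polygon (5), MultiPoint (8).
# Ring convention on disk follows the ESRI spec: outer rings clockwise,
# holes counter-clockwise.

.SHP_TYPE <- c(point = 1L, line = 3L, polygon = 5L, multipoint = 8L)

# ---- writing ---------------------------------------------------------------

# serialize one geometry to a raw vector of little-endian record contents
.shpRecord <- function(g) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  wI <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wD <- function(x) writeBin(as.double(x), con, size = 8, endian = "little")
  if (g$type %in% c("Point")) {
    wI(1L); wD(g$coords[1]); wD(g$coords[2])
  } else if (g$type == "MultiPoint") {
    m <- g$coords
    wI(8L); wD(c(min(m[, 1]), min(m[, 2]), max(m[, 1]), max(m[, 2])))
    wI(nrow(m)); wD(t(m))
  } else if (g$type %in% c("LineString", "MultiLineString")) {
    parts <- if (g$type == "LineString") list(g$coords) else g$coords
    all <- do.call(rbind, parts)
    wI(3L); wD(c(min(all[, 1]), min(all[, 2]), max(all[, 1]), max(all[, 2])))
    wI(length(parts)); wI(nrow(all))
    wI(cumsum(c(0L, vapply(parts, nrow, 0L)))[seq_along(parts)])
    wD(t(all))
  } else if (g$type %in% c("Polygon", "MultiPolygon")) {
    polys <- if (g$type == "Polygon") list(g$coords) else g$coords
    rings <- list()
    for (p in polys) for (i in seq_along(p)) {
      m <- p[[i]]
      a <- .ringSignedArea(m)
      # on disk: exterior CW (negative signed area), holes CCW
      flip <- if (i == 1L) a > 0 else a < 0
      if (flip) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
      rings <- c(rings, list(rbind(m, m[1, , drop = FALSE])))  # closed
    }
    all <- do.call(rbind, rings)
    wI(5L); wD(c(min(all[, 1]), min(all[, 2]), max(all[, 1]), max(all[, 2])))
    wI(length(rings)); wI(nrow(all))
    wI(cumsum(c(0L, vapply(rings, nrow, 0L)))[seq_along(rings)])
    wD(t(all))
  } else stop("cannot write geometry type ", g$type, " to shapefile")
  rawConnectionValue(con)
}

#' @noRd
writeShapefile <- function(layer, path) {
  base <- sub("\\.shp$", "", path, ignore.case = TRUE)
  recs <- lapply(layer@geoms, .shpRecord)
  shapeType <- if (length(layer@geoms)) {
    if (layer@geoms[[1]]$type == "MultiPoint") 8L
    else .SHP_TYPE[[layer@geomKind]]
  } else .SHP_TYPE[[layer@geomKind]]
  cm <- do.call(rbind, lapply(layer@geoms, geomCoordMat))
  bbox <- if (!is.null(cm) && nrow(cm))
    c(min(cm[, 1]), min(cm[, 2]), max(cm[, 1]), max(cm[, 2]))
  else c(0, 0, 0, 0)

  writeHeader <- function(con, fileLenWords) {
    writeBin(c(9994L, 0L, 0L, 0L, 0L, 0L, as.integer(fileLenWords)), con,
             size = 4, endian = "big")
    writeBin(c(1000L, shapeType), con, size = 4, endian = "little")
    writeBin(as.double(c(bbox, 0, 0, 0, 0)), con, size = 8, endian = "little")
  }
  # .shp
  lens <- vapply(recs, length, 0L) / 2L          # content length in words
  shpLen <- 50L + sum(lens + 4L)
  con <- file(paste0(base, ".shp"), "wb"); on.exit(close(con), add = TRUE)
  writeHeader(con, shpLen)
  for (i in seq_along(recs)) {
    writeBin(c(i, as.integer(lens[i])), con, size = 4, endian = "big")
    writeBin(recs[[i]], con)
  }
  close(con); on.exit(NULL)
  # .shx
  con <- file(paste0(base, ".shx"), "wb")
  writeHeader(con, 50L + 4L * length(recs))
  off <- 50L
  for (i in seq_along(recs)) {
    writeBin(c(off, as.integer(lens[i])), con, size = 4, endian = "big")
    off <- off + 4L + as.integer(lens[i])
  }
  close(con)
  # .dbf (dBase needs at least one column)
  df <- layer@attrs
  if (!ncol(df)) df <- data.frame(FID = seq_len(length(layer@geoms)))
  if (!nrow(df)) df <- df[0, , drop = FALSE]
  for (j in seq_along(df)) if (is.factor(df[[j]])) df[[j]] <- as.character(df[[j]])
  if (nrow(df)) foreign::write.dbf(df, paste0(base, ".dbf"))
  else suppressWarnings(foreign::write.dbf(df, paste0(base, ".dbf")))
  # .prj
  writeLines(crsInfo(layer@crs)$wkt, paste0(base, ".prj"))
  invisible(path)
}

# ---- reading ---------------------------------------------------------------

# group closed rings read from one record into a (Multi)Polygon: on-disk CW
# rings are exteriors, CCW rings holes
.shpAssemblePolys <- function(rings) {
  mats <- lapply(rings, function(m) m[-nrow(m), , drop = FALSE])  # unclose
  areas <- vapply(mats, .ringSignedArea, 0)
  keep <- areas != 0
  mats <- mats[keep]; areas <- areas[keep]
  if (!length(mats)) return(NULL)
  ext <- which(areas < 0); hol <- which(areas > 0)
  if (!length(ext)) { ext <- seq_along(mats); hol <- integer() }
  parts <- lapply(ext, function(i) list(mats[[i]]))
  for (h in hol) {
    px <- mats[[h]][1, 1]; py <- mats[[h]][1, 2]
    inside <- which(vapply(ext, function(i)
      sp::point.in.polygon(px, py, mats[[i]][, 1], mats[[i]][, 2]) > 0, NA))
    if (!length(inside)) next
    j <- inside[which.max(areas[ext][inside])]  # smallest |area|: areas<0
    parts[[j]] <- c(parts[[j]], list(mats[[h]]))
  }
  parts <- lapply(parts, .normalizePolyRings)
  if (length(parts) == 1L) mkGeom("Polygon", parts[[1]])
  else mkGeom("MultiPolygon", parts)
}

#' @noRd
readShapefile <- function(path, crs = NULL) {
  base <- sub("\\.shp$", "", path, ignore.case = TRUE)
  con <- file(paste0(base, ".shp"), "rb")
  on.exit(close(con))
  rI <- function(n, endian) readBin(con, "integer", n, size = 4, endian = endian)
  rD <- function(n) readBin(con, "double", n, size = 8, endian = "little")
  magic <- rI(1, "big")
  if (!length(magic) || magic != 9994L) stop("not a shapefile: ", path)
  rI(5, "big"); rI(1, "big")         # unused, file length
  rI(1, "little")                    # version
  headerType <- rI(1, "little")
  rD(8)                              # bbox + z/m ranges
  geoms <- list()
  repeat {
    hdr <- rI(2, "big")
    if (length(hdr) < 2) break
    contentStart <- seek(con, NA)
    typ <- rI(1, "little")
    g <- if (typ == 0L) NULL
    else if (typ %in% c(1L, 11L, 21L)) {
      mkGeom("Point", rD(2))
    } else if (typ %in% c(8L, 18L, 28L)) {
      rD(4); n <- rI(1, "little")
      mkGeom("MultiPoint", matrix(rD(2 * n), ncol = 2, byrow = TRUE))
    } else if (typ %in% c(3L, 13L, 23L, 5L, 15L, 25L)) {
      rD(4)
      np <- rI(1, "little"); npt <- rI(1, "little")
      parts <- rI(np, "little")
      pts <- matrix(rD(2 * npt), ncol = 2, byrow = TRUE)
      bounds <- c(parts, npt)
      pieces <- lapply(seq_len(np), function(i)
        pts[(bounds[i] + 1):bounds[i + 1], , drop = FALSE])
      if (typ %in% c(3L, 13L, 23L)) {
        if (length(pieces) == 1L) mkGeom("LineString", pieces[[1]])
        else mkGeom("MultiLineString", pieces)
      } else .shpAssemblePolys(pieces)
    } else stop("unsupported shapefile shape type: ", typ)
    geoms <- c(geoms, list(g))
    # reposition from the declared content length (hdr[2], 16-bit words),
    # which also skips any trailing Z/M payload
    seek(con, contentStart + 2 * hdr[2])
  }
  keep <- !vapply(geoms, is.null, NA)
  geoms <- geoms[keep]
  dbf <- paste0(base, ".dbf")
  attrs <- if (file.exists(dbf)) {
    df <- foreign::read.dbf(dbf, as.is = TRUE)
    df[keep, , drop = FALSE]
  } else data.frame(row.names = seq_along(geoms))
  if (is.null(crs)) {
    prj <- paste0(base, ".prj")
    if (file.exists(prj)) {
      crs <- crsFromWKT(paste(readLines(prj, warn = FALSE), collapse = ""))
      if (is.na(crs))
        stop("cannot identify the CRS in ", prj,
             "; pass crs= explicitly to readLayer()")
    } else {
      stop("no .prj file beside ", path,
           "; pass crs= explicitly to readLayer()")
    }
  }
  kind <- if (length(geoms)) geomKindOf(geoms[[1]]$type)
          else switch(as.character(headerType),
                      `1` = , `8` = , `11` = , `18` = , `21` = ,
                      `28` = "point",
                      `3` = , `13` = , `23` = "line", "polygon")
  vectorLayer(geoms, attrs, crs = crs, geomKind = kind)
}
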