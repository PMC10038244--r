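# GeoJSON reader/writer. Writing uses full double precision (%.17g) so that
# write-then-read round-trips within 1e-9. The CRS is carried in the legacy
# "crs" member (urn:ogc:def:crs:EPSG::<code>), which common GIS software
# emits and accepts; a file without one is taken as EPSG:4326 per RFC 7946.

.gjFmt <- function(x) {
  s <- sprintf("%.17g", x)
  sub("^(-?[0-9]+)\\.0+$", "\\1", s)
}

.gjCoordsMat <- function(m) {
  paste0("[", apply(m, 1, function(r)
    paste0("[", .gjFmt(r[1]), ",", .gjFmt(r[2]), "]")) |>
    paste(collapse = ","), "]")
}

.gjRing <- function(m) {
  # GeoJSON rings are closed
  .gjCoordsMat(rbind(m, m[1, , drop = FALSE]))
}

.gjGeometry <- function(g) {
  co <- switch(g$type,
    Point = paste0("[", .gjFmt(g$coords[1]), ",", .gjFmt(g$coords[2]), "]"),
    MultiPoint = , LineString = .gjCoordsMat(g$coords),
    MultiLineString = paste0("[", paste(vapply(g$coords, .gjCoordsMat, ""),
                                        collapse = ","), "]"),
    Polygon = paste0("[", paste(vapply(g$coords, .gjRing, ""),
                                collapse = ","), "]"),
    MultiPolygon = paste0("[", paste(vapply(g$coords, function(p)
      paste0("[", paste(vapply(p, .gjRing, ""), collapse = ","), "]"), ""),
      collapse = ","), "]"))
  paste0('{"type":"', g$type, '","coordinates":', co, "}")
}

#' @noRd
writeGeoJSON <- function(layer, path) {
  props <- layer@attrs
  feats <- vapply(seq_along(layer@geoms), function(i) {
    p <- if (ncol(props)) {
      jsonlite::toJSON(as.list(props[i, , drop = FALSE]),
                       auto_unbox = TRUE, digits = NA, na = "null")
    } else "{}"
    paste0('{"type":"Feature","properties":', p,
           ',"geometry":', .gjGeometry(layer@geoms[[i]]), "}")
  }, "")
  txt <- paste0('{"type":"FeatureCollection",',
                '"crs":{"type":"name","properties":{"name":',
                '"urn:ogc:def:crs:EPSG::', layer@crs, '"}},',
                '"features":[', paste(feats, collapse = ","), "]}")
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

.gjToMat <- function(co) {
  m <- matrix(unlist(lapply(co, function(p) as.numeric(p[1:2]))),
              ncol = 2, byrow = TRUE)
  m
}

.gjParseGeometry <- function(g) {
  if (is.null(g)) return(NULL)
  type <- g$type
  co <- g$coordinates
  dropClose <- function(m) {
    n <- nrow(m)
    if (n > 1 && m[1, 1] == m[n, 1] && m[1, 2] == m[n, 2])
      m[-n, , drop = FALSE] else m
  }
  coords <- switch(type,
    Point = as.numeric(co[1:2]),
    MultiPoint = , LineString = .gjToMat(co),
    MultiLineString = lapply(co, .gjToMat),
    Polygon = lapply(co, function(r) dropClose(.gjToMat(r))),
    MultiPolygon = lapply(co, function(p)
      lapply(p, function(r) dropClose(.gjToMat(r)))),
    stop("unsupported GeoJSON geometry type: ", type))
  normalizeGeom(mkGeom(type, coords))
}

#' @noRd
readGeoJSON <- function(path, crs = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$type)) stop("not a GeoJSON document: ", path)
  feats <- if (doc$type == "FeatureCollection") doc$features
           else if (doc$type == "Feature") list(doc)
           else list(list(type = "Feature", properties = NULL, geometry = doc))
  if (is.null(crs)) {
    crs <- 4326L
    nm <- tryCatch(doc$crs$properties$name, error = function(e) NULL)
    if (!is.null(nm)) {
      m <- regmatches(nm, regexpr("[0-9]+$", nm))
      if (length(m)) crs <- as.integer(m)
    }
  }
  geoms <- lapply(feats, function(f) .gjParseGeometry(f$geometry))
  keep <- !vapply(geoms, is.null, NA)
  geoms <- geoms[keep]; feats <- feats[keep]
  # collect the union of property names
  pnames <- unique(unlist(lapply(feats, function(f) names(f$properties))))
  attrs <- if (length(pnames)) {
    as.data.frame(lapply(pnames, function(nm) {
      vals <- lapply(feats, function(f) {
        v <- f$properties[[nm]]
        if (is.null(v)) NA else v
      })
      unlist(vals)
    }), col.names = pnames, check.names = FALSE,
    stringsAsFactors = FALSE)
  } else data.frame(row.names = seq_along(geoms))
  kind <- if (length(geoms)) geomKindOf(geoms[[1]]$type) else "polygon"
  vectorLayer(geoms, attrs, crs = crs, geomKind = kind)
}
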