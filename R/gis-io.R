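# User-facing layer I/O: format dispatch by file extension, schema
# validation, reprojection and validity repair. The pipeline core never
# touches files directly; everything enters and leaves through this surface.

.formatOf <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    shp = "shapefile",
    geojson = , json = "geojson",
    gpkg = "gpkg",
    stop("unknown or unsupported format for '", path,
         "' (expected .shp, .geojson/.json or .gpkg)"))
}

#' Read a vector layer from Shapefile, GeoJSON or GeoPackage
#'
#' Format is detected from the file extension (.shp, .geojson/.json, .gpkg).
#' The CRS is read from the file (.prj / "crs" member / gpkg_spatial_ref_sys);
#' \code{crs} overrides it when the file carries none. If \code{schema} is
#' given the layer is validated against it and reading fails with an error
#' naming any missing or mistyped attribute.
#'
#' @param path input file path
#' @param schema optional \code{LayerSchema}
#' @param crs optional EPSG override for files without CRS information
#' @param layer layer name inside a GeoPackage (default: first layer)
#' @return a \code{VectorLayer}
#' @examples
#' f <- tempfile(fileext = ".geojson")
#' writeLayer(vectorLayer(list(squareGeomExample()), crs = 2264), f)
#' readLayer(f)
#' @export
readLayer <- function(path, schema = NULL, crs = NULL, layer = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- switch(.formatOf(path),
    shapefile = readShapefile(path, crs = crs),
    geojson = readGeoJSON(path, crs = crs),
    gpkg = readGeoPackage(path, crs = crs, layer = layer))
  if (!is.null(schema)) validateSchema(out, schema)
  out
}

#' Write a vector layer to Shapefile, GeoJSON or GeoPackage
#'
#' The written file re-reads to an equal layer (coordinates within 1e-9).
#' An empty layer is written as a valid empty collection. Attribute-name case
#' is preserved on write.
#'
#' @param layer a \code{VectorLayer}
#' @param path output path; format from extension
#' @param layerName layer name used inside a GeoPackage
#' @return the path, invisibly
#' @export
writeLayer <- function(layer, path, layerName = "layer") {
  stopifnot(is(layer, "VectorLayer"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("parent directory does not exist: ", dir)
  switch(.formatOf(path),
    shapefile = writeShapefile(layer, path),
    geojson = writeGeoJSON(layer, path),
    gpkg = writeGeoPackage(layer, path, layerName = layerName))
  invisible(path)
}

#' Reproject a layer to another CRS
#'
#' Transforms every coordinate through the package's projection engine
#' (Lambert conformal conic State Plane zones and geographic NAD83/WGS84).
#' Reprojecting to the layer's own CRS is an exact identity. The attribute
#' table is unchanged.
#'
#' @param layer a \code{VectorLayer}
#' @param targetCrs EPSG code (must be registered; see \code{crsInfo})
#' @return the reprojected \code{VectorLayer}
#' @export
reprojectLayer <- function(layer, targetCrs) {
  targetCrs <- as.integer(targetCrs)
  crsInfo(targetCrs)  # errors on unknown code
  if (layer@crs == targetCrs) return(layer)
  from <- layer@crs
  geoms <- lapply(layer@geoms, function(g)
    geomMapCoords(g, function(m) transformCoords(m, from, targetCrs)))
  new("VectorLayer", geoms = geoms, attrs = layer@attrs,
      crs = targetCrs, geomKind = layer@geomKind)
}

#' Repair invalid geometries
#'
#' Polygons are resolved with an even-odd simplification (Clipper), which
#' turns self-intersecting rings (e.g. bow-ties) into valid multi-polygons
#' whose area equals the sum of the enclosed lobes. Degenerate zero-area
#' polygons and zero-length lines are dropped with a warning; the drop count
#' is attached as attribute \code{"dropped"}. Idempotent; already-valid
#' geometry is preserved (area within 1e-6 relative).
#'
#' @param layer a \code{VectorLayer}
#' @return the repaired \code{VectorLayer} (attribute "dropped" = drop count)
#' @export
makeValidLayer <- function(layer) {
  dropped <- 0L
  geoms <- vector("list", length(layer@geoms))
  for (i in seq_along(layer@geoms)) {
    g <- layer@geoms[[i]]
    kind <- geomKindOf(g$type)
    if (kind == "polygon") {
      rings <- polyclip::polysimplify(geomToRings(g), filltype = "evenodd",
                                      eps = .TZ_EPS)
      gg <- ringsToGeom(rings)
      if (is.null(gg) || geomArea(gg) <= 0) {
        dropped <- dropped + 1L
        geoms[i] <- list(NULL)
      } else geoms[[i]] <- gg
    } else if (kind == "line") {
      paths <- geomToPaths(g)
      paths <- Filter(function(p)
        length(p$x) >= 2 && any(diff(p$x) != 0 | diff(p$y) != 0), paths)
      if (!length(paths)) {
        dropped <- dropped + 1L
        geoms[i] <- list(NULL)
      } else {
        mats <- lapply(paths, function(p) cbind(p$x, p$y))
        geoms[[i]] <- if (length(mats) == 1L) mkGeom("LineString", mats[[1]])
                      else mkGeom("MultiLineString", mats)
      }
    } else geoms[[i]] <- g
  }
  keep <- !vapply(geoms, is.null, NA)
  if (dropped > 0L)
    warning("makeValidLayer: dropped ", dropped, " unrepairable geometr",
            if (dropped == 1L) "y" else "ies")
  out <- new("VectorLayer", geoms = geoms[keep],
             attrs = layer@attrs[keep, , drop = FALSE] |> `rownames<-`(NULL),
             crs = layer@crs, geomKind = layer@geomKind)
  attr(out, "dropped") <- dropped
  out
}

#' A unit-square example geometry (documentation helper)
#' @return a Polygon geometry covering the unit square
#' @export
squareGeomExample <- function() squareGeom(0, 0, 1)
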