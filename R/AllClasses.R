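#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib treatzones, .registration = TRUE
NULL

# ---- VectorLayer -----------------------------------------------------------

#' VectorLayer: a planar feature collection
#'
#' The universal currency of the pipeline: a list of geometries of one kind
#' (point, line or polygon; multi-part variants allowed), a parallel attribute
#' table, and an EPSG code. Coordinates are planar in the CRS's linear unit
#' (degrees for geographic CRSs, which the pipeline itself rejects).
#'
#' @slot geoms list of internal geometries (GeoJSON-shaped; see geom-core)
#' @slot attrs data.frame with one row per feature
#' @slot crs integer EPSG code
#' @slot geomKind "point", "line" or "polygon"
#' @export
setClass("VectorLayer",
  representation(geoms = "list", attrs = "data.frame", crs = "integer",
                 geomKind = "character"))

setValidity("VectorLayer", function(object) {
  msgs <- character()
  if (length(object@crs) != 1L || is.na(object@crs))
    msgs <- c(msgs, "crs must be a single EPSG code")
  if (!object@geomKind %in% c("point", "line", "polygon"))
    msgs <- c(msgs, "geomKind must be point, line or polygon")
  if (nrow(object@attrs) != length(object@geoms))
    msgs <- c(msgs, "attribute table and geometry list lengths differ")
  kinds <- vapply(object@geoms, function(g) geomKindOf(g$type), "")
  if (length(kinds) && any(kinds != object@geomKind))
    msgs <- c(msgs, "all geometries must share the layer's geometry kind")
  if (length(msgs)) msgs else TRUE
})

#' Construct a VectorLayer
#'
#' @param geoms list of internal geometries
#' @param attrs data.frame of feature attributes (one row per feature);
#'   defaults to an empty table
#' @param crs integer EPSG code
#' @param geomKind geometry kind; inferred from the first geometry if omitted
#' @return a \code{VectorLayer}
#' @export
vectorLayer <- function(geoms, attrs = NULL, crs, geomKind = NULL) {
  geoms <- lapply(geoms, normalizeGeom)
  if (is.null(geomKind)) {
    if (!length(geoms)) stop("geomKind must be given for an empty layer")
    geomKind <- geomKindOf(geoms[[1]]$type)
  }
  if (is.null(attrs)) attrs <- data.frame(row.names = seq_along(geoms))
  rownames(attrs) <- NULL
  new("VectorLayer", geoms = geoms, attrs = attrs, crs = as.integer(crs),
      geomKind = geomKind)
}

#' @describeIn vectorLayer number of features
#' @param x,object a VectorLayer
#' @export
nFeatures <- function(x) length(x@geoms)

#' Accessors for VectorLayer
#'
#' \code{layerCRS} returns the EPSG code, \code{layerKind} the geometry kind,
#' \code{attrTable} the attribute data.frame, \code{layerGeoms} the geometry
#' list and \code{layerArea} the summed planar polygon area.
#'
#' @param x a VectorLayer
#' @return see individual descriptions
#' @export
layerCRS <- function(x) x@crs

#' @rdname layerCRS
#' @export
layerKind <- function(x) x@geomKind

#' @rdname layerCRS
#' @export
attrTable <- function(x) x@attrs

#' @rdname layerCRS
#' @export
layerGeoms <- function(x) x@geoms

#' @rdname layerCRS
#' @export
layerArea <- function(x) sum(vapply(x@geoms, geomArea, 0))

setMethod("show", "VectorLayer", function(object) {
  cat(sprintf("VectorLayer: %d %s feature(s), EPSG:%d\n",
              nFeatures(object), object@geomKind, object@crs))
  if (ncol(object@attrs))
    cat("  attributes:", paste(names(object@attrs), collapse = ", "), "\n")
})

# case-insensitive attribute lookup; returns the stored column name or NA
#' @noRd
findAttr <- function(layer, name) {
  nm <- names(layer@attrs)
  hit <- which(tolower(nm) == tolower(name))
  if (length(hit)) nm[hit[1]] else NA_character_
}

# subset features of a layer
#' @noRd
layerSubset <- function(layer, idx) {
  new("VectorLayer", geoms = layer@geoms[idx],
      attrs = layer@attrs[idx, , drop = FALSE] |> `rownames<-`(NULL),
      crs = layer@crs, geomKind = layer@geomKind)
}

#' @noRd
stopIfMixedCRS <- function(...) {
  layers <- list(...)
  crss <- unique(vapply(layers, layerCRS, 0L))
  if (length(crss) > 1L)
    stop("layers have mixed CRSs (EPSG: ", paste(crss, collapse = ", "),
         "); reproject first")
  invisible(crss)
}

# ---- LayerSchema -----------------------------------------------------------

#' LayerSchema: required attributes and geometry kind for a layer role
#'
#' @slot requiredAttributes data.frame(name, kind) where kind is one of
#'   "character", "numeric", "integer", "logical", or "any"
#' @slot geometryKind expected geometry kind
#' @export
setClass("LayerSchema",
  representation(requiredAttributes = "data.frame", geometryKind = "character"))

#' Construct a LayerSchema
#'
#' @param attributes named character vector: names are required attribute
#'   names, values their required kinds ("character", "numeric", "integer",
#'   "logical" or "any")
#' @param geometryKind "point", "line" or "polygon"
#' @return a \code{LayerSchema}
#' @examples
#' heritageSchema <- layerSchema(
#'   c(GAP_STATUS = "any", OWNER_TYPE = "any"), "polygon")
#' @export
layerSchema <- function(attributes = character(), geometryKind) {
  new("LayerSchema",
      requiredAttributes = data.frame(name = names(attributes),
                                      kind = unname(attributes)),
      geometryKind = geometryKind)
}

#' Validate a layer against a schema
#'
#' Attribute names are matched case-insensitively. Fails (with an error
#' naming the offending attribute) iff a required attribute is absent or has
#' the wrong value kind, or the geometry kind differs.
#'
#' @param layer a VectorLayer
#' @param schema a LayerSchema
#' @return the layer, invisibly
#' @export
validateSchema <- function(layer, schema) {
  if (layer@geomKind != schema@geometryKind)
    stop("schema violation: expected ", schema@geometryKind,
         " geometry, got ", layer@geomKind)
  req <- schema@requiredAttributes
  for (i in seq_len(nrow(req))) {
    col <- findAttr(layer, req$name[i])
    if (is.na(col))
      stop("schema violation: required attribute '", req$name[i],
           "' is missing")
    kind <- req$kind[i]
    if (kind != "any") {
      v <- layer@attrs[[col]]
      ok <- switch(kind,
        character = is.character(v) || is.factor(v),
        numeric = is.numeric(v),
        integer = is.integer(v) || (is.numeric(v) && all(v == round(v), na.rm = TRUE)),
        logical = is.logical(v),
        stop("unknown schema kind: ", kind))
      if (!ok)
        stop("schema violation: attribute '", req$name[i],
             "' has the wrong kind (expected ", kind, ")")
    }
  }
  invisible(layer)
}

# ---- PipelineConfig --------------------------------------------------------

#' PipelineConfig: all protocol parameters
#'
#' Lengths and areas are interpreted in the linear unit of the working CRS
#' (US survey feet for the default EPSG:2264). Defaults are the protocol's
#' published parameters: 50 ft stream half-width, 100 ft sensitive-area
#' buffer, 100 ft warning distance, 1 mi^2 cells.
#'
#' @slot countyName county to select (case-insensitive)
#' @slot gapKeepValues integer GAP status codes kept as protected
#' @slot ownerKeepValues owner-type substrings kept as protected
#' @slot hydroHalfWidth stream/river buffer half-width
#' @slot sensitiveBuffer outward buffer applied to the merged sensitive layer
#' @slot warningDistance distance defining the Warning class
#' @slot cellArea fishnet cell area (default 5280^2 ft^2)
#' @slot keepEmptyCells retain cells containing no address point?
#' @slot apportionment "area_weighted" or "block_copy"
#' @slot sliverMinArea post-overlay slivers below this area are dropped
#' @slot workingCRS EPSG code of the (projected) working CRS
#' @export
setClass("PipelineConfig",
  representation(countyName = "character", gapKeepValues = "integer",
                 ownerKeepValues = "character", hydroHalfWidth = "numeric",
                 sensitiveBuffer = "numeric", warningDistance = "numeric",
                 cellArea = "numeric", keepEmptyCells = "logical",
                 apportionment = "character", sliverMinArea = "numeric",
                 workingCRS = "integer"))

setValidity("PipelineConfig", function(object) {
  msgs <- character()
  if (!nzchar(trimws(object@countyName)))
    msgs <- c(msgs, "countyName must be non-empty")
  for (f in c("hydroHalfWidth", "cellArea", "sliverMinArea")) {
    v <- slot(object, f)
    if (!is.finite(v) || v <= 0) msgs <- c(msgs, paste(f, "must be > 0"))
  }
  for (f in c("sensitiveBuffer", "warningDistance")) {
    v <- slot(object, f)
    if (!is.finite(v) || v < 0) msgs <- c(msgs, paste(f, "must be >= 0"))
  }
  if (!object@apportionment %in% c("area_weighted", "block_copy"))
    msgs <- c(msgs, "apportionment must be area_weighted or block_copy")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PipelineConfig
#'
#' @param countyName county to analyse
#' @param gapKeepValues GAP status codes (leading integers) treated as
#'   protected; matching compares the leading integer of the attribute, so
#'   "1: Managed for biodiversity..." matches 1
#' @param ownerKeepValues owner-type substrings (case-insensitive) treated as
#'   protected
#' @param hydroHalfWidth stream buffer half-width (working-CRS units; ft)
#' @param sensitiveBuffer buffer around the merged sensitive layer (ft)
#' @param warningDistance warning-class distance (ft)
#' @param cellArea fishnet cell area (working-CRS units squared; 1 mi^2)
#' @param keepEmptyCells keep address-free cells?
#' @param apportionment population apportionment mode
#' @param sliverMinArea minimum retained area after erase/clip
#' @param workingCRS projected working CRS (EPSG)
#' @return a \code{PipelineConfig}
#' @export
pipelineConfig <- function(countyName = "Synthetic",
                           gapKeepValues = c(1L, 2L),
                           ownerKeepValues = "federal",
                           hydroHalfWidth = 50,
                           sensitiveBuffer = 100,
                           warningDistance = 100,
                           cellArea = 5280^2,
                           keepEmptyCells = FALSE,
                           apportionment = c("area_weighted", "block_copy"),
                           sliverMinArea = 1,
                           workingCRS = 2264) {
  apportionment <- match.arg(apportionment)
  new("PipelineConfig", countyName = countyName,
      gapKeepValues = as.integer(gapKeepValues),
      ownerKeepValues = ownerKeepValues,
      hydroHalfWidth = hydroHalfWidth, sensitiveBuffer = sensitiveBuffer,
      warningDistance = warningDistance, cellArea = cellArea,
      keepEmptyCells = keepEmptyCells, apportionment = apportionment,
      sliverMinArea = sliverMinArea, workingCRS = as.integer(workingCRS))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat("  county:          ", object@countyName, "\n")
  cat("  GAP keep:        ", paste(object@gapKeepValues, collapse = ", "), "\n")
  cat("  owner keep:      ", paste(object@ownerKeepValues, collapse = ", "), "\n")
  cat("  hydro half-width:", object@hydroHalfWidth, "\n")
  cat("  sensitive buffer:", object@sensitiveBuffer, "\n")
  cat("  warning distance:", object@warningDistance, "\n")
  cat("  cell area:       ", object@cellArea,
      sprintf("(side %.0f)", sqrt(object@cellArea)), "\n")
  cat("  working CRS:      EPSG:", object@workingCRS, "\n", sep = "")
})

# ---- SensitiveArea ---------------------------------------------------------

#' SensitiveArea: the dissolved, buffered no-treatment region
#'
#' Output of protocol Steps 4-6: water bodies, buffered streams and filtered
#' protected lands, clipped to the county, buffered outward and dissolved
#' into a single (multi)polygon. May be empty when the county has no
#' sensitive features.
#'
#' @slot geom a single Polygon/MultiPolygon geometry, or NULL-equivalent
#'   empty list when no sensitive features exist
#' @slot componentCount number of disjoint components
#' @slot area planar area (working-CRS units squared)
#' @slot crs EPSG code
#' @export
setClass("SensitiveArea",
  representation(geom = "list", componentCount = "integer", area = "numeric",
                 crs = "integer"))

setValidity("SensitiveArea", function(object) {
  if (length(object@geom) &&
      !geomKindOf(object@geom$type) == "polygon")
    return("sensitive geometry must be polygonal")
  if (object@area < 0) return("area must be >= 0")
  TRUE
})

#' @noRd
sensitiveArea <- function(geom, crs) {
  if (is.null(geom))
    return(new("SensitiveArea", geom = list(), componentCount = 0L,
               area = 0, crs = as.integer(crs)))
  new("SensitiveArea", geom = geom,
      componentCount = geomComponentCount(geom),
      area = geomArea(geom), crs = as.integer(crs))
}

#' @noRd
isEmptySensitive <- function(s) length(s@geom) == 0L

setMethod("show", "SensitiveArea", function(object) {
  cat(sprintf("SensitiveArea: %d component(s), %.1f sq units, EPSG:%d\n",
              object@componentCount, object@area, object@crs))
})

# ---- ZoneGrid / ClassifiedGrid ---------------------------------------------

#' ZoneGrid: fishnet cells, possibly clipped, possibly classified
#'
#' Cells are stored column-wise: a data.frame of per-cell fields plus a
#' parallel list of cell geometries (axis-aligned squares before the erase
#' stage; clipped (multi)polygons after it).
#'
#' @slot cells data.frame with columns row, col, type, area, population,
#'   density (type is NA until classification)
#' @slot geoms list of cell geometries, parallel to \code{cells}
#' @slot crs EPSG code
#' @export
setClass("ZoneGrid",
  representation(cells = "data.frame", geoms = "list", crs = "integer"))

setValidity("ZoneGrid", function(object) {
  need <- c("row", "col", "type", "area", "population", "density")
  if (!all(need %in% names(object@cells)))
    return(paste("cells must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@cells) != length(object@geoms))
    return("cell table and geometry list lengths differ")
  ok <- is.na(object@cells$type) |
    object@cells$type %in% c("Approved", "Warning", "Not Significant")
  if (!all(ok)) return("invalid Type value")
  TRUE
})

#' @noRd
zoneGrid <- function(cells, geoms, crs) {
  rownames(cells) <- NULL
  new("ZoneGrid", cells = cells, geoms = geoms, crs = as.integer(crs))
}

#' Accessors for ZoneGrid / ClassifiedGrid
#'
#' \code{gridCells} returns the per-cell table, \code{gridGeoms} the cell
#' geometry list, \code{nCells} the cell count.
#'
#' @param x a ZoneGrid or ClassifiedGrid
#' @export
gridCells <- function(x) x@cells

#' @rdname gridCells
#' @export
gridGeoms <- function(x) x@geoms

#' @rdname gridCells
#' @export
nCells <- function(x) nrow(x@cells)

setMethod("show", "ZoneGrid", function(object) {
  cat(sprintf("ZoneGrid: %d cell(s), EPSG:%d\n", nCells(object), object@crs))
  if (any(!is.na(object@cells$type)))
    print(table(object@cells$type))
})

#' ClassifiedGrid: a fully classified treatment-zone grid
#'
#' The protocol's final geometry product: every retained cell carries a Type
#' in {Approved, Warning, Not Significant}, its post-erase area, and its
#' apportioned population. Carries a snapshot of the configuration that
#' produced it.
#'
#' @slot config the PipelineConfig used
#' @export
setClass("ClassifiedGrid", contains = "ZoneGrid",
  representation(config = "PipelineConfig"))

setValidity("ClassifiedGrid", function(object) {
  if (any(is.na(object@cells$type))) return("all cells must be classified")
  TRUE
})

setMethod("show", "ClassifiedGrid", function(object) {
  cat(sprintf("ClassifiedGrid: %d cell(s), EPSG:%d\n",
              nCells(object), object@crs))
  if (nCells(object)) print(table(object@cells$type))
})

# ---- ZoneSummary -----------------------------------------------------------

#' ZoneSummary: per-class areas, counts and populations
#'
#' Areas are reported in mi^2 rounded to 2 decimals (matching the reporting
#' precision of the protocol) and in acres (mi^2 x 640); populations and cell
#' counts per class, plus a Total row.
#'
#' @slot table data.frame with columns type, cell_count, area_ft2, area_mi2,
#'   area_acres, population
#' @export
setClass("ZoneSummary", representation(table = "data.frame"))

#' @rdname summarizeZones
#' @param x a ZoneSummary
#' @export
summaryTable <- function(x) x@table

setMethod("show", "ZoneSummary", function(object) {
  cat("ZoneSummary\n")
  print(object@table, row.names = FALSE)
})

# ---- CountyParams / ReferenceAreas -----------------------------------------

#' CountyParams: parameters of the synthetic-county generator
#'
#' @slot side county side length (working-CRS units; the county is square)
#' @slot nRivers number of river centerlines crossing the county
#' @slot nLakes number of lake polygons
#' @slot wetlandFraction target fraction of county area covered by wetlands
#' @slot nPreserves number of protected-land polygons
#' @slot nAddresses number of address points
#' @slot addressClustering "uniform" or "clustered"
#' @slot blockGrid census blocks form a blockGrid x blockGrid tiling
#' @slot seed RNG seed; fully determines the bundle
#' @export
setClass("CountyParams",
  representation(side = "numeric", nRivers = "integer", nLakes = "integer",
                 wetlandFraction = "numeric", nPreserves = "integer",
                 nAddresses = "integer", addressClustering = "character",
                 blockGrid = "integer", seed = "integer"))

setValidity("CountyParams", function(object) {
  msgs <- character()
  if (object@side <= 0) msgs <- c(msgs, "side must be > 0")
  if (object@wetlandFraction < 0 || object@wetlandFraction > 1)
    msgs <- c(msgs, "wetlandFraction must be in [0, 1]")
  if (any(c(object@nRivers, object@nLakes, object@nPreserves,
            object@nAddresses) < 0))
    msgs <- c(msgs, "counts must be >= 0")
  if (!object@addressClustering %in% c("uniform", "clustered"))
    msgs <- c(msgs, "addressClustering must be uniform or clustered")
  if (object@blockGrid < 1) msgs <- c(msgs, "blockGrid must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct CountyParams
#'
#' Defaults describe a 10-mile square coastal-plain county: a few rivers and
#' lakes, extensive wetlands, a handful of protected preserves, clustered
#' address points and an 8x8 census-block tiling.
#'
#' @param side county side (ft; default 10 miles)
#' @param nRivers,nLakes,nPreserves,nAddresses feature counts
#' @param wetlandFraction target wetland coverage of the county (0-1)
#' @param addressClustering "clustered" (default) or "uniform"
#' @param blockGrid census-block tiling order
#' @param seed integer RNG seed
#' @return a \code{CountyParams}
#' @export
countyParams <- function(side = 10 * 5280, nRivers = 3, nLakes = 4,
                         wetlandFraction = 0.35, nPreserves = 5,
                         nAddresses = 2000,
                         addressClustering = c("clustered", "uniform"),
                         blockGrid = 8, seed = 1) {
  addressClustering <- match.arg(addressClustering)
  new("CountyParams", side = side, nRivers = as.integer(nRivers),
      nLakes = as.integer(nLakes), wetlandFraction = wetlandFraction,
      nPreserves = as.integer(nPreserves), nAddresses = as.integer(nAddresses),
      addressClustering = addressClustering, blockGrid = as.integer(blockGrid),
      seed = as.integer(seed))
}

#' ReferenceAreas: per-class areas from the rasterized oracle
#'
#' @slot areas named numeric: Approved, Warning, `Not Significant` areas in
#'   working-CRS units squared
#' @slot resolution oracle pixel edge length
#' @export
setClass("ReferenceAreas",
  representation(areas = "numeric", resolution = "numeric"))

setMethod("show", "ReferenceAreas", function(object) {
  cat(sprintf("ReferenceAreas (resolution %.1f):\n", object@resolution))
  print(object@areas)
})

#' @rdname rasterOracle
#' @param x a ReferenceAreas
#' @export
referenceAreas <- function(x) x@areas
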