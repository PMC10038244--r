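# The treatment-zone protocol, step by step. Each exported function is one
# stage of the 18-step overlay analysis; runPipeline() (pipeline-run.R)
# chains them in protocol order.

#' Step 1: select (and dissolve) the county polygon
#'
#' Name comparison is case-insensitive and trimmed; several rows with the
#' same name (e.g. mainland + island parts) are dissolved into one
#' (multi)polygon feature.
#'
#' @param counties polygon \code{VectorLayer} with a county-name attribute
#' @param name county name
#' @param nameField attribute holding the name (case-insensitive lookup)
#' @return a single-feature polygon \code{VectorLayer}
#' @export
selectCounty <- function(counties, name, nameField = "County") {
  if (counties@geomKind != "polygon")
    stop("county layer must be polygonal")
  col <- findAttr(counties, nameField)
  if (is.na(col)) {
    # fall back to the first character attribute
    ch <- names(counties@attrs)[vapply(counties@attrs, function(v)
      is.character(v) || is.factor(v), NA)]
    if (!length(ch)) stop("county layer has no name attribute")
    col <- ch[1]
  }
  vals <- trimws(as.character(counties@attrs[[col]]))
  hit <- which(tolower(vals) == tolower(trimws(name)))
  if (!length(hit))
    stop("county '", name, "' not found; available: ",
         paste(sort(unique(vals)), collapse = ", "))
  geom <- if (length(hit) == 1L) counties@geoms[[hit]]
          else geomUnionAll(counties@geoms[hit])
  attrs <- data.frame(County = vals[hit[1]], stringsAsFactors = FALSE)
  names(attrs) <- col
  vectorLayer(list(geom), attrs, crs = counties@crs, geomKind = "polygon")
}

# leading integer of a GAP status value ("1: Managed for ..." -> 1)
.gapCode <- function(v) {
  v <- as.character(v)
  suppressWarnings(as.integer(
    ifelse(grepl("^\\s*[0-9]+", v), sub("^\\s*([0-9]+).*$", "\\1", v), NA)))
}

#' Step 2: filter protected-land polygons
#'
#' Keeps a feature iff its GAP status matches a configured keep code OR its
#' owner type matches a configured keep value. GAP matching compares the
#' leading integer of the attribute (so "1: Managed for biodiversity;
#' disturbance events proceed or mimicked" matches 1); owner matching is a
#' case-insensitive substring test (so "Federal Land" matches "federal").
#'
#' @param heritage polygon \code{VectorLayer} with GAP_STATUS and OWNER_TYPE
#' @param config a \code{PipelineConfig}
#' @return the filtered \code{VectorLayer}
#' @export
filterHeritage <- function(heritage, config) {
  validateSchema(heritage, layerSchema(
    c(GAP_STATUS = "any", OWNER_TYPE = "any"), "polygon"))
  gapCol <- findAttr(heritage, "GAP_STATUS")
  ownCol <- findAttr(heritage, "OWNER_TYPE")
  gap <- .gapCode(heritage@attrs[[gapCol]])
  own <- tolower(as.character(heritage@attrs[[ownCol]]))
  keepGap <- !is.na(gap) & gap %in% config@gapKeepValues
  keepOwn <- Reduce(`|`, lapply(tolower(config@ownerKeepValues), function(k)
    grepl(k, own, fixed = TRUE)), rep(FALSE, length(own)))
  layerSubset(heritage, which(keepGap | keepOwn))
}

#' Step 3: buffer stream/river centerlines
#'
#' Each line becomes a polygon of total width 2 x halfWidth with round end
#' caps and round joins (>= 64 arc segments per quarter circle). Zero-length
#' lines are dropped with a warning.
#'
#' @param lines line \code{VectorLayer}
#' @param halfWidth buffer half-width (> 0, working-CRS units)
#' @return polygon \code{VectorLayer}, one feature per retained line
#' @export
bufferHydroLines <- function(lines, halfWidth) {
  if (lines@geomKind != "line")
    stop("bufferHydroLines expects a line layer, got ", lines@geomKind)
  if (halfWidth <= 0) stop("halfWidth must be > 0")
  geoms <- lapply(lines@geoms, geomBufferLine, halfwidth = halfWidth)
  keep <- !vapply(geoms, is.null, NA)
  if (any(!keep))
    warning("bufferHydroLines: dropped ", sum(!keep), " degenerate line(s)")
  vectorLayer(geoms[keep],
              lines@attrs[keep, , drop = FALSE] |> `rownames<-`(NULL),
              crs = lines@crs, geomKind = "polygon")
}

#' Step 4: merge polygon layers (concatenation, no dissolve)
#'
#' Feature concatenation in the ESRI Merge sense: features are stacked,
#' overlaps untouched (dissolving happens later, in the sensitive-area
#' stage). Attribute tables are reduced to a source-layer tag.
#'
#' @param layers list of polygon \code{VectorLayer}s (same CRS); empty layers
#'   are ignored. Names of the list become the source tags.
#' @return polygon \code{VectorLayer} with attribute \code{src_layer}
#' @export
mergeLayers <- function(layers) {
  layers <- Filter(function(l) nFeatures(l) > 0, layers)
  if (!length(layers))
    return(vectorLayer(list(), crs = 2264, geomKind = "polygon"))
  do.call(stopIfMixedCRS, layers)
  for (l in layers) if (l@geomKind != "polygon")
    stop("mergeLayers expects polygon layers")
  tags <- names(layers)
  if (is.null(tags)) tags <- paste0("layer", seq_along(layers))
  geoms <- list(); src <- character()
  for (i in seq_along(layers)) {
    geoms <- c(geoms, layers[[i]]@geoms)
    src <- c(src, rep(tags[i], nFeatures(layers[[i]])))
  }
  vectorLayer(geoms, data.frame(src_layer = src, stringsAsFactors = FALSE),
              crs = layers[[1]]@crs, geomKind = "polygon")
}

#' Steps 5 and 7: clip a layer to a boundary polygon
#'
#' Cookie-cutter intersection: each feature is replaced by its intersection
#' with the boundary; empty intersections are dropped. Polygon and line
#' layers are supported; point features are kept when inside the boundary.
#'
#' @param layer \code{VectorLayer} to clip
#' @param boundary single-feature polygon \code{VectorLayer}
#' @return the clipped \code{VectorLayer}
#' @export
clipLayer <- function(layer, boundary) {
  if (boundary@geomKind != "polygon" || nFeatures(boundary) != 1L)
    stop("boundary must be a single polygon feature")
  stopIfMixedCRS(layer, boundary)
  bg <- boundary@geoms[[1]]
  if (geomArea(bg) <= 0) stop("empty clip boundary")
  brings <- geomToRings(bg)
  if (layer@geomKind == "polygon") {
    geoms <- lapply(layer@geoms, function(g) {
      out <- ringsToGeom(pcOp(geomToRings(g), brings, "intersection"))
      # features wholly inside the boundary keep their exact geometry
      if (!is.null(out)) {
        a0 <- geomArea(g)
        if (a0 > 0 && abs(geomArea(out) - a0) <= 1e-12 * a0) return(g)
      }
      out
    })
  } else if (layer@geomKind == "line") {
    geoms <- lapply(layer@geoms, function(g) {
      out <- polyclip::polyclip(geomToPaths(g), brings, op = "intersection",
                                closed = FALSE, fillB = "nonzero",
                                eps = .TZ_EPS)
      if (!length(out)) return(NULL)
      mats <- lapply(out, function(p) cbind(p$x, p$y))
      if (length(mats) == 1L) mkGeom("LineString", mats[[1]])
      else mkGeom("MultiLineString", mats)
    })
  } else {
    geoms <- lapply(layer@geoms, function(g) {
      m <- geomCoordMat(g)
      ins <- vapply(seq_len(nrow(m)), function(i) {
        any(vapply(brings, function(r)
          sp::point.in.polygon(m[i, 1], m[i, 2], r$x, r$y) > 0, NA))
      }, NA)
      if (!any(ins)) return(NULL)
      mm <- m[ins, , drop = FALSE]
      if (nrow(mm) == 1L) mkGeom("Point", mm[1, ])
      else mkGeom("MultiPoint", mm)
    })
  }
  keep <- !vapply(geoms, is.null, NA)
  vectorLayer(geoms[keep],
              layer@attrs[keep, , drop = FALSE] |> `rownames<-`(NULL),
              crs = layer@crs, geomKind = layer@geomKind)
}

#' Step 6: buffer and dissolve the merged sensitive layer
#'
#' Expands every polygon outward by \code{buffer} (round joins), then unions
#' everything into a single dissolved feature — the no-treatment
#' \code{SensitiveArea}. The buffer extends the distance between insecticide
#' release points and protected land to limit droplet drift.
#'
#' @param merged polygon \code{VectorLayer} (output of the merge/clip steps)
#' @param buffer outward buffer distance (>= 0)
#' @return a \code{SensitiveArea}
#' @export
bufferDissolveSensitive <- function(merged, buffer) {
  if (merged@geomKind != "polygon") stop("expected polygon layer")
  if (buffer < 0) stop("buffer must be >= 0")
  if (!nFeatures(merged)) return(sensitiveArea(NULL, merged@crs))
  u <- geomUnionAll(merged@geoms)
  if (is.null(u)) return(sensitiveArea(NULL, merged@crs))
  g <- if (buffer > 0) geomBufferPoly(u, buffer) else u
  sensitiveArea(g, merged@crs)
}

#' Step 8: build the address-indexed fishnet grid
#'
#' Axis-aligned square cells of side sqrt(cellArea). The grid origin is the
#' bounding-box minimum of the address points snapped DOWN to a multiple of
#' the cell side from the CRS origin, which makes cell boundaries independent
#' of feature order. By default only cells containing at least one address
#' point (boundary inclusive) are retained; \code{keepEmptyCells} retains the
#' full bounding block instead.
#'
#' @param addresses point \code{VectorLayer} with >= 1 feature
#' @param config a \code{PipelineConfig}
#' @return an (untyped) \code{ZoneGrid} of square cells
#' @export
buildFishnet <- function(addresses, config) {
  if (addresses@geomKind != "point") stop("address layer must be points")
  if (!nFeatures(addresses)) stop("empty address layer")
  pts <- do.call(rbind, lapply(addresses@geoms, geomCoordMat))
  side <- sqrt(config@cellArea)
  ox <- floor(min(pts[, 1]) / side) * side
  oy <- floor(min(pts[, 2]) / side) * side
  cellIds <- function(v, o) {
    f <- (v - o) / side
    i <- floor(f)
    extra <- which(f == i & i > 0)           # boundary-inclusive
    list(main = i, extra = extra, extraIdx = i[extra] - 1L)
  }
  cx <- cellIds(pts[, 1], ox); cy <- cellIds(pts[, 2], oy)
  occupied <- unique(rbind(
    cbind(cy$main, cx$main),
    if (length(cx$extra)) cbind(cy$main[cx$extra], cx$extraIdx),
    if (length(cy$extra)) cbind(cy$extraIdx, cx$main[cy$extra]),
    if (length(cx$extra) && length(cy$extra)) {
      both <- intersect(cx$extra, cy$extra)
      if (length(both))
        cbind(cy$main[both] - 1L, cx$main[both] - 1L)
    }))
  if (config@keepEmptyCells) {
    rows <- min(occupied[, 1]):max(occupied[, 1])
    cols <- min(occupied[, 2]):max(occupied[, 2])
    occupied <- as.matrix(expand.grid(rows, cols))
  }
  occupied <- occupied[order(occupied[, 1], occupied[, 2]), , drop = FALSE]
  geoms <- lapply(seq_len(nrow(occupied)), function(i)
    squareGeom(ox + occupied[i, 2] * side, oy + occupied[i, 1] * side, side))
  cells <- data.frame(row = as.integer(occupied[, 1]),
                      col = as.integer(occupied[, 2]),
                      type = NA_character_,
                      area = config@cellArea,
                      population = 0, density = 0)
  zoneGrid(cells, geoms, addresses@crs)
}

#' Step 9: erase the sensitive area from the grid
#'
#' Each cell geometry is replaced by cell \\ sensitive; cells whose remaining
#' area is at most \code{sliverMinArea} are dropped. Cell ids are preserved.
#'
#' @param grid untyped \code{ZoneGrid} from \code{buildFishnet}
#' @param sensitive a \code{SensitiveArea}
#' @param sliverMinArea minimum retained cell area
#' @return the erased \code{ZoneGrid}
#' @export
eraseSensitive <- function(grid, sensitive, sliverMinArea = 1) {
  if (isEmptySensitive(sensitive)) return(grid)
  srings <- geomToRings(sensitive@geom)
  sb <- geomBBox(sensitive@geom)
  geoms <- grid@geoms
  areas <- grid@cells$area
  for (i in seq_len(nCells(grid))) {
    cb <- geomBBox(geoms[[i]])
    if (cb[1] > sb[3] || sb[1] > cb[3] || cb[2] > sb[4] || sb[2] > cb[4])
      next  # disjoint bboxes: untouched
    g <- ringsToGeom(pcOp(geomToRings(geoms[[i]]), srings, "minus"))
    if (is.null(g)) { geoms[i] <- list(NULL); areas[i] <- 0; next }
    a <- geomArea(g)
    if (a <= sliverMinArea) { geoms[i] <- list(NULL); areas[i] <- 0 }
    else { geoms[[i]] <- g; areas[i] <- a }
  }
  keep <- !vapply(geoms, is.null, NA)
  cells <- grid@cells[keep, , drop = FALSE]
  cells$area <- areas[keep]
  zoneGrid(cells, geoms[keep], grid@crs)
}

#' Steps 10-13: split the grid into Warning and the inverted remainder
#'
#' A cell is Warning iff the distance from its post-erase geometry to the
#' buffered sensitive area is at most \code{warningDistance} (inclusive; a
#' cell abutting the erased boundary has distance 0). The remainder is
#' returned untyped. Warning and rest partition the input.
#'
#' @param grid post-erase \code{ZoneGrid}
#' @param sensitive the \code{SensitiveArea}
#' @param warningDistance inclusive distance threshold
#' @return list(warning = \code{ZoneGrid}, rest = \code{ZoneGrid})
#' @export
classifyWarning <- function(grid, sensitive, warningDistance) {
  n <- nCells(grid)
  if (isEmptySensitive(sensitive) || n == 0L) {
    empty <- zoneGrid(grid@cells[0, , drop = FALSE], list(), grid@crs)
    return(list(warning = empty, rest = grid))
  }
  srings <- geomToRings(sensitive@geom)
  sb <- geomBBox(sensitive@geom)
  isW <- logical(n)
  for (i in seq_len(n)) {
    cb <- geomBBox(grid@geoms[[i]])
    gap2 <- max(0, max(sb[1] - cb[3], cb[1] - sb[3]))^2 +
            max(0, max(sb[2] - cb[4], cb[2] - sb[4]))^2
    if (gap2 > warningDistance^2) next
    d <- rcpp_min_dist_paths(geomToRings(grid@geoms[[i]]), srings,
                             TRUE, TRUE, warningDistance * 1.0000001)
    isW[i] <- is.finite(d) && d <= warningDistance
  }
  w <- zoneGrid(grid@cells[isW, , drop = FALSE], grid@geoms[isW], grid@crs)
  w@cells$type <- if (nrow(w@cells)) "Warning" else character(0)
  r <- zoneGrid(grid@cells[!isW, , drop = FALSE], grid@geoms[!isW], grid@crs)
  list(warning = w, rest = r)
}

#' Steps 14-16: classify the non-warning remainder by wetland habitat
#'
#' A cell is Approved iff its post-erase geometry intersects any wetland
#' polygon (boundary contact counts, matching select-by-location semantics);
#' otherwise it is Not Significant.
#'
#' @param rest non-warning \code{ZoneGrid}
#' @param wetlands county-clipped wetland polygon \code{VectorLayer}
#' @return list(approved = \code{ZoneGrid}, notSignificant = \code{ZoneGrid})
#' @export
classifyRemainder <- function(rest, wetlands) {
  n <- nCells(rest)
  wet <- wetlands@geoms
  wbox <- lapply(wet, geomBBox)
  isA <- logical(n)
  for (i in seq_len(n)) {
    cb <- geomBBox(rest@geoms[[i]])
    for (j in seq_along(wet)) {
      bb <- wbox[[j]]
      if (cb[1] > bb[3] || bb[1] > cb[3] || cb[2] > bb[4] || bb[2] > cb[4])
        next
      if (geomIntersects(rest@geoms[[i]], wet[[j]])) { isA[i] <- TRUE; break }
    }
  }
  a <- zoneGrid(rest@cells[isA, , drop = FALSE], rest@geoms[isA], rest@crs)
  a@cells$type <- if (nrow(a@cells)) "Approved" else character(0)
  ns <- zoneGrid(rest@cells[!isA, , drop = FALSE], rest@geoms[!isA], rest@crs)
  ns@cells$type <- if (nrow(ns@cells)) "Not Significant" else character(0)
  list(approved = a, notSignificant = ns)
}

#' Step 17: merge the classified pieces into one grid
#'
#' Combines Warning, Approved and Not Significant cells into a completely
#' classified grid. The three inputs must be disjoint by cell id.
#'
#' @param warning,approved,notSignificant \code{ZoneGrid}s with types set
#' @param config the \code{PipelineConfig} snapshot to attach
#' @return a \code{ClassifiedGrid}
#' @export
mergeClassified <- function(warning, approved, notSignificant,
                            config = pipelineConfig()) {
  parts <- list(warning, approved, notSignificant)
  ids <- do.call(rbind, lapply(parts, function(p)
    p@cells[, c("row", "col"), drop = FALSE]))
  if (anyDuplicated(ids))
    stop("internal consistency error: duplicate cell id across classes")
  cells <- do.call(rbind, lapply(parts, gridCells))
  geoms <- do.call(c, lapply(parts, gridGeoms))
  ord <- order(cells$row, cells$col)
  crs <- unique(vapply(parts, function(p) p@crs, 0L))
  new("ClassifiedGrid", cells = cells[ord, , drop = FALSE] |>
        `rownames<-`(NULL),
      geoms = geoms[ord], crs = crs[1], config = config)
}

#' Step 18: attach census-block population to the grid
#'
#' In \code{area_weighted} mode (default) each cell receives, from every
#' intersecting block, block population x (overlap area / block area) — an
#' areal apportionment that conserves population over the covered blocks.
#' In \code{block_copy} mode each cell receives the full population of every
#' intersecting block (documented over-counting, mirroring a plain GIS
#' intersect-join). Density is population / post-erase cell area.
#'
#' @param grid a \code{ClassifiedGrid}
#' @param blocks polygon \code{VectorLayer} with a non-negative population
#'   attribute
#' @param popField population attribute name (case-insensitive)
#' @param mode "area_weighted" or "block_copy"; defaults to the grid config
#' @return the grid with population and density filled in
#' @export
attachPopulation <- function(grid, blocks, popField = "POPULATION",
                             mode = NULL) {
  if (is.null(mode)) mode <- grid@config@apportionment
  col <- findAttr(blocks, popField)
  if (is.na(col)) stop("blocks layer lacks a '", popField, "' attribute")
  pop <- as.numeric(blocks@attrs[[col]])
  if (any(is.na(pop) | pop < 0)) stop("negative or missing block population")
  if (grid@crs != blocks@crs)
    stop("grid and blocks have mixed CRSs; reproject first")
  barea <- vapply(blocks@geoms, geomArea, 0)
  bbox <- lapply(blocks@geoms, geomBBox)
  cellPop <- numeric(nCells(grid))
  for (i in seq_len(nCells(grid))) {
    cg <- grid@geoms[[i]]
    cb <- geomBBox(cg)
    for (j in seq_along(blocks@geoms)) {
      bb <- bbox[[j]]
      if (cb[1] > bb[3] || bb[1] > cb[3] || cb[2] > bb[4] || bb[2] > cb[4])
        next
      if (mode == "area_weighted") {
        inter <- geomIntersection(cg, blocks@geoms[[j]])
        if (is.null(inter)) next
        a <- geomArea(inter)
        if (a > 0 && barea[j] > 0)
          cellPop[i] <- cellPop[i] + pop[j] * a / barea[j]
      } else {
        if (geomIntersects(cg, blocks@geoms[[j]]))
          cellPop[i] <- cellPop[i] + pop[j]
      }
    }
  }
  grid@cells$population <- cellPop
  grid@cells$density <- ifelse(grid@cells$area > 0,
                               cellPop / grid@cells$area, 0)
  grid
}

#' Summarize a classified grid by zone
#'
#' Per-class planar areas are summed over the post-erase cell geometries in
#' ft^2, converted to mi^2 (reported at 2 decimals) and acres (mi^2 x 640),
#' with cell counts, population totals and a Total row.
#'
#' @param grid a \code{ClassifiedGrid}
#' @return a \code{ZoneSummary}
#' @export
summarizeZones <- function(grid) {
  classes <- c("Approved", "Warning", "Not Significant")
  rowFor <- function(cls) {
    idx <- which(grid@cells$type == cls)
    ft2 <- sum(grid@cells$area[idx])
    mi2 <- round(ft2 / .SQFT_PER_SQMI, 2)
    data.frame(type = cls, cell_count = length(idx), area_ft2 = ft2,
               area_mi2 = mi2, area_acres = mi2 * .ACRES_PER_SQMI,
               population = sum(grid@cells$population[idx]),
               stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, lapply(classes, rowFor))
  total <- data.frame(type = "Total", cell_count = sum(tab$cell_count),
                      area_ft2 = sum(tab$area_ft2),
                      area_mi2 = round(sum(tab$area_ft2) / .SQFT_PER_SQMI, 2),
                      area_acres = sum(tab$area_acres),
                      population = sum(tab$population),
                      stringsAsFactors = FALSE)
  new("ZoneSummary", table = rbind(tab, total))
}

#' Project treatment cost and product quantity from vetted acres
#'
#' Treatable ("vetted") acres are the Approved + Warning acres of the
#' summary; cost = acres x costPerAcre and product = acres x productRate.
#'
#' @param summary a \code{ZoneSummary}
#' @param costPerAcre application cost per acre (>= 0)
#' @param productRate formulated product per acre (>= 0)
#' @return data.frame(treatable_acres, cost, product)
#' @export
estimateTreatmentCost <- function(summary, costPerAcre, productRate) {
  if (costPerAcre < 0 || productRate < 0) stop("rates must be >= 0")
  tab <- summary@table
  acres <- sum(tab$area_acres[tab$type %in% c("Approved", "Warning")])
  data.frame(treatable_acres = acres,
             cost = acres * costPerAcre,
             product = acres * productRate)
}
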