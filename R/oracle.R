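# Independent rasterized classification oracle.
#
# Re-derives the per-class areas of the protocol by pixel sampling instead of
# vector overlay: polygon masks come from an even-odd scanline fill at pixel
# centers, buffers from exact point-to-segment distance bands and Euclidean
# distance transforms, and the per-cell classification from pixel aggregates.
# It shares no geometry code with the vector pipeline (which is built on
# Clipper), so agreement between the two is a genuine two-route check.
#
# The class semantics are cell-based, exactly as in the vector protocol: a
# retained cell is dropped when no non-sensitive pixel remains; it is Warning
# when the minimum distance from its remaining pixels to the sensitive region
# is at most the warning distance; otherwise Approved when any remaining
# pixel falls in a wetland, else Not Significant.

# scanline mask over all polygon features of a layer (union semantics)
.maskOfLayer <- function(layer, nx, ny, x0, y0, res) {
  if (!nFeatures(layer))
    return(rep(FALSE, as.double(nx) * ny))
  feats <- lapply(layer@geoms, geomToRings)
  rcpp_scanline_mask(feats, nx, ny, x0, y0, res)
}

.maskOfGeom <- function(geom, nx, ny, x0, y0, res) {
  rcpp_scanline_mask(list(geomToRings(geom)), nx, ny, x0, y0, res)
}

#' Rasterized reference classification
#'
#' Computes per-class areas of the treatment-zone protocol at a given pixel
#' resolution, entirely independently of the vector overlay engine. Used as
#' the validation oracle for the pipeline; the two routes must agree within
#' about one percent at 10 ft resolution on county-scale inputs, and converge
#' as the resolution shrinks.
#'
#' @param layers named bundle of \code{VectorLayer}s (as for
#'   \code{runPipeline})
#' @param config a \code{PipelineConfig}
#' @param resolution pixel edge length (working-CRS units); must be at most
#'   1/100 of the cell side
#' @return a \code{ReferenceAreas}
#' @export
rasterOracle <- function(layers, config, resolution = 10) {
  side <- sqrt(config@cellArea)
  if (resolution > side / 100)
    stop("resolution too coarse: must be <= cell side / 100 (",
         side / 100, ")")
  res <- resolution

  # retained cells from the address points (independent re-derivation of the
  # fishnet arithmetic)
  pts <- do.call(rbind, lapply(layers$addresses@geoms, geomCoordMat))
  if (is.null(pts) || !nrow(pts)) stop("empty address layer")
  ox <- floor(min(pts[, 1]) / side) * side
  oy <- floor(min(pts[, 2]) / side) * side
  ij <- unique(cbind(floor((pts[, 2] - oy) / side),
                     floor((pts[, 1] - ox) / side)))
  if (config@keepEmptyCells) {
    ij <- as.matrix(expand.grid(min(ij[, 1]):max(ij[, 1]),
                                min(ij[, 2]):max(ij[, 2])))
  }
  rows <- range(ij[, 1]); cols <- range(ij[, 2])
  x0 <- ox + cols[1] * side; y0 <- oy + rows[1] * side
  ncol_c <- cols[2] - cols[1] + 1L
  nrow_c <- rows[2] - rows[1] + 1L
  ppc <- as.integer(round(side / res))      # pixels per cell edge
  nx <- ncol_c * ppc; ny <- nrow_c * ppc

  county <- selectCounty(layers$counties, config@countyName)
  countyMask <- .maskOfGeom(county@geoms[[1]], nx, ny, x0, y0, res)

  heritage <- filterHeritage(layers$heritage, config)
  baseMask <- .maskOfLayer(heritage, nx, ny, x0, y0, res) |
              .maskOfLayer(layers$waterbodies, nx, ny, x0, y0, res)
  if (nFeatures(layers$streams)) {
    paths <- do.call(c, lapply(layers$streams@geoms, geomToPaths))
    baseMask <- baseMask | rcpp_seg_band(paths, nx, ny, x0, y0, res,
                                         config@hydroHalfWidth)
  }
  baseMask <- baseMask & countyMask        # Step 5 clip

  # Step 6 buffer via distance transform on the clipped base mask
  if (any(baseMask)) {
    dBase <- sqrt(rcpp_edt_sq(baseMask, nx, ny)) * res
    sensMask <- dBase <= config@sensitiveBuffer
    dSens <- sqrt(rcpp_edt_sq(sensMask, nx, ny)) * res
  } else {
    sensMask <- baseMask
    dSens <- rep(Inf, length(baseMask))
  }

  # wetland presence uses "all-touched" rasterization: a pixel counts when
  # its center is covered OR a wetland boundary passes through its square
  # (center within res/sqrt(2) of an edge). The cell-level Approved rule is
  # an intersects predicate, so boundary-grazing wetlands must register even
  # when they cover no pixel center.
  wetMask <- .maskOfLayer(layers$wetlands, nx, ny, x0, y0, res)
  if (nFeatures(layers$wetlands)) {
    ringPaths <- list()
    for (g in layers$wetlands@geoms)
      for (r in geomToRings(g))
        ringPaths <- c(ringPaths, list(list(x = c(r$x, r$x[1]),
                                            y = c(r$y, r$y[1]))))
    wetMask <- wetMask | rcpp_seg_band(ringPaths, nx, ny, x0, y0, res,
                                       res / sqrt(2))
  }
  wetMask <- wetMask & countyMask

  dim(sensMask) <- c(nx, ny); dim(dSens) <- c(nx, ny)
  dim(wetMask) <- c(nx, ny)

  acc <- c(Approved = 0, Warning = 0, `Not Significant` = 0)
  pxArea <- res * res
  sliverPx <- config@sliverMinArea / pxArea
  for (k in seq_len(nrow(ij))) {
    r <- ij[k, 1] - rows[1]; cc <- ij[k, 2] - cols[1]
    xi <- (cc * ppc + 1):((cc + 1) * ppc)
    yi <- (r * ppc + 1):((r + 1) * ppc)
    sens <- sensMask[xi, yi]
    keep <- !sens
    nKeep <- sum(keep)
    if (nKeep <= sliverPx) next               # cell fully erased
    # center-to-center distances between two pixelated regions overestimate
    # the true region-to-region distance by up to one pixel (half a pixel on
    # each side); correct the threshold accordingly (vanishes as res -> 0)
    if (min(dSens[xi, yi][keep]) <= config@warningDistance + res) {
      acc["Warning"] <- acc["Warning"] + nKeep * pxArea
    } else if (any(wetMask[xi, yi] & keep)) {
      acc["Approved"] <- acc["Approved"] + nKeep * pxArea
    } else {
      acc["Not Significant"] <- acc["Not Significant"] + nKeep * pxArea
    }
  }
  new("ReferenceAreas", areas = acc, resolution = res)
}
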