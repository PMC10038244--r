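# GeoPackage I/O, delegated to the bundled Python bridge (inst/python/
# gpkg_io.py): R <-> GeoJSON temp files <-> SQLite. Requires a python
# interpreter with the 'shapely' module (used only for WKB conversion).

#' @noRd
.pythonBin <- function() {
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop("GeoPackage support needs a 'python' interpreter on PATH")
}

#' @noRd
.gpkgScript <- function() {
  p <- system.file("python", "gpkg_io.py", package = "treatzones")
  if (!nzchar(p)) stop("bundled gpkg_io.py not found")
  p
}

#' @noRd
.runGpkg <- function(args) {
  out <- suppressWarnings(
    system2(.pythonBin(), c(shQuote(.gpkgScript()), args),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("GeoPackage bridge failed: ", paste(out, collapse = " "))
  invisible(out)
}

#' @noRd
readGeoPackage <- function(path, crs = NULL, layer = NULL) {
  tmp <- tempfile(fileext = ".geojson")
  on.exit(unlink(tmp))
  .runGpkg(c("read", shQuote(path), shQuote(tmp),
             if (!is.null(layer)) shQuote(layer)))
  readGeoJSON(tmp, crs = crs)
}

#' @noRd
writeGeoPackage <- function(layer, path, layerName = "layer") {
  tmp <- tempfile(fileext = ".geojson")
  on.exit(unlink(tmp))
  writeGeoJSON(layer, tmp)
  info <- crsInfo(layer@crs)
  .runGpkg(c("write", shQuote(tmp), shQuote(path), shQuote(layerName),
             layer@crs, shQuote(info$wkt)))
  invisible(path)
}
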