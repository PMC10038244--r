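# End-to-end protocol driver: Steps 1-18 in order, with a per-step log and
# step-labelled errors.

.STEP_NAMES <- c(
  "1" = "select county",
  "2" = "filter heritage",
  "3" = "buffer hydro lines",
  "4" = "merge sensitive layers",
  "5" = "clip merged to county",
  "6" = "buffer + dissolve sensitive",
  "7" = "clip wetlands to county",
  "8" = "build fishnet",
  "9" = "erase sensitive",
  "10-13" = "classify Warning",
  "14-16" = "classify remainder",
  "17" = "merge classified",
  "18" = "attach population")

.atStep <- function(step, expr) {
  tryCatch(expr, error = function(e)
    stop("Step ", step, " (", .STEP_NAMES[[as.character(step)]], "): ",
         conditionMessage(e), call. = FALSE))
}

#' Run the full 18-step treatment-zone protocol
#'
#' Executes select, filter, buffer, merge, clip, buffer-dissolve, wetland
#' clip, fishnet, erase, warning classification, wetland classification,
#' merge and population attachment in protocol order, and summarizes the
#' result. Deterministic: identical inputs and config yield identical output.
#'
#' @param layers named list of \code{VectorLayer}s with elements
#'   \code{counties}, \code{heritage}, \code{streams}, \code{waterbodies},
#'   \code{wetlands}, \code{addresses}, \code{blocks}; all must already be in
#'   \code{config@workingCRS} and validity-repaired (see \code{cmdRun} for a
#'   front-end that does this)
#' @param config a \code{PipelineConfig}
#' @param popField population attribute of the blocks layer
#' @return list(grid = \code{ClassifiedGrid}, summary = \code{ZoneSummary},
#'   sensitive = \code{SensitiveArea}, steps = per-step log data.frame)
#' @export
runPipeline <- function(layers, config, popField = "POPULATION") {
  need <- c("counties", "heritage", "streams", "waterbodies", "wetlands",
            "addresses", "blocks")
  miss <- setdiff(need, names(layers))
  if (length(miss))
    stop("missing required layer(s): ", paste(miss, collapse = ", "))
  if (crsIsGeographic(config@workingCRS))
    stop("working CRS must be projected (linear units), not geographic")
  crss <- vapply(layers[need], layerCRS, 0L)
  if (any(crss != config@workingCRS))
    stop("layer(s) not in working CRS EPSG:", config@workingCRS, ": ",
         paste(need[crss != config@workingCRS], collapse = ", "))

  log <- data.frame(step = character(), name = character(),
                    n_features = integer(), seconds = numeric())
  note <- function(step, n) {
    log[nrow(log) + 1L, ] <<- list(as.character(step),
                                   .STEP_NAMES[[as.character(step)]],
                                   as.integer(n),
                                   round(proc.time()[["elapsed"]] - t0, 3))
    t0 <<- proc.time()[["elapsed"]]
  }
  t0 <- proc.time()[["elapsed"]]

  county <- .atStep(1, selectCounty(layers$counties, config@countyName))
  note(1, nFeatures(county))
  heritage <- .atStep(2, filterHeritage(layers$heritage, config))
  note(2, nFeatures(heritage))
  hydro <- .atStep(3, bufferHydroLines(layers$streams, config@hydroHalfWidth))
  note(3, nFeatures(hydro))
  merged <- .atStep(4, mergeLayers(list(waterbodies = layers$waterbodies,
                                        streams = hydro,
                                        heritage = heritage)))
  note(4, nFeatures(merged))
  clipped <- .atStep(5, clipLayer(merged, county))
  note(5, nFeatures(clipped))
  sensitive <- .atStep(6, bufferDissolveSensitive(clipped,
                                                  config@sensitiveBuffer))
  note(6, sensitive@componentCount)
  wetlands <- .atStep(7, clipLayer(layers$wetlands, county))
  note(7, nFeatures(wetlands))
  fishnet <- .atStep(8, buildFishnet(layers$addresses, config))
  note(8, nCells(fishnet))
  erased <- .atStep(9, eraseSensitive(fishnet, sensitive,
                                      config@sliverMinArea))
  note(9, nCells(erased))
  if (nCells(erased) == 0L)
    warning("sensitive area covers the whole grid; result is empty")
  wsplit <- .atStep("10-13", classifyWarning(erased, sensitive,
                                             config@warningDistance))
  note("10-13", nCells(wsplit$warning))
  rsplit <- .atStep("14-16", classifyRemainder(wsplit$rest, wetlands))
  note("14-16", nCells(rsplit$approved))
  grid <- .atStep(17, mergeClassified(wsplit$warning, rsplit$approved,
                                      rsplit$notSignificant, config))
  note(17, nCells(grid))
  grid <- .atStep(18, attachPopulation(grid, layers$blocks,
                                       popField = popField))
  note(18, nCells(grid))
  list(grid = grid, summary = summarizeZones(grid), sensitive = sensitive,
       steps = log)
}
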