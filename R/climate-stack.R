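#' Create a climate stack
#'
#' @param grid A \linkS4class{GridSpec}.
#' @param scenario Scenario label.
#' @param years Contiguous integer years.
#' @param variables Character variable names.
#' @param layers Named list of value matrices keyed \code{"<var>:<year>"}.
#' @param mask Shared validity matrix (default: all valid).
#' @return A \linkS4class{ClimateStack}.
#' @export
ClimateStack <- function(grid, scenario, years, variables, layers,
                         mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, grid@nRows, grid@nCols)
  new("ClimateStack", grid = grid, scenario = scenario,
      years = as.integer(years), variables = variables,
      layers = layers, mask = mask)
}

#' @export
setMethod("show", "ClimateStack", function(object) {
  cat(sprintf("ClimateStack '%s': %d years (%d-%d), %d variables (%s), %d x %d grid\n",
              object@scenario, length(object@years), min(object@years),
              max(object@years), length(object@variables),
              paste(object@variables, collapse = ", "),
              object@grid@nRows, object@grid@nCols))
})

#' Extract one (year, variable) layer from a climate stack
#'
#' @param stack A \linkS4class{ClimateStack}.
#' @param year Integer year.
#' @param variable Variable name.
#' @return A \linkS4class{RasterLayer}.
#' @export
getLayer <- function(stack, year, variable) {
  key <- paste0(variable, ":", year)
  if (!key %in% names(stack@layers))
    .stopf("layer '%s' not present in the stack", key)
  new("RasterLayer", grid = stack@grid, values = stack@layers[[key]],
      mask = stack@mask)
}

#' Temporal mean of a climate stack
#'
#' Per-cell arithmetic mean across an inclusive year range, per variable.
#' This is how the "current climate" period (2000--2024 by convention) is
#' collapsed into the calibration layers.
#'
#' @param stack A \linkS4class{ClimateStack}.
#' @param yearRange Length-2 inclusive interval, e.g. \code{c(2000, 2024)}.
#' @return Named list of \linkS4class{RasterLayer}, one per variable.
#' @export
temporalMean <- function(stack, yearRange) {
  years <- intersect(seq(yearRange[1], yearRange[2]), stack@years)
  if (length(years) == 0L)
    .stopf("year range [%d, %d] does not intersect the stack's years",
           yearRange[1], yearRange[2])
  out <- lapply(stack@variables, function(v) {
    acc <- matrix(0, stack@grid@nRows, stack@grid@nCols)
    for (y in years) acc <- acc + stack@layers[[paste0(v, ":", y)]]
    new("RasterLayer", grid = stack@grid, values = acc / length(years),
        mask = stack@mask)
  })
  names(out) <- stack@variables
  out
}
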