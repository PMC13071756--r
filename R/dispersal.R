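# Annual dispersal-constrained colonization, 2025-2100: the core bespoke
# computation. Each year, every occupied cell emits one dispersal event
# (four directions, truncated-exponential distances); the convex hull of
# the source and the four endpoints is rasterized into a buffer; the union
# of buffers plus the previous range, intersected with that year's
# thresholded suitability, is the new occupied set. The unlimited-dispersal
# counterfactual instead equates occupancy with suitability.

#' Simulation grid for a species
#'
#' When a species' maximum annual dispersal distance is smaller than the
#' metric size of a base grid cell, yearly dispersal would be invisible at
#' the base resolution; the grid is therefore refined so the cell size
#' matches the dispersal distance (refinement factor
#' \code{ceiling(baseSize / dMax)}). Otherwise the base grid is returned
#' unchanged. \code{dMax = 0} leaves the grid unchanged (the run
#' degenerates to no-dispersal mode).
#'
#' @param profile A \linkS4class{SpeciesProfile}.
#' @param baseGrid The base \linkS4class{GridSpec}.
#' @return A \linkS4class{GridSpec}.
#' @export
simulationGrid <- function(profile, baseGrid) {
  base <- cellSizeKm(baseGrid)
  if (profile@dMax <= 0 || profile@dMax >= base) return(baseGrid)
  f <- ceiling(base / profile@dMax)
  GridSpec(baseGrid@lonMin, baseGrid@latMin, baseGrid@resDeg / f,
           baseGrid@nCols * f, baseGrid@nRows * f)
}

#' Dispersal buffer of one source cell
#'
#' Samples one distance per base direction, converts each
#' (direction, distance) pair to a lon/lat endpoint from the source-cell
#' center using the local metric scale (east-west km shrink with
#' \code{cos(latitude)}), and rasterizes the convex hull of the source
#' center and the four endpoints. The source cell is always included.
#'
#' @param cell Linear cell index of the source.
#' @param kernel A \linkS4class{DispersalKernel}.
#' @param grid Simulation \linkS4class{GridSpec}.
#' @param seed Optional seed for the four distance draws.
#' @param distances Optional numeric length-4, overriding the random
#'   draws (used for exact geometric checks).
#' @return Integer vector of buffer cell indices.
#' @export
disperseFrom <- function(cell, kernel, grid, seed = NULL, distances = NULL) {
  nCells <- grid@nRows * as.integer(grid@nCols)
  if (cell < 1 || cell > nCells) .stopf("source cell outside the grid")
  row <- (cell - 1) %% grid@nRows + 1
  col <- (cell - 1) %/% grid@nRows + 1
  lon <- grid@lonMin + (col - 0.5) * grid@resDeg
  lat <- grid@latMin + (row - 0.5) * grid@resDeg
  if (is.null(distances)) distances <- sampleKernel(kernel, 4, seed)
  if (all(distances <= 0)) return(as.integer(cell))
  a <- kernel@angles * pi / 180
  dLat <- distances * cos(a) / KM_PER_DEG
  dLon <- distances * sin(a) / (KM_PER_DEG * cos(lat * pi / 180))
  verts <- rbind(c(lon, lat), cbind(lon + dLon, lat + dLat))
  cells <- rasterizeHull(verts, grid)
  if (!cell %in% cells) cells <- sort(c(cells, as.integer(cell)))
  cells
}

#' Initial occupied range (year 2024)
#'
#' The starting occupancy is every currently suitable cell whose center
#' lies within \code{mInit * dMax} km (great-circle) of any occurrence
#' point -- \code{mInit = 1} for natives (range constrained by one year of
#' dispersal around known points) and 10 for invasives (whose short
#' invasion history makes the occupied neighbourhood wider than one annual
#' step). Cells containing an occurrence are always included if suitable.
#'
#' @param occ An \linkS4class{OccurrenceSet} (or data frame with
#'   decimalLongitude/decimalLatitude).
#' @param suitable Logical matrix (or \linkS4class{RasterLayer}) of
#'   currently suitable cells on the simulation grid.
#' @param profile A \linkS4class{SpeciesProfile}.
#' @param grid Simulation \linkS4class{GridSpec}.
#' @return Logical occupancy matrix; empty with a warning when no
#'   suitable cell is within reach.
#' @export
initialRange <- function(occ, suitable, profile, grid) {
  df <- if (is(occ, "OccurrenceSet")) occ@records else occ
  if (nrow(df) == 0) .stopf("no occurrence points supplied")
  if (is(suitable, "RasterLayer")) suitable <- suitable@values > 0 & suitable@mask
  pts <- cbind(df$decimalLongitude, df$decimalLatitude)
  reach <- profile@mInit * profile@dMax
  occCells <- cellFromLonLat(grid, pts[, 1], pts[, 2])
  occupied <- matrix(FALSE, grid@nRows, grid@nCols)
  suitIdx <- which(suitable)
  if (length(suitIdx) > 0 && reach > 0) {
    cc <- cellCenters(grid)[suitIdx, , drop = FALSE]
    dMin <- rep(Inf, length(suitIdx))
    for (i in seq_len(nrow(pts))) {
      d <- geosphere::distHaversine(pts[i, ], cc,
                                    r = EARTH_RADIUS_KM * 1000) / 1000
      dMin <- pmin(dMin, d)
    }
    occupied[suitIdx[dMin <= reach]] <- TRUE
  }
  inGrid <- occCells[!is.na(occCells)]
  occupied[inGrid[suitable[inGrid]]] <- TRUE
  if (!any(occupied))
    .warnf("no suitable cell within reach of any occurrence: empty initial range")
  occupied
}

#' One annual dispersal step
#'
#' For each of the species' \code{frequency} dispersal rounds, every
#' occupied cell emits a dispersal buffer; the candidate range (previous
#' occupancy plus all buffers) is then intersected with the year's
#' suitable cells, so occupied cells turning unsuitable are extirpated
#' immediately. Kernel draws are seeded per (cell, round) from
#' \code{seedBase}, which makes the step reproducible and gives common
#' random numbers across runs that share a seed.
#'
#' @param occupied Logical occupancy matrix from the previous year.
#' @param suitable Logical matrix of this year's suitable cells.
#' @param kernel A \linkS4class{DispersalKernel}.
#' @param grid Simulation \linkS4class{GridSpec}.
#' @param seedBase Integer seed for this step's draws.
#' @param frequency Dispersal events this year (default 1).
#' @param frontierOnly When TRUE, only occupied cells bordering (queen
#'   neighbourhood) a non-occupied cell emit buffers -- an optimization
#'   for large contiguous ranges whose interior buffers cannot reach new
#'   cells. Because draws are seeded per cell, the frontier run uses the
#'   same draws as the full run for the cells it shares.
#' @return New logical occupancy matrix.
#' @export
stepDispersal <- function(occupied, suitable, kernel, grid, seedBase,
                          frequency = 1L, frontierOnly = FALSE) {
  if (!all(dim(occupied) == dim(suitable)) ||
      !all(dim(occupied) == c(grid@nRows, grid@nCols)))
    .stopf("occupied/suitable grids do not match the simulation grid")
  for (round in seq_len(frequency)) {
    src <- which(if (frontierOnly) occupied & !.interiorCells(occupied)
                 else occupied)
    if (length(src) == 0L) break
    if (kernel@dMax > 0) {
      buffers <- lapply(src, function(cell)
        disperseFrom(cell, kernel, grid,
                     seed = deriveSeed(seedBase, cell, round)))
      candidate <- occupied
      candidate[unique(unlist(buffers))] <- TRUE
    } else candidate <- occupied
    occupied <- candidate & suitable
  }
  occupied & suitable
}

# cells whose full queen neighbourhood (inside the grid) is occupied
.interiorCells <- function(occupied) {
  nr <- nrow(occupied); nc <- ncol(occupied)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- occupied
  interior <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    shifted <- pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    edge <- matrix(FALSE, nr, nc)
    edge[] <- (row(interior) + dr < 1) | (row(interior) + dr > nr) |
      (col(interior) + dc < 1) | (col(interior) + dc > nc)
    interior <- interior & (shifted | edge)
  }
  interior & occupied
}

#' Run the annual dispersal simulation for one species and scenario
#'
#' Per year: projects the niche model onto that year's climate layers,
#' binarizes at the species' threshold, applies the hard elevation mask,
#' and advances occupancy -- via \code{\link{stepDispersal}} in
#' \code{"limited"} mode, or by equating occupancy with suitability in
#' \code{"unlimited"} mode (which consumes no random numbers). Both modes
#' run on the species' simulation grid (refined when \code{dMax} is below
#' the base cell size) so their areas are directly comparable. Fully
#' reproducible from \code{(inputs, seed)}.
#'
#' @param profile A \linkS4class{SpeciesProfile}.
#' @param occ Cleaned, thinned \linkS4class{OccurrenceSet}.
#' @param model Fitted \linkS4class{NicheModel}.
#' @param stack \linkS4class{ClimateStack} covering the simulated years.
#' @param tau Binarization threshold from \code{\link{optimalThreshold}}.
#' @param years Integer years to simulate (default 2025:2100).
#' @param mode \code{"limited"} or \code{"unlimited"}.
#' @param elevation Optional elevation \linkS4class{RasterLayer} on the
#'   base grid.
#' @param currentRange Length-2 year interval defining the current-climate
#'   period (default \code{c(2000, 2024)}).
#' @param seed Integer stream seed for kernel draws.
#' @return A \linkS4class{DispersalRun}.
#' @export
runDispersal <- function(profile, occ, model, stack, tau,
                         years = 2025:2100, mode = c("limited", "unlimited"),
                         elevation = NULL, currentRange = c(2000, 2024),
                         seed = 1L) {
  mode <- match.arg(mode)
  years <- as.integer(years)
  if (!all(years %in% stack@years))
    .stopf("stack does not cover all simulated years")
  simGrid <- simulationGrid(profile, stack@grid)
  refine <- simGrid@resDeg < stack@grid@resDeg
  kernel <- dispersalKernel(profile@dMax)

  suitAsBinary <- function(layers) {
    s <- projectSuitability(model, layers, elevation, profile@elevationBound)
    if (refine) s <- resampleLayer(s, simGrid@resDeg)
    s@values >= tau & s@mask
  }
  currentSuit <- suitAsBinary(temporalMean(stack, currentRange))
  initial <- if (mode == "limited")
    suppressWarnings(initialRange(occ, currentSuit, profile, simGrid))
  else currentSuit

  suitable <- occupied <- stats::setNames(vector("list", length(years)),
                                          years)
  state <- initial
  for (i in seq_along(years)) {
    y <- years[i]
    layers <- stats::setNames(
      lapply(model@variables, function(v) getLayer(stack, y, v)),
      model@variables)
    suitY <- suitAsBinary(layers)
    state <- if (mode == "unlimited") suitY
    else stepDispersal(state, suitY, kernel, simGrid,
                       seedBase = deriveSeed(seed, "year", y),
                       frequency = profile@frequency)
    suitable[[i]] <- suitY
    occupied[[i]] <- state
  }
  new("DispersalRun", speciesId = profile@speciesId,
      scenario = stack@scenario, mode = mode, years = years, tau = tau,
      grid = simGrid, suitable = suitable, occupied = occupied,
      initial = initial,
      seed = if (mode == "limited") as.integer(seed) else NA_integer_)
}

#' @export
setMethod("show", "DispersalRun", function(object) {
  occ <- vapply(object@occupied, sum, 0L)
  cat(sprintf("DispersalRun '%s' %s/%s: %d years (%d-%d), tau = %.3f, occupied cells %d -> %d\n",
              object@speciesId, object@scenario, object@mode,
              length(object@years), min(object@years), max(object@years),
              object@tau, occ[1], occ[length(occ)]))
})
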