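#' @import methods
NULL

#' Regular longitude/latitude grid specification
#'
#' Describes a regular geographic grid with square (in degrees) cells.
#' Cell (row 1, col 1) is the south-west corner; cell boundaries are
#' half-open \code{[edge, edge + resolution)}. All raster layers and the
#' dispersal simulation share this data model.
#'
#' @slot lonMin,latMin Numeric, west/south edge of the grid in degrees.
#' @slot resDeg Numeric, cell size in degrees (same in both axes).
#' @slot nCols,nRows Integer grid dimensions.
#' @export
setClass("GridSpec",
  representation(lonMin = "numeric", latMin = "numeric", resDeg = "numeric",
                 nCols = "integer", nRows = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@resDeg) != 1L || !is.finite(object@resDeg) ||
        object@resDeg <= 0) msg <- c(msg, "resDeg must be a positive number")
    if (object@nCols < 1L || object@nRows < 1L)
      msg <- c(msg, "nCols and nRows must be >= 1")
    if (length(msg) == 0L) {
      if (object@latMin < -90 ||
          object@latMin + object@nRows * object@resDeg > 90 + 1e-9)
        msg <- c(msg, "grid exceeds the [-90, 90] latitude range")
    }
    if (length(msg)) msg else TRUE
  })

#' Single-band raster layer on a GridSpec
#'
#' @slot grid A \linkS4class{GridSpec}.
#' @slot values Numeric matrix \code{[nRows, nCols]}; row 1 is the
#'   southernmost row.
#' @slot mask Logical matrix of the same shape; \code{FALSE} marks nodata.
#' @export
setClass("RasterLayer",
  representation(grid = "GridSpec", values = "matrix", mask = "matrix"),
  validity = function(object) {
    g <- object@grid
    if (!all(dim(object@values) == c(g@nRows, g@nCols)))
      return("values matrix does not match grid dimensions")
    if (!all(dim(object@mask) == c(g@nRows, g@nCols)))
      return("mask matrix does not match grid dimensions")
    if (!is.logical(object@mask)) return("mask must be logical")
    if (any(!is.finite(object@values[object@mask])))
      return("non-finite values inside the validity mask")
    TRUE
  })

#' Annual multi-variable climate stack
#'
#' One raster layer per (year, variable) pair, all sharing a grid and a
#' validity mask. The environmental driver of model fitting and of the
#' annual dispersal simulation.
#'
#' @slot grid A \linkS4class{GridSpec}.
#' @slot scenario Character scenario label (e.g. \code{"RCP4.5-like"}).
#' @slot years Integer vector, contiguous.
#' @slot variables Character vector of variable names (BIO-style).
#' @slot layers Named list of value matrices keyed \code{"<var>:<year>"}.
#' @slot mask Shared logical validity matrix.
#' @export
setClass("ClimateStack",
  representation(grid = "GridSpec", scenario = "character",
                 years = "integer", variables = "character",
                 layers = "list", mask = "matrix"),
  validity = function(object) {
    if (length(object@years) && any(diff(object@years) != 1L))
      return("years must be a contiguous integer sequence")
    need <- as.vector(outer(object@variables, object@years,
                            function(v, y) paste0(v, ":", y)))
    if (!all(need %in% names(object@layers)))
      return("a (variable, year) layer is missing")
    g <- object@grid
    if (!all(dim(object@mask) == c(g@nRows, g@nCols)))
      return("mask does not match grid dimensions")
    TRUE
  })

#' Virtual species with a Gaussian product niche
#'
#' True suitability is \code{s(z) = exp(-sum_j (z_j - mu_j)^2 / (2 sigma_j^2))},
#' so \code{s = 1} exactly at the niche optimum. Used to generate occurrence
#' fixtures with known truth for pipeline validation.
#'
#' @slot optima Named numeric, niche optimum per variable.
#' @slot breadths Named numeric, niche breadth (sigma) per variable; > 0.
#' @slot detectionEffort Numeric scalar scaling sampling intensity.
#' @slot nativity \code{"native"} or \code{"invasive"}.
#' @export
setClass("VirtualSpecies",
  representation(optima = "numeric", breadths = "numeric",
                 detectionEffort = "numeric", nativity = "character"),
  validity = function(object) {
    if (!identical(sort(names(object@optima)), sort(names(object@breadths))))
      return("optima and breadths must cover the same variables")
    if (any(object@breadths <= 0)) return("breadths must be > 0")
    if (!object@nativity %in% c("native", "invasive"))
      return("nativity must be 'native' or 'invasive'")
    TRUE
  })

#' Species dispersal/ecology profile
#'
#' Carries the per-species traits the simulation needs: maximum annual
#' dispersal distance (km/yr, within the 0--50 envelope), dispersal
#' frequency (events per year), the initialization buffer multiplier
#' (1 for natives, 10 for invasives, reflecting the short invasion history
#' of introduced species), and an optional hard elevation bound in metres.
#'
#' @slot speciesId Character identifier.
#' @slot taxon Character taxon group (e.g. "bird", "amphibian", "insect").
#' @slot nativity \code{"native"} or \code{"invasive"}.
#' @slot dMax Numeric, maximum annual dispersal distance in km/yr.
#' @slot frequency Integer, dispersal events per year (>= 1).
#' @slot mInit Numeric, initialization buffer multiplier (>= 1).
#' @slot elevationBound Numeric, metres; \code{Inf} when unbounded.
#' @export
setClass("SpeciesProfile",
  representation(speciesId = "character", taxon = "character",
                 nativity = "character", dMax = "numeric",
                 frequency = "integer", mInit = "numeric",
                 elevationBound = "numeric"),
  validity = function(object) {
    if (object@dMax < 0 || object@dMax > 50)
      return("dMax must lie in [0, 50] km/yr")
    if (object@frequency < 1L) return("frequency must be >= 1")
    if (object@mInit < 1) return("mInit must be >= 1")
    if (!object@nativity %in% c("native", "invasive"))
      return("nativity must be 'native' or 'invasive'")
    TRUE
  })

#' Truncated-exponential dispersal kernel
#'
#' Per-event dispersal distances are exponential with rate
#' \code{rate = 3 / dMax}, truncated at \code{dMax}, so about 95\% of the
#' untruncated mass lies below the species' maximum. Each event disperses
#' along four base directions (default the cardinals).
#'
#' @slot dMax Numeric, maximum distance in km (the truncation point).
#' @slot angles Numeric length-4, direction azimuths in degrees
#'   (0 = north, 90 = east).
#' @slot rate Numeric, exponential rate in 1/km.
#' @export
setClass("DispersalKernel",
  representation(dMax = "numeric", angles = "numeric", rate = "numeric"),
  validity = function(object) {
    if (object@dMax < 0) return("dMax must be >= 0")
    if (length(object@angles) != 4L) return("exactly four directions required")
    TRUE
  })

#' Fitted presence-background niche model
#'
#' A Gibbs density over landscape cells: \code{p(x) = exp(beta . f(x)) / Z}
#' with linear/quadratic/product features of min-max scaled predictors and
#' an L1 penalty scaled by the regularization multiplier. Suitability output
#' uses the complementary log-log transform.
#'
#' @slot fc Character feature-class code, one of L, Q, P, LQ, LP, QP, LQP.
#' @slot rm Numeric regularization multiplier.
#' @slot variables Character, predictor names in order.
#' @slot bounds Numeric matrix 2 x nvar (rows min, max) of calibration
#'   scaling bounds.
#' @slot beta Named numeric coefficient vector, one per feature.
#' @slot Z Numeric landscape normalizer over the calibration sample.
#' @slot entropy Numeric, entropy of the calibration raw distribution
#'   (drives the cloglog transform).
#' @slot report List of fit diagnostics (LL, k, n, AICc, convergence).
#' @export
setClass("NicheModel",
  representation(fc = "character", rm = "numeric", variables = "character",
                 bounds = "matrix", beta = "numeric", Z = "numeric",
                 entropy = "numeric", report = "list"),
  validity = function(object) {
    if (!object@fc %in% c("L", "Q", "P", "LQ", "LP", "QP", "LQP"))
      return("fc must be one of L, Q, P, LQ, LP, QP, LQP")
    if (ncol(object@bounds) != length(object@variables))
      return("bounds must have one column per variable")
    if (object@Z <= 0) return("normalizer Z must be positive")
    TRUE
  })

#' Cleaned occurrence set with filter provenance
#'
#' @slot records Data frame of occurrence records (Darwin-Core-like
#'   columns: decimalLongitude, decimalLatitude, year,
#'   coordinateUncertaintyInMeters, basisOfRecord, species).
#' @slot provenance Data frame logging each filter stage with records kept
#'   and rejected.
#' @export
setClass("OccurrenceSet",
  representation(records = "data.frame", provenance = "data.frame"),
  validity = function(object) {
    need <- c("decimalLongitude", "decimalLatitude")
    if (!all(need %in% names(object@records)))
      return("records must carry decimalLongitude and decimalLatitude")
    TRUE
  })

#' Yearly dispersal simulation result
#'
#' Holds, for one species x scenario x mode, the per-year thresholded
#' suitability maps and occupied-cell maps on the simulation grid.
#'
#' @slot speciesId,scenario,mode Character labels
#'   (mode is \code{"limited"} or \code{"unlimited"}).
#' @slot years Integer vector of simulated years.
#' @slot tau Numeric binarization threshold.
#' @slot grid Simulation \linkS4class{GridSpec} (possibly refined).
#' @slot suitable,occupied Lists of logical matrices, one per year
#'   (names are the years). \code{occupied[[t]]} is always a subset of
#'   \code{suitable[[t]]}.
#' @slot initial Logical matrix, the year-2024 starting occupancy.
#' @slot seed Integer stream seed used for kernel draws (NA for unlimited).
#' @export
setClass("DispersalRun",
  representation(speciesId = "character", scenario = "character",
                 mode = "character", years = "integer", tau = "numeric",
                 grid = "GridSpec", suitable = "list", occupied = "list",
                 initial = "matrix", seed = "integer"),
  validity = function(object) {
    if (!object@mode %in% c("limited", "unlimited"))
      return("mode must be 'limited' or 'unlimited'")
    if (length(object@suitable) != length(object@years) ||
        length(object@occupied) != length(object@years))
      return("one suitable and one occupied map per year required")
    for (i in seq_along(object@years)) {
      if (any(object@occupied[[i]] & !object@suitable[[i]]))
        return("occupied cells must be a subset of suitable cells")
    }
    TRUE
  })

#' Paired limited/unlimited area trajectories for one species x scenario
#'
#' @slot speciesId,scenario Character labels.
#' @slot years Integer vector (starting at the 2024 baseline).
#' @slot areaLimited,areaUnlimited Numeric km^2 series.
#' @slot standardizedLimited,standardizedUnlimited Series divided by their
#'   2024 baseline value.
#' @slot proportion Numeric percent series,
#'   \code{100 * areaLimited / areaUnlimited}.
#' @slot trendLimited,trendUnlimited Character trajectory pattern labels.
#' @slot proportionClass Character, one of decreased/unchanged/increased.
#' @export
setClass("ScenarioSeries",
  representation(speciesId = "character", scenario = "character",
                 years = "integer", areaLimited = "numeric",
                 areaUnlimited = "numeric", standardizedLimited = "numeric",
                 standardizedUnlimited = "numeric", proportion = "numeric",
                 trendLimited = "character", trendUnlimited = "character",
                 proportionClass = "character"),
  validity = function(object) {
    n <- length(object@years)
    lens <- c(length(object@areaLimited), length(object@areaUnlimited),
              length(object@proportion))
    if (any(lens != n)) return("series lengths are inconsistent")
    ok <- is.finite(object@proportion)
    if (any(object@proportion[ok] < -1e-9)) return("negative proportion")
    TRUE
  })
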