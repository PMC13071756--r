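# Synthetic study system: climate stacks with a monotone forcing trend and
# AR(1) interannual variability, virtual species with Gaussian niches, and
# occurrence tables carrying the metadata the cleaning filters act on.

#' Parameters for synthetic annual climate stacks
#'
#' Each variable is generated as
#' \code{baseline + gradLat * (lat - latC) + gradLon * (lon - lonC) +
#' trend * multiplier * (year - y0) + anomaly(year)},
#' where the anomaly is a grid-wide AR(1) series with stationary standard
#' deviation \code{noiseSd} (interannual variability shared across the
#' region, the dominant mode of annual climate layers). The scenario
#' multiplier separates a moderate-forcing from a high-forcing pathway.
#'
#' @param grid A \linkS4class{GridSpec}; default a 50 x 50 grid at 0.1
#'   degrees anchored at (100 E, 25 N).
#' @param years Integer years, default 2000:2100.
#' @param variables Named list; each element a list with fields
#'   \code{baseline}, \code{gradLat}, \code{gradLon} (units per degree),
#'   \code{trend} (units per year), \code{noiseSd}, \code{ar1}.
#' @param multipliers Named numeric scenario trend multipliers; the
#'   high-forcing multiplier must be >= the moderate one.
#' @return A list of class \code{"SyntheticClimateParams"}.
#' @export
syntheticClimateParams <- function(
    grid = GridSpec(100, 25, 0.1, 50, 50),
    years = 2000:2100,
    variables = list(
      bio01 = list(baseline = 14,  gradLat = -1.2, gradLon = 0.10,
                   trend = 0.02, noiseSd = 0.25, ar1 = 0.3),
      bio12 = list(baseline = 900, gradLat = -15,  gradLon = 40,
                   trend = -0.8, noiseSd = 25,    ar1 = 0.3),
      bio04 = list(baseline = 650, gradLat = 8,     gradLon = -3,
                   trend = 0.3,  noiseSd = 12,    ar1 = 0.3)),
    multipliers = c("RCP4.5-like" = 1, "RCP8.5-like" = 2)) {
  for (v in variables) {
    stopifnot(v$noiseSd >= 0, abs(v$ar1) < 1)
  }
  stopifnot(length(multipliers) >= 1, all(multipliers >= 0))
  structure(list(grid = grid, years = as.integer(years),
                 variables = variables, multipliers = multipliers),
            class = "SyntheticClimateParams")
}

#' Generate a synthetic annual climate stack
#'
#' Deterministic given \code{(params, scenario, seed)}; the AR(1) anomaly
#' draws depend on the seed but not on the scenario, so stacks generated
#' for two scenarios from the same seed share their weather noise and
#' differ only through the forcing trend.
#'
#' @param params A \code{\link{syntheticClimateParams}} object.
#' @param scenario Scenario name; must match a multiplier name.
#' @param seed Integer seed.
#' @return A \linkS4class{ClimateStack}.
#' @export
makeClimateStack <- function(params, scenario = names(params$multipliers)[1],
                             seed = 1L) {
  stopifnot(inherits(params, "SyntheticClimateParams"))
  if (!scenario %in% names(params$multipliers))
    .stopf("unknown scenario '%s'", scenario)
  mult <- params$multipliers[[scenario]]
  g <- params$grid
  years <- params$years
  y0 <- years[1]
  lonC <- g@lonMin + g@nCols * g@resDeg / 2
  latC <- g@latMin + g@nRows * g@resDeg / 2
  dLat <- gridLats(g) - latC   # length nRows
  dLon <- gridLons(g) - lonC   # length nCols
  layers <- list()
  for (v in names(params$variables)) {
    p <- params$variables[[v]]
    base <- p$baseline + outer(dLat * p$gradLat, dLon * p$gradLon, `+`)
    # grid-wide AR(1) anomaly with stationary SD = noiseSd; seeded per
    # variable (not per scenario) so scenarios share weather draws
    .maybeSeed(deriveSeed(seed, "climate-anomaly", v))
    n <- length(years)
    if (p$noiseSd > 0) {
      innovSd <- p$noiseSd * sqrt(1 - p$ar1^2)
      eps <- numeric(n)
      eps[1] <- stats::rnorm(1, 0, p$noiseSd)
      if (n > 1) {
        z <- stats::rnorm(n - 1, 0, innovSd)
        for (t in 2:n) eps[t] <- p$ar1 * eps[t - 1] + z[t - 1]
      }
    } else eps <- numeric(n)
    for (i in seq_along(years)) {
      layers[[paste0(v, ":", years[i])]] <-
        base + p$trend * mult * (years[i] - y0) + eps[i]
    }
  }
  ClimateStack(g, scenario, years, names(params$variables), layers)
}

#' Create a virtual species
#'
#' @param optima Named numeric niche optima (one per climate variable).
#' @param breadths Named numeric niche breadths (sigma), > 0.
#' @param detectionEffort Sampling-intensity scalar (default 1).
#' @param nativity \code{"native"} (default) or \code{"invasive"}.
#' @return A \linkS4class{VirtualSpecies}.
#' @export
#' @examples
#' virtualSpecies(c(bio01 = 13, bio12 = 950), c(bio01 = 1, bio12 = 60))
virtualSpecies <- function(optima, breadths, detectionEffort = 1,
                           nativity = "native") {
  new("VirtualSpecies", optima = optima, breadths = breadths[names(optima)],
      detectionEffort = detectionEffort, nativity = nativity)
}

#' True suitability of a virtual species
#'
#' Gaussian product niche:
#' \code{s(z) = exp(-sum_j (z_j - mu_j)^2 / (2 sigma_j^2))}, in [0, 1]
#' with 1 exactly at the optimum.
#'
#' @param vs A \linkS4class{VirtualSpecies}.
#' @param env Named numeric vector, or a matrix/data frame with one column
#'   per niche variable.
#' @return Suitability value(s) in [0, 1].
#' @export
trueSuitability <- function(vs, env) {
  vars <- names(vs@optima)
  if (is.null(dim(env))) {
    if (!all(vars %in% names(env)))
      .stopf("env is missing niche variable(s): %s",
             paste(setdiff(vars, names(env)), collapse = ", "))
    env <- matrix(env[vars], nrow = 1, dimnames = list(NULL, vars))
  } else {
    env <- as.matrix(env)
    if (!all(vars %in% colnames(env)))
      .stopf("env is missing niche variable(s): %s",
             paste(setdiff(vars, colnames(env)), collapse = ", "))
    env <- env[, vars, drop = FALSE]
  }
  d2 <- sweep(env, 2, vs@optima[vars])^2
  d2 <- sweep(d2, 2, 2 * vs@breadths[vars]^2, `/`)
  exp(-rowSums(d2))
}

#' True-suitability raster of a virtual species
#'
#' @param vs A \linkS4class{VirtualSpecies}.
#' @param meanLayers Named list of \linkS4class{RasterLayer} (e.g. from
#'   \code{\link{temporalMean}}).
#' @return A \linkS4class{RasterLayer} of suitabilities.
#' @export
trueSuitabilityLayer <- function(vs, meanLayers) {
  vars <- names(vs@optima)
  g <- meanLayers[[1]]@grid
  env <- vapply(vars, function(v) as.vector(meanLayers[[v]]@values),
                numeric(g@nRows * g@nCols))
  mask <- Reduce(`&`, lapply(meanLayers[vars], function(l) l@mask))
  RasterLayer(g, matrix(trueSuitability(vs, env), g@nRows, g@nCols), mask)
}

#' Sample occurrence records of a virtual species
#'
#' Presence cells are drawn with probability proportional to the true
#' suitability of the period-mean climate; coordinates are jittered by a
#' positional error, and each record carries the Darwin-Core-like metadata
#' the cleaning filters act on, drawn from configurable mixtures (so that
#' filter tests have genuinely rejectable material).
#'
#' @param vs A \linkS4class{VirtualSpecies}.
#' @param stack A \linkS4class{ClimateStack}.
#' @param n Number of records (>= 1).
#' @param positionalErrorKm SD of isotropic coordinate jitter in km.
#' @param yearRange Period whose mean climate drives sampling and from
#'   which record years are drawn (default 2000--2024).
#' @param seed Integer seed; the same seed reproduces the same table.
#' @param speciesId Species label written into the table.
#' @param pMissingUncertainty,pLargeUncertainty Probabilities that the
#'   uncertainty field is missing / drawn above 10 km.
#' @param basisProbs Named probabilities over basisOfRecord tokens.
#' @param pOldYear Probability a record's year falls before the period.
#' @param pMissingCoord Probability a record loses its coordinates.
#' @return Data frame with columns species, decimalLongitude,
#'   decimalLatitude, year, coordinateUncertaintyInMeters, basisOfRecord.
#' @export
sampleOccurrences <- function(vs, stack, n, positionalErrorKm = 0,
                              yearRange = c(2000, 2024), seed = 1L,
                              speciesId = "virtual_species",
                              pMissingUncertainty = 0.3,
                              pLargeUncertainty = 0.1,
                              basisProbs = c(HUMAN_OBSERVATION = 0.60,
                                             PRESERVED_SPECIMEN = 0.15,
                                             MACHINE_OBSERVATION = 0.10,
                                             OBSERVATION = 0.05,
                                             FOSSIL_SPECIMEN = 0.05,
                                             LIVING_SPECIMEN = 0.05),
                              pOldYear = 0, pMissingCoord = 0) {
  stopifnot(n >= 1)
  meanLayers <- temporalMean(stack, yearRange)
  suit <- trueSuitabilityLayer(vs, meanLayers)
  w <- as.vector(suit@values) * as.vector(suit@mask)
  if (sum(w) <= 0)
    .stopf("true suitability is identically zero over the valid landscape")
  .maybeSeed(deriveSeed(seed, "occurrences", speciesId))
  cells <- sample.int(length(w), n, replace = TRUE, prob = w)
  cc <- cellCenters(stack@grid)
  lon <- cc[cells, 1]
  lat <- cc[cells, 2]
  if (positionalErrorKm > 0) {
    lat <- lat + stats::rnorm(n, 0, positionalErrorKm / KM_PER_DEG)
    lon <- lon + stats::rnorm(n, 0, positionalErrorKm /
                                   (KM_PER_DEG * cos(pmin(abs(lat), 89) * pi / 180)))
  }
  year <- sample(seq(yearRange[1], yearRange[2]), n, replace = TRUE)
  if (pOldYear > 0) {
    old <- stats::runif(n) < pOldYear
    year[old] <- sample(seq(yearRange[1] - 20, yearRange[1] - 1),
                        sum(old), replace = TRUE)
  }
  unc <- exp(stats::rnorm(n, log(3000), 0.8))
  big <- stats::runif(n) < pLargeUncertainty
  unc[big] <- stats::runif(sum(big), 12000, 60000)
  unc[stats::runif(n) < pMissingUncertainty] <- NA
  basis <- sample(names(basisProbs), n, replace = TRUE, prob = basisProbs)
  if (pMissingCoord > 0) {
    drop <- stats::runif(n) < pMissingCoord
    lon[drop] <- NA; lat[drop] <- NA
  }
  data.frame(species = speciesId, decimalLongitude = lon,
             decimalLatitude = lat, year = year,
             coordinateUncertaintyInMeters = round(unc),
             basisOfRecord = basis, stringsAsFactors = FALSE)
}

#' Synthetic elevation layer
#'
#' Deterministic terrain with a north-south ramp and a ridge, used to
#' exercise the hard elevation bound of montane-limited species.
#'
#' @param grid A \linkS4class{GridSpec}.
#' @param base Elevation (m) at the grid's southern edge.
#' @param rampPerDeg Elevation gain per degree of latitude.
#' @param ridgeHeight,ridgeLon,ridgeWidthDeg Gaussian ridge parameters
#'   (height m, center longitude, width in degrees).
#' @return A \linkS4class{RasterLayer} of elevations in metres.
#' @export
syntheticElevation <- function(grid, base = 500, rampPerDeg = 400,
                               ridgeHeight = 3500,
                               ridgeLon = grid@lonMin + grid@nCols * grid@resDeg / 2,
                               ridgeWidthDeg = grid@nCols * grid@resDeg / 8) {
  lats <- gridLats(grid); lons <- gridLons(grid)
  ramp <- base + rampPerDeg * (lats - grid@latMin)
  ridge <- ridgeHeight * exp(-(lons - ridgeLon)^2 / (2 * ridgeWidthDeg^2))
  RasterLayer(grid, outer(ramp, ridge, `+`))
}
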