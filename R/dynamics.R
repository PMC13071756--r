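# Range dynamics: area series on the sphere, limited/unlimited proportion
# curves, trajectory-pattern classification, and dispersal-class counts.

#' Area of yearly boolean maps
#'
#' Sums the spherical cell areas (latitude-dependent, see
#' \code{\link{cellArea}}) over the TRUE cells of each map, avoiding the
#' spatial bias of counting equally-weighted cells.
#'
#' @param maps A logical matrix, a list of logical matrices, or a
#'   \linkS4class{DispersalRun} (whose occupied maps are used).
#' @param grid The \linkS4class{GridSpec} the maps live on (taken from
#'   the run when one is supplied).
#' @return Numeric vector of areas in km^2 (one per map).
#' @export
areaSeries <- function(maps, grid = NULL) {
  if (is(maps, "DispersalRun")) {
    grid <- maps@grid
    maps <- maps@occupied
  }
  if (is.matrix(maps)) maps <- list(maps)
  rowArea <- cellArea(grid, seq_len(grid@nRows))
  vapply(maps, function(m) sum(rowArea * rowSums(m)), numeric(1))
}

#' Limited-to-unlimited area proportion series
#'
#' \code{100 * limited / unlimited} percent per year. Years with zero
#' unlimited area are flagged \code{NA} (undefined), not dropped.
#'
#' @param limited,unlimited Numeric km^2 series of equal length.
#' @return Numeric percent series with an \code{"undefined"} attribute
#'   marking the flagged years.
#' @export
proportionSeries <- function(limited, unlimited) {
  stopifnot(length(limited) == length(unlimited))
  if (any(limited < 0) || any(unlimited < 0))
    .stopf("areas must be nonnegative")
  out <- ifelse(unlimited > 0, 100 * limited / unlimited, NA_real_)
  attr(out, "undefined") <- which(unlimited == 0)
  out
}

#' Classify an area-trajectory pattern
#'
#' Smooths the series with a centered moving average, then reads the sign
#' sequence of the smoothed first differences (runs shorter than
#' \code{minRun} years merged into their neighbours) and maps it onto the
#' canonical patterns: \code{+} linear-increase, \code{+-+}
#' increase-decrease-increase, \code{-+-} decrease-increase-decrease,
#' \code{-} decrease. A series whose smoothed total relative variation
#' (range over baseline) stays below \code{flatTol} is classified
#' no-change first; sign sequences outside the catalogue return
#' \code{"other"}. Depends only on relative change, so it is invariant to
#' uniform rescaling of the series.
#'
#' @param series Numeric series (>= 10 points).
#' @param window Moving-average window in years (default 10).
#' @param flatTol Relative-variation tolerance for no-change (default 0.10).
#' @param minRun Minimum run length in years before merging (default 5).
#' @return One of \code{"linear-increase"}, \code{"inc-dec-inc"},
#'   \code{"dec-inc-dec"}, \code{"no-change"}, \code{"decrease"},
#'   \code{"other"}.
#' @export
classifyTrend <- function(series, window = 10, flatTol = 0.10, minRun = 5) {
  series <- as.numeric(series)
  if (length(series) < max(10, window))
    .stopf("series shorter than the smoothing window")
  sm <- as.numeric(stats::filter(series, rep(1 / window, window),
                                 sides = 2))
  sm <- sm[!is.na(sm)]
  baseline <- abs(sm[1])
  if (baseline < .Machine$double.eps) baseline <- max(abs(sm), 1e-12)
  if ((max(sm) - min(sm)) / baseline < flatTol) return("no-change")
  d <- diff(sm)
  signs <- sign(d)
  # zero differences continue the previous movement
  for (i in seq_along(signs))
    if (signs[i] == 0) signs[i] <- if (i > 1) signs[i - 1] else 0
  signs <- signs[signs != 0]
  if (!length(signs)) return("no-change")
  r <- rle(signs)
  while (length(r$lengths) > 1 && min(r$lengths) < minRun) {
    i <- which.min(r$lengths)
    j <- if (i == 1) 2 else if (i == length(r$lengths)) i - 1
         else if (r$lengths[i - 1] >= r$lengths[i + 1]) i - 1 else i + 1
    r$values[i] <- r$values[j]
    r <- rle(inverse.rle(r))
  }
  pattern <- paste(ifelse(r$values > 0, "+", "-"), collapse = "")
  switch(pattern,
         "+" = "linear-increase",
         "+-+" = "inc-dec-inc",
         "-+-" = "dec-inc-dec",
         "-" = "decrease",
         "other")
}

#' Classify the change of a proportion series
#'
#' Compares the mean of the last \code{k} years with the mean of the
#' first \code{k}; absolute changes below \code{tolerance} percentage
#' points are \code{"unchanged"}, otherwise the sign of the change
#' decides \code{"decreased"} / \code{"increased"}.
#'
#' @param proportion Numeric percent series (>= 2 points).
#' @param tolerance Percentage-point tolerance (default 5).
#' @param k Averaging span in years (default 5).
#' @return One of \code{"decreased"}, \code{"unchanged"},
#'   \code{"increased"}.
#' @export
classifyProportionChange <- function(proportion, tolerance = 5, k = 5) {
  p <- proportion[is.finite(proportion)]
  if (length(p) < 2) .stopf("need at least 2 defined proportion values")
  k <- min(k, floor(length(p) / 2))
  delta <- mean(utils::tail(p, k)) - mean(utils::head(p, k))
  if (abs(delta) < tolerance) "unchanged"
  else if (delta > 0) "increased" else "decreased"
}

#' Count species per dispersal-capacity class
#'
#' Classes by maximum annual dispersal distance: above 10 km/yr, 2--10
#' km/yr (boundaries inclusive), below 2 km/yr.
#'
#' @param registry Data frame with columns \code{speciesId} and
#'   \code{dMax} (e.g. \code{\link{defaultSpeciesRegistry}()}), or a list
#'   of \linkS4class{SpeciesProfile}.
#' @return List with \code{counts} (named integer vector over
#'   \code{">10"}, \code{"2-10"}, \code{"<2"}) and \code{members} (named
#'   list of species ids).
#' @export
#' @examples
#' classifyDispersalClass(defaultSpeciesRegistry())$counts  # 4, 2, 4
classifyDispersalClass <- function(registry) {
  if (is.list(registry) && !is.data.frame(registry) &&
      all(vapply(registry, is, TRUE, "SpeciesProfile")))
    registry <- data.frame(
      speciesId = vapply(registry, function(p) p@speciesId, ""),
      dMax = vapply(registry, function(p) p@dMax, 0))
  classes <- c(">10", "2-10", "<2")
  if (nrow(registry) == 0) {
    return(list(counts = stats::setNames(integer(3), classes),
                members = stats::setNames(vector("list", 3), classes)))
  }
  cls <- factor(dispersalClass(registry$dMax), levels = classes)
  list(counts = stats::setNames(as.integer(table(cls)), classes),
       members = split(registry$speciesId, cls))
}

#' The ten-species dispersal registry
#'
#' The study system: five resident birds, two amphibians (1 km/yr by
#' taxon convention) and three invasive insects (10--50 km/yr envelope),
#' with maximum annual dispersal distances spanning 0.5--50 km/yr, an
#' elevation bound of 3000 m for the insects, and the initialization
#' buffer multiplier (10x) for the invasives.
#'
#' @return Data frame with columns speciesId, taxon, nativity, dMax,
#'   elevationBound, mInit.
#' @export
defaultSpeciesRegistry <- function() {
  data.frame(
    speciesId = c("Hyla_chinensis", "Rana_kukunoris",
                  "Pomatorhinus_ferruginosus", "Grammatoptila_striata",
                  "Certhia_discolor", "Fulvetta_ludlowi",
                  "Tephrodornis_virgatus", "Cydia_pomonella",
                  "Tuta_absoluta", "Leptinotarsa_decemlineata"),
    taxon = c("amphibian", "amphibian", "bird", "bird", "bird", "bird",
              "bird", "insect", "insect", "insect"),
    nativity = c(rep("native", 7), rep("invasive", 3)),
    dMax = c(1, 1, 0.5, 1.5, 3, 5, 14, 30, 20, 50),
    elevationBound = c(rep(Inf, 7), rep(3000, 3)),
    mInit = c(rep(1, 7), rep(10, 3)),
    stringsAsFactors = FALSE)
}

#' Build the paired limited/unlimited series for one species x scenario
#'
#' Computes km^2 area series for both runs (prepending the 2024 baseline:
#' the limited run's initial occupancy and the unlimited run's current
#' suitable area), standardizes by the 2024 value, forms the percent
#' proportion curve, and classifies the trajectory patterns and the
#' proportion change.
#'
#' @param limitedRun,unlimitedRun \linkS4class{DispersalRun} objects for
#'   the same species, scenario and grid.
#' @param window,flatTol Trend-classification settings (see
#'   \code{\link{classifyTrend}}).
#' @param tolerance Proportion-change tolerance in percentage points.
#' @return A \linkS4class{ScenarioSeries}.
#' @export
scenarioSeries <- function(limitedRun, unlimitedRun, window = 10,
                           flatTol = 0.10, tolerance = 5) {
  stopifnot(identical(limitedRun@years, unlimitedRun@years))
  g <- limitedRun@grid
  years <- c(min(limitedRun@years) - 1L, limitedRun@years)
  aL <- c(areaSeries(limitedRun@initial, g), areaSeries(limitedRun))
  aU <- c(areaSeries(unlimitedRun@initial, g), areaSeries(unlimitedRun))
  baseL <- if (aL[1] > 0) aL[1] else NA_real_
  baseU <- if (aU[1] > 0) aU[1] else NA_real_
  prop <- proportionSeries(aL, aU)
  new("ScenarioSeries", speciesId = limitedRun@speciesId,
      scenario = limitedRun@scenario, years = years,
      areaLimited = aL, areaUnlimited = aU,
      standardizedLimited = aL / baseL, standardizedUnlimited = aU / baseU,
      proportion = as.numeric(prop),
      trendLimited = classifyTrend(aL, window, flatTol),
      trendUnlimited = classifyTrend(aU, window, flatTol),
      proportionClass = classifyProportionChange(prop, tolerance))
}

#' @export
setMethod("show", "ScenarioSeries", function(object) {
  n <- length(object@years)
  cat(sprintf("ScenarioSeries '%s' (%s), %d-%d\n", object@speciesId,
              object@scenario, object@years[1], object@years[n]))
  cat(sprintf("  area limited   %0.0f -> %0.0f km^2 (%s)\n",
              object@areaLimited[1], object@areaLimited[n],
              object@trendLimited))
  cat(sprintf("  area unlimited %0.0f -> %0.0f km^2 (%s)\n",
              object@areaUnlimited[1], object@areaUnlimited[n],
              object@trendUnlimited))
  cat(sprintf("  proportion %0.1f%% -> %0.1f%% (%s)\n",
              object@proportion[1], object@proportion[n],
              object@proportionClass))
})

#' Convert a scenario series to a data frame
#'
#' @param x A \linkS4class{ScenarioSeries}.
#' @param ... Ignored.
#' @return Data frame with one row per year.
#' @export
setMethod("as.data.frame", "ScenarioSeries", function(x, ...) {
  data.frame(speciesId = x@speciesId, scenario = x@scenario,
             year = x@years, areaLimited = x@areaLimited,
             areaUnlimited = x@areaUnlimited,
             standardizedLimited = x@standardizedLimited,
             standardizedUnlimited = x@standardizedUnlimited,
             proportion = x@proportion, stringsAsFactors = FALSE)
})

#' Plot the paired area trajectories and proportion curve
#'
#' Two-panel base-graphics figure: standardized limited (solid) and
#' unlimited (dotted) areas, and the limited/unlimited percent curve with
#' its smoothed trend.
#'
#' @param x A \linkS4class{ScenarioSeries}.
#' @param y Ignored.
#' @param ... Passed to \code{plot}.
#' @export
setMethod("plot", signature(x = "ScenarioSeries", y = "missing"),
  function(x, y, ...) {
    op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    ylim <- range(c(x@standardizedLimited, x@standardizedUnlimited),
                  finite = TRUE)
    plot(x@years, x@standardizedUnlimited, type = "l", lty = 3,
         ylim = ylim, xlab = "year", ylab = "area (2024 = 1)",
         main = paste(x@speciesId, x@scenario), ...)
    graphics::lines(x@years, x@standardizedLimited, lty = 1)
    graphics::legend("topleft", lty = c(1, 3),
                     legend = c("limited", "unlimited"), bty = "n")
    plot(x@years, x@proportion, type = "l", col = "grey60",
         xlab = "year", ylab = "limited / unlimited (%)",
         main = x@proportionClass)
    sm <- stats::filter(x@proportion, rep(0.1, 10), sides = 2)
    graphics::lines(x@years, sm, lwd = 2)
    invisible(NULL)
  })
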