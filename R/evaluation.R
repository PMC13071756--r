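# Model evaluation: TSS-optimal binarization, TSS, Cohen's Kappa, and the
# partial-ROC AUC ratio for presence-background models (background cells
# serve as pseudo-absences).

#' Confusion counts
#'
#' @param TP,FN,TN,FP Nonnegative counts (presences predicted
#'   present/absent, absences predicted absent/present).
#' @return A list of class \code{"ConfusionCounts"}.
#' @export
confusionCounts <- function(TP, FN, TN, FP) {
  stopifnot(TP >= 0, FN >= 0, TN >= 0, FP >= 0)
  structure(list(TP = TP, FN = FN, TN = TN, FP = FP),
            class = "ConfusionCounts")
}

#' True Skill Statistic
#'
#' \code{TSS = sensitivity + specificity - 1}, in [-1, 1]; 0 for a
#' prediction statistically independent of truth.
#'
#' @param c A \code{\link{confusionCounts}} object.
#' @return TSS value.
#' @export
#' @examples
#' tss(confusionCounts(40, 10, 35, 15))  # 0.5
tss <- function(c) {
  if (c$TP + c$FN == 0 || c$TN + c$FP == 0)
    .stopf("TSS undefined: a truth class is empty")
  c$TP / (c$TP + c$FN) + c$TN / (c$TN + c$FP) - 1
}

#' Cohen's Kappa
#'
#' Chance-corrected agreement \code{(p_o - p_e) / (1 - p_e)} with the
#' chance agreement \code{p_e} computed from the marginals. Degenerate
#' marginals (\code{p_e = 1}) return 0 with a warning.
#'
#' @param c A \code{\link{confusionCounts}} object.
#' @return Kappa value in [-1, 1].
#' @export
#' @examples
#' cohenKappa(confusionCounts(45, 5, 45, 5))  # 0.8
cohenKappa <- function(c) {
  n <- c$TP + c$FN + c$TN + c$FP
  if (n < 1) .stopf("Kappa undefined: empty table")
  po <- (c$TP + c$TN) / n
  pe <- ((c$TP + c$FN) * (c$TP + c$FP) + (c$TN + c$FP) * (c$TN + c$FN)) / n^2
  if (abs(1 - pe) < 1e-12) {
    .warnf("degenerate marginals (p_e = 1); Kappa defined as 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

.extractVals <- function(surface, coords) {
  if (is.numeric(surface) && is.null(coords)) return(surface)
  cells <- cellFromLonLat(surface@grid, coords[, 1], coords[, 2])
  if (anyNA(cells)) .stopf("some points fall outside the surface grid")
  as.vector(surface@values)[cells]
}

#' TSS-optimal binarization threshold
#'
#' Scans every unique suitability value observed at the presences and
#' pseudo-absences (prediction positive when suitability >= threshold)
#' and returns the threshold maximizing TSS, ties broken by the smallest
#' threshold.
#'
#' @param presVals Suitability at presences (numeric vector), or a
#'   \linkS4class{RasterLayer} combined with \code{presCoords}.
#' @param bgVals Suitability at background/pseudo-absence points, or
#'   \code{bgCoords} with a surface.
#' @param presCoords,bgCoords Optional (lon, lat) matrices when the first
#'   argument is a surface.
#' @return List with \code{tau}, \code{tss}, \code{sensitivity},
#'   \code{specificity} and \code{kappa} at the optimum.
#' @export
#' @examples
#' optimalThreshold(c(0.9, 0.8), c(0.3, 0.7))  # tau = 0.8, TSS = 1
optimalThreshold <- function(presVals, bgVals, presCoords = NULL,
                             bgCoords = NULL) {
  if (is(presVals, "RasterLayer")) {
    surface <- presVals
    presVals <- .extractVals(surface, presCoords)
    bgVals <- .extractVals(surface, bgCoords)
  }
  if (length(presVals) < 1 || length(bgVals) < 1)
    .stopf("need at least one presence and one background value")
  if (max(c(presVals, bgVals)) == min(c(presVals, bgVals)))
    .stopf("constant suitability surface: no threshold separates anything")
  taus <- sort(unique(c(presVals, bgVals)))
  nP <- length(presVals); nB <- length(bgVals)
  best <- NULL
  for (tau in taus) {
    sens <- sum(presVals >= tau) / nP
    spec <- sum(bgVals < tau) / nB
    score <- sens + spec - 1
    if (is.null(best) || score > best$tss + 1e-12) {
      cc <- confusionCounts(sum(presVals >= tau), sum(presVals < tau),
                            sum(bgVals < tau), sum(bgVals >= tau))
      best <- list(tau = tau, tss = score, sensitivity = sens,
                   specificity = spec,
                   kappa = suppressWarnings(cohenKappa(cc)))
    }
  }
  best
}

#' Partial-ROC AUC ratio
#'
#' Significance test for presence-background predictions following the
#' partial-ROC bootstrap scheme: per iteration, a fraction of the
#' presences is resampled with replacement, the curve of sensitivity
#' (1 - omission) against the proportion of the landscape predicted
#' present is integrated over the low-omission region
#' (sensitivity >= 1 - E), and the area is divided by the area of the
#' random-prediction diagonal over the same region. A mean ratio above 1
#' indicates better-than-random discrimination; the reported p is the
#' proportion of bootstrap ratios <= 1.
#'
#' @param surface A \linkS4class{RasterLayer} suitability surface (or a
#'   numeric vector of landscape suitabilities).
#' @param presences Two-column (lon, lat) matrix of presences (or a
#'   numeric vector of presence suitabilities when \code{surface} is a
#'   vector).
#' @param E Omission tolerance (default 0.05).
#' @param iterations Bootstrap iterations (default 500).
#' @param fraction Presence resampling fraction per iteration (default 0.5).
#' @param seed Integer seed.
#' @return List with \code{meanRatio}, \code{pValue}, and the vector of
#'   bootstrap \code{ratios}.
#' @export
partialAucRatio <- function(surface, presences, E = 0.05, iterations = 500,
                            fraction = 0.5, seed = 1L) {
  if (is(surface, "RasterLayer")) {
    landVals <- as.vector(surface@values)[as.vector(surface@mask)]
    presVals <- .extractVals(surface, as.matrix(presences))
  } else {
    landVals <- surface
    presVals <- presences
  }
  if (length(presVals) < 10) .stopf("need at least 10 presences")
  # pre-sort landscape once; x(t) = proportion of area with suitability >= t
  taus <- sort(unique(landVals))
  landSorted <- sort(landVals)
  nLand <- length(landVals)
  xAll <- 1 - (findInterval(taus, landSorted, left.open = TRUE)) / nLand
  .maybeSeed(seed)
  m <- max(1L, round(fraction * length(presVals)))
  ratios <- vapply(seq_len(iterations), function(i) {
    pv <- sample(presVals, m, replace = TRUE)
    pvSorted <- sort(pv)
    yAll <- 1 - findInterval(taus, pvSorted, left.open = TRUE) / m
    .pAucRatioCurve(xAll, yAll, E)
  }, numeric(1))
  list(meanRatio = mean(ratios, na.rm = TRUE),
       pValue = mean(ratios <= 1, na.rm = TRUE),
       ratios = ratios)
}

# integrate the (proportion-of-area, sensitivity) curve over the region
# sensitivity >= 1 - E and divide by the diagonal's area there
.pAucRatioCurve <- function(x, y, E) {
  # thresholds ascending => x and y descending; orient curve by increasing x
  ord <- order(x)
  x <- c(0, x[ord], 1)
  y <- c(0, y[ord], 1)
  keep <- y >= 1 - E
  if (!any(keep)) return(NA_real_)
  xs <- x[keep]; ys <- y[keep]
  if (length(xs) < 2) return(NA_real_)
  auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  null <- (max(xs)^2 - min(xs)^2) / 2
  if (null <= 0) return(NA_real_)
  auc / null
}
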