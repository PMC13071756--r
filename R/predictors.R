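# Predictor selection: pairwise Pearson screening (|r| < 0.7) in a
# configurable priority order, plus a VIF (< 10) check on the survivors.

#' Pearson correlation matrix of current-period mean layers
#'
#' Computed over the valid cells of the calibration extent. Variables with
#' zero variance are flagged in the \code{"degenerate"} attribute and get
#' NA correlations (they are excluded from selection downstream).
#'
#' @param meanLayers Named list of \linkS4class{RasterLayer}.
#' @param cells Optional integer vector of linear cell indices to evaluate
#'   on; default all jointly valid cells.
#' @return Correlation matrix with a \code{"degenerate"} attribute.
#' @export
pearsonMatrix <- function(meanLayers, cells = NULL) {
  vars <- names(meanLayers)
  mask <- Reduce(`&`, lapply(meanLayers, function(l) l@mask))
  if (is.null(cells)) cells <- which(as.vector(mask))
  if (length(cells) < 3) .stopf("need at least 3 evaluation cells")
  X <- vapply(meanLayers, function(l) as.vector(l@values)[cells],
              numeric(length(cells)))
  sds <- apply(X, 2, stats::sd)
  degenerate <- vars[sds == 0]
  r <- suppressWarnings(stats::cor(X))
  dimnames(r) <- list(vars, vars)
  attr(r, "degenerate") <- degenerate
  r
}

#' Greedy selection of mutually weakly-correlated variables
#'
#' Scans candidates in priority order and accepts a variable iff its
#' absolute correlation with every already-accepted variable is below the
#' threshold. The priority ordering is where biological judgement enters
#' (temperature and precipitation first by default), making the otherwise
#' subjective choice reproducible.
#'
#' @param r Correlation matrix (from \code{\link{pearsonMatrix}}).
#' @param threshold Absolute-correlation threshold, default 0.7.
#' @param priority Character ordering of candidates; defaults to the
#'   matrix's column order.
#' @return Character vector of selected variable names.
#' @export
selectUncorrelated <- function(r, threshold = 0.7, priority = colnames(r)) {
  candidates <- intersect(priority, colnames(r))
  candidates <- setdiff(candidates, attr(r, "degenerate"))
  if (length(candidates) == 0L) .stopf("no candidate variables to select from")
  selected <- character()
  for (v in candidates) {
    if (length(selected) == 0L || all(abs(r[v, selected]) < threshold))
      selected <- c(selected, v)
  }
  selected
}

#' Variance inflation factors of a predictor subset
#'
#' \code{VIF_j = 1 / (1 - R^2_j)} where \code{R^2_j} comes from an
#' ordinary least-squares regression of variable j on the remaining
#' selected variables over valid cells. A warning is issued when any VIF
#' reaches 10; perfect collinearity yields \code{Inf} with a violation
#' flag.
#'
#' @param meanLayers Named list of \linkS4class{RasterLayer}.
#' @param vars Character, selected variable subset.
#' @param cells Optional evaluation cell indices (default all valid).
#' @return Named numeric VIFs with a logical \code{"violation"} attribute.
#' @export
vifCheck <- function(meanLayers, vars, cells = NULL) {
  mask <- Reduce(`&`, lapply(meanLayers[vars], function(l) l@mask))
  if (is.null(cells)) cells <- which(as.vector(mask))
  if (length(cells) < length(vars) + 2)
    .stopf("need at least %d evaluation cells", length(vars) + 2)
  X <- as.data.frame(vapply(meanLayers[vars],
                            function(l) as.vector(l@values)[cells],
                            numeric(length(cells))))
  if (length(vars) < 2) {
    out <- stats::setNames(rep(1, length(vars)), vars)
    attr(out, "violation") <- FALSE
    return(out)
  }
  vif <- vapply(vars, function(v) {
    fit <- stats::lm(stats::reformulate(setdiff(vars, v), response = v),
                     data = X)
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  attr(vif, "violation") <- any(!is.finite(vif) | vif >= 10)
  if (attr(vif, "violation"))
    .warnf("VIF >= 10 for: %s",
           paste(names(vif)[!is.finite(vif) | vif >= 10], collapse = ", "))
  vif
}

#' Full predictor-selection report
#'
#' Runs the correlation screen and the VIF check and bundles the evidence:
#' candidates, correlation matrix, priority ordering used, selected
#' subset, and per-variable VIFs.
#'
#' @param meanLayers Named list of \linkS4class{RasterLayer}.
#' @param priority Priority ordering (default: BIO01 and BIO12 first if
#'   present, then the remaining variables in input order).
#' @param threshold Absolute-correlation threshold.
#' @param cells Optional evaluation cells.
#' @return List of class \code{"SelectionReport"}.
#' @export
selectPredictors <- function(meanLayers, priority = NULL, threshold = 0.7,
                             cells = NULL) {
  vars <- names(meanLayers)
  if (is.null(priority)) {
    lead <- intersect(c("bio01", "BIO01", "bio12", "BIO12"), vars)
    priority <- c(lead, setdiff(vars, lead))
  }
  r <- pearsonMatrix(meanLayers, cells)
  selected <- selectUncorrelated(r, threshold, priority)
  vif <- suppressWarnings(vifCheck(meanLayers, selected, cells))
  structure(list(candidates = vars, correlation = r, priority = priority,
                 threshold = threshold, selected = selected, vif = vif,
                 vifViolation = attr(vif, "violation")),
            class = "SelectionReport")
}

#' @export
print.SelectionReport <- function(x, ...) {
  cat(sprintf("SelectionReport: %d candidates -> %d selected (%s); max VIF %.3g%s\n",
              length(x$candidates), length(x$selected),
              paste(x$selected, collapse = ", "), max(x$vif),
              if (isTRUE(x$vifViolation)) " [VIF violation]" else ""))
  invisible(x)
}
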