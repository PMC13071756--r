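# Feature construction for the presence-background Gibbs model.
# Variables are min-max scaled to [0,1] using calibration bounds; the
# feature classes are linear (the scaled variables), quadratic (their
# squares) and product (all pairwise products), combined as one of
# L, Q, P, LQ, LP, QP, LQP.

#' Calibration scaling bounds of an environment matrix
#'
#' @param env Numeric matrix, one column per variable, rows = cells.
#' @return 2 x nvar matrix with rows \code{min} and \code{max}. Variables
#'   constant over the calibration cells are flagged in the
#'   \code{"constant"} attribute (they carry no information and are
#'   dropped by \code{\link{buildFeatures}} with a warning).
#' @export
featureBounds <- function(env) {
  b <- apply(env, 2, range)
  rownames(b) <- c("min", "max")
  attr(b, "constant") <- colnames(env)[b["max", ] - b["min", ] <= 0]
  b
}

#' Build the model feature matrix
#'
#' @param env Numeric matrix (cells x variables) of raw predictor values.
#' @param fc Feature-class code: one of L, Q, P, LQ, LP, QP, LQP.
#' @param bounds Calibration bounds from \code{\link{featureBounds}}.
#' @param clamp Clamp scaled values to [0, 1] (default TRUE): projection
#'   values outside the calibration range are pinned to the range edge
#'   rather than extrapolated.
#' @return Feature matrix with named columns, ordered L block, then Q,
#'   then P (pairwise products in \code{combn} order).
#' @export
#' @examples
#' env <- cbind(a = runif(10), b = runif(10))
#' ncol(buildFeatures(env, "LQP", featureBounds(env)))  # 2 + 2 + 1
buildFeatures <- function(env, fc, bounds, clamp = TRUE) {
  stopifnot(fc %in% c("L", "Q", "P", "LQ", "LP", "QP", "LQP"))
  env <- as.matrix(env)
  vars <- colnames(bounds)
  const <- attr(bounds, "constant")
  if (length(const)) {
    .warnf("dropping constant variable(s): %s", paste(const, collapse = ", "))
    vars <- setdiff(vars, const)
  }
  # a landscape with no informative variable yields a zero-column matrix,
  # for which the fit degenerates to the uniform maximum-entropy density
  if (length(vars) == 0L)
    return(matrix(numeric(0), nrow = nrow(env), ncol = 0))
  if (!all(vars %in% colnames(env)))
    .stopf("env lacks variable(s): %s",
           paste(setdiff(vars, colnames(env)), collapse = ", "))
  X <- env[, vars, drop = FALSE]
  lo <- bounds["min", vars]; hi <- bounds["max", vars]
  X <- sweep(sweep(X, 2, lo), 2, hi - lo, `/`)
  if (clamp) X[] <- pmin(pmax(X, 0), 1)
  classes <- strsplit(fc, "")[[1]]
  out <- NULL
  if ("L" %in% classes) {
    L <- X; colnames(L) <- paste0("L:", vars)
    out <- cbind(out, L)
  }
  if ("Q" %in% classes) {
    Q <- X^2; colnames(Q) <- paste0("Q:", vars)
    out <- cbind(out, Q)
  }
  if ("P" %in% classes && length(vars) >= 2) {
    pairs <- utils::combn(vars, 2)
    P <- apply(pairs, 2, function(p) X[, p[1]] * X[, p[2]])
    if (is.null(dim(P))) P <- matrix(P, nrow = nrow(X))
    colnames(P) <- apply(pairs, 2, paste, collapse = "*")
    colnames(P) <- paste0("P:", colnames(P))
    out <- cbind(out, P)
  }
  if (is.null(out)) out <- matrix(numeric(0), nrow = nrow(X), ncol = 0)
  out
}
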