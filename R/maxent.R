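# Presence-background Gibbs density (MaxEnt-style), fitted from first
# principles: L1-penalized maximum likelihood over the landscape sample
# (presence + background cells), optimized with an accelerated proximal
# gradient method (FISTA with backtracking and restart). The optimization
# problem is convex, so the fit is deterministic given its inputs.

#' Sample background cells
#'
#' The background size follows the 1\%-of-valid-cells-times-variables
#' rule: \code{n_bg = round(0.01 * n_valid * n_vars)}, capped at the
#' number of valid cells (and floored at 1), sampled uniformly without
#' replacement.
#'
#' @param mask Logical validity matrix (or a \linkS4class{RasterLayer}).
#' @param nVars Number of environmental variables in the model.
#' @param seed Integer seed (deterministic sample for a given seed).
#' @return Sorted integer vector of linear cell indices.
#' @export
sampleBackground <- function(mask, nVars, seed = 1L) {
  if (is(mask, "RasterLayer")) mask <- mask@mask
  valid <- which(as.vector(mask))
  if (length(valid) == 0L) .stopf("no valid cells to sample background from")
  nBg <- min(length(valid), max(1L, round(0.01 * length(valid) * nVars)))
  .maybeSeed(seed)
  sort(sample(valid, nBg, replace = FALSE))
}

#' Small-sample-corrected Akaike information criterion
#'
#' \code{AICc = 2k - 2LL + 2k(k + 1)/(n - k - 1)}; infinite when
#' \code{n <= k + 1}.
#'
#' @param LL Log-likelihood of the presences under the raw density.
#' @param k Number of nonzero coefficients.
#' @param n Number of presence cells.
#' @return AICc value.
#' @export
#' @examples
#' aicc(-100, 5, 50)  # 211.364
aicc <- function(LL, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  2 * k - 2 * LL + 2 * k * (k + 1) / (n - k - 1)
}

.logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# smooth part of the objective (mean scale) and its gradient
.gibbsObjective <- function(beta, Xp, Xl) {
  etaL <- drop(Xl %*% beta)
  lse <- .logSumExp(etaL)
  g <- -mean(drop(Xp %*% beta)) + lse
  p <- exp(etaL - lse)
  grad <- -colMeans(Xp) + drop(crossprod(Xl, p))
  list(value = g, grad = grad)
}

#' Fit the presence-background niche model
#'
#' Maximizes the penalized presence log-likelihood
#' \deqn{\sum_{presences} \log p(x) - RM \sum_f \lambda_f^0 |\beta_f|}
#' where \eqn{p(x) = \exp(\beta \cdot f(x)) / Z} is a Gibbs density over
#' the landscape sample (presence plus background cells) and the default
#' per-feature penalty \eqn{\lambda_f^0 = \sqrt{s_f^2 / n}} (feature
#' variance over presences, floored at 1e-4) shrinks with presence sample
#' size in the spirit of the published MaxEnt defaults.
#'
#' @param presEnv Numeric matrix of raw predictor values at presence
#'   cells (one column per variable, named).
#' @param bgEnv Same for background cells.
#' @param fc Feature-class code (L, Q, P, LQ, LP, QP, LQP).
#' @param rm Regularization multiplier.
#' @param bounds Optional scaling bounds; default
#'   \code{featureBounds(rbind(presEnv, bgEnv))}.
#' @param maxit,tol Optimizer budget and relative-objective tolerance.
#' @return A \linkS4class{NicheModel}; its \code{report} slot carries
#'   LL, k, n, AICc and convergence diagnostics.
#' @export
fitMaxent <- function(presEnv, bgEnv, fc = "LQ", rm = 1, bounds = NULL,
                      maxit = 5000L, tol = 1e-10) {
  presEnv <- as.matrix(presEnv); bgEnv <- as.matrix(bgEnv)
  n <- nrow(presEnv)
  if (n < 5) .stopf("need at least 5 presence cells (got %d)", n)
  if (is.null(bounds)) bounds <- featureBounds(rbind(presEnv, bgEnv))
  Xl <- buildFeatures(rbind(presEnv, bgEnv), fc, bounds)
  Xp <- Xl[seq_len(n), , drop = FALSE]
  d <- ncol(Xp)
  if (d == 0L) {
    beta <- stats::setNames(numeric(0), character(0))
    etaL <- rep(0, nrow(Xl))
  } else {
    # per-feature default penalty, on the mean-log-likelihood scale
    s2 <- apply(Xp, 2, stats::var)
    lambda0 <- pmax(sqrt(s2 / n), 1e-4)
    pen <- rm * lambda0 / n
    beta <- numeric(d)
    y <- beta; tAcc <- 1; L <- 1
    gy <- .gibbsObjective(y, Xp, Xl)
    fCur <- gy$value  # objective at beta = 0 (penalty term is 0 there)
    conv <- FALSE
    it <- 0L
    while (it < maxit) {
      it <- it + 1L
      repeat {  # backtracking on the majorizing step size 1/L
        cand <- y - gy$grad / L
        betaNew <- sign(cand) * pmax(abs(cand) - pen / L, 0)
        gNew <- .gibbsObjective(betaNew, Xp, Xl)
        dlt <- betaNew - y
        if (gNew$value <= gy$value + sum(gy$grad * dlt) +
              L / 2 * sum(dlt^2) + 1e-14) break
        L <- L * 2
      }
      fNew <- gNew$value + sum(pen * abs(betaNew))
      if (fNew > fCur + 1e-14 && any(y != beta)) {
        # acceleration overshot: restart from the last accepted iterate
        # (a prox step from beta itself is guaranteed to descend)
        y <- beta; tAcc <- 1
        gy <- .gibbsObjective(y, Xp, Xl)
        next
      }
      if (it > 5 && abs(fCur - fNew) <= tol * (abs(fCur) + 1e-12)) {
        beta <- betaNew; conv <- TRUE
        break
      }
      tNew <- (1 + sqrt(1 + 4 * tAcc^2)) / 2
      y <- betaNew + (tAcc - 1) / tNew * (betaNew - beta)
      beta <- betaNew; tAcc <- tNew; fCur <- fNew
      gy <- .gibbsObjective(y, Xp, Xl)
      L <- L / 1.5  # let the step size grow back between iterations
    }
    if (!conv)
      .warnf("fitMaxent: optimizer stopped at maxit = %d", maxit)
    names(beta) <- colnames(Xp)
    etaL <- drop(Xl %*% beta)
  }
  lse <- .logSumExp(etaL)
  Z <- exp(lse)
  raw <- exp(etaL - lse)
  H <- -sum(raw * log(pmax(raw, 1e-300)))
  etaP <- if (d == 0L) rep(0, n) else drop(Xp %*% beta)
  LL <- sum(etaP) - n * lse
  k <- sum(abs(beta) > 1e-8)
  report <- list(LL = LL, k = k, n = n, AICc = aicc(LL, k, n),
                 nFeatures = d, converged = if (d == 0L) TRUE else conv)
  new("NicheModel", fc = fc, rm = rm, variables = colnames(bounds),
      bounds = bounds, beta = beta, Z = Z, entropy = H, report = report)
}

#' @export
setMethod("show", "NicheModel", function(object) {
  r <- object@report
  cat(sprintf("NicheModel FC=%s RM=%.1f: %d/%d nonzero features, n=%d, LL=%.3f, AICc=%.3f\n",
              object@fc, object@rm, r$k, r$nFeatures, r$n, r$LL, r$AICc))
})

#' Model coefficients accessor
#' @param object A \linkS4class{NicheModel}.
#' @param ... Ignored.
#' @return Named numeric coefficient vector.
#' @export
setMethod("coef", "NicheModel", function(object, ...) object@beta)

#' Fit report accessor
#' @param model A \linkS4class{NicheModel}.
#' @return List with LL, k, n, AICc, convergence flag (and, after tuning,
#'   the candidate table and block-validation omission).
#' @export
fitReport <- function(model) model@report

#' Assign presences to four spatial validation blocks
#'
#' Geographic quadrants split at the presence-median longitude and
#' latitude; points lying exactly on a median go to the lower block.
#' Deterministic (no RNG).
#'
#' @param coords Two-column matrix (lon, lat) of presence locations.
#' @return Integer vector in 1..4 (1 = SW, 2 = SE, 3 = NW, 4 = NE).
#' @export
spatialBlocks <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 8) .stopf("need at least 8 presences for 4 blocks")
  if (all(coords[, 1] == coords[1, 1]) && all(coords[, 2] == coords[1, 2]))
    .stopf("all presences share one location; blocks are undefined")
  medLon <- stats::median(coords[, 1])
  medLat <- stats::median(coords[, 2])
  as.integer(1L + (coords[, 1] > medLon) + 2L * (coords[, 2] > medLat))
}

#' Project a fitted model onto environment layers
#'
#' Applies the trained min-max scaling (clamped to [0, 1]), evaluates the
#' Gibbs density with the calibration normalizer, and returns the
#' complementary log-log suitability
#' \code{1 - exp(-exp(H) * exp(beta . f(x)) / Z)} in [0, 1]. Cells failing
#' the hard elevation bound are set to zero suitability regardless of
#' climate.
#'
#' @param model A \linkS4class{NicheModel}.
#' @param layers Named list of \linkS4class{RasterLayer} covering the
#'   model's variables (a \linkS4class{ClimateStack} year can be expanded
#'   with \code{\link{getLayer}}).
#' @param elevation Optional elevation \linkS4class{RasterLayer} (metres).
#' @param elevationBound Hard upper bound in metres (default \code{Inf},
#'   i.e. no bound).
#' @return A \linkS4class{RasterLayer} of suitabilities in [0, 1].
#' @export
projectSuitability <- function(model, layers, elevation = NULL,
                               elevationBound = Inf) {
  vars <- model@variables
  if (!all(vars %in% names(layers)))
    .stopf("projection layers missing variable(s): %s",
           paste(setdiff(vars, names(layers)), collapse = ", "))
  g <- layers[[vars[1]]]@grid
  env <- vapply(vars, function(v) as.vector(layers[[v]]@values),
                numeric(g@nRows * g@nCols))
  colnames(env) <- vars
  X <- buildFeatures(env, model@fc, model@bounds, clamp = TRUE)
  eta <- if (ncol(X) == 0L) rep(0, nrow(env)) else drop(X %*% model@beta)
  suit <- 1 - exp(-exp(model@entropy) * exp(eta) / model@Z)
  mask <- Reduce(`&`, lapply(layers[vars], function(l) l@mask))
  if (!is.null(elevation) && is.finite(elevationBound)) {
    tooHigh <- elevation@values > elevationBound & elevation@mask
    suit[as.vector(tooHigh)] <- 0
  }
  RasterLayer(g, matrix(suit, g@nRows, g@nCols), mask)
}

.FC_ORDER <- c("L", "Q", "P", "LQ", "LP", "QP", "LQP")

#' Tune feature class and regularization multiplier by AICc
#'
#' Fits every candidate in the FC x RM grid (7 feature-class combinations
#' by default, RM from 1 to 3 in steps of 0.5, i.e. 35 candidates) and
#' selects the minimum-AICc model (\code{dAICc = 0}). Ties are broken by
#' fewer nonzero coefficients, then by simpler feature class in the order
#' L < Q < P < LQ < LP < QP < LQP, then by smaller RM. When presence
#' coordinates are supplied, 4-fold spatial-block omission is reported for
#' the winner.
#'
#' @param presEnv,bgEnv Raw environment matrices as in
#'   \code{\link{fitMaxent}}.
#' @param fcGrid,rmGrid Candidate feature classes and multipliers.
#' @param presCoords Optional two-column (lon, lat) matrix for block
#'   validation of the winning candidate.
#' @return The winning \linkS4class{NicheModel}; its report gains a
#'   \code{candidates} data frame (fc, rm, LL, k, AICc, dAICc) and, if
#'   coordinates were given, \code{blockOmission}.
#' @export
tuneModel <- function(presEnv, bgEnv, fcGrid = .FC_ORDER,
                      rmGrid = seq(1, 3, by = 0.5), presCoords = NULL) {
  grid <- expand.grid(fc = fcGrid, rm = rmGrid, stringsAsFactors = FALSE)
  if (nrow(grid) < 1) .stopf("empty candidate grid")
  bounds <- featureBounds(rbind(as.matrix(presEnv), as.matrix(bgEnv)))
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid)))
    fits[[i]] <- fitMaxent(presEnv, bgEnv, grid$fc[i], grid$rm[i], bounds)
  tab <- data.frame(fc = grid$fc, rm = grid$rm,
                    LL = vapply(fits, function(f) f@report$LL, 0),
                    k = vapply(fits, function(f) f@report$k, 0),
                    AICc = vapply(fits, function(f) f@report$AICc, 0))
  if (all(!is.finite(tab$AICc)))
    .stopf("no candidate has finite AICc; more presences are needed")
  tab$dAICc <- tab$AICc - min(tab$AICc)
  ord <- order(tab$AICc, tab$k, match(tab$fc, .FC_ORDER), tab$rm)
  best <- fits[[ord[1]]]
  best@report$candidates <- tab
  if (!is.null(presCoords) && nrow(as.matrix(presCoords)) >= 8)
    best@report$blockOmission <-
      .blockOmission(presEnv, bgEnv, best@fc, best@rm, bounds, presCoords)
  best
}

# mean held-out omission rate over the 4 spatial blocks, at the
# TSS-optimal threshold fitted on the training folds
.blockOmission <- function(presEnv, bgEnv, fc, rm, bounds, coords) {
  blocks <- spatialBlocks(coords)
  omission <- rep(NA_real_, 4)
  for (b in sort(unique(blocks))) {
    train <- presEnv[blocks != b, , drop = FALSE]
    test <- presEnv[blocks == b, , drop = FALSE]
    if (nrow(train) < 5 || nrow(test) < 1) next
    fit <- fitMaxent(train, bgEnv, fc, rm, bounds)
    sTrain <- .suitabilityAt(fit, train)
    sBg <- .suitabilityAt(fit, bgEnv)
    tau <- optimalThreshold(sTrain, sBg)$tau
    omission[b] <- mean(.suitabilityAt(fit, test) < tau)
  }
  mean(omission, na.rm = TRUE)
}

# cloglog suitability at arbitrary raw environment rows
.suitabilityAt <- function(model, env) {
  X <- buildFeatures(as.matrix(env), model@fc, model@bounds, clamp = TRUE)
  eta <- if (ncol(X) == 0L) rep(0, nrow(as.matrix(env))) else drop(X %*% model@beta)
  1 - exp(-exp(model@entropy) * exp(eta) / model@Z)
}

#' Serialize / restore a fitted model as JSON
#'
#' @param model A \linkS4class{NicheModel}.
#' @param path JSON file path.
#' @return \code{readNicheModel} returns the restored model.
#' @export
writeNicheModel <- function(model, path) {
  obj <- list(fc = model@fc, rm = model@rm, variables = model@variables,
              bounds = model@bounds, beta = as.list(model@beta),
              Z = model@Z, entropy = model@entropy,
              report = model@report[c("LL", "k", "n", "AICc")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeNicheModel
#' @export
readNicheModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bounds <- as.matrix(obj$bounds)
  rownames(bounds) <- c("min", "max"); colnames(bounds) <- obj$variables
  attr(bounds, "constant") <- character(0)
  new("NicheModel", fc = obj$fc, rm = obj$rm, variables = obj$variables,
      bounds = bounds, beta = unlist(obj$beta), Z = obj$Z,
      entropy = obj$entropy, report = as.list(obj$report))
}
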