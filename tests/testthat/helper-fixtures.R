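# Shared fixture builders and independent oracles used across test files.

# small grid anchored near 25N (the synthetic study window's latitude)
toyGrid <- function(n = 10, res = 0.1, lon0 = 100, lat0 = 25) {
  GridSpec(lon0, lat0, res, n, n)
}

# climate stack with one linear-gradient variable and optional trend/noise
toyStack <- function(grid = toyGrid(), years = 2000:2010, trend = 0,
                     noiseSd = 0, seed = 1, baseline = 10, gradLat = 1) {
  params <- syntheticClimateParams(
    grid = grid, years = years,
    variables = list(env = list(baseline = baseline, gradLat = gradLat,
                                gradLon = 0, trend = trend,
                                noiseSd = noiseSd, ar1 = 0)),
    multipliers = c(only = 1))
  makeClimateStack(params, "only", seed = seed)
}

# numeric integration of R^2 * cos(phi) over a cell: independent area oracle
areaOracle <- function(lat0, lat1, dLonDeg, nSteps = 2000) {
  R <- 6371
  phi <- seq(lat0, lat1, length.out = nSteps + 1) * pi / 180
  f <- cos(phi)
  dphi <- diff(phi)[1]
  integral <- sum((f[-1] + f[-length(f)]) / 2) * dphi
  R^2 * (dLonDeg * pi / 180) * integral
}

# rank-based AUC (Mann-Whitney), independent of any package code
aucOracle <- function(pos, neg) {
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# brute-force point-in-convex-polygon rasterization oracle
hullOracle <- function(vertices, grid) {
  h <- grDevices::chull(vertices[, 1], vertices[, 2])
  poly <- vertices[h, , drop = FALSE]
  cc <- cellCenters(grid)
  inside <- vapply(seq_len(nrow(cc)), function(i) {
    pointInPoly(cc[i, 1], cc[i, 2], poly)
  }, logical(1))
  which(inside)
}

# ray casting with on-boundary acceptance
pointInPoly <- function(x, y, poly, eps = 1e-12) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # boundary test
    d <- abs((xj - xi) * (y - yi) - (yj - yi) * (x - xi))
    if (d < eps * max(1, abs(xj - xi) + abs(yj - yi)) &&
        x >= min(xi, xj) - eps && x <= max(xi, xj) + eps &&
        y >= min(yi, yj) - eps && y <= max(yi, yj) + eps) return(TRUE)
    if ((yi > y) != (yj > y) &&
        x < (xj - xi) * (y - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

# raw occurrence table exercising every filter rule
rawOccFixture <- function() {
  data.frame(
    species = "sp",
    decimalLongitude = c(100.05, 100.15, 100.25, 100.35, 100.45, NA,
                         100.65, 100.05, 100.06),
    decimalLatitude = c(25.05, 25.15, 25.25, 25.35, 25.45, 25.55,
                        25.65, 25.04, 25.06),
    year = c(2010, 1998, 2010, 2010, NA, 2010, 2024, 2010, 2012),
    coordinateUncertaintyInMeters = c(NA, 5000, 25000, 5000, 5000, 5000,
                                      NA, 100, 100),
    basisOfRecord = c("HUMAN_OBSERVATION", "HUMAN_OBSERVATION",
                      "HUMAN_OBSERVATION", "FOSSIL_SPECIMEN",
                      "OBSERVATION", "PRESERVED_SPECIMEN",
                      "MACHINE_OBSERVATION", "OBSERVATION",
                      "PRESERVED_SPECIMEN"),
    stringsAsFactors = FALSE)
}

# environment matrices for a toy presence-background fit: presences sit at
# high values of the first variable
toyFitData <- function(nPres = 50, nBg = 200, seed = 1) {
  set.seed(seed)
  bg <- cbind(a = runif(nBg), b = runif(nBg))
  pres <- cbind(a = runif(nPres, 0.7, 1), b = runif(nPres))
  list(pres = pres, bg = bg)
}

# small end-to-end run fixture: stack + model + thinned occurrences
runFixture <- function(n = 30, res = 0.01, dMax = 5, years = 2025:2034,
                       seed = 17) {
  g <- toyGrid(n = n, res = res)
  st <- toyStack(g, years = 2000:max(years), trend = 0.002, noiseSd = 0.05,
                 seed = seed, gradLat = 6)
  vs <- virtualSpecies(c(env = 10.9), c(env = 0.35))
  occ <- sampleOccurrences(vs, st, 150, seed = seed)
  th <- thinToGrid(filterRecords(occ), g)
  ml <- temporalMean(st, c(2000, 2024))
  cells <- th@records$cell
  env <- cbind(env = as.vector(ml$env@values))
  bg <- sampleBackground(st@mask, 1, seed = seed + 1)
  model <- fitMaxent(env[cells, , drop = FALSE], env[bg, , drop = FALSE],
                     fc = "LQ", rm = 1)
  tau <- optimalThreshold(as.vector(projectSuitability(model, ml)@values)[cells],
                          as.vector(projectSuitability(model, ml)@values)[bg])$tau
  list(grid = g, stack = st, occ = th, model = model, tau = tau,
       profile = speciesProfile("toy", dMax), years = years)
}

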