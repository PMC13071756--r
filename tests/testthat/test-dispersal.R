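test_that("kernel draws respect truncation and the closed-form mean", {
  k <- dispersalKernel(10)
  d <- sampleKernel(k, 100000, seed = 7)
  expect_true(all(d >= 0 & d <= 10))
  # closed-form mean of Exp(3/dMax) truncated at dMax
  lam <- 3 / 10
  mTheory <- 1 / lam - 10 * exp(-lam * 10) / (1 - exp(-lam * 10))
  expect_equal(mTheory, 0.2809 * 10, tolerance = 1e-3)
  mcSE <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - mTheory), 3 * mcSE)
  # zero-capacity kernel yields zero distances
  expect_equal(sampleKernel(dispersalKernel(0), 10), rep(0, 10))
  # determinism
  expect_identical(d, sampleKernel(k, 100000, seed = 7))
})

test_that("the simulation grid refines when dispersal is sub-cell", {
  base <- toyGrid(n = 10, res = 0.1)   # ~11.1 km cells
  pFast <- speciesProfile("fast", 50)
  expect_identical(simulationGrid(pFast, base), base)
  pSlow <- speciesProfile("slow", 1, taxon = "amphibian")
  fine <- simulationGrid(pSlow, base)
  f <- ceiling(cellSizeKm(base) / 1)
  expect_equal(fine@resDeg, base@resDeg / f)
  expect_equal(fine@nCols, base@nCols * f)
  expect_lte(cellSizeKm(fine), 1)
  # d_max = 0 leaves the grid unchanged (no-dispersal mode)
  expect_identical(simulationGrid(speciesProfile("none", 0), base), base)
})

test_that("dispersal buffers are bounded hulls containing their source", {
  g <- toyGrid(n = 21, res = 0.01)  # ~1.1 km cells
  center <- cellFromLonLat(g, 100.105, 25.105)
  # zero distance: buffer is the source cell alone
  expect_equal(disperseFrom(center, dispersalKernel(0), g), center)
  # every buffer cell center lies within dMax of the source center
  k <- dispersalKernel(5)
  cc <- cellCenters(g)
  for (seed in 1:10) {
    buf <- disperseFrom(center, k, g, seed = seed)
    expect_true(center %in% buf)
    d <- geosphere::distHaversine(cc[center, ], cc[buf, , drop = FALSE],
                                  r = 6371000) / 1000
    expect_true(all(d <= 5 * 1.05))  # 5% slack for cell discretization
  }
  # forced symmetric distances: buffer equals the rasterized diamond hull
  two <- 2 * cellSizeKm(g)
  buf <- disperseFrom(center, k, g, distances = rep(two, 4))
  dLonDeg <- 2 * g@resDeg / cos(25.105 * pi / 180)
  verts <- rbind(c(100.105, 25.105 + 2 * g@resDeg),
                 c(100.105 + dLonDeg, 25.105),
                 c(100.105, 25.105 - 2 * g@resDeg),
                 c(100.105 - dLonDeg, 25.105))
  oracle <- union(hullOracle(verts, g), center)
  expect_setequal(buf, oracle)
  expect_error(disperseFrom(10000, k, g), "outside")
})

test_that("initial ranges honour the reach rule for natives and invasives", {
  g <- toyGrid(n = 10, res = 0.1)
  suitable <- matrix(TRUE, 10, 10)
  occ <- data.frame(decimalLongitude = 100.05, decimalLatitude = 25.05)
  native <- speciesProfile("n", 5)            # reach 5 km
  invasive <- speciesProfile("i", 5, nativity = "invasive")  # reach 50 km
  occN <- initialRange(occ, suitable, native, g)
  occI <- initialRange(occ, suitable, invasive, g)
  # brute-force distance oracle
  cc <- cellCenters(g)
  d <- geosphere::distHaversine(c(100.05, 25.05), cc, r = 6371000) / 1000
  expect_identical(as.vector(occN), d <= 5)
  expect_identical(as.vector(occI), d <= 50)
  # a suitable cell at more than mInit * dMax from every occurrence is
  # excluded even for the invasive rule
  far <- which(d > 50)
  expect_true(length(far) > 0 && !any(occI[far]))
  # suitable everywhere, occurrences everywhere: all suitable occupied
  many <- data.frame(decimalLongitude = cc[, 1], decimalLatitude = cc[, 2])
  expect_true(all(initialRange(many, suitable, native, g)))
  # nothing suitable in reach: empty with warning
  none <- matrix(FALSE, 10, 10)
  expect_warning(empty <- initialRange(occ, none, native, g), "empty")
  expect_false(any(empty))
})

test_that("annual steps intersect, contain, and never teleport", {
  g <- toyGrid(n = 15, res = 0.01)
  suitable <- matrix(TRUE, 15, 15)
  occupied <- matrix(FALSE, 15, 15); occupied[8, 8] <- TRUE
  k <- dispersalKernel(2)

  # d_max = 0 reduces the step to intersection with suitability
  k0 <- dispersalKernel(0)
  suit2 <- matrix(FALSE, 15, 15); suit2[8, 8] <- TRUE; suit2[1, 1] <- TRUE
  expect_identical(stepDispersal(occupied, suit2, k0, g, 1),
                   occupied & suit2)

  # occupied_t is always within suitable_t, and new cells lie within
  # f * dMax of a previously occupied cell (no teleportation)
  state <- occupied
  cc <- cellCenters(g)
  for (t in 1:5) {
    nxt <- stepDispersal(state, suitable, k, g, seedBase = 100 + t)
    expect_true(all(nxt[!suitable] == FALSE))
    newCells <- which(nxt & !state)
    if (length(newCells)) {
      dOld <- vapply(newCells, function(cell) {
        min(geosphere::distHaversine(cc[cell, ],
                                     cc[which(state), , drop = FALSE],
                                     r = 6371000)) / 1000
      }, 0)
      # buffers always include the cells containing the hull vertices, so
      # a new center can exceed dMax by up to one cell diagonal
      expect_true(all(dOld <= 2 + cellSizeKm(g) * sqrt(2)))
    }
    expect_true(all(nxt[state & suitable]))  # still-suitable cells persist
    state <- nxt
  }

  # frontier-only optimization: always a subset of the full step (same
  # per-cell draws), and exactly equal when draws cannot escape the
  # interior (dMax at most one cell size)
  occ2 <- matrix(FALSE, 15, 15); occ2[6:10, 6:10] <- TRUE
  full2 <- stepDispersal(occ2, suitable, k, g, seedBase = 55)
  front2 <- stepDispersal(occ2, suitable, k, g, seedBase = 55,
                          frontierOnly = TRUE)
  expect_true(all(front2 <= full2))
  k1 <- dispersalKernel(1)
  expect_identical(stepDispersal(occ2, suitable, k1, g, seedBase = 56),
                   stepDispersal(occ2, suitable, k1, g, seedBase = 56,
                                 frontierOnly = TRUE))

  expect_error(stepDispersal(occupied[1:3, ], suitable, k, g, 1),
               "do not match")
})

test_that("occupancy is monotone in dispersal capacity (common draws)", {
  g <- toyGrid(n = 15, res = 0.01)
  suitable <- matrix(TRUE, 15, 15)
  start <- matrix(FALSE, 15, 15); start[8, 8] <- TRUE
  counts <- sapply(c(0.5, 1, 2, 4), function(dMax) {
    k <- dispersalKernel(dMax)
    state <- start
    for (t in 1:4) state <- stepDispersal(state, suitable, k, g,
                                          seedBase = 900 + t)
    sum(state)
  })
  expect_true(all(diff(counts) >= 0))
})
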