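test_that("cell areas match the spherical closed form and its oracle", {
  g <- GridSpec(0, -0.05, 0.1, 1, 1)  # 0.1 deg cell centered on the equator
  expect_equal(cellArea(g, 1), 123.6, tolerance = 0.1 / 123.6)
  expect_equal(cellArea(g, 1), areaOracle(-0.05, 0.05, 0.1),
               tolerance = 1e-8)

  # polar cell of the same angular size is smaller than the equatorial one
  gp <- GridSpec(0, 89.9, 0.1, 1, 1)
  expect_lt(cellArea(gp, 1), cellArea(g, 1))

  # whole-sphere conservation
  gs <- GridSpec(-180, -90, 1, 360, 180)
  total <- sum(cellArea(gs, seq_len(gs@nRows))) * gs@nCols
  expect_equal(total, 4 * pi * 6371^2, tolerance = 1e-6)

  # bounding-box conservation on an arbitrary grid
  g2 <- toyGrid(n = 17, res = 0.23, lat0 = 41.3)
  total2 <- sum(cellArea(g2, seq_len(g2@nRows))) * g2@nCols
  lat1 <- g2@latMin + g2@nRows * g2@resDeg
  box <- 6371^2 * (g2@nCols * g2@resDeg * pi / 180) *
    (sin(lat1 * pi / 180) - sin(g2@latMin * pi / 180))
  expect_equal(total2, box, tolerance = 1e-9)

  expect_error(cellArea(g, 2), "out of range")
})

test_that("temporal means collapse year ranges correctly", {
  g <- toyGrid(n = 5)
  # constant layers across years: mean equals the constant layer
  st <- toyStack(g, years = 2000:2004)
  m <- temporalMean(st, c(2000, 2004))
  expect_equal(m$env@values, st@layers[["env:2000"]])

  # two-year stack with values 1 and 3 in a cell -> 2
  layers <- list("v:2000" = matrix(1, 5, 5), "v:2001" = matrix(3, 5, 5))
  st2 <- ClimateStack(g, "s", 2000:2001, "v", layers)
  expect_equal(temporalMean(st2, c(2000, 2001))$v@values[1, 1], 2)

  # linear-trend stack: mean over the period equals the midpoint-year layer
  st3 <- toyStack(g, years = 2000:2010, trend = 0.5)
  m3 <- temporalMean(st3, c(2000, 2010))
  expect_equal(m3$env@values, st3@layers[["env:2005"]], tolerance = 1e-12)

  expect_error(temporalMean(st3, c(1980, 1990)), "does not intersect")
})

test_that("nearest-neighbour resampling preserves structure", {
  g <- toyGrid(n = 4)
  vals <- matrix(runif(16), 4, 4)
  lay <- RasterLayer(g, vals)
  expect_equal(resampleLayer(lay, g@resDeg)@values, vals)

  # refining a uniform layer stays uniform
  u <- RasterLayer(g, matrix(7, 4, 4))
  fine <- resampleLayer(u, g@resDeg / 2)
  expect_true(all(fine@values == 7))
  expect_equal(dim(fine@values), c(8L, 8L))

  # checkerboard refined by 2: each source cell becomes a 2x2 block
  cb <- RasterLayer(g, outer(1:4, 1:4, function(r, c) (r + c) %% 2))
  fine2 <- resampleLayer(cb, g@resDeg / 2)
  for (r in 1:4) for (cc in 1:4)
    expect_true(all(fine2@values[(2 * r - 1):(2 * r),
                                 (2 * cc - 1):(2 * cc)] ==
                      cb@values[r, cc]))

  # integer refine then coarsen back reproduces the original exactly
  back <- resampleLayer(resampleLayer(lay, g@resDeg / 3), g@resDeg)
  expect_identical(back@values, vals)
})

test_that("convex hulls rasterize to the cells the brute-force oracle finds", {
  g <- toyGrid(n = 5, res = 1, lon0 = 0, lat0 = 0)
  # hull equal to one full cell's corners -> that cell
  one <- rasterizeHull(rbind(c(2, 2), c(3, 2), c(3, 3), c(2, 3)), g)
  expect_true(cellFromLonLat(g, 2.5, 2.5) %in% one)

  # square spanning 3x3 cell centers -> 9 cells, matching the oracle
  sq <- rbind(c(0.5, 0.5), c(2.5, 0.5), c(2.5, 2.5), c(0.5, 2.5))
  got <- rasterizeHull(sq, g)
  expect_length(got, 9)
  expect_setequal(got, hullOracle(sq, g))

  # random triangles agree with the oracle
  set.seed(42)
  for (i in 1:20) {
    tri <- cbind(runif(3, 0, 5), runif(3, 0, 5))
    expect_setequal(rasterizeHull(tri, g), union(hullOracle(tri, g),
                    cellFromLonLat(g, tri[, 1], tri[, 2])))
  }

  # all vertices identical -> the single containing cell
  expect_equal(rasterizeHull(rbind(c(1.5, 1.5), c(1.5, 1.5), c(1.5, 1.5)), g),
               cellFromLonLat(g, 1.5, 1.5))

  # collinear points degrade to the cells along the segment
  seg <- rasterizeHull(rbind(c(0.5, 0.5), c(4.5, 0.5), c(2.5, 0.5)), g)
  expect_setequal(seg, cellFromLonLat(g, c(0.5, 1.5, 2.5, 3.5, 4.5),
                                      rep(0.5, 5)))

  # invariance under vertex reordering
  set.seed(7)
  pts <- cbind(runif(6, 0, 5), runif(6, 0, 5))
  a <- rasterizeHull(pts, g)
  b <- rasterizeHull(pts[sample(6), ], g)
  expect_identical(a, b)
})

test_that("ascii grid round trip preserves layers including nodata", {
  g <- toyGrid(n = 6)
  vals <- matrix(rnorm(36), 6, 6)
  mask <- matrix(TRUE, 6, 6); mask[2, 3] <- FALSE
  lay <- RasterLayer(g, vals, mask)
  path <- tempfile(fileext = ".asc")
  writeAsciiGrid(lay, path, digits = 15)
  back <- readAsciiGrid(path)
  expect_equal(back@values[mask], lay@values[mask], tolerance = 1e-12)
  expect_identical(back@mask, mask)
  expect_equal(back@grid@resDeg, g@resDeg)
  unlink(path)
})
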