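test_that("feature construction scales, combines and counts correctly", {
  env <- cbind(a = c(0, 5, 10), b = c(100, 150, 200))
  b <- featureBounds(env)
  X <- buildFeatures(env, "LQP", b)
  expect_equal(ncol(X), 2 + 2 + 1)
  expect_equal(colnames(X), c("L:a", "L:b", "Q:a", "Q:b", "P:a*b"))
  # value at the calibration minimum scales to 0
  expect_equal(unname(X[1, "L:a"]), 0)
  expect_equal(unname(X[3, "L:a"]), 1)
  expect_equal(unname(X[2, "Q:a"]), 0.25)
  expect_equal(unname(X[2, "P:a*b"]), 0.25)
  # FC = L on 3 variables: identity up to scaling
  env3 <- cbind(a = 1:4, b = 5:8, c = 9:12)
  expect_equal(ncol(buildFeatures(env3, "L", featureBounds(env3))), 3)
  # clamping pins out-of-range projection values
  Xc <- buildFeatures(cbind(a = 20, b = 0), "L", b)
  expect_equal(unname(Xc[1, ]), c(1, 0))
  # constant variable is dropped with a warning
  envC <- cbind(a = 1:5, k = rep(2, 5))
  expect_warning(Xd <- buildFeatures(envC, "L", featureBounds(envC)),
                 "constant")
  expect_equal(colnames(Xd), "L:a")
})

test_that("background sampling follows the 1% rule deterministically", {
  mask <- matrix(TRUE, 100, 100)
  bg <- sampleBackground(mask, 4, seed = 1)
  expect_length(bg, 400)        # round(0.01 * 10000 * 4)
  expect_identical(bg, sampleBackground(mask, 4, seed = 1))
  expect_false(identical(bg, sampleBackground(mask, 4, seed = 2)))
  # cap at the number of valid cells
  tiny <- matrix(TRUE, 2, 2)
  expect_length(sampleBackground(tiny, 200, seed = 1), 4)
  expect_true(all(sampleBackground(tiny, 200, seed = 1) %in% 1:4))
})

test_that("AICc matches formula arithmetic and drives tie-breaking", {
  expect_equal(aicc(-100, 5, 50), 211.364, tolerance = 0.001 / 211)
  expect_equal(aicc(-50, 0, 20), 100)
  expect_true(is.infinite(aicc(-10, 5, 6)))
  # equal LL, k = 3 vs k = 5 at n = 50: the smaller model wins
  expect_lt(aicc(-100, 3, 50), aicc(-100, 5, 50))
})

test_that("the Gibbs fit honours maximum-entropy limits and sign logic", {
  # uniform environment: raw density uniform, no informative coefficients
  env <- cbind(a = rep(3, 60))
  expect_warning(m <- fitMaxent(env[1:10, , drop = FALSE],
                                env[11:60, , drop = FALSE], fc = "L"),
                 "constant")
  expect_length(coef(m), 0)
  expect_equal(m@Z, 60)  # sum over landscape of exp(0)
  expect_equal(fitReport(m)$k, 0)

  # presences at high values of one variable, FC = L: positive coefficient,
  # sign confirmed by a coarse brute-force grid search over beta
  d <- toyFitData(seed = 2)
  m2 <- fitMaxent(d$pres, d$bg, fc = "L", rm = 1)
  expect_gt(coef(m2)["L:a"], 0)
  bounds <- featureBounds(rbind(d$pres, d$bg))
  Xp <- buildFeatures(d$pres, "L", bounds)
  Xl <- buildFeatures(rbind(d$pres, d$bg), "L", bounds)
  gridLL <- function(b1) {
    eta <- Xl[, "L:a"] * b1
    sum(Xp[, "L:a"] * b1) - nrow(Xp) * log(sum(exp(eta)))
  }
  cand <- seq(-10, 10, by = 0.5)
  expect_gt(cand[which.max(vapply(cand, gridLL, 0))], 0)

  # landscape raw density always normalizes to 1
  Xall <- buildFeatures(rbind(d$pres, d$bg), "LQ", bounds)
  m3 <- fitMaxent(d$pres, d$bg, fc = "LQ", rm = 1)
  Xl3 <- buildFeatures(rbind(d$pres, d$bg), "LQ", m3@bounds)
  raw <- exp(drop(Xl3 %*% coef(m3))) / m3@Z
  expect_equal(sum(raw), 1, tolerance = 1e-8)

  expect_error(fitMaxent(d$pres[1:3, ], d$bg), "at least 5")
})

test_that("nonzero-coefficient count is non-increasing in RM", {
  for (seed in 1:5) {
    d <- toyFitData(nPres = 30, nBg = 120, seed = seed)
    ks <- vapply(seq(1, 3, by = 0.5), function(rm)
      fitReport(fitMaxent(d$pres, d$bg, fc = "LQP", rm = rm))$k, 0)
    expect_true(all(diff(ks) <= 0),
                info = sprintf("seed %d: k = %s", seed,
                               paste(ks, collapse = ",")))
  }
})

test_that("tuning selects by AICc with deterministic tie-breaking", {
  d <- toyFitData(seed = 3)
  # candidate set of one returns that model
  one <- tuneModel(d$pres, d$bg, fcGrid = "L", rmGrid = 1)
  expect_equal(one@fc, "L")
  expect_equal(one@rm, 1)
  # the winner attains the minimum AICc of its candidate table
  best <- tuneModel(d$pres, d$bg, fcGrid = c("L", "LQ"), rmGrid = c(1, 2))
  tab <- fitReport(best)$candidates
  expect_equal(nrow(tab), 4)
  expect_equal(min(tab$dAICc), 0)
  expect_equal(fitReport(best)$AICc, min(tab$AICc))
})

test_that("spatial blocks split presences into geographic quadrants", {
  corners <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  pts <- corners[rep(1:4, each = 2), ]
  blocks <- spatialBlocks(pts)
  expect_setequal(unique(blocks), 1:4)
  expect_equal(unname(table(blocks)), rep(2L, 4), ignore_attr = TRUE)
  # deterministic: no RNG involved
  expect_identical(blocks, spatialBlocks(pts))
  # each side of either median split is balanced up to ties (oracle:
  # brute-force partition by the medians)
  set.seed(13)
  pts2 <- cbind(runif(40), runif(40))
  b2 <- spatialBlocks(pts2)
  expect_equal(sum(b2 %in% c(2, 4)), sum(pts2[, 1] > median(pts2[, 1])))
  expect_equal(sum(b2 %in% c(3, 4)), sum(pts2[, 2] > median(pts2[, 2])))
  expect_length(b2, 40)  # every presence in exactly one block
  expect_error(spatialBlocks(matrix(1, 10, 2)), "share one location")
  expect_error(spatialBlocks(corners), "at least 8")
})

test_that("projection reproduces calibration and enforces hard bounds", {
  g <- toyGrid(n = 8)
  set.seed(6)
  ls <- list(a = RasterLayer(g, matrix(runif(64, 0, 10), 8, 8)),
             b = RasterLayer(g, matrix(runif(64, 50, 80), 8, 8)))
  cells <- sample(64, 20)
  env <- cbind(a = as.vector(ls$a@values), b = as.vector(ls$b@values))
  bgCells <- sample(64, 30)
  m <- fitMaxent(env[cells, ], env[bgCells, ], fc = "LQ")
  suit <- projectSuitability(m, ls)
  expect_true(all(suit@values >= 0 & suit@values <= 1))
  # projecting twice onto the same layers is exact
  expect_identical(suit@values, projectSuitability(m, ls)@values)
  # random projection layers still give [0, 1]
  ls2 <- list(a = RasterLayer(g, matrix(rnorm(64, 5, 20), 8, 8)),
              b = RasterLayer(g, matrix(rnorm(64, 60, 100), 8, 8)))
  s2 <- projectSuitability(m, ls2)
  expect_true(all(s2@values >= 0 & s2@values <= 1))
  # cells above the elevation bound are unsuitable regardless of climate
  elev <- RasterLayer(g, matrix(500, 8, 8))
  elev@values[3, 4] <- 3500
  s3 <- projectSuitability(m, ls, elevation = elev, elevationBound = 3000)
  expect_equal(s3@values[3, 4], 0)
  expect_equal(s3@values[-3, ], suit@values[-3, ])
  expect_error(projectSuitability(m, ls["a"]), "missing variable")
})

test_that("model JSON serialization round-trips", {
  d <- toyFitData(seed = 4)
  m <- fitMaxent(d$pres, d$bg, fc = "LQ")
  path <- tempfile(fileext = ".json")
  writeNicheModel(m, path)
  back <- readNicheModel(path)
  expect_equal(coef(back), coef(m))
  expect_equal(back@Z, m@Z)
  expect_equal(back@entropy, m@entropy)
  # restored model projects identically
  env <- cbind(a = runif(20), b = runif(20))
  g <- GridSpec(0, 0, 1, 5, 4)
  ls <- list(a = RasterLayer(g, matrix(env[, 1], 4, 5)),
             b = RasterLayer(g, matrix(env[, 2], 4, 5)))
  expect_equal(projectSuitability(back, ls)@values,
               projectSuitability(m, ls)@values)
  unlink(path)
})
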