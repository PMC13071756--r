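layersFrom <- function(..., grid = GridSpec(0, 0, 1, 2, 2)) {
  vals <- list(...)
  lapply(vals, function(v) RasterLayer(grid, matrix(v, 2, 2)))
}

test_that("pearson matrix matches hand computation and flags degeneracy", {
  ls <- layersFrom(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8) + 5,
                   c = c(4, 3, 2, 1), d = c(1, 3, 2, 5))
  r <- pearsonMatrix(ls)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(r["a", "b"], 1)    # affine invariance
  expect_equal(r["a", "c"], -1)
  # hand computation for the (a, d) pair on the 4-cell table
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 5)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r["a", "d"], hand)
  expect_true(all(r >= -1 - 1e-12 & r <= 1 + 1e-12))

  ls2 <- layersFrom(a = c(1, 2, 3, 4), z = rep(5, 4))
  expect_equal(attr(pearsonMatrix(ls2), "degenerate"), "z")
})

test_that("greedy correlation screening respects priority and threshold", {
  r <- matrix(c(1, 0.95, 0.95, 1), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(selectUncorrelated(r, 0.7, priority = c("a", "b")), "a")
  expect_equal(selectUncorrelated(r, 0.7, priority = c("b", "a")), "b")

  # mutually independent variables: all kept
  r2 <- diag(3); dimnames(r2) <- list(letters[1:3], letters[1:3])
  expect_equal(selectUncorrelated(r2), c("a", "b", "c"))

  # 5-variable toy: greedy oracle run by hand
  vars <- letters[1:5]
  r5 <- diag(5); dimnames(r5) <- list(vars, vars)
  r5["a", "b"] <- r5["b", "a"] <- 0.9   # b rejected (a first)
  r5["a", "c"] <- r5["c", "a"] <- 0.3
  r5["c", "d"] <- r5["d", "c"] <- 0.8   # d rejected (conflicts with c)
  r5["a", "e"] <- r5["e", "a"] <- 0.65
  r5["c", "e"] <- r5["e", "c"] <- 0.2
  sel <- selectUncorrelated(r5, 0.7, priority = vars)
  expect_equal(sel, c("a", "c", "e"))
  # output never violates its own constraint
  sub <- abs(r5[sel, sel]); diag(sub) <- 0
  expect_true(all(sub < 0.7))

  # adding a variable duplicating a rejected one does not change the result
  vars6 <- c(vars, "b2")
  r6 <- diag(6); dimnames(r6) <- list(vars6, vars6)
  r6[vars, vars] <- r5
  r6["b2", ] <- r6[, "b2"] <- c(r5["b", ], 1)
  r6["b2", "b2"] <- 1
  expect_equal(selectUncorrelated(r6, 0.7, priority = vars6), sel)

  expect_error(selectUncorrelated(r[0, 0, drop = FALSE]), "no candidate")
})

test_that("variance inflation factors agree with least-squares oracles", {
  g <- GridSpec(0, 0, 1, 5, 4)
  set.seed(21)
  # orthogonal-by-construction predictors have VIF 1
  x1 <- rnorm(20); x2 <- residuals(lm(rnorm(20) ~ x1))
  ls <- list(a = RasterLayer(g, matrix(x1, 4, 5)),
             b = RasterLayer(g, matrix(x2, 4, 5)))
  v <- vifCheck(ls, c("a", "b"))
  expect_equal(as.numeric(v), c(1, 1), tolerance = 1e-10)
  expect_false(attr(v, "violation"))

  # duplicated predictor: infinite VIF with violation flag
  ls$b2 <- ls$a
  expect_warning(v2 <- vifCheck(ls, c("a", "b2")), "VIF")
  expect_true(all(!is.finite(v2)))
  expect_true(attr(v2, "violation"))

  # constructed R^2 = 0.5 gives VIF = 2
  z <- rnorm(20); e <- residuals(lm(rnorm(20) ~ z))
  e <- e / sqrt(sum(e^2)) * sqrt(sum((z - mean(z))^2))  # equal SS
  y <- z + e  # half the variance of y is explained by z
  ls3 <- list(a = RasterLayer(g, matrix(y, 4, 5)),
              b = RasterLayer(g, matrix(z, 4, 5)))
  r2 <- summary(lm(y ~ z))$r.squared
  expect_equal(unname(vifCheck(ls3, c("a", "b"))["a"]), 1 / (1 - r2),
               tolerance = 1e-10)
})

test_that("the selection report bundles screen and check coherently", {
  g <- toyGrid(n = 8)
  set.seed(5)
  base <- matrix(rnorm(64), 8, 8)
  ls <- list(bio01 = RasterLayer(g, base),
             bio12 = RasterLayer(g, matrix(rnorm(64), 8, 8)),
             bioX = RasterLayer(g, base * 2 + 1 +
                                  matrix(rnorm(64, 0, 0.1), 8, 8)))
  rep <- selectPredictors(ls)
  expect_s3_class(rep, "SelectionReport")
  expect_true("bio01" %in% rep$selected)   # priority leads
  expect_false("bioX" %in% rep$selected)   # collinear with bio01
  expect_true(all(rep$vif < 10))
})
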