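test_that("area series sum spherical cell areas", {
  g <- GridSpec(0, -0.05, 0.1, 3, 1)
  empty <- matrix(FALSE, 1, 3)
  expect_equal(areaSeries(empty, g), 0)
  one <- matrix(c(TRUE, FALSE, FALSE), 1, 3)
  expect_equal(areaSeries(one, g), 123.6, tolerance = 0.1 / 123.6)
  expect_equal(areaSeries(one, g), areaOracle(-0.05, 0.05, 0.1),
               tolerance = 1e-8)
  # additivity over disjoint maps
  a <- matrix(c(TRUE, FALSE, FALSE), 1, 3)
  b <- matrix(c(FALSE, TRUE, TRUE), 1, 3)
  expect_equal(areaSeries(a | b, g), areaSeries(a, g) + areaSeries(b, g))
})

test_that("proportion series divide and flag correctly", {
  expect_equal(proportionSeries(c(1, 2), c(1, 2)), c(100, 100),
               ignore_attr = TRUE)
  expect_equal(proportionSeries(50, 200), 25, ignore_attr = TRUE)
  p <- proportionSeries(c(10, 0), c(20, 0))
  expect_true(is.na(p[2]))
  expect_equal(attr(p, "undefined"), 2L)
  expect_error(proportionSeries(-1, 2), "nonnegative")
  # containment implies proportions of at most 100
  set.seed(2)
  u <- runif(30, 1, 10); l <- u * runif(30)
  expect_true(all(proportionSeries(l, u) <= 100))
})

test_that("trajectory patterns are recovered from constructed series", {
  yrs <- 76
  expect_equal(classifyTrend(seq(1, 5, length.out = yrs)), "linear-increase")
  expect_equal(classifyTrend(rep(3, yrs)), "no-change")
  expect_equal(classifyTrend(seq(5, 1, length.out = yrs)), "decrease")
  # rise(25) - fall(25) - rise(26)
  s <- c(seq(1, 3, length.out = 25), seq(3, 1.5, length.out = 25),
         seq(1.5, 4, length.out = 26))
  expect_equal(classifyTrend(s), "inc-dec-inc")
  s2 <- c(seq(4, 2, length.out = 25), seq(2, 3.5, length.out = 25),
          seq(3.5, 1, length.out = 26))
  expect_equal(classifyTrend(s2), "dec-inc-dec")
  # invariance to uniform rescaling
  expect_equal(classifyTrend(s * 1e6), classifyTrend(s))
  expect_equal(classifyTrend(s2 / 17), classifyTrend(s2))
  # small fluctuations below the tolerance stay no-change
  set.seed(1)
  wiggle <- 100 + cumsum(rnorm(yrs, 0, 0.05))
  expect_equal(classifyTrend(wiggle), "no-change")
  expect_error(classifyTrend(1:5), "shorter")
})

test_that("proportion-change classes follow the endpoint rule", {
  expect_equal(classifyProportionChange(rep(80, 20)), "unchanged")
  expect_equal(classifyProportionChange(seq(90, 40, length.out = 30)),
               "decreased")
  expect_equal(classifyProportionChange(seq(50, 95, length.out = 30)),
               "increased")
  # changes inside the tolerance band are unchanged
  expect_equal(classifyProportionChange(seq(80, 83, length.out = 30)),
               "unchanged")
  expect_error(classifyProportionChange(NA_real_), "at least 2")
})

test_that("the ten-species registry classifies 4 / 2 / 4", {
  reg <- defaultSpeciesRegistry()
  expect_equal(nrow(reg), 10)
  cls <- classifyDispersalClass(reg)
  expect_equal(unname(cls$counts), c(4L, 2L, 4L))
  expect_setequal(cls$members[["<2"]],
                  c("Hyla_chinensis", "Rana_kukunoris",
                    "Grammatoptila_striata", "Pomatorhinus_ferruginosus"))
  expect_setequal(cls$members[[">10"]],
                  c("Tephrodornis_virgatus", "Cydia_pomonella",
                    "Tuta_absoluta", "Leptinotarsa_decemlineata"))
  # boundary values belong to the middle class
  expect_equal(dispersalClass(c(2, 10)), c("2-10", "2-10"))
  expect_equal(classifyDispersalClass(
    data.frame(speciesId = "x", dMax = 10))$counts[["2-10"]], 1L)
  # empty registry
  empty <- classifyDispersalClass(data.frame(speciesId = character(),
                                             dMax = numeric()))
  expect_equal(unname(empty$counts), c(0L, 0L, 0L))
  # the amphibians follow the 1 km/yr convention; insects sit in 10-50
  expect_true(all(reg$dMax[reg$taxon == "amphibian"] == 1))
  expect_true(all(reg$dMax[reg$taxon == "insect"] >= 10 &
                    reg$dMax[reg$taxon == "insect"] <= 50))
  expect_true(all(reg$mInit[reg$nativity == "invasive"] == 10))
})
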