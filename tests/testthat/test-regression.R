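table1 <- data.frame(
  deformation = c(4, 8, 12, 16),
  damage_mean = c(3.82, 5.74, 10.81, 16.58),
  decay_rate = c(15, 20, 35, 45))

test_that("the decay regression is recovered in closed form", {
  m <- fitRateModel(table1$deformation, table1$decay_rate, "Y2")
  expect_equal(m@slope, 210 / 80, tolerance = 1e-12)
  expect_equal(m@intercept, 2.5, tolerance = 1e-12)
  expect_equal(m@rSquared, 1 - 17.5 / 568.75, tolerance = 1e-12)
  expect_identical(round(m@rSquared, 2), 0.97)
  expect_lt(m@slopePValue, 0.05)
  expect_identical(formatModelEquation(m), "Y2 = 2.625X + 2.5")
})

test_that("perfect linear data give slope 1, intercept 0, R^2 = 1", {
  m <- fitRateModel(c(1, 2, 5, 9), c(1, 2, 5, 9))
  expect_equal(m@slope, 1, tolerance = 1e-12)
  expect_equal(m@intercept, 0, tolerance = 1e-12)
  expect_equal(m@rSquared, 1, tolerance = 1e-12)
})

test_that("fits agree with the normal-equations oracle on random data", {
  set.seed(202)
  for (k in 1:100) {
    n <- sample(3:12, 1)
    x <- runif(n, 0, 20)
    if (length(unique(x)) < 2) next
    y <- 2 + 1.5 * x + rnorm(n, 0, 3)
    m <- fitRateModel(x, y)
    o <- oracleOls(x, y)
    expect_equal(m@slope, o[["slope"]], tolerance = 1e-10)
    expect_equal(m@intercept, o[["intercept"]], tolerance = 1e-10)
    expect_lt(abs(sum(m@residuals)), 1e-8)
  }
})

test_that("R^2 is invariant under affine rescaling of the deformation axis", {
  set.seed(7)
  x <- c(4, 8, 12, 16); y <- c(14, 22, 33, 47)
  r2 <- fitRateModel(x, y)@rSquared
  expect_equal(fitRateModel(3 * x + 11, y)@rSquared, r2, tolerance = 1e-12)
  expect_equal(fitRateModel(-0.5 * x, y)@rSquared, r2, tolerance = 1e-12)
})

test_that("prediction is affine with extrapolation flagged and OLS mean identity", {
  m <- fitRateModel(table1$deformation, table1$decay_rate, "Y2")
  expect_equal(as.numeric(predictRate(m, 0)), 2.5, tolerance = 1e-12)
  expect_equal(as.numeric(predictRate(m, 8)), 23.5, tolerance = 1e-12)
  p <- predictRate(m, c(0, 8, 20))
  expect_identical(attr(p, "extrapolated"), c(TRUE, FALSE, TRUE))
  expect_equal(as.numeric(predictRate(m, mean(table1$deformation))),
               mean(table1$decay_rate), tolerance = 1e-12)
})

test_that("degenerate designs and tiny samples are handled", {
  expect_error(fitRateModel(c(4, 4, 4), c(1, 2, 3)), "singular")
  m2 <- fitRateModel(c(4, 8), c(10, 20))
  expect_true(is.na(m2@slopePValue))  # no inference with n < 3
})

test_that("group-mean damage fit is reported honestly, not forced to a reference", {
  m <- fitRateModel(table1$deformation, table1$damage_mean, "Y1")
  o <- oracleOls(table1$deformation, table1$damage_mean)
  expect_equal(m@slope, o[["slope"]], tolerance = 1e-10)
  expect_equal(round(m@slope, 3), 1.084)
  expect_equal(round(m@intercept, 2), -1.6)

  rep <- rateModelReport(
    damagePoints = data.frame(X = table1$deformation, Y = table1$damage_mean),
    decayPoints = data.frame(X = table1$deformation, Y = table1$decay_rate),
    referenceCoefficients = list(
      Y1 = c(intercept = -0.468, slope = 0.964),
      Y2 = c(intercept = 2.5, slope = 2.625)))
  expect_length(rep$notes, 1)        # Y1 flagged, Y2 clean
  expect_match(rep$notes, "^Y1")
  expect_identical(rep$table$r_squared_2dp[rep$table$response == "Y2"], 0.97)
  expect_error(rateModelReport(), "at least one")
})
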