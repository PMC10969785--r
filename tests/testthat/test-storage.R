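test_that("respiration rate follows (C1 - C2) V / (m t)", {
  expect_identical(respirationRate(0.02, 0.02, 1500, 0.4, 3), 0)
  expect_equal(respirationRate(0.01, 0, 2000, 0.5, 3), 40 / 3,
               tolerance = 1e-12)
  # homogeneity: doubling both mass and volume leaves the rate unchanged
  expect_equal(respirationRate(0.013, 0.003, 4000, 1.0, 3),
               respirationRate(0.013, 0.003, 2000, 0.5, 3), tolerance = 1e-12)
  # linear in C1 - C2, inverse in m and t
  r1 <- respirationRate(0.02, 0.01, 1000, 0.5, 2)
  expect_equal(respirationRate(0.03, 0.01, 1000, 0.5, 2), 2 * r1,
               tolerance = 1e-12)
  expect_equal(respirationRate(0.02, 0.01, 1000, 1.0, 2), r1 / 2,
               tolerance = 1e-12)
  expect_equal(respirationRate(0.02, 0.01, 1000, 0.5, 4), r1 / 2,
               tolerance = 1e-12)

  expect_warning(r <- respirationRate(0.01, 0.02, 1000, 0.5, 2), "suspect")
  expect_lt(r, 0)
  expect_error(respirationRate(0.01, 0, 0, 0.5, 2), "positive")
  expect_error(respirationRate(0.01, 0, 1000, 0.5, -1), "positive")
})

test_that("decay rate is the group percentage, bounded and monotone", {
  expect_identical(decayRate(9, 20), 45)
  expect_identical(decayRate(0, 20), 0)
  expect_identical(decayRate(20, 20), 100)
  expect_error(decayRate(3, 0), "groupSize")
  expect_error(decayRate(21, 20), "decayedCount")
  counts <- 0:20
  r <- decayRate(counts, 20)
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= 0 & r <= 100))
})

test_that("percent change versus control follows the lower-than-control sign convention", {
  expect_identical(percentChangeVsControl(10, 10), 0)
  expect_equal(percentChangeVsControl(5.9, 10), 41, tolerance = 1e-12)
  expect_identical(percentChangeVsControl(11, 10), -10)
  expect_error(percentChangeVsControl(5, 0), "control")
})

test_that("storage observation tables are validated against their invariants", {
  obs <- data.frame(group = c(0, 4), day = c(0, 10),
                    decayed_count = c(0, 3), group_size = c(20, 20))
  expect_silent(validateStorageObservations(obs))
  bad <- obs; bad$decayed_count[2] <- 25
  expect_error(validateStorageObservations(bad), "decayed_count")
  expect_error(validateStorageObservations(data.frame(group = 1)), "day")
  neg <- obs; neg$day[1] <- -1
  expect_error(validateStorageObservations(neg), "day")
})
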