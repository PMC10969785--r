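test_that("phantom sections honour degenerate and by-construction cases", {
  ph <- generateSection(smallSpec(blockageFraction = 0))
  expect_false(isBlocked(ph$truth))
  expect_identical(blockageArea(ph$truth), 0L + 0)

  ph0 <- generateSection(smallSpec(cavityRadius = 0))
  expect_identical(cavityArea(ph0$truth), 0L + 0)

  expect_error(PhantomSpec(imageSize = 128, fruitRadius = 40,
                           peelThickness = 6, cavityRadius = 40),
               "geometry")
})

test_that("circular cavity area matches the exhaustive pixel-membership count", {
  spec <- PhantomSpec(imageSize = 256, fruitRadius = 100, peelThickness = 10,
                      cavityRadius = 30, lobeAmplitude = 0, noiseSd = 0,
                      seed = 2)
  ph <- generateSection(spec)
  ctr <- (256 + 1) / 2
  count <- 0L
  for (i in 1:256) for (j in 1:256)
    if ((i - ctr)^2 + (j - ctr)^2 <= 30^2) count <- count + 1L
  expect_identical(as.integer(cavityArea(ph$truth)), count)
})

test_that("identical specs render byte-identical images and truths", {
  a <- generateSection(smallSpec(noiseSd = 4, blockageFraction = 0.15,
                                 ruptureCount = 4, seed = 9))
  b <- generateSection(smallSpec(noiseSd = 4, blockageFraction = 0.15,
                                 ruptureCount = 4, seed = 9))
  expect_identical(pixels(a$image), pixels(b$image))
  expect_identical(a$truth@labels, b$truth@labels)
  expect_identical(cavityArea(a$truth), cavityArea(b$truth))
})

test_that("truths are consistent with the label grid across random specs", {
  set.seed(42)
  for (k in 1:100) {
    spec <- PhantomSpec(
      imageSize = 72, fruitRadius = runif(1, 24, 32),
      peelThickness = runif(1, 2, 4), cavityRadius = runif(1, 5, 12),
      nSegments = sample(5:10, 1), septumWidth = runif(1, 1, 2),
      blockageFraction = sample(c(0, runif(1, 0.05, 0.3)), 1),
      lobeAmplitude = runif(1, 0, 0.15), noiseSd = runif(1, 0, 5),
      seed = k)
    ph <- generateSection(spec)
    lbl <- ph$truth@labels
    expect_identical(sum(lbl == 1L | lbl == 5L), as.integer(cavityArea(ph$truth)))
    expect_identical(sum(lbl == 5L), as.integer(blockageArea(ph$truth)))
    expect_identical(isBlocked(ph$truth), blockageArea(ph$truth) > 0)
  }
})

test_that("pair damage rates follow the cavity-area formula exactly", {
  for (s in 1:5) {
    p <- generatePair(smallSpec(seed = s), deformationMm = 12)
    s1 <- cavityArea(p@preTruth); s2 <- cavityArea(p@postTruth)
    expect_equal(trueDamageRate(p), (s2 - s1) / s1 * 100, tolerance = 1e-12)
  }
})

test_that("damage models drive the pair generator as specified", {
  p0 <- generatePair(smallSpec(seed = 3), 0, damageModel = identityDamageModel)
  expect_identical(trueDamageRate(p0), 0)

  tenPct <- function(d) list(areaScale = 1.10, blockageFraction = 0)
  p10 <- generatePair(smallSpec(seed = 4), 8, damageModel = tenPct)
  expect_gt(cavityArea(p10@preTruth), 1000)
  expect_lt(abs(trueDamageRate(p10) - 10), 0.5)

  expect_error(generatePair(smallSpec(), -1), "deformation")
})

test_that("additive noise is clipped, seeded, and unbiased", {
  img <- SliceImage(matrix(100, 128, 128), valueRange = c(0, 255))
  expect_identical(addNoise(img, 0), img)
  n1 <- addNoise(img, 5, seed = 7)
  n2 <- addNoise(img, 5, seed = 7)
  expect_identical(pixels(n1), pixels(n2))
  expect_false(identical(pixels(n1), pixels(img)))
  expect_lt(abs(mean(pixels(n1)) - 100), 3 * 5 / sqrt(128^2))
  expect_true(all(pixels(n1) >= 0 & pixels(n1) <= 255))
})

test_that("blockage fragments land wholly inside the cavity near target area", {
  ph <- generateSection(smallSpec(blockageFraction = 0.2, seed = 6))
  lbl <- ph$truth@labels
  expect_true(isBlocked(ph$truth))
  # fragments are strictly interior: their neighbourhood never touches
  # tissue, only cavity or other blockage
  ring <- dilateMask(lbl == 5L, diskElement(1)) & lbl != 5L
  expect_true(all(lbl[ring] == 1L))
  frac <- blockageArea(ph$truth) / cavityArea(ph$truth)
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.35)
})
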