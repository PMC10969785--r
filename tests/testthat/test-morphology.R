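test_that("erosion and dilation match their set-definition oracles", {
  # worked example: eroding a full 5x5 grid by a 3x3 square leaves the
  # centred 3x3 interior
  full <- matrix(TRUE, 5, 5)
  box <- matrix(TRUE, 3, 3)
  expected <- matrix(FALSE, 5, 5); expected[2:4, 2:4] <- TRUE
  expect_identical(erodeMask(full, box), expected)
  expect_identical(oracleErode(full, box), expected)

  # dilating an isolated pixel paints the element
  dot <- matrix(FALSE, 5, 5); dot[3, 3] <- TRUE
  expect_identical(sum(dilateMask(dot, box)), 9L)          # 3x3 block
  expect_identical(sum(dilateMask(dot, diskElement(1))), 5L)  # 4-conn cross

  set.seed(101)
  elements <- list(diskElement(1), diskElement(2), box,
                   matrix(c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE,
                            FALSE, TRUE, FALSE), 3, 3))
  for (k in 1:60) {
    m <- randomGrid()
    se <- elements[[sample.int(length(elements), 1)]]
    expect_identical(erodeMask(m, se), oracleErode(m, se))
    expect_identical(dilateMask(m, se), oracleDilate(m, se))
  }
})

test_that("component labeling respects connectivity", {
  m <- matrix(FALSE, 3, 3); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_identical(max(labelComponents(m, 8)), 1L)  # diagonal touch
  expect_identical(max(labelComponents(m, 4)), 2L)
})

test_that("region growing fills cavity and enclosed blockage alike", {
  # 15x15 toy: dark ring (cavity wall) enclosing a 9-px bright blob;
  # growth from the centre must cover ring + enclosed area
  m <- matrix(FALSE, 15, 15)
  m[4:12, 4:12] <- TRUE        # cavity block
  m[6:8, 6:8] <- FALSE         # 9-px bright blockage = hole
  filled <- regionGrowFill(m, c(7, 7))
  expect_identical(sum(pixels(filled)), sum(m) + 9L)
  expect_identical(pixels(filled),
                   oracleRegionFill(m, c(7, 7), 8))

  # unblocked cavity: nothing to fill
  solid <- matrix(FALSE, 9, 9); solid[3:6, 3:6] <- TRUE
  expect_identical(pixels(regionGrowFill(solid, c(4, 4))), solid)

  # seed in the exterior background is an error
  expect_error(regionGrowFill(solid, c(1, 1)), "exterior")
})

test_that("region growing agrees with the flood-fill oracle on random grids", {
  set.seed(77)
  for (k in 1:60) {
    m <- randomGrid(12)
    conn <- sample(c(4, 8), 1)
    fg <- which(m, arr.ind = TRUE)
    if (!nrow(fg)) next
    seed <- fg[sample.int(nrow(fg), 1), ]
    expect_identical(pixels(regionGrowFill(m, seed, conn)),
                     oracleRegionFill(m, seed, conn))
  }
})

test_that("hole filling turns enclosed background into foreground", {
  ring <- matrix(FALSE, 9, 9)
  ring[3:7, 3:7] <- TRUE; ring[5, 5] <- FALSE
  expect_identical(sum(fillHoles(ring)), 25L)
  # a bay open to the border is exterior-connected, not a hole
  bay <- ring; bay[5, 6:9] <- FALSE
  expect_false(fillHoles(bay, 4)[5, 5])
  expect_false(fillHoles(bay, 8)[5, 5])
})

test_that("morphology agrees with EBImage on interior objects", {
  set.seed(5)
  m <- matrix(FALSE, 64, 64)
  m[20:45, 18:40] <- matrix(runif(26 * 23) < 0.7, 26, 23)
  box <- matrix(TRUE, 3, 3)
  eb <- EBImage::makeBrush(3, "box")
  expect_identical(erodeMask(m, box),
                   EBImage::erode(m * 1, eb) == 1)
  expect_identical(dilateMask(m, box),
                   EBImage::dilate(m * 1, eb) == 1)
})
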