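test_that("Otsu binarization separates bimodal data and records the threshold", {
  img <- SliceImage(matrix(c(10, 200)[c(1, 1, 2, 1, 2, 2, 1, 2, 1, 1, 2, 2,
                                        1, 2, 1, 2)], 4, 4),
                    valueRange = c(0, 255))
  b <- binarize(img)
  expect_identical(pixels(b), pixels(img) == 200)
  thr <- attr(b, "threshold")
  expect_true(thr > 10 && thr < 200)
  # histogram Otsu partitions like the exhaustive intra-class-variance search
  set.seed(31)
  for (k in 1:20) {
    v <- c(rnorm(40, 30, 6), rnorm(60, 160, 20))
    tOr <- oracleOtsu(v)
    tPk <- otsuThreshold(v)
    expect_identical(v > tPk, v > tOr)
  }
})

test_that("binarize handles constant images and boundary thresholds", {
  flat <- SliceImage(matrix(7, 4, 4), valueRange = c(0, 255))
  expect_warning(b <- binarize(flat), "constant")
  expect_false(any(pixels(b)))

  img <- SliceImage(matrix(1:16, 4, 4), valueRange = c(0, 255))
  atMax <- binarize(img, SegmentationParams(thresholdMethod = "fixed",
                                            thresholdValue = 16))
  expect_false(any(pixels(atMax)))  # strict > comparison
  above <- binarize(flat, SegmentationParams(thresholdMethod = "fixed",
                                             thresholdValue = 10))
  expect_false(any(pixels(above)))
})

test_that("mask construction erodes the largest filled component only", {
  m <- matrix(FALSE, 12, 12)
  m[2:11, 2:8] <- TRUE              # 70 px component
  m[2:4, 10:12] <- TRUE             # 9 px distractor
  mk <- buildMask(BinaryMask(m), erosionCoreRadius = 0)
  expect_identical(pixels(mk), m & col(m) <= 8)

  full <- matrix(TRUE, 5, 5)
  mk3 <- buildMask(BinaryMask(full), erosionCoreRadius = 1)
  expect_identical(sum(pixels(mk3)), 9L)  # cross-eroded 3x3 interior

  expect_error(buildMask(BinaryMask(full), erosionCoreRadius = 10),
               "erosion core too large")
  # the cavity (a hole in the fruit disk) stays inside the mask
  disk <- matrix(FALSE, 21, 21)
  disk[3:19, 3:19] <- TRUE; disk[9:12, 9:12] <- FALSE
  mkF <- buildMask(BinaryMask(disk), erosionCoreRadius = 1)
  expect_true(all(pixels(mkF)[9:12, 9:12]))
})

test_that("mask multiplication preserves interior intensities and zeroes the rest", {
  img <- SliceImage(matrix(1:12, 3, 4), valueRange = c(0, 255))
  all_fg <- BinaryMask(matrix(TRUE, 3, 4))
  expect_identical(pixels(applyMask(img, all_fg)), pixels(img))
  none <- BinaryMask(matrix(FALSE, 3, 4))
  expect_true(all(pixels(applyMask(img, none)) == 0))
  one <- matrix(FALSE, 3, 4); one[2, 3] <- TRUE
  out <- pixels(applyMask(img, BinaryMask(one)))
  expect_identical(out[2, 3], pixels(img)[2, 3])
  expect_identical(sum(out != 0), 1L)
  expect_error(applyMask(img, BinaryMask(matrix(TRUE, 2, 2))), "dimensions")
})

test_that("cavity isolation picks the dark component nearest the fruit centroid", {
  ph <- generateSection(smallSpec(seed = 21))
  res <- extractCavity(ph$image, smallParams())
  cand <- intermediates(res)$candidate
  expect_identical(pixels(cand), ph$truth@labels == 1L)

  bright <- SliceImage(matrix(200, 20, 20), valueRange = c(0, 255))
  expect_error(isolateCavity(bright, smallParams(),
                             mask = matrix(TRUE, 20, 20), threshold = 50),
               "no cavity found")

  # central 100-px vs peripheral 400-px dark component: central wins
  px <- matrix(200, 40, 40)
  px[16:25, 16:25] <- 10       # central, 100 px
  px[1:40, 31:40] <- 10        # peripheral strip, 400 px
  img <- SliceImage(px, valueRange = c(0, 255))
  cand <- isolateCavity(img, smallParams(), mask = matrix(TRUE, 40, 40),
                        threshold = 50)
  expect_identical(sum(pixels(cand)), 100L)
  expect_true(all(which(pixels(cand), arr.ind = TRUE)[, 1] %in% 16:25))
})

test_that("refinement is a closing with identity at zero radii", {
  ring <- matrix(FALSE, 11, 11)
  ring[3:9, 3:9] <- TRUE; ring[4:8, 4:8] <- FALSE  # 1-px square annulus
  id <- refineCandidate(BinaryMask(ring),
                        smallParams(refineDilateRadius = 0,
                                    refineErodeRadius = 0))
  expect_identical(pixels(id), ring)

  # single-pixel gap in the cavity wall: before closing the interior leaks
  # to the exterior; after a radius-1.5 closing it is enclosed again
  gap <- ring; gap[3, 6] <- FALSE
  expect_error(regionGrowFill(gap, c(6, 6)), "exterior")
  closed <- refineCandidate(BinaryMask(gap),
                            smallParams(refineDilateRadius = 1.5,
                                        refineErodeRadius = 1.5))
  expected <- oracleErode(oracleDilate(gap, diskElement(1.5)),
                          diskElement(1.5))
  expect_identical(pixels(closed), expected)
  filled <- regionGrowFill(pixels(closed), c(6, 6))
  expect_true(all(pixels(filled)[4:8, 4:8]))
})

test_that("blockage classification uses a strict enclosed-bright criterion", {
  ph <- generateSection(smallSpec(seed = 8))
  res <- extractCavity(ph$image, smallParams())
  expect_false(isBlocked(res))
  phB <- generateSection(smallSpec(blockageFraction = 0.2, seed = 8))
  resB <- extractCavity(phB$image, smallParams())
  expect_true(isBlocked(resB))

  # enclosed bright area exactly at threshold -> unblocked (strict >)
  m <- matrix(FALSE, 20, 20)
  m[4:17, 4:17] <- TRUE            # 196 px
  m[8:11, 8:11] <- FALSE           # 16-px hole
  px <- matrix(0, 20, 20); px[m] <- 10; px[8:11, 8:11] <- 200
  cavArea <- sum(m)
  frac <- 16 / cavArea
  img <- SliceImage(px, valueRange = c(0, 255))
  expect_false(classifyBlockage(BinaryMask(m), img,
                                smallParams(blockageFractionThreshold = frac),
                                threshold = 50))
  expect_true(classifyBlockage(BinaryMask(m), img,
                               smallParams(blockageFractionThreshold =
                                             frac * 0.99),
                               threshold = 50))
})

test_that("end-to-end extraction recovers phantom cavities and names failing stages", {
  ph <- generateSection(smallSpec(seed = 13))
  res <- extractCavity(ph$image, smallParams())
  expect_lt(abs(areaPx(res) - cavityArea(ph$truth)) / cavityArea(ph$truth),
            0.02)

  phB <- generateSection(smallSpec(blockageFraction = 0.2, seed = 13))
  resB <- extractCavity(phB$image, smallParams())
  expect_lt(abs(areaPx(resB) - cavityArea(phB$truth)) / cavityArea(phB$truth),
            0.03)
  expect_identical(max(labelComponents(pixels(resB@filledMask))), 1L)

  blank <- SliceImage(matrix(0, 64, 64), valueRange = c(0, 255))
  err <- tryCatch(suppressWarnings(extractCavity(blank, smallParams())),
                  error = identity)
  expect_match(conditionMessage(err), "stage [AB]")
})

test_that("re-extracting from a rendered result mask is idempotent", {
  ph <- generateSection(smallSpec(seed = 17))
  res <- extractCavity(ph$image, smallParams())
  again <- extractCavity(renderMaskImage(res@filledMask), smallParams())
  expect_identical(areaPx(again), areaPx(res))
})

test_that("moderate noise moves the measured area by at most 5 percent", {
  contrast <- 170 - 15
  for (s in 1:4) {
    clean <- generateSection(smallSpec(seed = s))
    a0 <- areaPx(extractCavity(clean$image, smallParams()))
    noisy <- generateSection(smallSpec(seed = s, noiseSd = 0.05 * contrast))
    a1 <- areaPx(extractCavity(noisy$image, smallParams()))
    expect_lt(abs(a1 - a0) / a0, 0.05)
  }
})
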