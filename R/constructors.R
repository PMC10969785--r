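#' Create a grayscale section image
#'
#' @param pixels numeric matrix of intensities.
#' @param valueRange numeric(2) valid intensity range; defaults to
#'   \code{c(0, 255)} expanded if the data exceed it.
#' @param sectionKind \code{"cross"} or \code{"longitudinal"}.
#' @return A [SliceImage-class].
#' @examples
#' img <- SliceImage(matrix(runif(64, 0, 255), 8, 8))
#' dim(pixels(img))
#' @export
SliceImage <- function(pixels, valueRange = NULL, sectionKind = "cross") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (is.null(valueRange)) {
    valueRange <- c(0, 255)
    if (length(pixels)) {
      valueRange[1] <- min(valueRange[1], min(pixels))
      valueRange[2] <- max(valueRange[2], max(pixels))
    }
  }
  new("SliceImage", pixels = pixels, valueRange = as.numeric(valueRange),
      sectionKind = sectionKind)
}

#' Create a binary mask
#'
#' @param pixels logical matrix (numeric input is coerced; nonzero =
#'   foreground).
#' @param provenance name of the producing stage.
#' @return A [BinaryMask-class].
#' @export
BinaryMask <- function(pixels, provenance = "user") {
  pixels <- as.matrix(pixels)
  if (!is.logical(pixels)) {
    pixels <- pixels != 0
  }
  new("BinaryMask", pixels = pixels, provenance = provenance)
}

#' Create segmentation parameters
#'
#' Defaults are calibrated on the phantom suite at 512 x 512: an Otsu
#' threshold, a 15 px erosion core for cross sections and 25 px for
#' longitudinal sections, a 2 px closing for blocked-cavity refinement,
#' 8-connectivity, a 1\% blockage-area criterion, and region-growing seeds at
#' the candidate cavity centroid.
#'
#' @param thresholdMethod \code{"otsu"} (default) or \code{"fixed"}.
#' @param thresholdValue threshold intensity when \code{thresholdMethod =
#'   "fixed"}.
#' @param erosionCoreRadius named numeric with entries \code{cross} and
#'   \code{longitudinal} (pixels); a single unnamed value is used for both.
#' @param refineDilateRadius,refineErodeRadius closing radii (pixels).
#' @param connectivity 4 or 8.
#' @param blockageFractionThreshold fraction of cavity area in (0,1) that
#'   enclosed bright pixels must strictly exceed for a "blocked" call.
#' @param seedRule \code{"cavity_centroid"}, \code{"image_center"} or
#'   \code{"explicit"}.
#' @param seedPoint \code{c(row, col)} seed when \code{seedRule =
#'   "explicit"}.
#' @return A [SegmentationParams-class].
#' @examples
#' SegmentationParams(thresholdMethod = "fixed", thresholdValue = 60)
#' @export
SegmentationParams <- function(thresholdMethod = "otsu",
                               thresholdValue = NA_real_,
                               erosionCoreRadius = c(cross = 15,
                                                     longitudinal = 25),
                               refineDilateRadius = 2,
                               refineErodeRadius = 2,
                               connectivity = 8,
                               blockageFractionThreshold = 0.01,
                               seedRule = "cavity_centroid",
                               seedPoint = c(NA_real_, NA_real_)) {
  if (is.null(names(erosionCoreRadius)) && length(erosionCoreRadius) == 1L)
    erosionCoreRadius <- c(cross = unname(erosionCoreRadius),
                           longitudinal = unname(erosionCoreRadius))
  new("SegmentationParams", thresholdMethod = thresholdMethod,
      thresholdValue = as.numeric(thresholdValue),
      erosionCoreRadius = erosionCoreRadius,
      refineDilateRadius = refineDilateRadius,
      refineErodeRadius = refineErodeRadius,
      connectivity = connectivity,
      blockageFractionThreshold = blockageFractionThreshold,
      seedRule = seedRule, seedPoint = as.numeric(seedPoint))
}

#' Create a phantom specification
#'
#' Defaults render a 512 x 512 cross section of a fruit of radius 210 px with
#' an 18 px peel, a lobed elliptical cavity with semi-axes 60 x 48 px, nine
#' pulp wedges separated by 3 px septa, no blockage or ruptures, and Gaussian
#' noise of sd 4 on the 0-255 intensity scale.
#'
#' @param imageSize,fruitRadius,peelThickness,cavityRadius,nSegments,septumWidth
#'   geometry in pixels; see [PhantomSpec-class].
#' @param blockageFraction target blockage area / cavity area in [0,1].
#' @param ruptureCount number of point-like dark pulp ruptures.
#' @param noiseSd additive Gaussian noise sd (intensity units).
#' @param intensityLevels named intensity levels; cavity must be the darkest
#'   interior level.
#' @param lobeAmplitude,lobeCount lobed perturbation of the cavity outline.
#' @param sectionKind \code{"cross"} or \code{"longitudinal"}.
#' @param invert invert polarity (bright cavity) for non-CT-like modalities.
#' @param seed RNG seed; (spec, seed) fully determines the rendered image.
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- PhantomSpec(imageSize = 128, fruitRadius = 52, peelThickness = 6,
#'                     cavityRadius = 16, noiseSd = 0)
#' @export
PhantomSpec <- function(imageSize = 512,
                        fruitRadius = 210,
                        peelThickness = 18,
                        cavityRadius = c(60, 48),
                        nSegments = 9,
                        septumWidth = 3,
                        blockageFraction = 0,
                        ruptureCount = 0,
                        noiseSd = 4,
                        intensityLevels = c(background = 5, cavity = 15,
                                            rupture = 40, septum = 120,
                                            pulp = 170, blockage = 200,
                                            peel = 230),
                        lobeAmplitude = 0.12,
                        lobeCount = 5,
                        sectionKind = "cross",
                        invert = FALSE,
                        seed = 1) {
  if (length(cavityRadius) == 1L) cavityRadius <- rep(cavityRadius, 2L)
  new("PhantomSpec", imageSize = imageSize, fruitRadius = fruitRadius,
      peelThickness = peelThickness, cavityRadius = cavityRadius,
      nSegments = nSegments, septumWidth = septumWidth,
      blockageFraction = blockageFraction, ruptureCount = ruptureCount,
      noiseSd = noiseSd, intensityLevels = intensityLevels,
      lobeAmplitude = lobeAmplitude, lobeCount = lobeCount,
      sectionKind = sectionKind, invert = invert, seed = seed)
}
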