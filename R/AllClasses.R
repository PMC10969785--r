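#' @useDynLib pulpscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Grayscale section image
#'
#' A single 2-D grayscale section view (one CT slice) of a fruit.  Intensities
#' are stored as a numeric matrix; \code{valueRange} records the valid
#' intensity range of the modality (e.g. \code{c(0, 255)} for 8-bit data), and
#' \code{sectionKind} records whether the slice is a transverse
#' (\code{"cross"}) or axial (\code{"longitudinal"}) section, which controls
#' segmentation defaults such as the erosion-core radius.
#'
#' @slot pixels numeric matrix of intensities (rows = image rows).
#' @slot valueRange numeric(2), minimum and maximum representable intensity.
#' @slot sectionKind character, \code{"cross"} or \code{"longitudinal"}.
#' @seealso [SliceImage()], [extractCavity()]
#' @exportClass SliceImage
setClass("SliceImage",
  representation(pixels = "matrix", valueRange = "numeric",
                 sectionKind = "character"))

setValidity("SliceImage", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels))
    msg <- c(msg, "'pixels' must be a numeric matrix")
  if (length(object@valueRange) != 2L || any(!is.finite(object@valueRange)) ||
      object@valueRange[1] >= object@valueRange[2])
    msg <- c(msg, "'valueRange' must be two finite values (min < max)")
  else if (is.numeric(object@pixels) && length(object@pixels) &&
           (min(object@pixels) < object@valueRange[1] ||
            max(object@pixels) > object@valueRange[2]))
    msg <- c(msg, "pixel intensities fall outside 'valueRange'")
  if (length(object@sectionKind) != 1L ||
      !object@sectionKind %in% c("cross", "longitudinal"))
    msg <- c(msg, "'sectionKind' must be \"cross\" or \"longitudinal\"")
  if (length(msg)) msg else TRUE
})

#' Binary image mask
#'
#' A logical pixel mask with the same geometry as the image it was derived
#' from.  \code{provenance} names the pipeline stage that produced it
#' (e.g. \code{"binarize"}, \code{"mask"}, \code{"cavity"}, \code{"filled"}).
#'
#' @slot pixels logical matrix, \code{TRUE} = foreground.
#' @slot provenance character, producing stage.
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(pixels = "matrix", provenance = "character"))

setValidity("BinaryMask", function(object) {
  msg <- character()
  if (!is.logical(object@pixels)) msg <- c(msg, "'pixels' must be logical")
  if (anyNA(object@pixels)) msg <- c(msg, "'pixels' must not contain NA")
  if (length(object@provenance) != 1L)
    msg <- c(msg, "'provenance' must be a single string")
  if (length(msg)) msg else TRUE
})

#' Segmentation parameters
#'
#' Tunable parameters of the cavity-extraction pipeline.  The erosion-core
#' radius is given per section kind because transverse and axial sections need
#' masks that retreat different distances from the peel.
#'
#' @slot thresholdMethod character, \code{"otsu"} or \code{"fixed"}.
#' @slot thresholdValue numeric, threshold used when \code{thresholdMethod}
#'   is \code{"fixed"} (ignored otherwise).
#' @slot erosionCoreRadius named numeric, disk radius in pixels of the
#'   mask-erosion structuring element for \code{cross} and \code{longitudinal}
#'   sections.
#' @slot refineDilateRadius,refineErodeRadius numeric, disk radii of the
#'   refinement closing applied to blocked cavities.
#' @slot connectivity numeric, 4 or 8; used for component labeling and
#'   region growing.
#' @slot blockageFractionThreshold numeric in (0,1); a cavity is classified
#'   blocked when enclosed bright area strictly exceeds this fraction of the
#'   cavity area.
#' @slot seedRule character, \code{"cavity_centroid"}, \code{"image_center"}
#'   or \code{"explicit"}.
#' @slot seedPoint numeric(2), row/column of the explicit seed (NA unless
#'   \code{seedRule == "explicit"}).
#' @seealso [SegmentationParams()]
#' @exportClass SegmentationParams
setClass("SegmentationParams",
  representation(thresholdMethod = "character", thresholdValue = "numeric",
                 erosionCoreRadius = "numeric", refineDilateRadius = "numeric",
                 refineErodeRadius = "numeric", connectivity = "numeric",
                 blockageFractionThreshold = "numeric", seedRule = "character",
                 seedPoint = "numeric"))

setValidity("SegmentationParams", function(object) {
  msg <- character()
  if (!object@thresholdMethod %in% c("otsu", "fixed"))
    msg <- c(msg, "'thresholdMethod' must be \"otsu\" or \"fixed\"")
  if (object@thresholdMethod == "fixed" && !is.finite(object@thresholdValue))
    msg <- c(msg, "fixed thresholding needs a finite 'thresholdValue'")
  if (!all(c("cross", "longitudinal") %in% names(object@erosionCoreRadius)))
    msg <- c(msg, "'erosionCoreRadius' needs entries \"cross\" and \"longitudinal\"")
  if (any(object@erosionCoreRadius < 0) || object@refineDilateRadius < 0 ||
      object@refineErodeRadius < 0)
    msg <- c(msg, "radii must be >= 0")
  if (!object@connectivity %in% c(4, 8))
    msg <- c(msg, "'connectivity' must be 4 or 8")
  if (object@blockageFractionThreshold <= 0 ||
      object@blockageFractionThreshold >= 1)
    msg <- c(msg, "'blockageFractionThreshold' must lie in (0,1)")
  if (!object@seedRule %in% c("cavity_centroid", "image_center", "explicit"))
    msg <- c(msg, "unknown 'seedRule'")
  if (object@seedRule == "explicit" &&
      (length(object@seedPoint) != 2L || anyNA(object@seedPoint)))
    msg <- c(msg, "explicit seed rule needs 'seedPoint' = c(row, col)")
  if (length(msg)) msg else TRUE
})

#' Cavity segmentation result
#'
#' Output of [extractCavity()]: the filled cavity mask, its pixel area (the
#' S1 or S2 of the damage-rate statistic), the blockage classification, the
#' binarization threshold actually used, and all stage-by-stage intermediates
#' for audit.
#'
#' @slot filledMask [BinaryMask-class], the single-component cavity mask.
#' @slot areaPx numeric, foreground pixel count of \code{filledMask}.
#' @slot blocked logical, \code{TRUE} if the cavity contained blockage.
#' @slot threshold numeric, binarization threshold used.
#' @slot intermediates named list of stage outputs, in pipeline order.
#' @slot params [SegmentationParams-class] used for the run.
#' @exportClass CavityResult
setClass("CavityResult",
  representation(filledMask = "BinaryMask", areaPx = "numeric",
                 blocked = "logical", threshold = "numeric",
                 intermediates = "list", params = "SegmentationParams"))

setValidity("CavityResult", function(object) {
  msg <- character()
  if (object@areaPx != sum(object@filledMask@pixels))
    msg <- c(msg, "'areaPx' must equal the foreground count of 'filledMask'")
  if (length(msg)) msg else TRUE
})

#' Phantom specification
#'
#' Geometry, intensity and noise parameters of a synthetic fruit-section
#' phantom.  The phantom emulates the structures segmentation must cope with:
#' a bright peel annulus, mid-intensity pulp wedges separated by darker septa,
#' a dark (optionally lobed, elliptical) central cavity, optional bright
#' blockage fragments inside the cavity, point-like pulp ruptures, and
#' additive Gaussian noise.
#'
#' @slot imageSize numeric, side length in pixels (square image).
#' @slot fruitRadius numeric, outer fruit radius in pixels.
#' @slot peelThickness numeric, peel annulus thickness in pixels.
#' @slot cavityRadius numeric(2), cavity semi-axes in pixels (row, column);
#'   a single value is recycled to a circle.
#' @slot nSegments numeric, number of pulp wedges.
#' @slot septumWidth numeric, septum half-structure width in pixels.
#' @slot blockageFraction numeric in [0,1], target bright-fragment area as a
#'   fraction of cavity area.
#' @slot ruptureCount numeric, number of point-like dark ruptures in the pulp.
#' @slot noiseSd numeric, standard deviation of additive Gaussian noise in
#'   intensity units.
#' @slot intensityLevels named numeric: \code{background}, \code{cavity},
#'   \code{rupture}, \code{septum}, \code{pulp}, \code{blockage}, \code{peel}.
#' @slot lobeAmplitude,lobeCount numeric, relative amplitude and angular count
#'   of the lobed perturbation of the cavity outline (0 disables).
#' @slot sectionKind character, \code{"cross"} or \code{"longitudinal"}.
#' @slot invert logical, invert intensity polarity (bright cavity on dark
#'   tissue) for other modalities.
#' @slot seed numeric, RNG seed; the same spec (including seed) always
#'   renders a byte-identical image.
#' @seealso [PhantomSpec()], [generateSection()]
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(imageSize = "numeric", fruitRadius = "numeric",
                 peelThickness = "numeric", cavityRadius = "numeric",
                 nSegments = "numeric", septumWidth = "numeric",
                 blockageFraction = "numeric", ruptureCount = "numeric",
                 noiseSd = "numeric", intensityLevels = "numeric",
                 lobeAmplitude = "numeric", lobeCount = "numeric",
                 sectionKind = "character", invert = "logical",
                 seed = "numeric"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  need <- c("background", "cavity", "rupture", "septum", "pulp", "blockage",
            "peel")
  lv <- object@intensityLevels
  if (!all(need %in% names(lv)))
    msg <- c(msg, paste("'intensityLevels' needs entries:",
                        paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(lv[need]))
      msg <- c(msg, "intensity levels must be distinct")
    interior <- c("rupture", "septum", "pulp", "blockage", "peel")
    if (any(lv["cavity"] >= lv[interior]))
      msg <- c(msg, "the cavity must be the darkest interior level")
  }
  if (object@imageSize < 8) msg <- c(msg, "'imageSize' too small")
  if (length(object@cavityRadius) < 1L || length(object@cavityRadius) > 2L ||
      any(object@cavityRadius < 0))
    msg <- c(msg, "'cavityRadius' must be one or two non-negative radii")
  else {
    rmax <- max(object@cavityRadius) * (1 + max(0, object@lobeAmplitude))
    if (rmax >= object@fruitRadius - object@peelThickness)
      msg <- c(msg,
        "invalid geometry: cavity must fit strictly inside the fruit interior (cavityRadius < fruitRadius - peelThickness)")
  }
  if (object@blockageFraction < 0 || object@blockageFraction > 1)
    msg <- c(msg, "'blockageFraction' must lie in [0,1]")
  if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
  if (!object@sectionKind %in% c("cross", "longitudinal"))
    msg <- c(msg, "'sectionKind' must be \"cross\" or \"longitudinal\"")
  if (length(msg)) msg else TRUE
})

#' Phantom ground truth
#'
#' Exact pixel-level ground truth recorded while rendering a phantom:
#' the label grid (before noise), the cavity area in pixels (blockage
#' included, since blockage is displaced pulp *inside* the cavity region),
#' the blockage area, and the blocked flag.
#'
#' Label codes: 0 background, 1 cavity, 2 pulp, 3 septum, 4 peel,
#' 5 blockage (inside cavity), 6 rupture.
#'
#' @slot cavityAreaPx numeric, pixels of the full cavity region.
#' @slot blockageAreaPx numeric, pixels of blockage fragments.
#' @slot blocked logical, \code{blockageAreaPx > 0}.
#' @slot labels integer matrix of label codes.
#' @slot spec [PhantomSpec-class] that produced the image.
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  representation(cavityAreaPx = "numeric", blockageAreaPx = "numeric",
                 blocked = "logical", labels = "matrix", spec = "PhantomSpec"))

setValidity("PhantomTruth", function(object) {
  msg <- character()
  if (object@blockageAreaPx > object@cavityAreaPx)
    msg <- c(msg, "'blockageAreaPx' cannot exceed 'cavityAreaPx'")
  if (!identical(object@blocked, object@blockageAreaPx > 0))
    msg <- c(msg, "'blocked' must be TRUE exactly when 'blockageAreaPx' > 0")
  if (length(msg)) msg else TRUE
})

#' Pre/post compression phantom pair
#'
#' A matched pair of phantom sections for one simulated fruit: the
#' pre-compression section and the post-compression section rendered with an
#' enlarged (and possibly blocked) cavity, together with the true damage rate
#' computed from the exact pixel truths.
#'
#' @slot preImage,postImage [SliceImage-class] sections.
#' @slot preTruth,postTruth [PhantomTruth-class] ground truths.
#' @slot deformationMm numeric, simulated compression deformation in mm.
#' @slot trueDamageRate numeric, percent;
#'   \code{(post - pre)/pre * 100} on the truth cavity areas.
#' @exportClass PhantomPair
setClass("PhantomPair",
  representation(preImage = "SliceImage", postImage = "SliceImage",
                 preTruth = "PhantomTruth", postTruth = "PhantomTruth",
                 deformationMm = "numeric", trueDamageRate = "numeric"))

setValidity("PhantomPair", function(object) {
  s1 <- object@preTruth@cavityAreaPx
  s2 <- object@postTruth@cavityAreaPx
  if (s1 <= 0) return("pre-compression cavity area must be positive")
  expect <- (s2 - s1) / s1 * 100
  if (abs(object@trueDamageRate - expect) > 1e-9)
    return("'trueDamageRate' must equal (post - pre)/pre * 100 on truth areas")
  TRUE
})

#' Fitted deformation-rate linear model
#'
#' Ordinary least-squares fit of a rate (damage rate Y1 or storage decay rate
#' Y2, percent) on compression deformation X (mm): slope, intercept,
#' coefficient of determination, and the two-sided t-test p-value of the
#' slope.
#'
#' @slot response character, name of the dependent rate (e.g. \code{"Y1"}).
#' @slot slope,intercept numeric, OLS coefficients (percent per mm, percent).
#' @slot rSquared numeric in [0,1].
#' @slot slopePValue numeric, two-sided p-value of the slope t-statistic on
#'   n-2 degrees of freedom (NA when n < 3).
#' @slot n numeric, number of points fitted.
#' @slot residuals numeric, OLS residuals.
#' @slot xRange numeric(2), range of the fitted X values (predictions outside
#'   it are flagged as extrapolation).
#' @seealso [fitRateModel()], [predictRate()]
#' @exportClass RateModel
setClass("RateModel",
  representation(response = "character", slope = "numeric",
                 intercept = "numeric", rSquared = "numeric",
                 slopePValue = "numeric", n = "numeric",
                 residuals = "numeric", xRange = "numeric"))

setValidity("RateModel", function(object) {
  msg <- character()
  if (is.finite(object@rSquared) &&
      (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12))
    msg <- c(msg, "'rSquared' must lie in [0,1]")
  if (is.finite(object@slopePValue) &&
      (object@slopePValue <= 0 || object@slopePValue > 1))
    msg <- c(msg, "'slopePValue' must lie in (0,1]")
  if (length(msg)) msg else TRUE
})

#' Pipeline run report
#'
#' Aggregated output of [runPipeline()]: per-sample damage records, group
#' summaries, fitted deformation-rate models, failed samples, and provenance
#' (parameters, seed, package version).
#'
#' @slot records data.frame of per-sample damage records
#'   (sample_id, deformation_mm, S1, S2, A, blocked_pre, blocked_post).
#' @slot summaries data.frame of per-deformation summaries
#'   (deformation_mm, n, mean_A, sd_A).
#' @slot models named list of [RateModel-class] fits (possibly empty).
#' @slot failures data.frame (sample_id, stage, message) of excluded samples.
#' @slot provenance named list (seed, params, version, timestamp).
#' @exportClass RunReport
setClass("RunReport",
  representation(records = "data.frame", summaries = "data.frame",
                 models = "list", failures = "data.frame",
                 provenance = "list"))
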