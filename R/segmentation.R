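## Cavity-extraction pipeline for fruit CT section images:
## (A) binarization, (B) erosion-based mask of the fruit interior,
## (C) image multiplication, (D) background conversion + cavity isolation,
## (E,F) morphological refinement, (G) region-growing fill and area
## measurement.

#' Otsu threshold
#'
#' Global threshold maximizing the between-class intensity variance over a
#' fixed-bin histogram.  Foreground is defined as strictly above the
#' returned threshold.
#'
#' @param values numeric vector or matrix of intensities.
#' @param breaks number of histogram bins (default 256).
#' @param range numeric(2) histogram range; defaults to the data range.
#' @return The threshold intensity (a bin edge).  For a constant input the
#'   threshold is undefined; the maximum value is returned with a warning so
#'   that strict-\code{>} binarization yields all background.
#' @examples
#' otsuThreshold(c(rep(10, 9), rep(200, 7)))
#' @export
otsuThreshold <- function(values, breaks = 256L, range = NULL) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite intensities to threshold")
  if (min(values) == max(values)) {
    warning("constant image: Otsu threshold undefined, returning max (all background)")
    return(max(values))
  }
  if (is.null(range)) range <- c(min(values), max(values))
  lo <- range[1]; hi <- range[2]
  w <- (hi - lo) / breaks
  bin <- pmin(breaks, pmax(1L, ceiling((values - lo) / w)))
  bin[values <= lo] <- 1L
  counts <- tabulate(bin, nbins = breaks)
  mids <- lo + (seq_len(breaks) - 0.5) * w
  p <- counts / sum(counts)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[breaks]
  # between-class variance at each candidate split (threshold = edge k)
  k <- seq_len(breaks - 1L)
  w1 <- 1 - w0[k]
  valid <- w0[k] > 0 & w1 > 0
  bcv <- rep(-Inf, breaks - 1L)
  bcv[valid] <- (muT * w0[k][valid] - mu[k][valid])^2 /
    (w0[k][valid] * w1[valid])
  lo + which.max(bcv) * w
}

## Resolve the binarization threshold for an image under the given params.
.resolveThreshold <- function(values, params) {
  if (params@thresholdMethod == "fixed") params@thresholdValue
  else otsuThreshold(values)
}

#' Binarize a section image
#'
#' Stage A of the cavity pipeline: foreground = pixels strictly above the
#' threshold (fruit tissue is bright; cavity and background are dark).
#'
#' @param image a [SliceImage-class].
#' @param params a [SegmentationParams-class]; its threshold method is used.
#' @return A [BinaryMask-class] with provenance \code{"binarize"}; the
#'   threshold actually used is attached as attribute \code{"threshold"}.
#' @examples
#' img <- SliceImage(matrix(c(10, 10, 200, 200), 2, 2))
#' pixels(binarize(img))
#' @export
binarize <- function(image, params = SegmentationParams()) {
  stopifnot(is(image, "SliceImage"))
  if (!length(image@pixels)) stop("empty image")
  thr <- .resolveThreshold(image@pixels, params)
  out <- BinaryMask(image@pixels > thr, provenance = "binarize")
  attr(out, "threshold") <- thr
  out
}

#' Build the fruit-interior mask
#'
#' Stage B: the largest foreground component (the fruit disk) is selected,
#' its enclosed holes (the dark cavity reads as a hole in the binarized
#' fruit) are filled, and the result is eroded by a disk-shaped structuring
#' element so the mask lies strictly inside the fruit, excluding the peel
#' and the exterior.  The erosion-core radius is the tuning knob that adapts
#' the mask to cross versus longitudinal sections.
#'
#' @param binary a [BinaryMask-class] (or logical matrix) from [binarize()].
#' @param erosionCoreRadius disk radius in pixels of the erosion core.
#' @param connectivity 4 or 8 for component labeling.
#' @param fill fill enclosed holes of the component before eroding
#'   (default TRUE; the cavity must remain inside the mask).
#' @return A [BinaryMask-class] with provenance \code{"mask"}.
#' @export
buildMask <- function(binary, erosionCoreRadius = 15, connectivity = 8,
                      fill = TRUE) {
  stopifnot(erosionCoreRadius >= 0)
  m <- .maskPixels(binary)
  lab <- labelComponents(m, connectivity)
  if (max(lab) == 0L) stop("no foreground component to mask")
  sizes <- tabulate(lab[lab > 0])
  comp <- lab == which.max(sizes)
  if (fill) comp <- fillHoles(comp, connectivity)
  out <- if (erosionCoreRadius > 0)
    erodeMask(comp, diskElement(erosionCoreRadius)) else comp
  if (!any(out))
    stop("erosion core too large: mask erosion annihilated the fruit component")
  BinaryMask(out, provenance = "mask")
}

#' Multiply an image by a mask
#'
#' Stage C: intensities are preserved inside the mask and set to zero
#' outside it.
#'
#' @param image a [SliceImage-class].
#' @param mask a [BinaryMask-class] or logical matrix of the same dimensions.
#' @return A [SliceImage-class] with the exterior zeroed.
#' @export
applyMask <- function(image, mask) {
  stopifnot(is(image, "SliceImage"))
  m <- .maskPixels(mask)
  if (!identical(dim(image@pixels), dim(m)))
    stop("image and mask dimensions differ")
  vr <- image@valueRange
  SliceImage(image@pixels * m, valueRange = c(min(0, vr[1]), vr[2]),
             sectionKind = image@sectionKind)
}

#' Isolate the central cavity candidate
#'
#' Stage D: dark (at-or-below-threshold) pixels inside the mask become
#' candidate-cavity foreground; the zeroed exterior is treated as background
#' so it cannot merge with the cavity.  Among candidate components the
#' cavity is the one whose centroid is nearest the fruit centroid (ties go
#' to the larger component), reflecting that compression damage concentrates
#' near the fruit axis.
#'
#' @param masked a [SliceImage-class] produced by [applyMask()].
#' @param params a [SegmentationParams-class].
#' @param mask optional [BinaryMask-class]/logical matrix delimiting the
#'   fruit interior; defaults to the nonzero pixels of \code{masked}.
#' @param threshold optional darkness threshold; defaults to the params'
#'   fixed value or an Otsu threshold of the in-mask intensities.
#' @return A [BinaryMask-class] (single component) with provenance
#'   \code{"cavity"}.
#' @export
isolateCavity <- function(masked, params = SegmentationParams(), mask = NULL,
                          threshold = NULL) {
  stopifnot(is(masked, "SliceImage"))
  px <- masked@pixels
  m <- if (is.null(mask)) px > 0 else .maskPixels(mask)
  if (!any(m)) stop("no cavity found: empty fruit mask")
  if (is.null(threshold)) threshold <- .resolveThreshold(px[m], params)
  cand <- m & (px <= threshold)
  lab <- labelComponents(cand, params@connectivity)
  if (max(lab) == 0L)
    stop("no cavity found: no dark component inside the mask")
  stats <- .componentStats(lab)
  midx <- which(m, arr.ind = TRUE)
  centre <- c(mean(midx[, 1]), mean(midx[, 2]))
  d <- sqrt((stats$row - centre[1])^2 + (stats$col - centre[2])^2)
  best <- order(d, -stats$size)[1]
  BinaryMask(lab == stats$id[best], provenance = "cavity")
}

#' Refine a cavity candidate
#'
#' Stages E and F: dilation followed by erosion (a morphological closing)
#' of the candidate cavity, so that bright blockage fragments enclosed by
#' the cavity are severed from any thin connection to the exterior tissue.
#'
#' @param candidate a [BinaryMask-class] or logical matrix.
#' @param params a [SegmentationParams-class] supplying the two radii.
#' @return A [BinaryMask-class] with provenance \code{"refined"}.
#' @export
refineCandidate <- function(candidate, params = SegmentationParams()) {
  m <- .maskPixels(candidate)
  if (!any(m)) stop("cannot refine an empty candidate mask")
  if (params@refineDilateRadius > 0)
    m <- dilateMask(m, diskElement(params@refineDilateRadius))
  if (params@refineErodeRadius > 0)
    m <- erodeMask(m, diskElement(params@refineErodeRadius))
  if (!any(m)) stop("refinement emptied the cavity mask")
  BinaryMask(m, provenance = "refined")
}

#' Classify a cavity as blocked or unblocked
#'
#' A cavity is blocked when bright (above-threshold) pixels fully enclosed
#' by the cavity region strictly exceed \code{blockageFractionThreshold}
#' times the cavity area.
#'
#' @param candidate the isolated cavity component ([BinaryMask-class]).
#' @param masked the masked [SliceImage-class] the candidate came from.
#' @param params a [SegmentationParams-class].
#' @param threshold brightness threshold; defaults as in [isolateCavity()].
#' @return logical: \code{TRUE} if blocked.
#' @export
classifyBlockage <- function(candidate, masked,
                             params = SegmentationParams(),
                             threshold = NULL) {
  m <- .maskPixels(candidate)
  px <- masked@pixels
  if (is.null(threshold)) threshold <- .resolveThreshold(px[px > 0], params)
  part <- .backgroundPartition(m, params@connectivity)
  holes <- matrix(part$labels %in% part$holes, nrow(m), ncol(m))
  enclosedBright <- sum(holes & (px > threshold))
  enclosedBright > params@blockageFractionThreshold * sum(m)
}

## Seed pixel for region growing, per the configured rule.
.resolveSeed <- function(candidate, params) {
  switch(params@seedRule,
    cavity_centroid = {
      idx <- which(.maskPixels(candidate), arr.ind = TRUE)
      round(c(mean(idx[, 1]), mean(idx[, 2])))
    },
    image_center = round((dim(.maskPixels(candidate)) + 1) / 2),
    explicit = round(params@seedPoint))
}

#' Extract the central cavity and measure its area
#'
#' Runs the full pipeline in order: binarization (A), mask construction (B),
#' image multiplication (C), cavity isolation (D), and — for blocked
#' cavities only — refinement (E, F) and region-growing fill (G).  For an
#' unblocked cavity the dark candidate component's pixel count is the area
#' directly; for a blocked cavity the area is the pixel count of the fully
#' filled (blockage-absorbing) region-grown mask.  All intermediates are
#' retained for audit; stage failures are re-signalled with the failing
#' stage named.
#'
#' @param image a [SliceImage-class].
#' @param params a [SegmentationParams-class].
#' @return A [CavityResult-class].
#' @examples
#' ph <- generateSection(PhantomSpec(imageSize = 160, fruitRadius = 66,
#'                                   peelThickness = 7, cavityRadius = 20,
#'                                   noiseSd = 0, seed = 7))
#' res <- extractCavity(ph$image, SegmentationParams(
#'   erosionCoreRadius = c(cross = 6, longitudinal = 9)))
#' areaPx(res) / cavityArea(ph$truth)
#' @export
extractCavity <- function(image, params = SegmentationParams()) {
  stopifnot(is(image, "SliceImage"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  binary <- stage("A (binarize)", binarize(image, params))
  thr <- attr(binary, "threshold")
  radius <- unname(params@erosionCoreRadius[image@sectionKind])
  mask <- stage("B (build mask)",
                buildMask(binary, radius, params@connectivity))
  masked <- stage("C (apply mask)", applyMask(image, mask))
  candidate <- stage("D (isolate cavity)",
                     isolateCavity(masked, params, mask = mask,
                                   threshold = thr))
  blocked <- classifyBlockage(candidate, masked, params, threshold = thr)
  inter <- list(binarized = binary, mask = mask, masked = masked,
                candidate = candidate)
  if (blocked) {
    refined <- stage("E/F (refine)", refineCandidate(candidate, params))
    seed <- .resolveSeed(refined, params)
    filled <- stage("G (region growing)",
                    regionGrowFill(refined, seed, params@connectivity))
    inter$refined <- refined
    inter$filled <- filled
  } else {
    filled <- BinaryMask(.maskPixels(candidate), provenance = "filled")
    inter$filled <- filled
  }
  new("CavityResult", filledMask = filled,
      areaPx = sum(filled@pixels), blocked = blocked, threshold = thr,
      intermediates = inter, params = params)
}

#' Render a cavity mask as a synthetic section image
#'
#' Renders a binary cavity mask back into a [SliceImage-class] (dark cavity
#' on bright tissue), e.g. to re-run [extractCavity()] on a previous result
#' for an idempotence audit.
#'
#' @param mask a [BinaryMask-class] or logical matrix (foreground = cavity).
#' @param cavityLevel,tissueLevel intensities for cavity and surrounding
#'   tissue.
#' @param sectionKind section kind of the rendered image.
#' @return A [SliceImage-class] with value range \code{c(0, 255)}.
#' @export
renderMaskImage <- function(mask, cavityLevel = 15, tissueLevel = 170,
                            sectionKind = "cross") {
  m <- .maskPixels(mask)
  SliceImage(ifelse(m, cavityLevel, tissueLevel), valueRange = c(0, 255),
             sectionKind = sectionKind)
}
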