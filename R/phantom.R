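## Synthetic fruit-section phantom generator.  Renders the structures the
## segmentation pipeline must cope with -- bright peel annulus, pulp wedges
## separated by darker septa, a dark lobed-elliptical central cavity,
## optional bright blockage fragments inside the cavity, point-like pulp
## ruptures, additive Gaussian noise -- with exact pixel-level ground truth.

## Label codes of the truth grid.
.LBL <- c(background = 0L, cavity = 1L, pulp = 2L, septum = 3L, peel = 4L,
          blockage = 5L, rupture = 6L)

## Evaluate expr under a temporary RNG state seeded with `seed`.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a synthetic fruit section with ground truth
#'
#' Renders the phantom described by \code{spec} and returns the noisy image
#' together with the exact (pre-noise) label grid and pixel counts.  The
#' cavity area in the truth is the exact count of pixels assigned to the
#' cavity region (blockage fragments included, since blockage is displaced
#' pulp inside the cavity).  Identical specs (including the seed) render
#' byte-identical images and truths.
#'
#' @param spec a [PhantomSpec-class].
#' @return A list with elements \code{image} ([SliceImage-class]) and
#'   \code{truth} ([PhantomTruth-class]).
#' @examples
#' ph <- generateSection(PhantomSpec(imageSize = 128, fruitRadius = 52,
#'                                   peelThickness = 6, cavityRadius = 15,
#'                                   noiseSd = 0))
#' cavityArea(ph$truth)
#' @export
generateSection <- function(spec) {
  validObject(spec)
  .withSeed(spec@seed, .renderSection(spec))
}

.renderSection <- function(spec) {
  n <- as.integer(spec@imageSize)
  lv <- spec@intensityLevels
  vr <- c(0, 255)
  ctr <- (n + 1) / 2
  dy <- matrix(seq_len(n) - ctr, n, n)        # row offset
  dx <- t(dy)                                 # column offset

  # fruit outline: circle for cross sections, vertically squashed ellipse
  # for longitudinal sections (mandarins are wider than tall)
  fy <- if (spec@sectionKind == "longitudinal") 0.8 else 1
  R <- spec@fruitRadius
  Ri <- R - spec@peelThickness
  inFruit <- (dy / (fy * R))^2 + (dx / R)^2 <= 1
  inPulp <- (dy / (fy * Ri))^2 + (dx / Ri)^2 <= 1

  labels <- matrix(.LBL["background"], n, n)
  labels[inFruit] <- .LBL["peel"]
  labels[inPulp] <- .LBL["pulp"]

  # septa: radial lines between pulp wedges, rotated by a seeded phase
  rot <- stats::runif(1, 0, 2 * pi)
  if (spec@nSegments >= 2 && spec@septumWidth > 0) {
    half <- spec@septumWidth / 2
    for (j in seq_len(as.integer(spec@nSegments))) {
      a <- rot + 2 * pi * j / spec@nSegments
      along <- dx * cos(a) + dy * sin(a)
      perp <- abs(dx * sin(a) - dy * cos(a))
      sep <- inPulp & along > 0 & perp <= half
      labels[sep] <- .LBL["septum"]
    }
  }

  # cavity: lobed ellipse, overrides pulp and septa
  phase <- stats::runif(1, 0, 2 * pi)
  a1 <- spec@cavityRadius[1]; a2 <- spec@cavityRadius[2]
  if (a1 > 0 && a2 > 0) {
    mod <- 1 + spec@lobeAmplitude *
      cos(spec@lobeCount * atan2(dy, dx) + phase)
    inCavity <- (dy / a1)^2 + (dx / a2)^2 <= mod^2
  } else inCavity <- matrix(FALSE, n, n)
  labels[inCavity] <- .LBL["cavity"]
  cavityAreaPx <- sum(inCavity)

  # blockage: 1-5 convex bright fragments wholly inside the cavity
  if (spec@blockageFraction > 0 && cavityAreaPx > 0) {
    target <- round(spec@blockageFraction * cavityAreaPx)
    if (target >= 1) .placeBlockage(labels, inCavity, target) -> labels
  }
  blockageAreaPx <- sum(labels == .LBL["blockage"])

  # point-like pulp ruptures, kept clear of the cavity
  if (spec@ruptureCount > 0) {
    margin <- dilateMask(inCavity, diskElement(5))
    ok <- which(labels == .LBL["pulp"] & !margin &
                  (dy / (fy * (Ri - 4)))^2 + (dx / (Ri - 4))^2 <= 1)
    if (length(ok)) {
      pts <- ok[sample.int(length(ok),
                           min(spec@ruptureCount, length(ok)))]
      dot <- matrix(FALSE, n, n); dot[pts] <- TRUE
      dot <- dilateMask(dot, diskElement(1.5))
      labels[dot & labels == .LBL["pulp"]] <- .LBL["rupture"]
    }
  }

  px <- matrix(lv[["background"]], n, n)
  for (nm in c("peel", "pulp", "septum", "cavity", "blockage", "rupture"))
    px[labels == .LBL[nm]] <- lv[[nm]]
  if (spec@noiseSd > 0) {
    px <- px + stats::rnorm(length(px), 0, spec@noiseSd)
    px <- pmin(pmax(px, vr[1]), vr[2])
  }
  if (spec@invert) px <- vr[1] + vr[2] - px

  image <- SliceImage(px, valueRange = vr, sectionKind = spec@sectionKind)
  truth <- new("PhantomTruth",
               cavityAreaPx = as.numeric(cavityAreaPx),
               blockageAreaPx = as.numeric(blockageAreaPx),
               blocked = blockageAreaPx > 0,
               labels = labels, spec = spec)
  list(image = image, truth = truth)
}

## Place convex disk fragments of ~`target` total pixels inside the cavity,
## at least 2 px clear of the cavity boundary.  Mutates and returns labels.
.placeBlockage <- function(labels, inCavity, target) {
  nFrag <- sample.int(5L, 1L)
  placed <- matrix(FALSE, nrow(labels), ncol(labels))
  centres <- NULL
  remaining <- target
  for (f in seq_len(nFrag)) {
    if (remaining < 1) break
    af <- remaining / (nFrag - f + 1)
    rf <- max(1, sqrt(af / pi))
    allowed <- erodeMask(inCavity, diskElement(rf + 2))
    while (!any(allowed) && rf > 1) {       # shrink until it fits
      rf <- rf / 2
      allowed <- erodeMask(inCavity, diskElement(rf + 2))
    }
    if (!any(allowed)) next
    ok <- which(allowed)
    ctr <- ok[sample.int(length(ok), 1L)]
    # prefer centres separated from earlier fragments (20 tries)
    if (!is.null(centres)) {
      for (try in 1:20) {
        rc <- arrayInd(ctr, dim(labels))
        if (all(sqrt((centres[, 1] - rc[1])^2 +
                     (centres[, 2] - rc[2])^2) > 2 * rf)) break
        ctr <- ok[sample.int(length(ok), 1L)]
      }
    }
    rc <- arrayInd(ctr, dim(labels))
    centres <- rbind(centres, rc)
    frag <- matrix(FALSE, nrow(labels), ncol(labels))
    frag[ctr] <- TRUE
    frag <- dilateMask(frag, diskElement(rf))
    frag <- frag & inCavity & !placed
    placed <- placed | frag
    remaining <- remaining - sum(frag)
  }
  labels[placed] <- .LBL["blockage"]
  labels
}

#' Add clipped Gaussian noise to an image
#'
#' Additive zero-mean Gaussian noise, clipped to the image's value range;
#' deterministic for a given seed.  \code{noiseSd = 0} returns the input
#' unchanged.
#'
#' @param image a [SliceImage-class].
#' @param noiseSd noise standard deviation (intensity units, >= 0).
#' @param seed RNG seed.
#' @return A [SliceImage-class].
#' @export
addNoise <- function(image, noiseSd, seed = 1) {
  stopifnot(is(image, "SliceImage"), noiseSd >= 0)
  if (noiseSd == 0) return(image)
  vr <- image@valueRange
  px <- .withSeed(seed,
                  image@pixels + stats::rnorm(length(image@pixels), 0, noiseSd))
  SliceImage(pmin(pmax(px, vr[1]), vr[2]), valueRange = vr,
             sectionKind = image@sectionKind)
}

#' Damage models: deformation to cavity growth
#'
#' A damage model maps a compression deformation (mm) to the factor by which
#' the cavity area grows and the blockage fraction of the post-compression
#' cavity.  \code{identityDamageModel} leaves the fruit untouched.
#' \code{tableCalibratedDamageModel} is calibrated to the study conditions:
#' group-mean damage rates of 3.82, 5.74, 10.81 and 16.58 percent at 4, 8,
#' 12 and 16 mm (linearly interpolated, linearly extrapolated beyond 16 mm),
#' with per-fruit Gaussian scatter matching the reported group standard
#' deviations (0.35, 0.46, 0.89, 1.07), truncated at zero; blockage appears
#' above 10 mm, ramping to a blockage fraction of 0.15 at 12 mm and 0.25 at
#' 16 mm.
#'
#' @param deformationMm compression deformation in mm (>= 0).
#' @return A list with elements \code{areaScale} (>= 1 cavity area scale
#'   factor) and \code{blockageFraction} (in [0,1]).
#' @export
tableCalibratedDamageModel <- function(deformationMm) {
  stopifnot(deformationMm >= 0)
  xs <- c(0, 4, 8, 12, 16)
  mus <- c(0, 3.82, 5.74, 10.81, 16.58)
  sds <- c(0, 0.35, 0.46, 0.89, 1.07)
  interp <- function(v, x) {
    if (x <= 16) stats::approx(xs, v, xout = x)$y
    else v[5] + (v[5] - v[4]) / 4 * (x - 16)    # extend the last segment
  }
  mu <- interp(mus, deformationMm)
  sd <- interp(sds, deformationMm)
  A <- max(0, stats::rnorm(1, mu, sd))
  bf <- if (deformationMm <= 10) 0
        else min(0.25, stats::approx(c(10, 12, 16), c(0, 0.15, 0.25),
                                     xout = min(deformationMm, 16))$y)
  list(areaScale = 1 + A / 100, blockageFraction = bf)
}

#' @rdname tableCalibratedDamageModel
#' @export
identityDamageModel <- function(deformationMm) {
  stopifnot(deformationMm >= 0)
  list(areaScale = 1, blockageFraction = 0)
}

#' Generate a matched pre/post compression phantom pair
#'
#' Renders the pre-compression section from \code{spec}, applies the damage
#' model to obtain the post-compression cavity scale factor and blockage
#' fraction, and renders the post section with the cavity semi-axes enlarged
#' by the square root of the area scale (so the cavity area grows by the
#' requested factor up to pixel discretization).  Both sections share the
#' spec's seed, so they depict the same fruit (same wedge rotation and
#' cavity lobe phase) before and after compression.  The true damage rate
#' is computed from the exact pixel truths.
#'
#' @param spec a [PhantomSpec-class] describing the undamaged fruit.
#' @param deformationMm compression deformation in mm (>= 0).
#' @param damageModel a function of deformation returning
#'   \code{list(areaScale, blockageFraction)}; see
#'   [tableCalibratedDamageModel()].  Any randomness inside it is seeded
#'   from \code{spec@seed}, so pairs are reproducible.
#' @return A [PhantomPair-class].
#' @examples
#' p <- generatePair(PhantomSpec(imageSize = 128, fruitRadius = 52,
#'                               peelThickness = 6, cavityRadius = 16,
#'                               noiseSd = 0, lobeAmplitude = 0),
#'                   deformationMm = 0, damageModel = identityDamageModel)
#' trueDamageRate(p)
#' @export
generatePair <- function(spec, deformationMm,
                         damageModel = tableCalibratedDamageModel) {
  if (deformationMm < 0) stop("deformation must be >= 0")
  dmSeed <- (abs(spec@seed) + 499979) %% 2147483647
  dm <- .withSeed(dmSeed, damageModel(deformationMm))
  stopifnot(dm$areaScale >= 1, dm$blockageFraction >= 0,
            dm$blockageFraction <= 1)
  pre <- generateSection(spec)
  postSpec <- spec
  postSpec@cavityRadius <- spec@cavityRadius * sqrt(dm$areaScale)
  postSpec@blockageFraction <- dm$blockageFraction
  validObject(postSpec)
  post <- generateSection(postSpec)
  s1 <- pre$truth@cavityAreaPx
  s2 <- post$truth@cavityAreaPx
  new("PhantomPair", preImage = pre$image, postImage = post$image,
      preTruth = pre$truth, postTruth = post$truth,
      deformationMm = deformationMm,
      trueDamageRate = (s2 - s1) / s1 * 100)
}
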