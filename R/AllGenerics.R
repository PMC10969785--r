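#' @name pulpscan-accessors
#' @title Accessors for pulpscan classes
#' @description Slot accessors for the package's S4 classes; user code should
#'   use these rather than reach into slots with \code{@}.
#' @param x an object of the documented class.
#' @return The slot value (see the individual accessor).
NULL

#' @describeIn pulpscan-accessors intensity or logical pixel matrix.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @describeIn pulpscan-accessors valid intensity range of a [SliceImage-class].
#' @export
setGeneric("valueRange", function(x) standardGeneric("valueRange"))

#' @describeIn pulpscan-accessors section kind (\code{"cross"} or
#'   \code{"longitudinal"}).
#' @export
setGeneric("sectionKind", function(x) standardGeneric("sectionKind"))

#' @describeIn pulpscan-accessors producing stage of a [BinaryMask-class].
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @describeIn pulpscan-accessors cavity pixel area of a [CavityResult-class].
#' @export
setGeneric("areaPx", function(x) standardGeneric("areaPx"))

#' @describeIn pulpscan-accessors blockage classification.
#' @export
setGeneric("isBlocked", function(x) standardGeneric("isBlocked"))

#' @describeIn pulpscan-accessors ordered list of stage intermediates of a
#'   [CavityResult-class].
#' @export
setGeneric("intermediates", function(x) standardGeneric("intermediates"))

#' @describeIn pulpscan-accessors true cavity pixel area of a
#'   [PhantomTruth-class] (blockage included).
#' @export
setGeneric("cavityArea", function(x) standardGeneric("cavityArea"))

#' @describeIn pulpscan-accessors true blockage pixel area.
#' @export
setGeneric("blockageArea", function(x) standardGeneric("blockageArea"))

#' @describeIn pulpscan-accessors true damage rate (percent) of a
#'   [PhantomPair-class].
#' @export
setGeneric("trueDamageRate", function(x) standardGeneric("trueDamageRate"))

setMethod("pixels", "SliceImage", function(x) x@pixels)
setMethod("pixels", "BinaryMask", function(x) x@pixels)
setMethod("valueRange", "SliceImage", function(x) x@valueRange)
setMethod("sectionKind", "SliceImage", function(x) x@sectionKind)
setMethod("sectionKind", "PhantomSpec", function(x) x@sectionKind)
setMethod("provenance", "BinaryMask", function(x) x@provenance)
setMethod("areaPx", "CavityResult", function(x) x@areaPx)
setMethod("isBlocked", "CavityResult", function(x) x@blocked)
setMethod("isBlocked", "PhantomTruth", function(x) x@blocked)
setMethod("intermediates", "CavityResult", function(x) x@intermediates)
setMethod("cavityArea", "PhantomTruth", function(x) x@cavityAreaPx)
setMethod("blockageArea", "PhantomTruth", function(x) x@blockageAreaPx)
setMethod("trueDamageRate", "PhantomPair", function(x) x@trueDamageRate)

#' @describeIn pulpscan-accessors slope and intercept of a [RateModel-class].
#' @param object,... a [RateModel-class] (stats generic signature).
#' @export
setMethod("coef", "RateModel", function(object, ...)
  c(intercept = object@intercept, slope = object@slope))

#' @describeIn pulpscan-accessors residuals of a [RateModel-class] fit.
#' @export
setMethod("residuals", "RateModel", function(object, ...) object@residuals)

setMethod("show", "SliceImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SliceImage: %d x %d %s section, intensities in [%g, %g] (range [%g, %g])\n",
              d[1], d[2], object@sectionKind,
              min(object@pixels), max(object@pixels),
              object@valueRange[1], object@valueRange[2]))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("BinaryMask [%s]: %d x %d, %d foreground px\n",
              object@provenance, d[1], d[2], sum(object@pixels)))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: cavity %d px, blockage %d px (%s)\n",
              as.integer(object@cavityAreaPx),
              as.integer(object@blockageAreaPx),
              if (object@blocked) "blocked" else "unblocked"))
})

setMethod("show", "PhantomPair", function(object) {
  cat(sprintf("PhantomPair: deformation %g mm, S1 = %d px, S2 = %d px, true A = %.3f%%\n",
              object@deformationMm,
              as.integer(object@preTruth@cavityAreaPx),
              as.integer(object@postTruth@cavityAreaPx),
              object@trueDamageRate))
})

setMethod("show", "CavityResult", function(object) {
  cat(sprintf("CavityResult: area %d px, %s (threshold %.4g, stages: %s)\n",
              as.integer(object@areaPx),
              if (object@blocked) "blocked" else "unblocked",
              object@threshold,
              paste(names(object@intermediates), collapse = " -> ")))
})

setMethod("show", "RateModel", function(object) {
  cat(sprintf("RateModel %s: %s  (R^2 = %.2f, slope p = %.3g, n = %d)\n",
              object@response, formatModelEquation(object),
              object@rSquared, object@slopePValue, as.integer(object@n)))
})

setMethod("show", "RunReport", function(object) {
  cat(sprintf("RunReport: %d samples (%d failed), %d deformation groups, %d fitted models\n",
              nrow(object@records) + nrow(object@failures),
              nrow(object@failures), nrow(object@summaries),
              length(object@models)))
})
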