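## Binary morphology primitives used by the cavity pipeline.  The heavy
## loops live in src/morphology.cpp; these wrappers define the conventions
## (disk elements, outside-the-image = background, connectivity 4/8).

.maskPixels <- function(x) {
  if (is(x, "BinaryMask")) return(x@pixels)
  x <- as.matrix(x)
  if (!is.logical(x)) x <- x != 0
  x
}

#' Disk-shaped structuring element
#'
#' Logical matrix of the pixels whose centre lies within Euclidean distance
#' \code{radius} of the anchor; \code{radius = 0} gives the 1 x 1 identity
#' element.
#'
#' @param radius disk radius in pixels (non-negative; fractional allowed).
#' @return Logical (2r+1) x (2r+1) matrix.
#' @examples
#' diskElement(1)  # the 4-neighbourhood cross
#' @export
diskElement <- function(radius) {
  stopifnot(radius >= 0)
  r <- floor(radius)
  d <- seq(-r, r)
  outer(d, d, function(i, j) i * i + j * j <= radius * radius)
}

#' Binary erosion and dilation
#'
#' Set-definition morphology with pixels outside the image treated as
#' background: erosion keeps a pixel when the whole structuring element fits
#' in the foreground around it; dilation paints the element over every
#' foreground pixel.
#'
#' @param x logical matrix or [BinaryMask-class].
#' @param se logical structuring-element matrix with odd dimensions
#'   (e.g. from [diskElement()]).
#' @return Logical matrix of the same dimensions as \code{x}.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
#' sum(dilateMask(m, diskElement(1)))  # the 5-pixel cross
#' @export
erodeMask <- function(x, se) {
  x <- .maskPixels(x)
  se <- .maskPixels(se)
  stopifnot(nrow(se) %% 2 == 1, ncol(se) %% 2 == 1)
  .cpp_erode(x, se)
}

#' @rdname erodeMask
#' @export
dilateMask <- function(x, se) {
  x <- .maskPixels(x)
  se <- .maskPixels(se)
  stopifnot(nrow(se) %% 2 == 1, ncol(se) %% 2 == 1)
  .cpp_dilate(x, se)
}

#' Connected-component labeling
#'
#' Labels foreground components 1, 2, ... in raster order of first
#' encounter; background is 0.
#'
#' @param x logical matrix or [BinaryMask-class].
#' @param connectivity 4 or 8 (default 8).
#' @return Integer matrix of labels.
#' @export
labelComponents <- function(x, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  .cpp_label(.maskPixels(x), as.integer(connectivity))
}

## Component centroids and sizes from a label matrix.
.componentStats <- function(lab) {
  ids <- seq_len(max(lab))
  if (!length(ids))
    return(data.frame(id = integer(), size = integer(),
                      row = numeric(), col = numeric()))
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  data.frame(id = ids,
             size = as.integer(tabulate(l, nbins = length(ids))),
             row = as.numeric(tapply(idx[, 1], l, mean)),
             col = as.numeric(tapply(idx[, 2], l, mean)))
}

## Background components reachable from the image border ("exterior") vs
## enclosed ("holes"), under the given connectivity for the background.
.backgroundPartition <- function(mask, connectivity = 8) {
  bg <- !mask
  lab <- .cpp_label(bg, as.integer(connectivity))
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  list(labels = lab, exterior = border,
       holes = setdiff(seq_len(max(lab, 0)), border))
}

#' Fill enclosed holes of a binary mask
#'
#' Background components not connected to the image border are turned into
#' foreground.
#'
#' @inheritParams labelComponents
#' @return Logical matrix.
#' @export
fillHoles <- function(x, connectivity = 8) {
  mask <- .maskPixels(x)
  part <- .backgroundPartition(mask, connectivity)
  mask | (part$labels %in% part$holes &
            matrix(TRUE, nrow(mask), ncol(mask)))
}

#' Fill a cavity by seeded region growing
#'
#' Grows from a seed pixel across every pixel enclosed by the cavity
#' boundary: dark cavity pixels (mask foreground) and bright blockage pixels
#' (enclosed holes of the mask) alike, yielding a fully filled cavity mask.
#' The growth set is \{foreground\} union \{holes\}; the seed may sit on
#' either (a seed inside a blockage fragment still grows to the whole
#' cavity).  A seed in the exterior background is an error.
#'
#' @param x logical matrix or [BinaryMask-class]; foreground = candidate
#'   cavity pixels.
#' @param seed integer \code{c(row, col)} of the seed pixel.
#' @param connectivity 4 or 8 (default 8), used both for growth and for
#'   deciding which background is enclosed.
#' @return A [BinaryMask-class] with provenance \code{"filled"}.
#' @examples
#' ring <- matrix(FALSE, 9, 9)
#' ring[3:7, 3:7] <- TRUE; ring[4:6, 4:6] <- FALSE  # square annulus
#' sum(pixels(regionGrowFill(ring, c(5, 5))))       # 16 + 9 = 25
#' @export
regionGrowFill <- function(x, seed, connectivity = 8) {
  mask <- .maskPixels(x)
  seed <- as.integer(round(seed))
  if (length(seed) != 2L || anyNA(seed) ||
      seed[1] < 1L || seed[1] > nrow(mask) ||
      seed[2] < 1L || seed[2] > ncol(mask))
    stop("seed must be c(row, col) inside the image")
  part <- .backgroundPartition(mask, connectivity)
  bglab <- part$labels[seed[1], seed[2]]
  if (bglab > 0 && bglab %in% part$exterior)
    stop("seed lies in the exterior background, not inside a cavity region")
  grow <- mask | matrix(part$labels %in% part$holes, nrow(mask), ncol(mask))
  lab <- .cpp_label(grow, as.integer(connectivity))
  BinaryMask(lab == lab[seed[1], seed[2]], provenance = "filled")
}
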