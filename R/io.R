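## Reading and writing single-slice grayscale TIFFs via the tiff package.

#' Load a grayscale TIFF slice
#'
#' Reads an 8-, 16- or 32-bit single-channel TIFF.  Integer images are
#' returned on their native scale (0..255 or 0..65535) with the value range
#' set from the bit depth; 32-bit float images are returned as stored, on
#' the normalized [0, 1] scale.  Multi-channel (color) images and
#' unreadable files are rejected with a diagnosis.
#'
#' @param path path to the TIFF file.
#' @param sectionKind section kind to record on the image.
#' @return A [SliceImage-class].
#' @export
loadSlice <- function(path, sectionKind = "cross") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  info <- tryCatch(tiff::readTIFF(path, payload = FALSE),
                   error = function(e)
                     stop("not a readable TIFF (", conditionMessage(e), "): ",
                          path, call. = FALSE))
  if (info$samples.per.pixel[1] > 1L)
    stop("multi-channel color TIFF not supported (",
         info$samples.per.pixel[1], " channels): ", path)
  bits <- info$bits.per.sample[1]
  if (bits >= 32) {               # stored as normalized float
    px <- tiff::readTIFF(path)
    vr <- c(0, 1)
  } else {                        # native integer scale
    px <- tiff::readTIFF(path, as.is = TRUE)
    vr <- c(0, 2^bits - 1)
  }
  img <- matrix(as.numeric(px), nrow(px), ncol(px))
  vr[1] <- min(vr[1], min(img)); vr[2] <- max(vr[2], max(img))
  SliceImage(img, valueRange = vr, sectionKind = sectionKind)
}

#' Write a section image as a grayscale TIFF
#'
#' Intensities are mapped from the image's value range to the storage scale:
#' 8- and 16-bit integer TIFFs quantize to the native levels; 32-bit float
#' TIFFs store \code{(pixels - min) / (max - min)} in [0, 1].  An image
#' whose value range already is 0..255 round-trips exactly through the
#' 8-bit path when its intensities are integers.
#'
#' @param image a [SliceImage-class].
#' @param path output path.
#' @param bits 8, 16 or 32 bits per sample (32 = float).
#' @return \code{path}, invisibly.
#' @export
writeSlice <- function(image, path, bits = 8) {
  stopifnot(is(image, "SliceImage"), bits %in% c(8, 16, 32))
  vr <- image@valueRange
  norm <- (image@pixels - vr[1]) / (vr[2] - vr[1])
  tiff::writeTIFF(norm, path, bits.per.sample = as.integer(bits))
  invisible(path)
}
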