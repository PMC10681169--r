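#' Calibrated image
#'
#' A pixel raster together with the physical calibration and channel
#' semantics that every micron-denominated threshold downstream converts
#' through. Pixels are stored as an `H x W` matrix (single channel) or an
#' `H x W x C` array of integer intensities at the declared bit depth.
#'
#' Coordinate convention, used throughout the package: pixels are 0-based
#' with the origin at the top-left corner; `x` is the column index and `y`
#' the row index. The centre of pixel `(x, y)` lies at physical position
#' `((x + 0.5) * microns_per_pixel, (y + 0.5) * microns_per_pixel)`.
#' Grid and distance computations use half-open pixel intervals
#' `[start, end)` so that cells partition the raster exactly.
#'
#' @param pixels numeric matrix or 3-d array of non-negative integer
#'   intensities.
#' @param microns_per_pixel positive finite scalar; physical size of one
#'   pixel in microns. Mandatory: it is never inferred from the file.
#' @param channel_semantics character vector with one role name per
#'   channel (e.g. `c("red", "green", "blue")` for an RGB composite that
#'   the colour model will decompose). Defaults to `"red","green","blue"`
#'   for 3-channel input and `"gray"` for single-channel input.
#' @param bit_depth integer, 8 or 16; declared intensity range.
#'
#' @return An object of class `calibrated_image` with elements `pixels`,
#'   `microns_per_pixel`, `channel_semantics`, `bit_depth`.
#' @export
calibrated_image <- function(pixels, microns_per_pixel,
                             channel_semantics = NULL, bit_depth = 8L) {
  if (missing(microns_per_pixel) || is.null(microns_per_pixel))
    stop("microns_per_pixel is mandatory and is never inferred")
  stopifnot(is.numeric(microns_per_pixel), length(microns_per_pixel) == 1L,
            is.finite(microns_per_pixel), microns_per_pixel > 0)
  if (!is.array(pixels) && !is.matrix(pixels))
    stop("pixels must be a matrix or a 3-d array")
  nd <- length(dim(pixels))
  if (nd != 2L && nd != 3L) stop("pixels must have 2 or 3 dimensions")
  if (any(dim(pixels)[1:2] < 1L)) stop("image must be at least 1 x 1")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  vmax <- 2^bit_depth - 1
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > vmax)
    stop(sprintf("intensities outside [0, %d] for declared bit depth", vmax))
  nch <- if (nd == 2L) 1L else dim(pixels)[3]
  if (is.null(channel_semantics))
    channel_semantics <- if (nch == 3L) c("red", "green", "blue") else
      rep("gray", nch)
  if (length(channel_semantics) != nch)
    stop("channel_semantics length must equal the channel count")
  structure(list(pixels = pixels,
                 microns_per_pixel = microns_per_pixel,
                 channel_semantics = channel_semantics,
                 bit_depth = bit_depth),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("calibrated_image: %d x %d px, %d channel(s) [%s], %d-bit, %.4g um/px\n",
              d[1], d[2], length(x$channel_semantics),
              paste(x$channel_semantics, collapse = ","),
              x$bit_depth, x$microns_per_pixel))
  invisible(x)
}

#' @export
dim.calibrated_image <- function(x) dim(x$pixels)

#' Read a calibrated TIFF image
#'
#' Loads a single-plane or RGB TIFF without modifying pixel values and
#' attaches the physical calibration supplied by the caller. The
#' calibration is a required argument: whole-lobe stitches carry no
#' reliable resolution metadata, and a silently guessed scale would
#' corrupt every micron-denominated threshold downstream.
#'
#' @param path path to a TIFF file.
#' @inheritParams calibrated_image
#' @return A [calibrated_image].
#' @export
read_image <- function(path, microns_per_pixel, channel_semantics = NULL) {
  if (missing(microns_per_pixel) || is.null(microns_per_pixel))
    stop("microns_per_pixel is mandatory and is never inferred")
  if (!file.exists(path)) stop("file not found: ", path)
  px <- tiff::readTIFF(path, info = TRUE)
  bps <- attr(px, "bits.per.sample")
  if (is.null(bps)) bps <- 8L
  vmax <- 2^as.integer(bps) - 1
  px <- round(px * vmax)
  attributes(px) <- attributes(px)["dim"]
  calibrated_image(px, microns_per_pixel, channel_semantics,
                   bit_depth = as.integer(bps))
}

#' Write a calibrated image (or a mask) as TIFF
#'
#' Pixel values round-trip exactly at both 8 and 16 bit. Logical masks are
#' written as single-channel 8-bit images with values 0/255.
#'
#' @param image a [calibrated_image] or a logical matrix (mask).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (is.logical(image)) {
    tiff::writeTIFF(matrix(as.numeric(image), nrow(image)), path,
                    bits.per.sample = 8L)
    return(invisible(path))
  }
  stopifnot(inherits(image, "calibrated_image"))
  vmax <- 2^image$bit_depth - 1
  tiff::writeTIFF(image$pixels / vmax, path,
                  bits.per.sample = image$bit_depth)
  invisible(path)
}

#' Convert a physical length to pixels
#'
#' Returns `length_um / microns_per_pixel` without rounding; consumers
#' apply their own documented rounding rule (e.g. the quadrat grid rounds
#' to the nearest whole pixel with a floor of 1).
#'
#' @param length_um non-negative length in microns.
#' @param image a [calibrated_image], or a bare microns-per-pixel scalar.
#' @return length in pixels (real-valued).
#' @export
um_to_px <- function(length_um, image) {
  stopifnot(all(length_um >= 0))
  mpp <- if (inherits(image, "calibrated_image")) image$microns_per_pixel
         else image
  stopifnot(is.numeric(mpp), mpp > 0)
  length_um / mpp
}

#' @rdname um_to_px
#' @param length_px non-negative length in pixels.
#' @export
px_to_um <- function(length_px, image) {
  stopifnot(all(length_px >= 0))
  mpp <- if (inherits(image, "calibrated_image")) image$microns_per_pixel
         else image
  length_px * mpp
}
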