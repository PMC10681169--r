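#' HSV colour model for pixel classification
#'
#' Defines the per-pixel rules that separate the three colour classes of a
#' whole-lobe fluorescence image: fluorescent particle signal (red
#' microspheres or dsRed+ cells), tissue of any characteristic colour, and
#' the bright peri-airway autofluorescence that must be excluded from the
#' particle signal. Rules operate in hue/saturation/value space because
#' HSV ranges are robust to the brightness variation seen across a
#' stitched lobe; each rule is a pure function of a single pixel's channel
#' values, with no spatial context.
#'
#' A pixel matching the autofluorescence rule is never counted as particle
#' signal, regardless of the particle rule — autofluorescence acts as an
#' exclusion criterion for the particle class but still counts as tissue
#' for coverage purposes.
#'
#' @param particle_hue length-2 hue interval in degrees for the particle
#'   class; may wrap through 0 (default `c(330, 30)`, i.e. red).
#' @param particle_s_min,particle_v_min minimum saturation / value (0-1)
#'   for the particle class.
#' @param autofluor_hue hue interval in degrees for the autofluorescence
#'   class (default green-yellow, `c(55, 105)`).
#' @param autofluor_s_min,autofluor_v_min minimum saturation / value for
#'   the autofluorescence class.
#' @param tissue_v_min minimum value (brightness, 0-1) above which a pixel
#'   counts as tissue; background and airway lumens fall below it.
#' @param min_object_px optional small-object removal: connected particle
#'   components smaller than this many pixels are dropped. Default 0 (off),
#'   keeping the masks minimally processed.
#' @return An object of class `color_model`.
#' @export
color_model <- function(particle_hue = c(330, 30),
                        particle_s_min = 0.40, particle_v_min = 0.30,
                        autofluor_hue = c(55, 105),
                        autofluor_s_min = 0.40, autofluor_v_min = 0.50,
                        tissue_v_min = 0.08,
                        min_object_px = 0L) {
  stopifnot(length(particle_hue) == 2L, length(autofluor_hue) == 2L,
            particle_s_min >= 0, particle_s_min <= 1,
            particle_v_min >= 0, particle_v_min <= 1,
            autofluor_s_min >= 0, autofluor_s_min <= 1,
            autofluor_v_min >= 0, autofluor_v_min <= 1,
            tissue_v_min >= 0, tissue_v_min <= 1,
            min_object_px >= 0)
  structure(list(particle_hue = particle_hue,
                 particle_s_min = particle_s_min,
                 particle_v_min = particle_v_min,
                 autofluor_hue = autofluor_hue,
                 autofluor_s_min = autofluor_s_min,
                 autofluor_v_min = autofluor_v_min,
                 tissue_v_min = tissue_v_min,
                 min_object_px = as.integer(min_object_px)),
            class = "color_model")
}

# hue interval membership, handling intervals that wrap through 0/360
hue_in_range <- function(h, range) {
  lo <- range[1] %% 360; hi <- range[2] %% 360
  if (lo <= hi) h >= lo & h <= hi else h >= lo | h <= hi
}

# H x W x 3 integer array -> list of H x W matrices h (deg), s, v (0-1)
pixel_hsv <- function(image) {
  px <- image$pixels
  stopifnot(length(dim(px)) == 3L, dim(px)[3] == 3L)
  d <- dim(px)[1:2]
  vmax <- 2^image$bit_depth - 1
  m <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = vmax)
  list(h = matrix(hsv[1, ] * 360, d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

check_rgb <- function(image) {
  if (length(dim(image$pixels)) != 3L || dim(image$pixels)[3] != 3L)
    stop("colour classification requires a 3-channel (RGB) image")
}

autofluor_rule <- function(hsv, model)
  hue_in_range(hsv$h, model$autofluor_hue) &
    hsv$s >= model$autofluor_s_min & hsv$v >= model$autofluor_v_min

particle_rule <- function(hsv, model)
  hue_in_range(hsv$h, model$particle_hue) &
    hsv$s >= model$particle_s_min & hsv$v >= model$particle_v_min

#' Build the particle-signal mask
#'
#' True exactly where the particle colour rule holds and the
#' autofluorescence rule does not. Optionally removes connected particle
#' components below `min_object_px` pixels.
#'
#' @param image a [calibrated_image] with 3 channels.
#' @param model a [color_model].
#' @return logical `H x W` matrix.
#' @export
build_particle_mask <- function(image, model = color_model()) {
  check_rgb(image)
  hsv <- pixel_hsv(image)
  m <- particle_rule(hsv, model) & !autofluor_rule(hsv, model)
  if (model$min_object_px >= 2L && any(m)) {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(m * 1)))
    keep <- which(tabulate(lab[lab > 0]) >= model$min_object_px)
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  m
}

#' Build the tissue-coverage mask
#'
#' True where the pixel shows any tissue-characteristic colour, including
#' peri-airway autofluorescence (autofluorescent pixels are excluded from
#' particle signal but are plainly tissue for coverage purposes). Airway
#' lumens and off-lobe background are False.
#'
#' @inheritParams build_particle_mask
#' @return logical `H x W` matrix.
#' @export
build_tissue_mask <- function(image, model = color_model()) {
  check_rgb(image)
  hsv <- pixel_hsv(image)
  hsv$v >= model$tissue_v_min | autofluor_rule(hsv, model)
}

#' Classify pixels into the three colour classes
#'
#' Runs the particle, tissue and autofluorescence rules in one pass and
#' returns the three masks that drive all downstream quantification. The
#' invariants `particle & autofluor == empty` and `autofluor` contained in
#' `tissue` are enforced by construction.
#'
#' @inheritParams build_particle_mask
#' @return An object of class `class_masks`: list with logical matrices
#'   `particle`, `tissue`, `autofluor` and a `model` element recording the
#'   colour model used (provenance).
#' @export
classify_pixels <- function(image, model = color_model()) {
  check_rgb(image)
  hsv <- pixel_hsv(image)
  af <- autofluor_rule(hsv, model)
  pm <- particle_rule(hsv, model) & !af
  if (model$min_object_px >= 2L && any(pm)) {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(pm * 1)))
    keep <- which(tabulate(lab[lab > 0]) >= model$min_object_px)
    pm <- matrix(lab %in% keep, nrow(pm), ncol(pm))
  }
  tm <- hsv$v >= model$tissue_v_min | af
  structure(list(particle = pm, tissue = tm, autofluor = af, model = model),
            class = "class_masks")
}

#' Construct class masks from user-supplied rasters
#'
#' For segmentations produced outside the package (e.g. expert
#' annotation). Enforces the class invariants: equal shapes,
#' `particle & autofluor` empty (autofluorescent pixels are removed from
#' the particle mask), and `autofluor` contained in `tissue`
#' (autofluorescent pixels are added to the tissue mask).
#'
#' @param particle,tissue,autofluor logical `H x W` matrices.
#' @param model optional provenance (a [color_model] or description).
#' @return A `class_masks` object.
#' @export
class_masks <- function(particle, tissue,
                        autofluor = matrix(FALSE, nrow(particle),
                                           ncol(particle)),
                        model = NULL) {
  stopifnot(is.logical(particle), is.logical(tissue), is.logical(autofluor),
            identical(dim(particle), dim(tissue)),
            identical(dim(particle), dim(autofluor)))
  structure(list(particle = particle & !autofluor,
                 tissue = tissue | autofluor,
                 autofluor = autofluor, model = model),
            class = "class_masks")
}

#' @export
print.class_masks <- function(x, ...) {
  cat(sprintf("class_masks: %d x %d px; particle %d, tissue %d, autofluor %d px\n",
              nrow(x$particle), ncol(x$particle),
              sum(x$particle), sum(x$tissue), sum(x$autofluor)))
  invisible(x)
}
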