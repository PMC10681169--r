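#' Airway geometry
#'
#' Holds the airway lumen mask used as the reference structure for
#' peri-airway proximity analysis, together with the detection floor and
#' the provenance of the mask (expert annotation file or derivation from
#' the tissue mask).
#'
#' @param lumen_mask logical raster; TRUE inside airway lumens.
#' @param min_lumen_area_um2 area floor used (or to be used) to separate
#'   medium/large airways from alveolar spaces.
#' @param source `"annotation_file"` or `"derived_from_tissue_mask"`.
#' @return An object of class `airway_geometry`.
#' @export
airway_geometry <- function(lumen_mask, min_lumen_area_um2 = 5000,
                            source = c("derived_from_tissue_mask",
                                       "annotation_file")) {
  source <- match.arg(source)
  stopifnot(is.logical(lumen_mask), is.matrix(lumen_mask),
            min_lumen_area_um2 > 0)
  structure(list(lumen_mask = lumen_mask,
                 min_lumen_area_um2 = min_lumen_area_um2,
                 source = source),
            class = "airway_geometry")
}

#' Derive airway lumens from a tissue mask
#'
#' Airway lumens are the holes in the tissue: connected non-tissue
#' components fully enclosed by tissue (components touching the image
#' border are off-lobe background, never lumens), filtered by an area
#' floor that separates medium and large airways from alveolar spaces.
#' When an expert annotation mask is available it should be used instead
#' (see [proximity_fraction()]); hole derivation is a heuristic.
#'
#' @param tissue_mask logical raster from [build_tissue_mask()] /
#'   [classify_pixels()].
#' @param min_lumen_area_um2 minimum lumen area in square microns
#'   (default 5000).
#' @param microns_per_pixel calibration, or a [calibrated_image] to take
#'   it from. Square pixels are assumed.
#' @return An [airway_geometry] with `source = "derived_from_tissue_mask"`.
#' @export
derive_airways <- function(tissue_mask, min_lumen_area_um2 = 5000,
                           microns_per_pixel) {
  stopifnot(is.logical(tissue_mask), is.matrix(tissue_mask))
  if (!any(tissue_mask)) stop("empty tissue mask: nothing to derive from")
  mpp <- if (inherits(microns_per_pixel, "calibrated_image"))
    microns_per_pixel$microns_per_pixel else microns_per_pixel
  stopifnot(is.numeric(mpp), mpp > 0)
  holes <- !tissue_mask
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(holes * 1)))
  H <- nrow(lab); W <- ncol(lab)
  border_labels <- unique(c(lab[1, ], lab[H, ], lab[, 1], lab[, W]))
  min_px <- min_lumen_area_um2 / mpp^2
  sizes <- tabulate(lab[lab > 0])
  keep <- setdiff(which(sizes >= min_px), border_labels)
  lumen <- matrix(lab %in% keep, H, W)
  airway_geometry(lumen, min_lumen_area_um2, "derived_from_tissue_mask")
}

#' Euclidean distance to the nearest airway lumen, in microns
#'
#' Exact Euclidean distance transform on the lumen complement: every
#' pixel's distance to the nearest lumen pixel, scaled by the
#' calibration. Pixels inside lumens have distance 0; if no lumens are
#' present all distances are infinite.
#'
#' @param airways an [airway_geometry].
#' @param microns_per_pixel calibration (square pixels assumed), or a
#'   [calibrated_image].
#' @return numeric `H x W` matrix of distances in microns.
#' @export
airway_distance_map <- function(airways, microns_per_pixel) {
  stopifnot(inherits(airways, "airway_geometry"))
  mpp <- if (inherits(microns_per_pixel, "calibrated_image"))
    microns_per_pixel$microns_per_pixel else microns_per_pixel
  stopifnot(is.numeric(mpp), mpp > 0)
  distance_to_lumen_px(airways$lumen_mask) * mpp
}

#' Fraction of deposition within a radius of the airways
#'
#' Computes, at pixel resolution, the fraction of total particle (or
#' cell) signal lying within `radius_um` of the nearest airway lumen
#' pixel. Distances are Euclidean, measured outward from the lumen
#' through tissue via an exact distance transform. Proximity is accounted
#' per pixel rather than per grid cell so that cells straddling the band
#' boundary are not arbitrarily assigned.
#'
#' @param signal logical particle mask, or a non-negative numeric weight
#'   raster (e.g. particle-channel intensities under the mask).
#' @param airways an [airway_geometry]. With no lumen pixels the fraction
#'   is undefined and flagged, never reported as 0.
#' @param radius_um proximity radius in microns (default 200).
#' @param microns_per_pixel calibration, or a [calibrated_image].
#' @return An object of class `proximity_result`: `radius_um`,
#'   `periairway_signal`, `total_signal`, `fraction` (`NA` with
#'   `defined = FALSE` when the total signal is 0 or no airways exist).
#' @export
proximity_fraction <- function(signal, airways, radius_um = 200,
                               microns_per_pixel) {
  stopifnot(radius_um > 0)
  w <- if (is.logical(signal)) signal * 1 else {
    stopifnot(is.numeric(signal), all(signal >= 0))
    signal
  }
  stopifnot(identical(dim(w), dim(airways$lumen_mask)))
  total <- sum(w)
  if (!any(airways$lumen_mask)) {
    return(structure(list(radius_um = radius_um,
                          periairway_signal = NA_real_,
                          total_signal = total,
                          fraction = NA_real_, defined = FALSE,
                          reason = "no airways present"),
                     class = "proximity_result"))
  }
  d <- airway_distance_map(airways, microns_per_pixel)
  peri <- sum(w[d <= radius_um])
  defined <- total > 0
  structure(list(radius_um = radius_um,
                 periairway_signal = peri,
                 total_signal = total,
                 fraction = if (defined) peri / total else NA_real_,
                 defined = defined,
                 reason = if (defined) NULL else "no signal present"),
            class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  if (x$defined)
    cat(sprintf("proximity_result: %.2f%% of signal within %g um of airways (%g / %g)\n",
                100 * x$fraction, x$radius_um, x$periairway_signal,
                x$total_signal))
  else
    cat(sprintf("proximity_result: undefined (%s)\n", x$reason))
  invisible(x)
}

#' Compare peri-airway fractions between groups
#'
#' Delegates to [compare_groups()] on per-specimen fractions.
#'
#' @param a,b lists of `proximity_result` objects or numeric vectors of
#'   per-specimen fractions.
#' @param ... passed to [compare_groups()].
#' @return A `group_comparison`.
#' @export
compare_proximity <- function(a, b, ...) {
  pull <- function(g) {
    if (is.list(g) && all(vapply(g, inherits, TRUE, "proximity_result")))
      vapply(g, function(r) r$fraction, numeric(1))
    else as.numeric(g)
  }
  compare_groups(pull(a), pull(b), ...)
}
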