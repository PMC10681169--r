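#' Configuration for a synthetic lung scene
#'
#' Describes a lung-like fluorescence scene with known ground truth: a
#' single rounded lobe silhouette of parenchymal tissue perforated by
#' non-overlapping elliptical airway lumens, an autofluorescent band
#' hugging each airway, and red-fluorescent point deposits placed either
#' uniformly over tissue (the aerosol-chamber regime, complete spatial
#' randomness over tissue pixels) or preferentially within
#' `cluster_range_um` of an airway boundary (the intranasal regime).
#'
#' @param width_px,height_px image size in pixels.
#' @param microns_per_pixel physical pixel size (um/px).
#' @param airway_count number of airway lumens to place.
#' @param airway_radius_range_um `(min, max)` geometric-mean radius of the
#'   elliptical lumens, in microns. Eccentricity is drawn uniformly up to
#'   2:1, matching the appearance of sectioned airways.
#' @param autofluor_ring_um width of the autofluorescent band measured
#'   outward from the lumen boundary; 0 disables the band.
#' @param particle_count number of particles to deposit.
#' @param regime `"uniform"` or `"clustered"`.
#' @param cluster_fraction for the clustered regime: probability that a
#'   particle is placed uniformly over tissue within `cluster_range_um` of
#'   a lumen, rather than uniformly over all tissue. Forced to 0 for the
#'   uniform regime.
#' @param cluster_range_um clustering length scale and also the radius at
#'   which the ground-truth peri-airway fraction is evaluated (default
#'   200 um, the peri-airway analysis radius).
#' @param particle_radius_um radius of each rendered particle disk. The
#'   default 0.5 um corresponds to 1-um-diameter microspheres; at typical
#'   calibrations this renders a single pixel per particle.
#' @param blur_sigma_um optional Gaussian blur (sigma, um) applied to the
#'   particle layer before compositing; 0 renders hard disks.
#' @param noise_sd additive Gaussian intensity noise (sd, in intensity
#'   units of the 8-bit image); 0 renders noiselessly.
#' @param intraluminal_fraction fraction of particles deposited inside
#'   airway lumens, emulating intraluminal trapping. Default 0 so that the
#'   particles-on-tissue invariant holds.
#' @param rng_seed integer seed; identical configurations (including the
#'   seed) generate bit-identical scenes.
#' @param colors named list of RGB triplets (0-255) for `tissue`,
#'   `autofluor` and `particle` classes; defaults are a dim green tissue,
#'   a bright yellow-green peri-airway band and red particles, matching
#'   the default [color_model()].
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(width_px = 1500L, height_px = 1500L,
                         microns_per_pixel = 2,
                         airway_count = 6L,
                         airway_radius_range_um = c(50, 150),
                         autofluor_ring_um = 30,
                         particle_count = 1000L,
                         regime = c("uniform", "clustered"),
                         cluster_fraction = if (regime[1] == "clustered") 0.8 else 0,
                         cluster_range_um = 200,
                         particle_radius_um = 0.5,
                         blur_sigma_um = 0,
                         noise_sd = 0,
                         intraluminal_fraction = 0,
                         rng_seed = 1L,
                         colors = NULL) {
  regime <- match.arg(regime)
  stopifnot(width_px >= 1, height_px >= 1,
            is.finite(microns_per_pixel), microns_per_pixel > 0,
            airway_count >= 0,
            length(airway_radius_range_um) == 2L,
            all(airway_radius_range_um > 0),
            airway_radius_range_um[1] <= airway_radius_range_um[2],
            autofluor_ring_um >= 0, particle_count >= 0,
            cluster_fraction >= 0, cluster_fraction <= 1,
            cluster_range_um > 0,
            particle_radius_um > 0, blur_sigma_um >= 0, noise_sd >= 0,
            intraluminal_fraction >= 0, intraluminal_fraction <= 1)
  if (regime == "uniform") cluster_fraction <- 0
  extent_um <- c(width_px, height_px) * microns_per_pixel
  if (cluster_range_um >= min(extent_um) / 2)
    stop("cluster_range_um must be smaller than half the image extent")
  if (is.null(colors))
    colors <- list(tissue = c(70, 120, 70),
                   autofluor = c(160, 210, 60),
                   particle = c(235, 40, 40))
  stopifnot(all(c("tissue", "autofluor", "particle") %in% names(colors)))
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 microns_per_pixel = microns_per_pixel,
                 airway_count = as.integer(airway_count),
                 airway_radius_range_um = airway_radius_range_um,
                 autofluor_ring_um = autofluor_ring_um,
                 particle_count = as.integer(particle_count),
                 regime = regime,
                 cluster_fraction = cluster_fraction,
                 cluster_range_um = cluster_range_um,
                 particle_radius_um = particle_radius_um,
                 blur_sigma_um = blur_sigma_um,
                 noise_sd = noise_sd,
                 intraluminal_fraction = intraluminal_fraction,
                 rng_seed = as.integer(rng_seed),
                 colors = colors),
            class = "scene_config")
}

# run expr under a private RNG stream, restoring global state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# rounded-polygon lobe silhouette: radial Fourier perturbation of a disk.
# the boundary radius is tabulated over 8192 angles (sub-pixel resolution
# at whole-lobe sizes) to keep the per-pixel test cheap
lobe_silhouette <- function(W, H) {
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  R0 <- 0.46 * min(W, H)
  k <- 2:5
  a <- stats::runif(length(k), -0.05, 0.05)
  phi <- stats::runif(length(k), 0, 2 * pi)
  nb <- 8192L
  th_tab <- seq(-pi, pi, length.out = nb)
  rmax2 <- (R0 * (1 + Reduce(`+`, lapply(seq_along(k), function(i)
    a[i] * cos(k[i] * th_tab + phi[i])))))^2
  dx <- rep(seq_len(W) - cx, each = H)
  dy <- rep(seq_len(H) - cy, times = W)
  idx <- as.integer(round((atan2(dy, dx) + pi) / (2 * pi) * (nb - 1L))) + 1L
  matrix(dx * dx + dy * dy <= rmax2[idx], H, W)
}

# fill one ellipse into a logical matrix, restricted to its bounding box
fill_ellipse <- function(mask, cx, cy, ax, bx, phi) {
  H <- nrow(mask); W <- ncol(mask)
  r <- max(ax, bx)
  rows <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  dx <- matrix(rep(cols - cx, each = length(rows)), length(rows))
  dy <- matrix(rep(rows - cy, times = length(cols)), length(rows))
  u <- (dx * cos(phi) + dy * sin(phi)) / ax
  v <- (-dx * sin(phi) + dy * cos(phi)) / bx
  mask[rows, cols] <- mask[rows, cols] | (u * u + v * v <= 1)
  mask
}

# place non-overlapping elliptical lumens fully inside the lobe;
# conservative bounding-circle overlap test; bounded rejection sampling
place_airways <- function(lobe, config) {
  W <- config$width_px; H <- config$height_px
  mpp <- config$microns_per_pixel
  n <- config$airway_count
  lumen <- matrix(FALSE, H, W)
  if (n == 0L) return(lumen)
  centers <- matrix(NA_real_, n, 2)
  radii <- numeric(n)
  gap_px <- 4
  ang <- seq(0, 2 * pi, length.out = 25L)[-25L]
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(500L)) {
      r_um <- stats::runif(1, config$airway_radius_range_um[1],
                           config$airway_radius_range_um[2])
      ecc <- stats::runif(1, 1, 2)
      phi <- stats::runif(1, 0, pi)
      a <- (r_um / mpp) * sqrt(ecc)   # semi-axes in px, geometric mean r
      b <- (r_um / mpp) / sqrt(ecc)
      if (1 + a >= W - a || 1 + a >= H - a) next
      cx <- stats::runif(1, 1 + a, W - a)
      cy <- stats::runif(1, 1 + a, H - a)
      # boundary (plus a 2 px margin) must lie on lobe tissue
      bx <- cx + (a + 2) * cos(ang) * cos(phi) - (b + 2) * sin(ang) * sin(phi)
      by <- cy + (a + 2) * cos(ang) * sin(phi) + (b + 2) * sin(ang) * cos(phi)
      bi <- round(cbind(pmin(pmax(by, 1), H), pmin(pmax(bx, 1), W)))
      if (!all(lobe[bi])) next
      if (i > 1L) {
        prev <- seq_len(i - 1L)
        dd <- sqrt((centers[prev, 1] - cx)^2 + (centers[prev, 2] - cy)^2)
        if (any(dd <= radii[prev] + a + gap_px)) next
      }
      centers[i, ] <- c(cx, cy); radii[i] <- a
      lumen <- fill_ellipse(lumen, cx, cy, a, b, phi)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("infeasible geometry: could not place ", n,
           " non-overlapping airways inside the lobe")
  }
  lumen
}

# Euclidean distance (px) from every pixel to the nearest lumen pixel;
# Inf everywhere when there are no lumens
distance_to_lumen_px <- function(lumen) {
  if (!any(lumen))
    return(matrix(Inf, nrow(lumen), ncol(lumen)))
  d <- EBImage::distmap(EBImage::Image(1 - lumen))
  matrix(EBImage::imageData(d), nrow(lumen), ncol(lumen))
}

#' Generate a synthetic lung scene with ground truth
#'
#' Builds the lobe silhouette, places airway lumens, deposits particles
#' under the configured regime, renders the RGB image via
#' [render_channels()], and records the ground truth: tissue and lumen
#' rasters, particle centres in microns, and the true peri-airway
#' fraction (the fraction of particle centres within `cluster_range_um`
#' of the nearest lumen pixel, computed from the truth rasters, never
#' from the image).
#'
#' Every particle centre lies on a tissue pixel — never inside a lumen or
#' off the lobe — unless `intraluminal_fraction > 0`. Generation is
#' deterministic for a fixed `rng_seed` and leaves the caller's RNG state
#' untouched.
#'
#' @param config a [scene_config].
#' @return An object of class `synthetic_scene`: list with elements
#'   `image` ([calibrated_image]), `tissue_truth`, `airway_truth`,
#'   `autofluor_band_truth` (logical rasters),
#'   `particle_centers_um` (n x 2 matrix, columns
#'   `x_um`, `y_um`), `particle_pixels` (n x 2 matrix of 1-based row/col),
#'   `true_periairway_fraction`, and `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$rng_seed, {
    W <- config$width_px; H <- config$height_px
    mpp <- config$microns_per_pixel
    lobe <- lobe_silhouette(W, H)
    lumen <- place_airways(lobe, config)
    tissue <- lobe & !lumen
    dist_um <- distance_to_lumen_px(lumen) * mpp

    n <- config$particle_count
    tissue_idx <- which(tissue)
    if (n > 0L && length(tissue_idx) == 0L)
      stop("infeasible geometry: no tissue pixels to deposit particles on")
    pidx <- integer(0)
    if (n > 0L) {
      n_lum <- round(config$intraluminal_fraction * n)
      n_tis <- n - n_lum
      take <- integer(0)
      if (n_tis > 0L) {
        near <- stats::runif(n_tis) < config$cluster_fraction
        if (any(near)) {
          near_idx <- tissue_idx[dist_um[tissue_idx] <= config$cluster_range_um]
          if (length(near_idx) == 0L)
            stop("clustered regime requires tissue within cluster_range_um of an airway")
          take <- c(take, near_idx[sample.int(length(near_idx),
                                              sum(near), replace = TRUE)])
        }
        if (any(!near))
          take <- c(take, tissue_idx[sample.int(length(tissue_idx),
                                                sum(!near), replace = TRUE)])
      }
      if (n_lum > 0L) {
        lum_idx <- which(lumen)
        if (length(lum_idx) == 0L)
          stop("intraluminal deposition requested but no lumens present")
        take <- c(take, lum_idx[sample.int(length(lum_idx), n_lum,
                                           replace = TRUE)])
      }
      pidx <- take
    }
    prow <- ((pidx - 1L) %% H) + 1L
    pcol <- ((pidx - 1L) %/% H) + 1L
    centers_um <- cbind(x_um = (pcol - 0.5) * mpp, y_um = (prow - 0.5) * mpp)
    frac <- if (n > 0L)
      mean(dist_um[pidx] <= config$cluster_range_um) else 0

    scene <- structure(list(image = NULL,
                            tissue_truth = tissue,
                            airway_truth = lumen,
                            autofluor_band_truth =
                              tissue & dist_um <= config$autofluor_ring_um,
                            particle_centers_um = centers_um,
                            particle_pixels = cbind(row = prow, col = pcol),
                            true_periairway_fraction = frac,
                            config = config),
                       class = "synthetic_scene")
    scene$image <- render_channels(scene)
    scene
  })
}

#' Render the RGB channels of a synthetic scene
#'
#' Composites background (black), tissue, the autofluorescent peri-airway
#' band, and particle disks into an 8-bit RGB [calibrated_image] that the
#' default [color_model()] separates into the three classes. Rendering is
#' reproducible in isolation: the noise substream is seeded from
#' `config$rng_seed + 1`, so calling `render_channels()` on a stored
#' scene reproduces the generated image bit-identically.
#'
#' @param scene a `synthetic_scene` (the `image` element may be `NULL`).
#' @return A [calibrated_image] (8-bit, 3 channels).
#' @export
render_channels <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  config <- scene$config
  with_seed(config$rng_seed + 1L, {
    H <- config$height_px; W <- config$width_px
    mpp <- config$microns_per_pixel
    tissue <- scene$tissue_truth
    band <- if (!is.null(scene$autofluor_band_truth))
      scene$autofluor_band_truth
    else
      tissue & distance_to_lumen_px(scene$airway_truth) * mpp <=
        config$autofluor_ring_um

    base <- lapply(1:3, function(ch) {
      m <- matrix(0, H, W)
      m[tissue] <- config$colors$tissue[ch]
      m[band] <- config$colors$autofluor[ch]
      m
    })

    # particle layer: hard disks (always at least the centre pixel),
    # optionally Gaussian-blurred, composited over the base colours
    p <- matrix(0, H, W)
    np <- nrow(scene$particle_pixels)
    if (np > 0L) {
      r_px <- config$particle_radius_um / mpp
      p[scene$particle_pixels] <- 1
      if (r_px >= 1) {
        off <- expand.grid(dr = -floor(r_px):floor(r_px),
                           dc = -floor(r_px):floor(r_px))
        off <- off[off$dr^2 + off$dc^2 <= r_px^2, , drop = FALSE]
        for (i in seq_len(nrow(off))) {
          rr <- scene$particle_pixels[, 1] + off$dr[i]
          cc <- scene$particle_pixels[, 2] + off$dc[i]
          ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
          p[cbind(rr[ok], cc[ok])] <- 1
        }
      }
      if (config$blur_sigma_um > 0) {
        p <- EBImage::imageData(EBImage::gblur(
          EBImage::Image(p), sigma = config$blur_sigma_um / mpp))
        p <- pmin(pmax(p / max(p), 0), 1)
      }
    }

    px <- array(0, c(H, W, 3))
    for (ch in 1:3)
      px[, , ch] <- base[[ch]] * (1 - p) + config$colors$particle[ch] * p
    if (config$noise_sd > 0)
      px <- px + stats::rnorm(length(px), 0, config$noise_sd)
    px <- round(pmin(pmax(px, 0), 255))
    calibrated_image(px, mpp, c("red", "green", "blue"), bit_depth = 8L)
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(paste0("synthetic_scene: %d x %d px @ %.3g um/px, %d airway(s), ",
                     "%d particle(s), regime %s, true peri-airway fraction %.3f\n"),
              x$config$height_px, x$config$width_px,
              x$config$microns_per_pixel, x$config$airway_count,
              nrow(x$particle_centers_um), x$config$regime,
              x$true_periairway_fraction))
  invisible(x)
}

#' Write a synthetic scene and its ground truth to disk
#'
#' Writes the rendered image and the truth rasters as TIFF, particle
#' centres as CSV (`x_um`, `y_um`), and the configuration as YAML, so a
#' scene can stand in for an acquired specimen in a pipeline run.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image(scene$image, file.path(dir, "image.tif"))
  write_image(scene$airway_truth, file.path(dir, "airway_mask.tif"))
  write_image(scene$tissue_truth, file.path(dir, "tissue_mask.tif"))
  utils::write.csv(as.data.frame(scene$particle_centers_um),
                   file.path(dir, "particle_centers.csv"), row.names = FALSE)
  cfg <- scene$config
  class(cfg) <- NULL
  cfg$true_periairway_fraction <- scene$true_periairway_fraction
  yaml::write_yaml(cfg, file.path(dir, "scene_config.yaml"))
  invisible(dir)
}
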