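# small scene factory used across tests: 400 x 400 px at 2 um/px keeps a
# full generate/classify/quantify cycle under a second
tiny_scene_config <- function(seed = 1L, regime = "uniform",
                              particle_count = 300L,
                              width_px = 400L, height_px = 400L,
                              microns_per_pixel = 2, airway_count = 2L,
                              airway_radius_range_um = c(40, 80), ...) {
  scene_config(width_px = width_px, height_px = height_px,
               microns_per_pixel = microns_per_pixel,
               airway_count = airway_count,
               airway_radius_range_um = airway_radius_range_um,
               particle_count = particle_count, regime = regime,
               rng_seed = seed, ...)
}

# brute-force nearest-lumen-pixel distance, the oracle for the exact
# Euclidean distance transform (only usable on small rasters)
brute_force_distance_px <- function(lumen) {
  H <- nrow(lumen); W <- ncol(lumen)
  idx <- which(lumen, arr.ind = TRUE)
  out <- matrix(Inf, H, W)
  if (nrow(idx) == 0L) return(out)
  for (r in seq_len(H)) for (c in seq_len(W))
    out[r, c] <- sqrt(min((idx[, 1] - r)^2 + (idx[, 2] - c)^2))
  out
}

# brute-force assignment of particle pixels to grid cells (0-based bins)
brute_force_cell_counts <- function(particle_pixels, cell_px, H, W,
                                    origin_px = c(0, 0)) {
  rb <- floor((particle_pixels[, 1] - 1 - origin_px[2]) / cell_px)
  cb <- floor((particle_pixels[, 2] - 1 - origin_px[1]) / cell_px)
  key <- paste(rb, cb)
  table(key)
}

# flat RGB image helper
flat_rgb <- function(rgb, H = 20L, W = 20L, mpp = 1) {
  px <- array(0, c(H, W, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  calibrated_image(px, mpp)
}
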