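test_that("identical configurations generate bit-identical scenes", {
  cfg <- tiny_scene_config(seed = 5, regime = "clustered",
                           cluster_fraction = 0.7, noise_sd = 3)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$particle_centers_um, b$particle_centers_um)
  expect_identical(a$true_periairway_fraction, b$true_periairway_fraction)
  # generation leaves the caller's RNG stream untouched
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_scene(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("degenerate particle configurations behave as defined", {
  empty <- generate_scene(tiny_scene_config(particle_count = 0L))
  expect_identical(nrow(empty$particle_centers_um), 0L)
  expect_identical(empty$true_periairway_fraction, 0)

  forced <- generate_scene(tiny_scene_config(
    regime = "clustered", cluster_fraction = 1.0, particle_count = 200L))
  expect_identical(forced$true_periairway_fraction, 1.0)
})

test_that("every particle centre lies on a tissue pixel", {
  for (cfg in list(tiny_scene_config(seed = 2),
                   tiny_scene_config(seed = 3, regime = "clustered",
                                     cluster_fraction = 0.9))) {
    sc <- generate_scene(cfg)
    expect_true(all(sc$tissue_truth[sc$particle_pixels]))
    expect_false(any(sc$airway_truth[sc$particle_pixels]))
  }
  # unless intraluminal deposition is explicitly enabled
  sc <- generate_scene(tiny_scene_config(seed = 4,
                                         intraluminal_fraction = 0.5,
                                         particle_count = 200L))
  expect_true(any(sc$airway_truth[sc$particle_pixels]))
})

test_that("stored peri-airway truth equals a brute-force recomputation", {
  cfg <- tiny_scene_config(seed = 8, width_px = 150L, height_px = 150L,
                           microns_per_pixel = 4,
                           airway_count = 1L,
                           airway_radius_range_um = c(40, 60),
                           particle_count = 120L,
                           regime = "clustered", cluster_fraction = 0.5)
  sc <- generate_scene(cfg)
  d <- brute_force_distance_px(sc$airway_truth) * cfg$microns_per_pixel
  frac <- mean(d[sc$particle_pixels] <= cfg$cluster_range_um)
  expect_identical(sc$true_periairway_fraction, frac)
})

test_that("uniform-regime truth fraction matches the peri-airway tissue area fraction", {
  cfg <- scene_config(width_px = 2000L, height_px = 2000L,
                      microns_per_pixel = 1, airway_count = 5L,
                      airway_radius_range_um = c(50, 150),
                      particle_count = 500L, regime = "uniform",
                      rng_seed = 7L)
  sc <- generate_scene(cfg)
  d_um <- EBImage::imageData(EBImage::distmap(
    EBImage::Image(1 - sc$airway_truth))) * cfg$microns_per_pixel
  area_frac <- mean(d_um[sc$tissue_truth] <= cfg$cluster_range_um)
  se <- sqrt(area_frac * (1 - area_frac) / cfg$particle_count)
  expect_lt(abs(sc$true_periairway_fraction - area_frac), 3.5 * se)
})

test_that("infeasible airway geometry is rejected with a clear error", {
  cfg <- tiny_scene_config(airway_count = 60L,
                           airway_radius_range_um = c(90, 100))
  expect_error(generate_scene(cfg), "infeasible geometry")
})

test_that("rendering honours the configured colour classes", {
  # zero autofluorescence ring: no pixels in the autofluorescence class
  sc0 <- generate_scene(tiny_scene_config(autofluor_ring_um = 0))
  expect_identical(sum(sc0$autofluor_band_truth), 0L)
  expect_identical(sum(classify_pixels(sc0$image)$autofluor), 0L)

  # noiseless single particle occupies exactly its rendered pixel block
  sc1 <- generate_scene(tiny_scene_config(particle_count = 1L))
  pm <- build_particle_mask(sc1$image)
  expect_identical(which(pm),
                   unname((sc1$particle_pixels[, 2] - 1L) * 400L +
                            sc1$particle_pixels[, 1]))

  # re-rendering a stored scene reproduces the image bit-identically
  sc2 <- generate_scene(tiny_scene_config(seed = 6, noise_sd = 3))
  expect_identical(render_channels(sc2)$pixels, sc2$image$pixels)
})

test_that("write_scene emits image, truth and config that round-trip", {
  sc <- generate_scene(tiny_scene_config(seed = 9, particle_count = 40L))
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  img <- read_image(file.path(dir, "image.tif"),
                    sc$config$microns_per_pixel)
  expect_identical(as.integer(img$pixels), as.integer(sc$image$pixels))
  centers <- utils::read.csv(file.path(dir, "particle_centers.csv"))
  expect_equal(as.matrix(centers), sc$particle_centers_um,
               ignore_attr = TRUE)
  cfg <- yaml::read_yaml(file.path(dir, "scene_config.yaml"))
  expect_equal(cfg$rng_seed, sc$config$rng_seed)
  expect_equal(cfg$true_periairway_fraction, sc$true_periairway_fraction)
})
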