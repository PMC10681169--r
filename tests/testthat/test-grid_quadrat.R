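make_masks <- function(particle, tissue) class_masks(particle, tissue)

test_that("a 400x400 px image at 1 um/px under a 200 um grid gives 4 full cells", {
  img <- calibrated_image(array(0, c(400, 400, 3)), 1.0)
  tissue <- matrix(TRUE, 400, 400)
  particle <- matrix(FALSE, 400, 400)
  particle[10, 10] <- TRUE; particle[399, 399] <- TRUE
  tab <- quantify_quadrats(make_masks(particle, tissue), img,
                           grid_spec(200, 0.9))
  expect_identical(nrow(tab), 4L)
  expect_identical(attr(tab, "cell_px"), 200L)
  expect_true(all(tab$tissue_fraction == 1))
  expect_true(all(tab$included))
  expect_identical(sum(tab$signal), 2)
  expect_identical(tab$signal[tab$cell_row == 0 & tab$cell_col == 0], 1)
  expect_identical(tab$signal[tab$cell_row == 1 & tab$cell_col == 1], 1)
})

test_that("empty particle masks give zero signal but coverage still drives inclusion", {
  img <- calibrated_image(array(0, c(100, 100, 3)), 2.0)
  tissue <- matrix(FALSE, 100, 100)
  tissue[1:50, ] <- TRUE
  tab <- quantify_quadrats(make_masks(matrix(FALSE, 100, 100), tissue),
                           img, grid_spec(100, 0.9))  # 50 px cells
  expect_true(all(tab$signal == 0))
  expect_identical(tab$included, tab$tissue_fraction >= 0.9)
  expect_identical(sum(tab$included), 2L)
})

test_that("signal is conserved across grid sizes and origins", {
  sc <- generate_scene(tiny_scene_config(seed = 21, particle_count = 400L))
  m <- classify_pixels(sc$image)
  total <- sum(m$particle)
  for (size in c(100, 200, 500))
    for (origin in list(c(0, 0), c(37, 59), c(-13, 101))) {
      tab <- quantify_quadrats(m, sc$image,
                               grid_spec(size, 0.9, origin_px = origin))
      expect_identical(sum(tab$signal), as.numeric(total))
    }
})

test_that("quadrat signals equal brute-force binning of ground-truth particles", {
  sc <- generate_scene(tiny_scene_config(seed = 22, particle_count = 250L))
  m <- classify_pixels(sc$image)
  for (origin in list(c(0, 0), c(50, 50))) {
    grid <- grid_spec(200, 0.9, origin_px = origin)
    tab <- quantify_quadrats(m, sc$image, grid)
    cell_px <- attr(tab, "cell_px")
    # oracle: bin the distinct true particle pixels by integer division
    pp <- unique(sc$particle_pixels)
    rb <- floor((pp[, 1] - 1 - origin[2]) / cell_px)
    cb <- floor((pp[, 2] - 1 - origin[1]) / cell_px)
    rb <- rb - min(floor((seq_len(400) - 1 - origin[2]) / cell_px))
    cb <- cb - min(floor((seq_len(400) - 1 - origin[1]) / cell_px))
    expected <- numeric(nrow(tab))
    for (i in seq_len(nrow(pp))) {
      j <- which(tab$cell_row == rb[i] & tab$cell_col == cb[i])
      expected[j] <- expected[j] + 1
    }
    expect_identical(tab$signal, expected)
  }
})

test_that("intensity_sum is affinely related to mask_area on noiseless scenes", {
  sc <- generate_scene(tiny_scene_config(seed = 23, particle_count = 300L))
  m <- classify_pixels(sc$image)
  area <- quantify_quadrats(m, sc$image, grid_spec(200, 0.9,
                                                   signal_mode = "mask_area"))
  intens <- quantify_quadrats(m, sc$image,
                              grid_spec(200, 0.9,
                                        signal_mode = "intensity_sum"))
  # every particle pixel carries the saturated particle red value
  expect_identical(intens$signal, area$signal * sc$config$colors$particle[1])
})

test_that("the grid sweep enumerates all combinations and inclusion is monotone", {
  sc <- generate_scene(tiny_scene_config(seed = 24))
  m <- classify_pixels(sc$image)
  tabs <- sweep_grids(m, sc$image)
  expect_identical(length(tabs), 12L)
  expect_identical(names(tabs)[1], "size100_cov50")
  for (size in c(100, 200, 500)) {
    prev <- NULL
    for (cov in c(50, 75, 90, 98)) {
      cur <- tabs[[sprintf("size%g_cov%g", size, cov)]]
      if (!is.null(prev))
        expect_true(all(prev$included[cur$included]))  # subset property
      prev <- cur
    }
  }
})

test_that("quadrat tables serialize to CSV with a JSON sidecar", {
  sc <- generate_scene(tiny_scene_config(seed = 25, particle_count = 60L))
  tab <- quantify_quadrats(classify_pixels(sc$image), sc$image)
  path <- withr::local_tempfile(fileext = ".csv")
  write_quadrat_table(tab, path)
  back <- utils::read.csv(path)
  expect_equal(back$signal, tab$signal)
  expect_identical(back$included, tab$included)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$grid$cell_size_um, 200)
  expect_equal(meta$cell_px, attr(tab, "cell_px"))
})
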