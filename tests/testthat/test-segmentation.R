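test_that("a centered disk phantom is recovered with its diameter", {
  # 40 px diameter disk at 5 um/px -> 200 um egg
  rc <- render_cube(one_egg_scene(radius_um = 100, pixel_size_um = 5,
                                  baseline_mu = 0.01))
  regs <- segment_eggs(rc$cube)
  expect_length(regs, 1)
  expect_equal(regs[[1]]$equivalent_diameter_um, 200,
               tolerance = 2 * 5 / 200)  # within 2 pixels
  expect_gt(regs[[1]]$circularity, 0.9)
  expect_lte(regs[[1]]$circularity, 1)
  # area within one perimeter's worth of the true disk area
  expect_lt(abs(regs[[1]]$area_px - pi * 20^2), pi * 2 * 20)
})

test_that("uniform and constant cubes yield no regions", {
  g <- make_grid(380, 1000, 5)
  flat <- hyper_cube(array(500, c(40, 40, 125)), g, 5)
  expect_length(segment_eggs(flat), 0)
})

test_that("two disjoint disks are found and sorted by centroid row", {
  grid <- default_grid()
  eggs <- list(
    synthetic_egg(50, c(90, 30), list(), 0.01, 0.04),
    synthetic_egg(50, c(30, 80), list(), 0.01, 0.04))
  sc <- scene_spec(120, 120, grid, eggs, 2.5)
  regs <- segment_eggs(render_cube(sc)$cube)
  expect_length(regs, 2)
  expect_lt(regs[[1]]$centroid["row"], regs[[2]]$centroid["row"])
  expect_equal(unname(regs[[1]]$centroid), c(30, 80), tolerance = 0.05)
})

test_that("segmentation is invariant to global intensity rescaling", {
  rc <- render_cube(one_egg_scene(radius_um = 60, pixel_size_um = 2.5,
                                  baseline_mu = 0.006))
  for (mode in c("relative", "otsu")) {
    r1 <- segment_eggs(rc$cube, threshold_mode = mode)
    scaled <- hyper_cube(rc$cube$intensities * 7.3, rc$cube$grid,
                         rc$cube$pixel_size_um)
    r2 <- segment_eggs(scaled, threshold_mode = mode)
    expect_length(r2, length(r1))
    expect_identical(r2[[1]]$mask, r1[[1]]$mask, label = mode)
  }
})

test_that("noise at SNR >= 20 shifts the diameter by at most 2 pixels", {
  noiseless <- render_cube(one_egg_scene(radius_um = 75, seed = 11))
  noisy <- render_cube(one_egg_scene(radius_um = 75, noise_sd = 1000 / 20,
                                     seed = 11))
  d0 <- segment_eggs(noiseless$cube)[[1]]$equivalent_diameter_um
  d1 <- segment_eggs(noisy$cube)[[1]]$equivalent_diameter_um
  expect_lt(abs(d1 - d0) / 2.5, 2)
  expect_lt(abs(d1 - 150) / 2.5, 2)
})

test_that("border-touching regions are rejected", {
  grid <- default_grid()
  a <- array(1000, c(60, 60, 125))
  rr <- row(matrix(0, 60, 60)); cc <- col(matrix(0, 60, 60))
  disk <- (rr - 5)^2 + (cc - 30)^2 <= 15^2   # pokes past the top border
  for (b in seq_len(125)) a[, , b][disk] <- 100
  cube <- hyper_cube(a, grid, 5)
  expect_length(segment_eggs(cube, min_area_px = 10), 0)
})

test_that("low-circularity components are filtered", {
  grid <- default_grid()
  a <- array(1000, c(80, 80, 125))
  bar <- row(matrix(0, 80, 80)) %in% 38:42 &
    col(matrix(0, 80, 80)) %in% 10:70       # 5 x 61 bar, circularity ~ 0.3
  for (b in seq_len(125)) a[, , b][bar] <- 100
  cube <- hyper_cube(a, grid, 5)
  expect_length(segment_eggs(cube, min_area_px = 10), 0)
  expect_length(segment_eggs(cube, min_area_px = 10, min_circularity = 0.1), 1)
})

test_that("equivalent diameter follows the equal-area circle definition", {
  reg <- structure(list(area_px = 1257, mask = NULL), class = "egg_region")
  expect_equal(estimate_diameter(reg, 5), 2 * 5 * sqrt(1257 / pi),
               tolerance = 1e-12)
  reg1 <- structure(list(area_px = 1), class = "egg_region")
  expect_equal(estimate_diameter(reg1, 1), 2 / sqrt(pi), tolerance = 1e-12)
})

test_that("the largest reported egg size renders and measures back", {
  rc <- render_cube(one_egg_scene(radius_um = 190.5, pixel_size_um = 2.5,
                                  baseline_mu = 0.004))
  regs <- segment_eggs(rc$cube)
  expect_length(regs, 1)
  expect_equal(regs[[1]]$equivalent_diameter_um, 381, tolerance = 5 / 381)
})

test_that("background mask excludes eggs plus the guard margin", {
  rc <- render_cube(one_egg_scene(radius_um = 50, pixel_size_um = 2.5,
                                  baseline_mu = 0.01))
  regs <- segment_eggs(rc$cube)
  bg <- background_mask(rc$cube, regs, guard_margin_px = 10)
  expect_false(any(bg$mask & regs[[1]]$mask))
  # pixels within 10 px of the disk edge are excluded
  cen <- regs[[1]]$centroid
  d <- sqrt((row(bg$mask) - 1 - cen["row"])^2 +
              (col(bg$mask) - 1 - cen["col"])^2)
  r_px <- 50 / 2.5
  expect_false(any(bg$mask[d <= r_px + 10 - 1]))
  expect_true(all(bg$mask[d > r_px + 10 + 2]))
  # zero regions: everything is background
  bg0 <- background_mask(rc$cube, list())
  expect_true(all(bg0$mask))
})

test_that("full coverage raises a field-of-view error", {
  rc <- render_cube(one_egg_scene(radius_um = 50, pixel_size_um = 2.5))
  regs <- segment_eggs(rc$cube)
  expect_error(background_mask(rc$cube, regs, guard_margin_px = 200),
               "field of view")
})

test_that("region export produces a label image and properties table", {
  rc <- render_cube(one_egg_scene(radius_um = 50, pixel_size_um = 2.5))
  regs <- segment_eggs(rc$cube)
  dir <- withr::local_tempdir()
  tab <- export_regions(regs, dim(rc$cube$intensities)[1:2],
                        tiff_path = file.path(dir, "labels.tif"),
                        csv_path = file.path(dir, "regions.csv"))
  expect_true(file.exists(file.path(dir, "labels.tif")))
  back <- utils::read.csv(file.path(dir, "regions.csv"))
  expect_equal(back$area_px, regs[[1]]$area_px)
})
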