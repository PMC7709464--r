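make_flat_cube <- function(level = 1000, H = 30, W = 30,
                           grid = make_grid(400, 440, 5)) {
  hyper_cube(array(level, c(H, W, length(grid$wavelengths))), grid, 5)
}

disk_region <- function(H, W, cen, r) {
  mask <- (row(matrix(0, H, W)) - 1 - cen[1])^2 +
    (col(matrix(0, H, W)) - 1 - cen[2])^2 <= r^2
  structure(list(label = 1L, mask = mask,
                 centroid = c(row = cen[1], col = cen[2]),
                 area_px = sum(mask),
                 equivalent_diameter_um = 2 * 5 * sqrt(sum(mask) / pi),
                 circularity = 1),
            class = "egg_region")
}

test_that("background spectrum is the per-band median, robust to outliers", {
  cube <- make_flat_cube(1000)
  bg <- background_mask(cube, list())
  sp <- estimate_background_spectrum(cube, bg)
  expect_equal(sp$values, rep(1000, 9))
  # 1% salt noise leaves the median untouched
  a <- cube$intensities
  set.seed(3)
  hot <- sample(length(a), length(a) %/% 100)
  a[hot] <- 1e6
  sp2 <- estimate_background_spectrum(
    hyper_cube(a, cube$grid, 5), bg)
  expect_equal(sp2$values, rep(1000, 9))
})

test_that("degenerate background bands are reported by wavelength", {
  grid <- make_grid(400, 410, 5)
  a <- array(100, c(10, 10, 3)); a[, , 2] <- 0
  cube <- hyper_cube(a, grid, 5)
  expect_error(estimate_background_spectrum(
    cube, background_mask(cube, list())), "405")
})

test_that("transmittance is the identity for specimen equal to background", {
  cube <- make_flat_cube(800)
  reg <- disk_region(30, 30, c(14, 14), 8)
  bg_mask <- background_mask(cube, list(reg), guard_margin_px = 2)
  bg <- estimate_background_spectrum(cube, bg_mask)
  tau <- egg_transmittance(cube, reg, bg)$tau
  expect_equal(tau, rep(1, 9))
})

test_that("specimen at half background gives tau one half, and tau rescales
           away any global illumination factor", {
  cube <- make_flat_cube(800)
  reg <- disk_region(30, 30, c(14, 14), 8)
  a <- cube$intensities
  for (b in 1:9) a[, , b][reg$mask] <- 400
  cube2 <- hyper_cube(a, cube$grid, 5)
  bg <- estimate_background_spectrum(
    cube2, background_mask(cube2, list(reg), 2))
  sp <- egg_transmittance(cube2, reg, bg)
  expect_equal(sp$tau, rep(0.5, 9))
  expect_equal(sp$n_pixels, reg$area_px)
  # multiply the whole cube by c > 0: tau unchanged
  cube3 <- hyper_cube(a * 3.7, cube$grid, 5)
  bg3 <- estimate_background_spectrum(
    cube3, background_mask(cube3, list(reg), 2))
  expect_equal(egg_transmittance(cube3, reg, bg3)$tau, sp$tau)
})

test_that("mean-of-ratios equals ratio-of-means on a flat background", {
  rc <- render_cube(one_egg_scene(radius_um = 50, pixel_size_um = 2.5,
                                  baseline_mu = 0.008))
  regs <- segment_eggs(rc$cube)
  bg <- estimate_background_spectrum(
    rc$cube, background_mask(rc$cube, regs))
  sp <- egg_transmittance(rc$cube, regs[[1]], bg)
  d <- dim(rc$cube$intensities)
  flat <- matrix(rc$cube$intensities, d[1] * d[2], d[3])
  ratio_of_means <- colMeans(flat[as.vector(regs[[1]]$mask), ]) / bg$values
  expect_equal(sp$tau, unname(ratio_of_means), tolerance = 1e-12)
})

test_that("band_mean averages inclusively and is monotone", {
  grid <- make_grid(400, 760, 5)
  ramp <- transmittance_spectrum(grid, seq(0, 1, length.out = 73), "ramp")
  expect_equal(band_mean(ramp, band_def("VIS", 400, 760)), 0.5)
  expect_equal(band_mean(const_spectrum(0.3, grid), band_def("b", 500, 600)),
               0.3)
  expect_error(band_mean(ramp, band_def("UVB", 300, 350)), "overlap")
  # monotonicity: pointwise tau1 >= tau2 -> band means ordered
  set.seed(5)
  for (i in 1:20) {
    t2 <- runif(73)
    t1 <- t2 + runif(73, 0, 0.2)
    s1 <- transmittance_spectrum(grid, t1, "a")
    s2 <- transmittance_spectrum(grid, t2, "b")
    expect_gte(band_mean(s1, visible_band()), band_mean(s2, visible_band()))
  }
})

test_that("monotone spectra yield no local minima", {
  grid <- default_grid()
  mono <- transmittance_spectrum(grid, seq(0.2, 0.9, length.out = 125), "m")
  expect_length(detect_local_minima(mono), 0)
})

test_that("a single Gaussian dip is located at its center", {
  grid <- default_grid()
  wl <- grid$wavelengths
  tau <- 0.8 - 0.3 * exp(-(wl - 480)^2 / (2 * 25^2))
  sp <- transmittance_spectrum(grid, tau, "dip")
  expect_equal(detect_local_minima(sp), 480)
})

test_that("two pigment bands produce dips at both centers, within 5 nm", {
  rc <- render_cube(preset_scene("two_pigment"))
  regs <- segment_eggs(rc$cube)
  bg <- estimate_background_spectrum(
    rc$cube, background_mask(rc$cube, regs))
  sp <- egg_transmittance(rc$cube, regs[[1]], bg)
  minima <- detect_local_minima(sp)
  expect_length(minima, 2)
  expect_lte(abs(minima[1] - 500), 5)
  expect_lte(abs(minima[2] - 600), 5)
})

test_that("shallow dips below the prominence threshold are ignored", {
  grid <- default_grid()
  wl <- grid$wavelengths
  tau <- 0.8 - 0.01 * exp(-(wl - 550)^2 / (2 * 20^2))
  sp <- transmittance_spectrum(grid, tau, "shallow")
  expect_length(detect_local_minima(sp, min_prominence = 0.02), 0)
  expect_equal(detect_local_minima(sp, min_prominence = 0.005), 550)
})

test_that("spectra export long and wide tables consistently", {
  grid <- make_grid(400, 410, 5)
  sps <- list(transmittance_spectrum(grid, c(0.1, 0.2, 0.3), "e1"),
              transmittance_spectrum(grid, c(0.4, 0.5, 0.6), "e2"))
  out <- export_spectra(sps)
  expect_equal(nrow(out$long), 6)
  expect_equal(out$wide$nm405, c(0.2, 0.5))
  expect_equal(out$long$tau[out$long$egg_id == "e2"], c(0.4, 0.5, 0.6))
})
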