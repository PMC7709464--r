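test_that("mu spectra superpose Gaussian pigment bands on a baseline", {
  grid <- default_grid()
  flat <- synthetic_egg(100, c(0, 0), list(), 0.002)
  expect_equal(mu_spectrum(flat, grid), rep(0.002, 125))
  one <- synthetic_egg(100, c(0, 0), list(pigment_band(500, 20, 0.01)), 0)
  mu <- mu_spectrum(one, grid)
  expect_equal(mu[band_index(grid, 500)], 0.01)
  expect_equal(mu[band_index(grid, 540)], 0.01 * exp(-2), tolerance = 1e-12)
  two <- synthetic_egg(100, c(0, 0),
                       list(pigment_band(500, 15, 0.01),
                            pigment_band(600, 15, 0.01)), 0)
  mu2 <- mu_spectrum(two, grid)
  # exactly two interior local maxima, at the band centers
  peaks <- which(diff(sign(diff(mu2))) == -2) + 1
  expect_equal(grid$wavelengths[peaks], c(500, 600))
})

test_that("chord path length follows sphere geometry", {
  expect_equal(chord_path_length(100, 0), 200)
  expect_equal(chord_path_length(100, 100), 0)
  expect_equal(chord_path_length(100, 60), 160)
  expect_error(chord_path_length(100, 101), "rho")
})

test_that("closed-form disk transmittance matches numerical quadrature
           across mu*r in [0, 5]", {
  for (mur in c(0, 1e-6, 1e-3, 0.05, 0.3, 1, 2, 3.5, 5)) {
    for (R in c(0, 0.04)) {
      a <- analytic_disk_transmittance(mur / 120, 120, R)
      q <- quadrature_disk_transmittance(mur / 120, 120, R)
      expect_equal(a, q, tolerance = 1e-8,
                   label = sprintf("mur=%g R=%g", mur, R))
    }
  }
  expect_equal(analytic_disk_transmittance(0, 100, 0), 1)
  expect_equal(analytic_disk_transmittance(0, 100, 0.04), 0.96)
  expect_equal(analytic_disk_transmittance(0.01, 100, 0),
               (1 - 3 * exp(-2)) / 2, tolerance = 1e-12)
})

test_that("rendering is deterministic given the seed", {
  sc <- one_egg_scene(noise_sd = 30, seed = 99)
  c1 <- render_cube(sc)$cube$intensities
  c2 <- render_cube(sc)$cube$intensities
  expect_identical(c1, c2)
  c3 <- render_cube(one_egg_scene(noise_sd = 30, seed = 100))$cube$intensities
  expect_false(identical(c1, c3))
})

test_that("a lossless egg is indistinguishable from background", {
  rc <- render_cube(one_egg_scene(baseline_mu = 0, reflection_loss = 0))
  a <- rc$cube$intensities
  expect_equal(max(a), min(a))
  expect_length(segment_eggs(rc$cube), 0)
})

test_that("noiseless per-band tau over the true mask matches the analytic
           oracle within 1% relative", {
  rc <- render_cube(one_egg_scene(radius_um = 75, pixel_size_um = 2.5,
                                  baseline_mu = 0.006,
                                  pigments = list(pigment_band(500, 30,
                                                               0.01))))
  truth <- rc$truth[[1]]
  reg <- structure(list(label = 1L, mask = truth$mask,
                        centroid = c(row = truth$center_px[1],
                                     col = truth$center_px[2]),
                        area_px = sum(truth$mask),
                        equivalent_diameter_um = truth$diameter_um,
                        circularity = 1), class = "egg_region")
  bg <- estimate_background_spectrum(
    rc$cube, background_mask(rc$cube, list(reg)))
  tau <- egg_transmittance(rc$cube, reg, bg)$tau
  expect_lt(max(abs(tau - truth$analytic_tau) / truth$analytic_tau), 0.01)
})

test_that("within an egg, per-pixel tau is non-decreasing in radial offset", {
  rc <- render_cube(one_egg_scene(radius_um = 75, baseline_mu = 0.01))
  truth <- rc$truth[[1]]
  band <- band_index(rc$cube$grid, 550)
  img <- rc$cube$intensities[, , band] / 1000
  rho <- sqrt((row(img) - 1 - truth$center_px[1])^2 +
                (col(img) - 1 - truth$center_px[2])^2)
  inside <- truth$mask
  ord <- order(rho[inside])
  tau_sorted <- img[inside][ord]
  expect_true(all(diff(tau_sorted) >= -1e-12))
})

test_that("slab-thickness mu underestimates the generator's mu, with bias
           growing in mu*r", {
  r <- 100
  murs <- c(0.2, 0.5, 1, 2, 4)
  bias <- vapply(murs, function(mur) {
    mu_true <- mur / r
    tbar <- analytic_disk_transmittance(mu_true, r, 0)
    mu_slab <- -log(tbar) / (2 * r)
    mu_true - mu_slab
  }, 0)
  expect_true(all(bias > 0))
  expect_true(all(diff(bias) > 0))
})

test_that("overlapping or out-of-frame eggs are rejected at scene build", {
  grid <- default_grid()
  e1 <- synthetic_egg(50, c(40, 40), list(), 0.01)
  e2 <- synthetic_egg(50, c(50, 50), list(), 0.01)
  expect_error(scene_spec(120, 120, grid, list(e1, e2), 2.5), "overlap")
  expect_error(scene_spec(50, 50, grid, list(e1), 2.5), "fit")
})

test_that("bt_sweep ground truths hit 10..90% within solver tolerance", {
  sc <- preset_scene("bt_sweep")
  truths <- vapply(render_cube(sc)$truth,
                   function(t) t$bio_transparency_pct, 0)
  expect_equal(sort(truths), seq(10, 90, 10), tolerance = 0.1 / 50)
})

test_that("transparent_like and size_sweep presets match their contracts", {
  tl <- render_cube(preset_scene("transparent_like"))
  expect_gte(tl$truth[[1]]$bio_transparency_pct, 85)
  ss <- preset_scene("size_sweep")
  expect_equal(sort(vapply(ss$eggs, function(e) 2 * e$radius_um, 0)),
               c(120, 200, 300, 381))
  mus <- vapply(ss$eggs, function(e) e$baseline_mu_per_um, 0)
  expect_equal(length(unique(mus)), 1)   # fixed mu across sizes
  expect_error(preset_scene("no_such_preset"))
})

test_that("scenes survive a JSON round trip", {
  sc <- one_egg_scene(pigments = list(pigment_band(520, 25, 0.003)),
                      noise_sd = 12, seed = 5)
  path <- file.path(withr::local_tempdir(), "scene.json")
  scene_to_json(sc, path)
  back <- scene_from_json(path)
  expect_equal(back$eggs[[1]]$radius_um, sc$eggs[[1]]$radius_um)
  expect_equal(back$eggs[[1]]$pigments[[1]]$center_nm, 520)
  expect_identical(render_cube(back)$cube$intensities,
                   render_cube(sc)$cube$intensities)
})

test_that("ground truth table flattens per-egg truths", {
  rc <- render_cube(preset_scene("size_sweep"))
  tab <- ground_truth_table(rc$truth)
  expect_equal(nrow(tab), 4)
  expect_equal(sort(tab$diameter_um), c(120, 200, 300, 381))
  expect_true(all(tab$bio_transparency_pct_truth > 0))
})
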