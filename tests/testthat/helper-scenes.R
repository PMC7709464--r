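# Shared builders for synthetic test scenes and independent oracles.

default_grid <- function() make_grid(380, 1000, 5)

# A small single-egg scene: radius in um, frame sized to fit with margin.
one_egg_scene <- function(radius_um = 75, pixel_size_um = 2.5,
                          baseline_mu = 0.004, pigments = list(),
                          reflection_loss = 0.04, noise_sd = 0, seed = 1,
                          gradient = 0) {
  r_px <- radius_um / pixel_size_um
  side <- 2 * ceiling(r_px) + 21
  egg <- synthetic_egg(radius_um, c((side - 1) / 2, (side - 1) / 2),
                       pigments, baseline_mu, reflection_loss)
  scene_spec(side, side, default_grid(), list(egg), pixel_size_um,
             background_intensity = 1000, illumination_gradient = gradient,
             noise_sd_counts = noise_sd, seed = seed)
}

# Numerical-quadrature oracle for the area-averaged sphere transmittance,
# independent of the closed form used by the package.
quadrature_disk_transmittance <- function(mu, radius_um, reflection_loss = 0) {
  (1 - reflection_loss) * 2 / radius_um^2 *
    stats::integrate(function(rho) exp(-2 * mu * sqrt(radius_um^2 - rho^2)) *
                       rho,
                     0, radius_um, rel.tol = 1e-12)$value
}

# Constant-tau spectrum on the default grid.
const_spectrum <- function(tau, grid = default_grid(), egg_id = "t") {
  transmittance_spectrum(grid, rep(tau, length(grid$wavelengths)),
                         egg_id = egg_id)
}

# Measure every egg of a rendered scene through the full pipeline; returns a
# data frame of recovered vs ground-truth values matched by centroid.
measure_scene <- function(rendered, ...) {
  regs <- segment_eggs(rendered$cube, ...)
  if (length(regs) == 0) return(NULL)
  bg <- estimate_background_spectrum(
    rendered$cube, background_mask(rendered$cube, regs))
  rows <- lapply(seq_along(regs), function(i) {
    reg <- regs[[i]]
    k <- which.min(vapply(rendered$truth, function(t)
      sum((t$center_px - reg$centroid)^2), 0))
    sp <- egg_transmittance(rendered$cube, reg, bg, egg_id = i)
    data.frame(
      bt_rec = bio_transparency(sp),
      bt_truth = rendered$truth[[k]]$bio_transparency_pct,
      diam_rec = reg$equivalent_diameter_um,
      diam_truth = rendered$truth[[k]]$diameter_um)
  })
  do.call(rbind, rows)
}
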