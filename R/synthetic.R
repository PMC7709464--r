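#' A Gaussian pigment absorption band
#'
#' One pigment's contribution to the attenuation spectrum: a Gaussian bump in
#' mu(lambda) centered on the absorption peak. Visible-range pigment bands are
#' what produce the characteristic transmittance dips of colored eggs.
#'
#' @param center_nm Absorption peak wavelength (nm).
#' @param width_nm Gaussian SD (nm), > 0.
#' @param amplitude_per_um Peak contribution to mu (1/um), >= 0.
#' @return A `pigment_band` object.
#' @export
pigment_band <- function(center_nm, width_nm, amplitude_per_um) {
  if (width_nm <= 0) stop("width_nm must be positive")
  if (amplitude_per_um < 0) stop("amplitude_per_um must be nonnegative")
  structure(list(center_nm = center_nm, width_nm = width_nm,
                 amplitude_per_um = amplitude_per_um),
            class = "pigment_band")
}

#' Specification of one synthetic egg
#'
#' The forward model treats an egg as a homogeneous attenuating sphere with a
#' wavelength-independent surface reflection loss. Scattering is not modeled
#' separately: it is folded into the total attenuation mu, which is all a
#' transmittance measurement can see.
#'
#' @param radius_um Sphere radius (um), > 0.
#' @param center_px Center `(row, col)` in 0-based pixel coordinates.
#' @param pigments List of [pigment_band()] objects.
#' @param baseline_mu_per_um Wavelength-independent attenuation floor (1/um).
#' @param reflection_loss Fraction of light lost at the surfaces, in [0, 1).
#' @return A `synthetic_egg` object.
#' @export
synthetic_egg <- function(radius_um, center_px, pigments = list(),
                          baseline_mu_per_um = 0, reflection_loss = 0.04) {
  if (radius_um <= 0) stop("radius_um must be positive")
  if (reflection_loss < 0 || reflection_loss >= 1) {
    stop("reflection_loss must be in [0, 1)")
  }
  if (baseline_mu_per_um < 0) stop("baseline_mu_per_um must be nonnegative")
  structure(list(radius_um = radius_um, center_px = center_px,
                 pigments = pigments,
                 baseline_mu_per_um = baseline_mu_per_um,
                 reflection_loss = reflection_loss),
            class = "synthetic_egg")
}

#' Attenuation spectrum of a synthetic egg
#'
#' `mu(lambda) = baseline + sum_k amplitude_k *
#' exp(-(lambda - center_k)^2 / (2 width_k^2))`.
#'
#' @param egg A `synthetic_egg`.
#' @param grid A `wavelength_grid`.
#' @return Per-band mu (1/um), length = band count.
#' @export
mu_spectrum <- function(egg, grid) {
  stopifnot(inherits(egg, "synthetic_egg"), inherits(grid, "wavelength_grid"))
  wl <- grid$wavelengths
  mu <- rep(egg$baseline_mu_per_um, length(wl))
  for (p in egg$pigments) {
    mu <- mu + p$amplitude_per_um *
      exp(-(wl - p$center_nm)^2 / (2 * p$width_nm^2))
  }
  mu
}

#' Chord path length through a sphere
#'
#' Light crossing a sphere at radial offset rho from the center travels
#' `2 * sqrt(r^2 - rho^2)`: the full diameter through the center, zero at the
#' tangent. This is why a homogeneous egg appears brighter toward its rim.
#'
#' @param radius_um Sphere radius (um).
#' @param rho_um Radial offset (um), in `[0, radius_um]`; vectorized.
#' @return Path length (um).
#' @export
chord_path_length <- function(radius_um, rho_um) {
  if (radius_um <= 0) stop("radius_um must be positive")
  if (any(rho_um < 0) || any(rho_um > radius_um)) {
    stop("rho_um must lie in [0, radius_um]")
  }
  2 * sqrt(radius_um^2 - rho_um^2)
}

#' Area-averaged transmittance of an attenuating sphere
#'
#' Closed form of the disk-average of Beer-Lambert transmission along chords,
#' `(2 / r^2) * integral_0^r exp(-2 mu sqrt(r^2 - rho^2)) rho drho`, times the
#' surface transmission `(1 - R)`:
#' `Tbar = (1 - R) * (1 - (1 + 2 mu r) exp(-2 mu r)) / (2 mu^2 r^2)`,
#' continuously extended to `(1 - R)` at `mu = 0`. This is the analytic
#' ground truth against which the imaging pipeline is validated.
#'
#' @param mu Attenuation coefficient (1/um); vectorized.
#' @param radius_um Sphere radius (um).
#' @param reflection_loss Surface loss fraction R in [0, 1).
#' @return Area-averaged transmittance, dimensionless.
#' @export
analytic_disk_transmittance <- function(mu, radius_um, reflection_loss = 0) {
  if (radius_um <= 0) stop("radius_um must be positive")
  if (any(mu < 0)) stop("mu must be nonnegative")
  z <- 2 * mu * radius_um
  out <- numeric(length(z))
  small <- z < 1e-4
  # series around z = 0: 2[1 - (1+z)e^-z]/z^2 = 1 - 2z/3 + z^2/4 - z^3/15
  out[small] <- 1 - 2 * z[small] / 3 + z[small]^2 / 4 - z[small]^3 / 15
  zb <- z[!small]
  out[!small] <- (1 - (1 + zb) * exp(-zb)) / (zb^2 / 2)
  (1 - reflection_loss) * out
}

#' Specification of a synthetic hyperspectral scene
#'
#' @param height_px,width_px Frame size (px).
#' @param grid `wavelength_grid` of the rendered cube.
#' @param eggs List of [synthetic_egg()]; must fit in the frame with a 2-px
#'   margin and be pairwise non-overlapping after a 2-px dilation.
#' @param pixel_size_um Pixel edge (um), shared by the whole frame.
#' @param background_intensity Incident level I0: a scalar (flat spectrum) or
#'   per-band vector (counts).
#' @param illumination_gradient Linear left-to-right illumination ramp as a
#'   fraction of I0 (0 = uniform); applied to background and specimens alike.
#' @param noise_sd_counts Additive Gaussian sensor noise SD (counts),
#'   truncated at zero.
#' @param seed Random seed used by [render_cube()].
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(height_px, width_px, grid, eggs, pixel_size_um,
                       background_intensity = 1000,
                       illumination_gradient = 0,
                       noise_sd_counts = 0, seed = 1L) {
  stopifnot(inherits(grid, "wavelength_grid"))
  if (noise_sd_counts < 0) stop("noise_sd_counts must be nonnegative")
  margin <- 2
  for (e in eggs) {
    r_px <- e$radius_um / pixel_size_um
    if (e$center_px[1] - r_px < margin || e$center_px[2] - r_px < margin ||
        e$center_px[1] + r_px > height_px - 1 - margin ||
        e$center_px[2] + r_px > width_px - 1 - margin) {
      stop("egg does not fit inside the frame with a ", margin, "-px margin")
    }
  }
  if (length(eggs) > 1) {
    for (i in seq_len(length(eggs) - 1)) {
      for (j in (i + 1):length(eggs)) {
        dist_px <- sqrt(sum((eggs[[i]]$center_px - eggs[[j]]$center_px)^2))
        min_dist <- (eggs[[i]]$radius_um + eggs[[j]]$radius_um) /
          pixel_size_um + 2 * margin
        if (dist_px < min_dist) {
          stop(sprintf("eggs %d and %d overlap after dilation", i, j))
        }
      }
    }
  }
  bg <- background_intensity
  if (!length(bg) %in% c(1L, n_bands(grid))) {
    stop("background_intensity must be scalar or one value per band")
  }
  if (any(bg <= 0)) stop("background_intensity must be positive")
  structure(list(height_px = height_px, width_px = width_px, grid = grid,
                 eggs = eggs, pixel_size_um = pixel_size_um,
                 background_intensity = bg,
                 illumination_gradient = illumination_gradient,
                 noise_sd_counts = noise_sd_counts, seed = seed),
            class = "scene_spec")
}

#' Render a synthetic scene into a hyperspectral cube
#'
#' Background pixels receive `I0(lambda)` times the illumination gradient;
#' pixels inside an egg's outline at radial offset rho receive
#' `I0(lambda) * (1 - R) * exp(-mu(lambda) * l(rho))` with `l` the chord path
#' length. Additive Gaussian noise (SD `noise_sd_counts`) is then applied to
#' every pixel and truncated at zero. Rendering is deterministic given the
#' scene seed. Ground truth is computed analytically from the scene
#' parameters, never from the rendered image, so oracle tests cannot be
#' circular.
#'
#' @param scene A `scene_spec`.
#' @return List with `cube` (a `hyper_cube`) and `truth`: one entry per egg
#'   holding `diameter_um`, `mu_spectrum`, `mu_visible_truth`, `analytic_tau`
#'   (per band), `bio_transparency_pct`, `center_px`, `radius_px` and the
#'   rendered pixel `mask`.
#' @export
render_cube <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  H <- scene$height_px; W <- scene$width_px
  B <- n_bands(scene$grid)
  I0 <- if (length(scene$background_intensity) == 1) {
    rep(scene$background_intensity, B)
  } else {
    scene$background_intensity
  }
  g <- scene$illumination_gradient
  col0 <- matrix(rep(0:(W - 1), each = H), H, W)
  grad <- 1 + g * (col0 / max(1, W - 1) - 0.5)
  flat <- outer(as.vector(grad), I0)          # (H*W) x B incident field
  truth <- vector("list", length(scene$eggs))
  vis_sel <- band_selector(scene$grid, visible_band())
  row0 <- matrix(rep(0:(H - 1), W), H, W)
  for (k in seq_along(scene$eggs)) {
    e <- scene$eggs[[k]]
    mu <- mu_spectrum(e, scene$grid)
    r_px <- e$radius_um / scene$pixel_size_um
    rho_px <- sqrt((row0 - e$center_px[1])^2 + (col0 - e$center_px[2])^2)
    inside <- rho_px <= r_px
    idx <- which(as.vector(inside))
    ell <- chord_path_length(e$radius_um,
                             pmin(rho_px[inside], r_px) * scene$pixel_size_um)
    trans <- (1 - e$reflection_loss) * exp(-outer(ell, mu))
    flat[idx, ] <- flat[idx, , drop = FALSE] * trans
    tau_true <- analytic_disk_transmittance(mu, e$radius_um,
                                            e$reflection_loss)
    truth[[k]] <- list(
      egg_index = k,
      diameter_um = 2 * e$radius_um,
      radius_px = r_px,
      center_px = e$center_px,
      mask = inside,
      mu_spectrum = mu,
      mu_visible_truth = mean(mu[vis_sel]),
      analytic_tau = tau_true,
      bio_transparency_pct = 100 * mean(tau_true[vis_sel])
    )
  }
  if (scene$noise_sd_counts > 0) {
    set.seed(scene$seed)
    flat <- pmax(0, flat + stats::rnorm(length(flat),
                                        sd = scene$noise_sd_counts))
  }
  cube <- hyper_cube(array(flat, dim = c(H, W, B)), scene$grid,
                     scene$pixel_size_um,
                     metadata = list(source = "ovitrans synthetic scene",
                                     seed = scene$seed))
  list(cube = cube, truth = truth)
}

#' Ground truth as a flat table
#'
#' @param truth The `truth` list from [render_cube()].
#' @return Data frame: egg_index, diameter_um, bio_transparency_pct_truth,
#'   mu_visible_truth.
#' @export
ground_truth_table <- function(truth) {
  do.call(rbind, lapply(truth, function(t) data.frame(
    egg_index = t$egg_index,
    diameter_um = t$diameter_um,
    bio_transparency_pct_truth = t$bio_transparency_pct,
    mu_visible_truth = t$mu_visible_truth)))
}

#' Solve the attenuation baseline that hits a target bio-transparency
#'
#' Root-solves the flat (baseline) part of mu so that the analytic visible
#' bio-transparency of a sphere -- with any fixed pigment bands on top --
#' equals `target_pct`.
#'
#' @param target_pct Target bio-transparency (percent, in (0, 100)).
#' @param radius_um Sphere radius (um).
#' @param reflection_loss Surface loss fraction.
#' @param pigments Fixed pigment bands included in mu.
#' @param grid Wavelength grid (default 380--1000 nm / 5 nm).
#' @param tol Absolute tolerance on the achieved percent.
#' @return Baseline mu (1/um).
#' @export
solve_baseline_for_bt <- function(target_pct, radius_um,
                                  reflection_loss = 0.04, pigments = list(),
                                  grid = make_grid(380, 1000, 5),
                                  tol = 1e-6) {
  if (target_pct <= 0 || target_pct >= 100) {
    stop("target_pct must be in (0, 100)")
  }
  vis <- band_selector(grid, visible_band())
  probe <- synthetic_egg(radius_um, c(0, 0), pigments, 0, reflection_loss)
  bt_of <- function(b) {
    mu <- mu_spectrum(probe, grid) + b
    100 * mean(analytic_disk_transmittance(mu[vis], radius_um,
                                           reflection_loss))
  }
  if (bt_of(0) < target_pct) {
    stop(sprintf(
      "target %.1f%% unreachable: pigments/reflection alone give %.1f%%",
      target_pct, bt_of(0)))
  }
  hi <- 1 / radius_um
  while (bt_of(hi) > target_pct) hi <- hi * 2
  stats::uniroot(function(b) bt_of(b) - target_pct, c(0, hi),
                 tol = tol / (100 * radius_um))$root
}

#' Named preset scenes spanning the observed trait ranges
#'
#' Deterministic scene builders used by the validation suite:
#' \describe{
#'   \item{transparent_like}{one highly transparent egg (ground-truth
#'     bio-transparency 88\%, like the most transparent eggs observed).}
#'   \item{opaque_like}{one strongly attenuating egg (ground truth 18.7\%).}
#'   \item{two_pigment}{one egg with Gaussian pigment bands at 500 and
#'     600 nm, producing two visible transmittance dips.}
#'   \item{size_sweep}{four eggs of diameter 120, 200, 300 and 381 um --
#'     the extremes and midrange of reported egg sizes -- at a fixed
#'     mu(lambda).}
#'   \item{bt_sweep}{nine eggs whose ground-truth bio-transparencies are
#'     10, 20, ..., 90\%, spanning the observed 10--90\% trait range, by
#'     root-solving the attenuation baseline.}
#' }
#'
#' @param name Preset name.
#' @param seed Seed stored on the scene (drives render noise only).
#' @param snr Background-to-noise ratio; `Inf` (default) renders noiselessly,
#'   otherwise `noise_sd = background / snr`.
#' @return A `scene_spec`.
#' @export
preset_scene <- function(name = c("transparent_like", "opaque_like",
                                  "two_pigment", "size_sweep", "bt_sweep"),
                         seed = 1L, snr = Inf) {
  name <- match.arg(name)
  grid <- make_grid(380, 1000, 5)
  bg <- 1000
  noise <- if (is.finite(snr)) bg / snr else 0
  R <- 0.04
  build <- function(H, W, eggs, ps) {
    scene_spec(H, W, grid, eggs, ps, background_intensity = bg,
               noise_sd_counts = noise, seed = seed)
  }
  dip <- list(pigment_band(490, 30, 0.002))   # mild 440-540 nm absorption
  switch(name,
    transparent_like = {
      r <- 80; ps <- 2.5
      b <- solve_baseline_for_bt(88, r, R, dip, grid)
      build(140, 140, list(
        synthetic_egg(r, c(69, 69), dip, b, R)), ps)
    },
    opaque_like = {
      r <- 80; ps <- 2.5
      b <- solve_baseline_for_bt(18.7, r, R, list(), grid)
      build(140, 140, list(
        synthetic_egg(r, c(69, 69), list(), b, R)), ps)
    },
    two_pigment = {
      r <- 100; ps <- 2.5
      pig <- list(pigment_band(500, 18, 0.008),
                  pigment_band(600, 18, 0.008))
      build(160, 160, list(
        synthetic_egg(r, c(79, 79), pig, 0.001, R)), ps)
    },
    size_sweep = {
      ps <- 2.5
      diam <- c(120, 200, 300, 381)
      radii_px <- diam / 2 / ps
      gaps <- 30
      centers_col <- cumsum(c(0, head(radii_px, -1) + radii_px[-1] + gaps)) +
        radii_px[1] + 10
      H <- 2 * ceiling(max(radii_px)) + 30
      eggs <- lapply(seq_along(diam), function(i) {
        synthetic_egg(diam[i] / 2, c((H - 1) / 2, centers_col[i]),
                      list(), 0.004, R)
      })
      build(H, ceiling(max(centers_col) + max(radii_px)) + 12, eggs, ps)
    },
    bt_sweep = {
      ps <- 5; r <- 100   # 200-um eggs, radius 20 px
      targets <- seq(10, 90, by = 10)
      centers <- expand.grid(row = c(40, 110, 180), col = c(40, 110, 180))
      eggs <- lapply(seq_along(targets), function(i) {
        b <- solve_baseline_for_bt(targets[i], r, R, list(), grid)
        synthetic_egg(r, c(centers$row[i], centers$col[i]), list(), b, R)
      })
      build(220, 220, eggs, ps)
    })
}

#' Serialize a scene to JSON
#' @param scene A `scene_spec`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
scene_to_json <- function(scene, path) {
  s <- list(
    height_px = scene$height_px, width_px = scene$width_px,
    grid = list(start_nm = scene$grid$start_nm, stop_nm = scene$grid$stop_nm,
                step_nm = scene$grid$step_nm),
    pixel_size_um = scene$pixel_size_um,
    background_intensity = scene$background_intensity,
    illumination_gradient = scene$illumination_gradient,
    noise_sd_counts = scene$noise_sd_counts, seed = scene$seed,
    eggs = lapply(scene$eggs, function(e) list(
      radius_um = e$radius_um, center_px = e$center_px,
      baseline_mu_per_um = e$baseline_mu_per_um,
      reflection_loss = e$reflection_loss,
      pigments = lapply(e$pigments, unclass)))
  )
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a scene from JSON
#' @param path JSON file written by [scene_to_json()].
#' @return A `scene_spec`.
#' @export
scene_from_json <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = FALSE)
  grid <- make_grid(s$grid$start_nm, s$grid$stop_nm, s$grid$step_nm)
  eggs <- lapply(s$eggs, function(e) synthetic_egg(
    e$radius_um, unlist(e$center_px),
    lapply(e$pigments, function(p)
      pigment_band(p$center_nm, p$width_nm, p$amplitude_per_um)),
    e$baseline_mu_per_um, e$reflection_loss))
  scene_spec(s$height_px, s$width_px, grid, eggs, s$pixel_size_um,
             unlist(s$background_intensity), s$illumination_gradient,
             s$noise_sd_counts, s$seed)
}
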