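#' Background intensity spectrum of a cube
#'
#' Per-band median intensity over the background pixels; the median keeps the
#' incident-light estimate robust to stray debris or dead pixels. This is the
#' incident spectrum I0(lambda) against which specimen transmittance is taken
#' (the background is the seawater-filled dish, not a separate blank frame).
#'
#' @param cube A `hyper_cube`.
#' @param bg A `background_mask` from [background_mask()].
#' @return An `intensity_spectrum` (fields `grid`, `values`, `source`).
#' @export
estimate_background_spectrum <- function(cube, bg) {
  validate_cube(cube)
  stopifnot(inherits(bg, "background_mask"))
  if (!any(bg$mask)) stop("background mask is empty")
  d <- cube_dims(cube)
  flat <- matrix(cube$intensities, d[1] * d[2], d[3])
  vals <- apply(flat[as.vector(bg$mask), , drop = FALSE], 2, stats::median)
  bad <- which(vals <= 0)
  if (length(bad)) {
    stop("degenerate background: median intensity <= 0 at band(s) ",
         paste(cube$grid$wavelengths[bad], collapse = ", "), " nm")
  }
  structure(list(grid = cube$grid, values = vals, source = "background"),
            class = "intensity_spectrum")
}

#' Transmittance spectrum of one egg
#'
#' Per band, tau(lambda) is the mean over the region's pixels of the
#' per-pixel ratio I(pixel, lambda) / I0(lambda). With I0 constant per band
#' this equals the ratio of means; the per-pixel form also supports spatially
#' varying QC. tau is not clipped at 1 -- clipping would bias the
#' bio-transparency statistic upward under noise; values above 1 are left for
#' downstream QC flagging.
#'
#' @param cube A `hyper_cube`.
#' @param region An `egg_region` from the same cube.
#' @param background `intensity_spectrum` of the background (I0).
#' @param egg_id Identifier stored on the spectrum.
#' @param roi_fraction Optional central-disk ROI: keep only pixels within this
#'   fraction of the equivalent radius from the centroid (default 1 = whole
#'   mask).
#' @return A `transmittance_spectrum` (fields `grid`, `tau`, `egg_id`,
#'   `n_pixels`).
#' @export
egg_transmittance <- function(cube, region, background,
                              egg_id = region$label, roi_fraction = 1) {
  validate_cube(cube)
  stopifnot(inherits(region, "egg_region"),
            inherits(background, "intensity_spectrum"))
  if (!identical(background$grid$wavelengths, cube$grid$wavelengths)) {
    stop("background spectrum grid does not match the cube grid")
  }
  if (any(background$values <= 0)) {
    stop("degenerate background: nonpositive I0 band(s)")
  }
  mask <- region$mask
  if (roi_fraction < 1) {
    r_eq <- sqrt(region$area_px / pi) * roi_fraction
    rr <- row(mask) - 1 - region$centroid["row"]
    cc <- col(mask) - 1 - region$centroid["col"]
    mask <- mask & (rr^2 + cc^2 <= r_eq^2)
    if (!any(mask)) stop("ROI fraction leaves no pixels")
  }
  d <- cube_dims(cube)
  flat <- matrix(cube$intensities, d[1] * d[2], d[3])
  px <- flat[as.vector(mask), , drop = FALSE]
  ratios <- sweep(px, 2, background$values, "/")
  structure(
    list(grid = cube$grid, tau = colMeans(ratios), egg_id = egg_id,
         n_pixels = nrow(px)),
    class = "transmittance_spectrum")
}

#' Construct a transmittance spectrum directly
#'
#' For spectra coming from sources other than a cube (tables, simulations).
#'
#' @param grid `wavelength_grid`.
#' @param tau Per-band transmittance, same length as the grid, all >= 0.
#' @param egg_id Identifier.
#' @param n_pixels Pixels averaged (informational).
#' @return A `transmittance_spectrum`.
#' @export
transmittance_spectrum <- function(grid, tau, egg_id = NA, n_pixels = NA) {
  stopifnot(inherits(grid, "wavelength_grid"))
  if (length(tau) != n_bands(grid)) stop("tau length must match the grid")
  if (anyNA(tau) || any(!is.finite(tau))) stop("tau must be finite")
  if (any(tau < 0)) stop("tau must be nonnegative")
  structure(list(grid = grid, tau = tau, egg_id = egg_id,
                 n_pixels = n_pixels),
            class = "transmittance_spectrum")
}

#' @export
print.transmittance_spectrum <- function(x, ...) {
  cat(sprintf(
    "transmittance_spectrum [%s]: %d bands, tau in [%.3f, %.3f], %s px\n",
    x$egg_id, n_bands(x$grid), min(x$tau), max(x$tau),
    format(x$n_pixels)))
  invisible(x)
}

#' Mean transmittance over a wavelength band
#'
#' Unweighted mean of tau over grid bands with
#' `low_nm <= lambda <= high_nm` (both edges inclusive).
#'
#' @param spectrum A `transmittance_spectrum`.
#' @param band A `band_def`; must overlap the grid.
#' @return Mean transmittance (dimensionless).
#' @export
band_mean <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "transmittance_spectrum"))
  sel <- band_selector(spectrum$grid, band)
  mean(spectrum$tau[sel])
}

#' Detect local transmittance minima (absorption dips)
#'
#' Smooths tau with a centered moving average (edges use the partial window),
#' then reports strict local minima inside `band` whose prominence -- the
#' lower of the two flanking maxima minus the minimum's value -- reaches
#' `min_prominence`. Flanking maxima are the largest smoothed values reached
#' walking outward from the minimum before a deeper value occurs (topographic
#' prominence of the inverted spectrum).
#'
#' @param spectrum A `transmittance_spectrum`.
#' @param smooth_window_bands Odd moving-average window (bands).
#' @param min_prominence Minimum dip depth, transmittance units.
#' @param band Search window; default visible 400--760 nm.
#' @return Sorted wavelengths (nm) of qualifying minima; possibly empty.
#' @export
detect_local_minima <- function(spectrum, smooth_window_bands = 3,
                                min_prominence = 0.02,
                                band = visible_band()) {
  stopifnot(inherits(spectrum, "transmittance_spectrum"))
  w <- as.integer(smooth_window_bands)
  if (w < 1 || w %% 2 == 0) stop("smooth_window_bands must be odd and >= 1")
  y <- moving_average(spectrum$tau, w)
  sel <- which(band_selector(spectrum$grid, band))
  n <- length(y)
  out <- numeric(0)
  for (i in sel) {
    if (i == 1 || i == n) next
    if (!(y[i] < y[i - 1] && y[i] < y[i + 1])) next    # strict local minimum
    left_max <- suppressWarnings(max(walk_extreme(y, i, -1L)))
    right_max <- suppressWarnings(max(walk_extreme(y, i, +1L)))
    if (min(left_max, right_max) - y[i] >= min_prominence) {
      out <- c(out, spectrum$grid$wavelengths[i])
    }
  }
  sort(out)
}

# Values encountered walking from position i in direction dir until a value
# below y[i] appears (or the edge); used for topographic prominence.
walk_extreme <- function(y, i, dir) {
  vals <- numeric(0)
  j <- i + dir
  while (j >= 1 && j <= length(y) && y[j] >= y[i]) {
    vals <- c(vals, y[j])
    j <- j + dir
  }
  if (length(vals) == 0) -Inf else vals
}

# Centered moving average preserving length; partial windows at the edges.
moving_average <- function(x, w) {
  if (w == 1) return(x)
  h <- (w - 1) / 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Export spectra as long- and wide-format CSV
#'
#' @param spectra List of `transmittance_spectrum`.
#' @param long_path Optional destination for long format
#'   (egg_id, wavelength_nm, tau).
#' @param wide_path Optional destination for wide format (one row per egg,
#'   one column per band).
#' @return List with `long` and `wide` data frames, invisibly when written.
#' @export
export_spectra <- function(spectra, long_path = NULL, wide_path = NULL) {
  stopifnot(length(spectra) > 0)
  grid <- spectra[[1]]$grid
  long <- do.call(rbind, lapply(spectra, function(s) {
    data.frame(egg_id = s$egg_id, wavelength_nm = grid$wavelengths,
               tau = s$tau)
  }))
  wide <- do.call(rbind, lapply(spectra, function(s) s$tau))
  wide <- data.frame(egg_id = vapply(spectra, function(s)
    as.character(s$egg_id), ""), wide)
  names(wide) <- c("egg_id", paste0("nm", grid$wavelengths))
  if (!is.null(long_path)) utils::write.csv(long, long_path, row.names = FALSE)
  if (!is.null(wide_path)) utils::write.csv(wide, wide_path, row.names = FALSE)
  res <- list(long = long, wide = wide)
  if (is.null(long_path) && is.null(wide_path)) res else invisible(res)
}
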