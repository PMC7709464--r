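#' Construct an evenly spaced wavelength grid
#'
#' The sampled wavelength axis shared by all spectra and cubes. The default
#' acquisition grid used throughout is 380--1000 nm at 5-nm steps (125 bands),
#' matching a visible/NIR hyperspectral camera sweep.
#'
#' @param start_nm First band-center wavelength (nm).
#' @param stop_nm Last band-center wavelength (nm); must exceed `start_nm`.
#' @param step_nm Band spacing (nm); must divide `stop_nm - start_nm` exactly.
#' @return An object of class `wavelength_grid` with fields `start_nm`,
#'   `stop_nm`, `step_nm` and the vector `wavelengths`.
#' @examples
#' g <- make_grid(380, 1000, 5)
#' length(g$wavelengths) # 125
#' @export
make_grid <- function(start_nm, stop_nm, step_nm) {
  if (!is.numeric(start_nm) || length(start_nm) != 1 || !is.finite(start_nm) ||
      start_nm <= 0) {
    stop("start_nm must be a single positive wavelength (nm)")
  }
  if (!is.numeric(stop_nm) || length(stop_nm) != 1 || !is.finite(stop_nm) ||
      stop_nm <= start_nm) {
    stop("stop_nm must be a single wavelength (nm) greater than start_nm")
  }
  if (!is.numeric(step_nm) || length(step_nm) != 1 || !is.finite(step_nm) ||
      step_nm <= 0) {
    stop("step_nm must be a single positive wavelength increment (nm)")
  }
  n_steps <- (stop_nm - start_nm) / step_nm
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stop("step_nm must divide (stop_nm - start_nm) exactly; got step_nm = ",
         step_nm, " over a span of ", stop_nm - start_nm, " nm")
  }
  wl <- start_nm + step_nm * seq(0, round(n_steps))
  structure(
    list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
         wavelengths = wl),
    class = "wavelength_grid"
  )
}

#' Build a wavelength grid from an explicit wavelength vector
#'
#' Validates even spacing; used when wavelengths come from file metadata.
#'
#' @param wavelengths Strictly increasing, evenly spaced band centers (nm).
#' @param tol Relative tolerance on spacing uniformity.
#' @return A `wavelength_grid`.
#' @export
grid_from_wavelengths <- function(wavelengths, tol = 1e-6) {
  if (length(wavelengths) < 2) {
    stop("need at least two wavelengths to define a grid")
  }
  d <- diff(wavelengths)
  if (any(d <= 0)) stop("wavelengths must be strictly increasing")
  step <- d[1]
  if (any(abs(d - step) > tol * step)) {
    stop("wavelengths are unevenly spaced; a regular grid is required")
  }
  make_grid(wavelengths[1], wavelengths[length(wavelengths)], step)
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("wavelength_grid: %g-%g nm, step %g nm (%d bands)\n",
              x$start_nm, x$stop_nm, x$step_nm, length(x$wavelengths)))
  invisible(x)
}

n_bands <- function(grid) length(grid$wavelengths)

#' Index of the band nearest a wavelength
#'
#' @param grid A `wavelength_grid`.
#' @param wavelength Query wavelength (nm), within `[start_nm, stop_nm]`.
#' @param zero_based Return 0-based index (default `FALSE`: R's 1-based).
#' @return Integer band position; wavelengths lying exactly on the grid map to
#'   their own band.
#' @export
band_index <- function(grid, wavelength, zero_based = FALSE) {
  stopifnot(inherits(grid, "wavelength_grid"))
  if (wavelength < grid$start_nm || wavelength > grid$stop_nm) {
    stop(sprintf("wavelength %g nm outside grid range [%g, %g]",
                 wavelength, grid$start_nm, grid$stop_nm))
  }
  i0 <- round((wavelength - grid$start_nm) / grid$step_nm)
  if (zero_based) as.integer(i0) else as.integer(i0) + 1L
}

#' Define a named wavelength band
#'
#' Band edges are inclusive on both sides; the visible band used for
#' bio-transparency is fixed at 400--760 nm and contains exactly 73 samples on
#' the default 5-nm grid.
#'
#' @param name Label, e.g. `"VIS"`.
#' @param low_nm Inclusive lower edge (nm).
#' @param high_nm Inclusive upper edge (nm).
#' @return A `band_def` object.
#' @export
band_def <- function(name, low_nm, high_nm) {
  if (!is.character(name) || length(name) != 1) stop("name must be a string")
  if (low_nm >= high_nm) stop("low_nm must be below high_nm")
  structure(list(name = name, low_nm = low_nm, high_nm = high_nm),
            class = "band_def")
}

#' Default spectral bands: UVA, visible, near-infrared
#'
#' @return Named list of `band_def`: UVA 380--400 nm, VIS 400--760 nm,
#'   NIR 760--1000 nm.
#' @export
default_bands <- function() {
  list(UVA = band_def("UVA", 380, 400),
       VIS = band_def("VIS", 400, 760),
       NIR = band_def("NIR", 760, 1000))
}

#' The visible band used by the bio-transparency statistic
#' @return `band_def` for 400--760 nm.
#' @export
visible_band <- function() band_def("VIS", 400, 760)

# Logical selector of grid bands inside a band definition (inclusive edges).
band_selector <- function(grid, band) {
  stopifnot(inherits(grid, "wavelength_grid"), inherits(band, "band_def"))
  sel <- grid$wavelengths >= band$low_nm & grid$wavelengths <= band$high_nm
  if (!any(sel)) {
    stop(sprintf("band %s [%g, %g] nm does not overlap grid [%g, %g] nm",
                 band$name, band$low_nm, band$high_nm,
                 grid$start_nm, grid$stop_nm))
  }
  sel
}
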