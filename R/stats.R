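#' Bio-transparency of a transmittance spectrum
#'
#' The headline statistic: 100 times the unweighted mean of tau over the
#' visible band, 400--760 nm inclusive. A perfectly transparent specimen
#' scores 100; an opaque one 0.
#'
#' @param spectrum A `transmittance_spectrum`.
#' @param visible `band_def`; defaults to the fixed visible band.
#' @return Percent, in `[0, 100 * max(tau)]`.
#' @export
bio_transparency <- function(spectrum, visible = visible_band()) {
  100 * band_mean(spectrum, visible)
}

#' Beer-Lambert attenuation coefficient spectrum
#'
#' Thickness-normalized log-loss per band:
#' `mu(lambda) = -log(tau(lambda)) / x`, with `x` the egg thickness --
#' here the equivalent-circle diameter in um, so mu is in 1/um. A large mu
#' means incident light is extinguished quickly along its path; mu removes
#' the egg-size dependence that bio-transparency retains. Bands with
#' `tau >= 1` give `mu <= 0` and are kept (flagged downstream); bands with
#' `tau <= 0` have no defined log-loss and are masked as `NA` (flooring them
#' would fabricate finite attenuation).
#'
#' @param spectrum A `transmittance_spectrum`.
#' @param diameter_um Egg thickness `x` (um), > 0.
#' @return An `attenuation_spectrum`: fields `grid`, `mu` (1/um, `NA` where
#'   masked), `diameter_um`, `n_masked`.
#' @export
attenuation_spectrum <- function(spectrum, diameter_um) {
  stopifnot(inherits(spectrum, "transmittance_spectrum"))
  if (!is.numeric(diameter_um) || length(diameter_um) != 1 ||
      diameter_um <= 0) {
    stop("diameter_um must be a single positive thickness (um)")
  }
  tau <- spectrum$tau
  mu <- rep(NA_real_, length(tau))
  ok <- tau > 0
  if (!any(ok)) {
    stop("degenerate spectrum: tau <= 0 at every band, mu undefined")
  }
  mu[ok] <- -log(tau[ok]) / diameter_um
  n_masked <- sum(!ok)
  if (n_masked > 0) {
    message(n_masked, " band(s) with tau <= 0 masked in attenuation spectrum")
  }
  structure(list(grid = spectrum$grid, mu = mu, diameter_um = diameter_um,
                 n_masked = n_masked),
            class = "attenuation_spectrum")
}

#' Mean attenuation coefficient over the visible band
#'
#' Unweighted mean of mu(lambda) over 400--760 nm, ignoring masked bands.
#' mu is computed per wavelength and then averaged, which preserves the
#' Beer-Lambert relation band-wise; the alternative (mu of the band-mean tau)
#' is available via `from_band_mean_tau`.
#'
#' @param mu_spectrum An `attenuation_spectrum`.
#' @param visible `band_def`, default 400--760 nm.
#' @return Mean visible attenuation (1/um).
#' @export
visible_attenuation <- function(mu_spectrum, visible = visible_band()) {
  stopifnot(inherits(mu_spectrum, "attenuation_spectrum"))
  sel <- band_selector(mu_spectrum$grid, visible)
  vals <- mu_spectrum$mu[sel]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    stop("degenerate spectrum: all visible bands masked")
  }
  mean(vals)
}

#' Attenuation from the band-mean transmittance (alternative ordering)
#'
#' `-log(band_mean(tau)) / x`: collapses the band first, then applies the
#' log; kept for comparison with the per-wavelength default.
#'
#' @inheritParams attenuation_spectrum
#' @param visible `band_def`.
#' @return Attenuation (1/um).
#' @export
from_band_mean_tau <- function(spectrum, diameter_um,
                               visible = visible_band()) {
  tbar <- band_mean(spectrum, visible)
  if (tbar <= 0) stop("band-mean tau is nonpositive; mu undefined")
  -log(tbar) / diameter_um
}

#' Per-egg statistics row
#'
#' Bundles the two statistics with identifiers into one tidy row, plus QC
#' flags: bands with tau above 1.05 (physically tau <= 1 up to noise) and
#' masked bands.
#'
#' @param spectrum A `transmittance_spectrum`.
#' @param diameter_um Egg thickness (um).
#' @param egg_id,individual_id,species Identifiers.
#' @param tau_qc_limit Per-band tau above this is counted as a QC flag.
#' @return One-row data frame: egg_id, individual_id, species, diameter_um,
#'   bio_transparency_pct, mu_visible_per_um, n_tau_gt1, n_masked_bands.
#' @export
compute_egg_stats <- function(spectrum, diameter_um, egg_id = spectrum$egg_id,
                              individual_id = NA, species = NA,
                              tau_qc_limit = 1.05) {
  mu <- attenuation_spectrum(spectrum, diameter_um)
  data.frame(
    egg_id = as.character(egg_id),
    individual_id = as.character(individual_id),
    species = as.character(species),
    diameter_um = diameter_um,
    bio_transparency_pct = bio_transparency(spectrum),
    mu_visible_per_um = visible_attenuation(mu),
    n_tau_gt1 = sum(spectrum$tau > tau_qc_limit),
    n_masked_bands = mu$n_masked,
    stringsAsFactors = FALSE
  )
}

#' Per-individual summary of egg statistics
#'
#' Mean and sample standard deviation (n - 1 denominator, the convention for
#' error bars) of bio-transparency and visible attenuation over the eggs of
#' one individual. With a single egg the SD is 0 and flagged.
#'
#' @param stats Data frame of per-egg rows (from [compute_egg_stats()]) for
#'   exactly one individual.
#' @return One-row data frame: individual_id, species, n_eggs, mean_bt_pct,
#'   sd_bt_pct, mean_mu, sd_mu, single_egg_flag.
#' @export
aggregate_individual <- function(stats) {
  stopifnot(is.data.frame(stats), nrow(stats) >= 1)
  ids <- unique(stats$individual_id)
  if (length(ids) != 1) {
    stop("aggregate_individual expects one individual; got ids: ",
         paste(ids, collapse = ", "))
  }
  n <- nrow(stats)
  sdev <- function(x) if (n == 1) 0 else stats::sd(x)
  data.frame(
    individual_id = ids,
    species = unique(stats$species)[1],
    n_eggs = n,
    mean_bt_pct = mean(stats$bio_transparency_pct),
    sd_bt_pct = sdev(stats$bio_transparency_pct),
    mean_mu = mean(stats$mu_visible_per_um),
    sd_mu = sdev(stats$mu_visible_per_um),
    single_egg_flag = n == 1,
    stringsAsFactors = FALSE
  )
}

#' Within-species spread of individual mean bio-transparencies
#'
#' Reports both readings of "variance across individuals": the population
#' variance (n denominator, in squared percent) of the individual means and
#' their range (max - min, in percent). Both are printed; with one individual
#' both are 0.
#'
#' @param summaries Data frame of per-individual rows (from
#'   [aggregate_individual()]) for exactly one species.
#' @return One-row data frame: species, n_individuals, variance_bt, range_bt,
#'   plus the individual means collapsed into a `individual_means` string.
#' @export
species_variance <- function(summaries) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1)
  sp <- unique(summaries$species)
  if (length(sp) != 1) {
    stop("species_variance expects one species; got: ",
         paste(sp, collapse = ", "))
  }
  m <- summaries$mean_bt_pct
  n <- length(m)
  data.frame(
    species = sp,
    n_individuals = n,
    variance_bt = if (n == 1) 0 else mean((m - mean(m))^2),
    range_bt = if (n == 1) 0 else max(m) - min(m),
    individual_means = paste(format(m, trim = TRUE), collapse = ";"),
    stringsAsFactors = FALSE
  )
}
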