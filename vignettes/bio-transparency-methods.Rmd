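---
title: "Measuring egg bio-transparency from hyperspectral cubes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring egg bio-transparency from hyperspectral cubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovitrans)
```

## The measurement problem

Ascidian (sea squirt) eggs range from nearly invisible to deeply pigmented.
`ovitrans` quantifies that variation from hyperspectral transmission imaging:
eggs resting in seawater on a dish, back-illuminated, imaged through a
microscope by a camera that records a full spectrum per pixel on a 380–1000 nm
grid sampled every 5 nm (125 bands).

Two statistics are computed per egg:

* **Transmittance** per wavelength, $\tau(\lambda) = I/I_0$, the ratio of
  intensity through the specimen to the incident intensity. $I_0$ is taken
  from the surrounding seawater background of the same frame, so no separate
  blank exposure is needed and the illumination spectrum cancels.
* **Bio-transparency**: the mean of $\tau \times 100$ over the visible range
  400–760 nm (73 bands on the default grid; both edges inclusive). A
  percentage: 100 for a perfectly transparent egg.
* **Attenuation coefficient**: $\mu(\lambda) = -\tfrac{1}{x}\ln \tau(\lambda)$
  with $x$ the egg thickness in µm. $\mu$ is a per-unit-length loss
  (µm⁻¹) and therefore decouples transparency from egg size: a large egg can
  have low bio-transparency yet a small $\mu$.

Thickness $x$ is the equivalent-circle diameter of the segmented egg,
$x = 2p\sqrt{A/\pi}$ for area $A$ pixels at pixel size $p$ µm. The statistic
thus treats the egg as a slab of thickness equal to its diameter, which is
what the formula above implies; the consequences of the egg actually being a
sphere are quantified below.

## Pipeline

1. **Segmentation** (`segment_eggs`). The cube is averaged over a reference
   band (default: the visible band, where eggs are darkest against the
   background) into one 2-D image, thresholded, hole-filled, and labelled
   with 4-connected components; components touching the border or with
   circularity $4\pi A/P^2 < 0.6$ are rejected. The default threshold is
   *relative*: a pixel is foreground when it falls below 0.98 × the image's
   upper-quartile intensity. The rationale: every specimen loses at least its
   surface reflection (a few percent) everywhere inside its outline, so a cut
   just below the background level captures the disk out to the rim, where
   transmittance approaches 1 and a contrast-based threshold (Otsu, also
   available) would erode the edge and bias both diameter and
   bio-transparency. The upper quartile is used as the background level
   rather than the median so the estimate survives a single egg covering up
   to three quarters of the frame. Both modes are invariant to global
   illumination rescaling. Perimeter is estimated by a four-direction
   Cauchy–Crofton crossing count, which is unbiased for convex shapes (a
   digitized disk scores circularity ≈ 0.98; boundary-pixel counting would
   exceed 1).
2. **Background spectrum** (`estimate_background_spectrum`). Per-band
   *median* intensity over all pixels further than a 10-px guard margin
   (disc dilation) from every egg; the median ignores debris and hot pixels.
3. **Transmittance** (`egg_transmittance`). Mean over the egg's pixels of the
   per-pixel ratio $I/I_0$. On a flat background this equals the
   ratio-of-means (asserted in the tests); the per-pixel form additionally
   supports a central-ROI sensitivity option (`roi_fraction`). $\tau$ is
   **not clipped at 1**: clipping would rectify noise and bias
   bio-transparency upward. Bands with $\tau > 1.05$ are QC-flagged instead.
4. **Statistics** (`bio_transparency`, `attenuation_spectrum`,
   `visible_attenuation`). $\mu$ is computed per wavelength and then averaged
   over the visible band, preserving the Beer–Lambert relation band-wise
   ($e^{-\mu(\lambda)x} = \tau(\lambda)$ exactly); computing $\mu$ from the
   band-mean $\tau$ instead is available as `from_band_mean_tau`. Bands with
   $\tau \le 0$ are masked, not floored — flooring would fabricate finite
   attenuation.
5. **Aggregation** (`aggregate_individual`, `species_variance`). Per
   individual: mean and sample SD ($n-1$) over eggs, the convention for
   error bars. Per species, the spread of individual means is reported two
   ways — population variance (%²) and range (max − min, %) — because
   "variance across individuals" is used loosely in this field; with the
   observed transparent-pair means 88.0 and 88.7% the range reading gives
   0.7 and the variance reading 0.1225, and the package prints both rather
   than deciding.

## The synthetic forward model

No raw recordings are deposited for this kind of study, so validation rests
on an optical phantom generator (`render_cube`) with analytic ground truth.
An egg is a homogeneous attenuating sphere of radius $r$: light crossing at
radial offset $\rho$ travels the chord $\ell(\rho) = 2\sqrt{r^2-\rho^2}$, so
an egg pixel receives

$$ I(\rho, \lambda) = I_0(\lambda)\,(1-R)\,e^{-\mu(\lambda)\ell(\rho)}, $$

with $R$ a wavelength-independent surface reflection loss (default 0.04,
a glass/water Fresnel-like figure) and

$$ \mu(\lambda) = \mu_0 + \sum_k a_k
   \exp\!\left(-\frac{(\lambda-c_k)^2}{2w_k^2}\right) $$

a baseline plus Gaussian pigment absorption bands, which reproduce the
observed spectral shapes: visible-range dips (e.g. 440–540 nm, or two dips at
500 and 600 nm) with higher UV and IR transmittance. Scattering is *not*
modelled as a point-spread function; it is folded into $\mu$ as total
attenuation, which is exactly what a transmittance measurement conflates.
Additive Gaussian sensor noise (SD = background/SNR, truncated at zero) and
an optional linear illumination gradient complete the scene. One noise field
is drawn for the whole cube per seed; since the noise is i.i.d., this is
statistically identical to any per-object ordering, and renders are
bit-reproducible for a given seed on one platform.

The area-averaged transmittance of such a sphere has the closed form

$$ \bar T = (1-R)\,\frac{1 - (1 + 2\mu r)e^{-2\mu r}}{2\mu^2 r^2}, $$

continuously extended to $(1-R)$ as $\mu \to 0$ (a series expansion is used
below $2\mu r < 10^{-4}$ to avoid cancellation). The tests verify this
closed form against direct numerical quadrature of the chord integral to
1e−8 relative across $\mu r \in [0,5]$, and then verify the *entire imaging
pipeline* against it: on a noiseless rendered sphere of ≥ 24 px diameter,
per-band pipeline $\tau$ agrees within 1% relative (the residual is pixel
discretization at the rim).

Ground truth is always computed from the scene parameters, never from the
rendered image, so these oracle tests cannot be circular.

### Preset scenes and study conditions

Presets span the reported trait ranges: `bt_sweep` renders nine 200-µm eggs
whose true bio-transparencies are exactly 10, 20, …, 90% (the observed
10–90% span), obtained by root-solving the attenuation baseline against the
closed form (`solve_baseline_for_bt`, achieved targets within 0.1 point);
`size_sweep` renders diameters 120, 200, 300 and 381 µm — the reported
extremes — at fixed $\mu(\lambda)$; `two_pigment` places absorption bands at
500 and 600 nm; `transparent_like` and `opaque_like` target 88% and 18.7%,
the most and least transparent individuals observed. Default imaging
conditions, stated assumptions where the study reports none: background
1000 counts, SNR 30 (SNR 20 for the diameter-recovery check), illumination
gradient 0, pixel size 2.5–5 µm/px.

### What the phantom does not emulate

Refraction and lensing by the egg, a distinct chorion/follicle-cell shell,
Poisson shot noise, point-spread blur, and uneven backgrounds beyond a linear
ramp. Passing the recovery tests therefore shows the *estimator chain* is
correct under the stated optical model, not that real eggs obey it; on real
cubes the QC flags ($\tau > 1.05$, masked bands, circularity) are the first
thing to inspect.

## Numerical and design choices

* Wavelengths are always nm internally; files declaring µm are converted on
  read. Band edges are inclusive; `band_index` requires an exact hit for
  on-grid wavelengths.
* Intensities are doubles regardless of file bit depth; fixture and ENVI I/O
  round-trip float32 exactly for integer counts (float64 available for
  arbitrary doubles).
* Minima detection smooths with a 3-band moving average (partial windows at
  the edges) and uses topographic prominence (min of flanking maxima minus
  the minimum) with default threshold 0.02 — deep enough to ignore noise
  ripple at SNR 30, shallow enough to keep real pigment dips.
* Segmentation defaults (min circularity 0.6, min area = a 50-µm disk,
  10-px background guard) bracket the 120–381 µm egg range with margin.
* The slab-thickness convention for $x$ understates a sphere's true $\mu$
  (chords are shorter than the diameter); the bias grows with optical
  thickness $\mu r$ — about 39% at $\mu r = 1$ — and is tabulated by
  `analysis/03_validation_statistics.R`. It is a *convention*, consistent
  across eggs, and is therefore left uncorrected in the statistic.
* Species with one sampled individual stay in the species table with spread
  0 and a flag, since most species in a field collection have $n = 1$.
* Tree annotation joins exactly (after underscore/space normalization and an
  explicit alias map); unmatched tips are kept with a missing-value mark.

## Problem sizes

The test suite and validation scripts run on 125-band cubes between 81² and
220² pixels: single-egg scenes for unit checks, the 9-egg sweep over 10–20
seeds for recovery statistics (180 egg × seed cases in the acceptance
checks), and 100 random spectra for the monotonicity and size-decoupling
property tests. These sizes give recovery errors an order of magnitude below
the tolerances being asserted while keeping a full run in about a minute.

## Limitations

Bio-transparency depends on egg size as well as material opacity — comparing
species on it alone conflates the two (that is why $\mu$ is reported
alongside). The background must be the same medium and illumination as
behind the specimen; vignetting beyond a linear ramp, touching eggs
(no watershed splitting), and sub-pixel contours are out of scope. The
attenuation statistic conflates absorption, scattering and reflection; no
decomposition is attempted.
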