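Package: ovitrans
Title: Bio-Transparency of Eggs from Hyperspectral Transmittance Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures the optical transparency of spherical specimens (ascidian
    eggs) from hyperspectral image cubes. Converts per-pixel intensities to
    transmittance relative to the surrounding seawater background, computes the
    bio-transparency statistic (mean visible-range transmittance, in percent)
    and the thickness-normalized Beer-Lambert attenuation coefficient, and
    aggregates both per individual and per species. Includes circular-object
    segmentation with equivalent-diameter measurement, spectral feature
    extraction (band means, local absorption minima), minimal ENVI and fixture
    cube I/O, continuous-trait annotation of phylogenies, and a physics-based
    synthetic hyperspectral egg generator with analytic ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    yaml,
    ape,
    tiff,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
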