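#' Segment egg regions in a hyperspectral cube
#'
#' Eggs are darker than the seawater background across the visible range, so
#' segmentation runs on a single 2-D reference image averaged over a spectral
#' band. Fixed procedure: (1) band-average to one image; (2) threshold --
#' Otsu, or relative (pixel below `relative_level` x the image's
#' upper-quartile intensity, a background-dominated level whenever the
#' background fills at least a quarter of the frame); (3) fill holes and drop objects below
#' `min_area_px`; (4) 4-connected components; (5) reject components touching
#' the image border or with circularity below `min_circularity`. Both
#' threshold modes are invariant to a global intensity rescaling.
#'
#' The default relative threshold sits just below the background level: any
#' specimen attenuates at least its surface reflection loss everywhere inside
#' its outline, so a cut a few percent under background recovers the full
#' disk out to the rim, where transmittance approaches unity.
#'
#' @param cube A `hyper_cube`.
#' @param reference_band `band_def` averaged to form the reference image
#'   (default: visible 400--760 nm, where eggs are darkest).
#' @param threshold_mode `"relative"` (default) or `"otsu"`.
#' @param relative_level Fraction of the background level used as the cut in
#'   relative mode.
#' @param min_area_px Minimum region area; default: area of a 50-um-diameter
#'   disk at the cube's pixel size.
#' @param min_circularity Minimum `4*pi*area/perimeter^2` (Crofton perimeter),
#'   in (0, 1].
#' @return List of `egg_region` objects sorted by centroid (row, then col),
#'   each with fields `label`, `mask` (logical H x W), `centroid` (0-based
#'   row, col), `area_px`, `equivalent_diameter_um`, `circularity`, and QC
#'   fields `major_axis_px`, `minor_axis_px`. Empty list when nothing is
#'   found.
#' @export
segment_eggs <- function(cube, reference_band = visible_band(),
                         threshold_mode = c("relative", "otsu"),
                         relative_level = 0.98,
                         min_area_px = NULL, min_circularity = 0.6) {
  validate_cube(cube)
  threshold_mode <- match.arg(threshold_mode)
  if (is.null(min_area_px)) {
    min_area_px <- pi * (25 / cube$pixel_size_um)^2
  }
  ref <- reference_image(cube, reference_band)
  rng <- range(ref)
  if (rng[2] - rng[1] <= 0) return(list())   # constant image: nothing to find
  fg <- if (threshold_mode == "otsu") {
    norm <- (ref - rng[1]) / (rng[2] - rng[1])
    thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    norm < thr
  } else {
    # upper-quartile intensity as the background level: robust as long as
    # background fills at least a quarter of the frame
    ref < relative_level * stats::quantile(ref, 0.75, names = FALSE)
  }
  fg <- EBImage::fillHull(fg * 1) > 0
  lab <- EBImage::bwlabel(fg * 1)           # 4-connectivity
  n <- max(lab)
  if (n == 0) return(list())
  regions <- list()
  for (id in seq_len(n)) {
    mask <- lab == id
    area <- sum(mask)
    if (area < min_area_px) next
    rows <- row(mask)[mask]; cols <- col(mask)[mask]
    if (min(rows) == 1 || max(rows) == nrow(mask) ||
        min(cols) == 1 || max(cols) == ncol(mask)) next  # touches border
    perim <- crofton_perimeter(mask)
    circ <- min(1, 4 * pi * area / perim^2)
    if (circ < min_circularity) next
    axes <- mask_axes(rows, cols)
    regions[[length(regions) + 1L]] <- structure(
      list(label = id, mask = mask,
           centroid = c(row = mean(rows) - 1, col = mean(cols) - 1),
           area_px = area,
           equivalent_diameter_um =
             2 * cube$pixel_size_um * sqrt(area / pi),
           circularity = circ,
           major_axis_px = axes[1], minor_axis_px = axes[2]),
      class = "egg_region")
  }
  ord <- order(vapply(regions, function(r) r$centroid["row"], 0),
               vapply(regions, function(r) r$centroid["col"], 0))
  regions[ord]
}

# Mean intensity over the bands of a band definition -> 2-D matrix.
reference_image <- function(cube, band) {
  sel <- band_selector(cube$grid, band)
  sub <- cube$intensities[, , sel, drop = FALSE]
  rowMeans(sub, dims = 2)
}

# Cauchy-Crofton boundary length from crossing counts along rows, columns and
# both diagonals; exact in expectation for convex shapes, P = pi*d for disks.
crofton_perimeter <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  mp <- matrix(FALSE, H + 2, W + 2)
  mp[2:(H + 1), 2:(W + 1)] <- mask
  n_h <- sum(mp[, -1] != mp[, -(W + 2)])
  n_v <- sum(mp[-1, ] != mp[-(H + 2), ])
  n_d1 <- sum(mp[-1, -1] != mp[-(H + 2), -(W + 2)])
  n_d2 <- sum(mp[-1, -(W + 2)] != mp[-(H + 2), -1])
  (pi / 8) * (n_h + n_v + (n_d1 + n_d2) / sqrt(2))
}

# Major/minor axis lengths (px) from second central moments, ellipse model.
mask_axes <- function(rows, cols) {
  mrr <- mean((rows - mean(rows))^2); mcc <- mean((cols - mean(cols))^2)
  mrc <- mean((rows - mean(rows)) * (cols - mean(cols)))
  tr <- mrr + mcc; det_ <- mrr * mcc - mrc^2
  disc <- sqrt(max(0, tr^2 / 4 - det_))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  c(4 * sqrt(max(0, l1)), 4 * sqrt(max(0, l2)))
}

#' @export
print.egg_region <- function(x, ...) {
  cat(sprintf(
    "egg_region %d: centroid (%.1f, %.1f), %d px, diameter %.1f um, circ %.2f\n",
    x$label, x$centroid["row"], x$centroid["col"], x$area_px,
    x$equivalent_diameter_um, x$circularity))
  invisible(x)
}

#' Background (seawater) mask around segmented eggs
#'
#' All pixels further than `guard_margin_px` from every egg region: the union
#' of region masks is dilated with a disc of that radius and complemented.
#'
#' @param cube The source `hyper_cube`.
#' @param regions List of `egg_region` from [segment_eggs()].
#' @param guard_margin_px Dilation radius (px) separating eggs from the
#'   background estimate.
#' @return A `background_mask` object (`mask`: logical H x W, nonempty).
#' @export
background_mask <- function(cube, regions, guard_margin_px = 10) {
  validate_cube(cube)
  d <- cube_dims(cube)
  occ <- matrix(FALSE, d[1], d[2])
  for (r in regions) {
    if (!all(dim(r$mask) == d[1:2])) {
      stop("region mask dimensions do not match the cube")
    }
    occ <- occ | r$mask
  }
  if (any(occ) && guard_margin_px > 0) {
    brush <- EBImage::makeBrush(2 * guard_margin_px + 1, shape = "disc")
    occ <- EBImage::dilate(occ * 1, brush) > 0
  }
  bg <- !occ
  if (!any(bg)) {
    stop("eggs plus guard margins cover the whole frame; ",
         "a larger field of view (or smaller margin) is needed")
  }
  structure(list(mask = bg), class = "background_mask")
}

#' Equivalent-circle diameter of a region
#'
#' Diameter of the circle whose area equals the region's pixel area; this is
#' the thickness `x` entering the attenuation coefficient.
#'
#' @param region An `egg_region`.
#' @param pixel_size_um Pixel edge (um).
#' @return Diameter in um: `2 * pixel_size_um * sqrt(area_px / pi)`.
#' @export
estimate_diameter <- function(region, pixel_size_um) {
  stopifnot(inherits(region, "egg_region"),
            is.numeric(pixel_size_um), pixel_size_um > 0)
  2 * pixel_size_um * sqrt(region$area_px / pi)
}

#' Export regions as a label image and a properties table
#'
#' @param regions List of `egg_region`.
#' @param dims Frame dims `c(H, W)`.
#' @param tiff_path Optional 16-bit TIFF label image destination.
#' @param csv_path Optional CSV destination.
#' @return Data frame of per-region properties, invisibly if written.
#' @export
export_regions <- function(regions, dims, tiff_path = NULL, csv_path = NULL) {
  lab <- matrix(0L, dims[1], dims[2])
  for (i in seq_along(regions)) lab[regions[[i]]$mask] <- i
  tab <- data.frame(
    label = seq_along(regions),
    centroid_row = vapply(regions, function(r) unname(r$centroid["row"]), 0),
    centroid_col = vapply(regions, function(r) unname(r$centroid["col"]), 0),
    area_px = vapply(regions, function(r) r$area_px, 0),
    equivalent_diameter_um =
      vapply(regions, function(r) r$equivalent_diameter_um, 0),
    circularity = vapply(regions, function(r) r$circularity, 0)
  )
  if (!is.null(tiff_path)) {
    tiff::writeTIFF(lab / 65535, tiff_path, bits.per.sample = 16L)
  }
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  if (is.null(tiff_path) && is.null(csv_path)) tab else invisible(tab)
}
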