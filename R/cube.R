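#' Construct a hyperspectral cube
#'
#' An H x W x B stack of nonnegative sensor intensities with a wavelength grid
#' and a pixel-size calibration. Intensities are held as doubles regardless of
#' the bit depth of the file they came from.
#'
#' @param intensities Numeric array, dims `c(H, W, B)`; all finite and >= 0.
#' @param grid `wavelength_grid` with `B` bands.
#' @param pixel_size_um Physical edge length of one pixel (um), > 0.
#' @param metadata Named list of free-form provenance (instrument, date, ...).
#' @return A `hyper_cube` object.
#' @export
hyper_cube <- function(intensities, grid, pixel_size_um, metadata = list()) {
  cube <- structure(
    list(intensities = intensities, grid = grid,
         pixel_size_um = pixel_size_um, metadata = metadata),
    class = "hyper_cube"
  )
  validate_cube(cube)
  cube
}

#' Validate a hyperspectral cube
#'
#' Checks dimensionality, band count against the grid, nonnegativity and
#' finiteness of intensities, and the pixel-size calibration.
#'
#' @param cube A `hyper_cube`.
#' @return The cube, invisibly; stops with a descriptive error otherwise.
#' @export
validate_cube <- function(cube) {
  if (!inherits(cube, "hyper_cube")) stop("not a hyper_cube")
  a <- cube$intensities
  if (!is.array(a) || length(dim(a)) != 3) {
    stop("intensities must be a 3-D array (H x W x B)")
  }
  if (dim(a)[1] < 1 || dim(a)[2] < 1) stop("cube must have H, W >= 1")
  if (!inherits(cube$grid, "wavelength_grid")) stop("grid missing or invalid")
  if (dim(a)[3] != n_bands(cube$grid)) {
    stop(sprintf("band dimension (%d) does not match grid band count (%d)",
                 dim(a)[3], n_bands(cube$grid)))
  }
  if (anyNA(a) || any(!is.finite(a))) {
    stop("intensities contain NA/NaN/Inf values")
  }
  if (any(a < 0)) stop("intensities must be nonnegative")
  if (!is.numeric(cube$pixel_size_um) || length(cube$pixel_size_um) != 1 ||
      !is.finite(cube$pixel_size_um) || cube$pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number")
  }
  invisible(cube)
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("hyper_cube: %d x %d px, %d bands (%g-%g nm), %g um/px\n",
              d[1], d[2], d[3], x$grid$start_nm, x$grid$stop_nm,
              x$pixel_size_um))
  invisible(x)
}

cube_dims <- function(cube) dim(cube$intensities)

guess_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         "json" = "fixture", "bin" = "fixture",
         "hdr" = "envi", "raw" = "envi", "img" = "envi",
         stop("cannot guess cube dialect from extension '.", ext,
              "'; pass dialect explicitly"))
}

#' Write a hyperspectral cube to disk
#'
#' Two dialects are supported. `fixture`: a `<name>.json` sidecar holding the
#' grid, pixel size, dtype and metadata next to a `<name>.bin` of row-major
#' H x W x B little-endian floats. `envi`: a minimal ENVI raster, `<name>.hdr`
#' ASCII header plus flat binary `<name>.raw` (interleave BSQ/BIL/BIP,
#' float32/float64, little-endian, wavelength list in the header).
#'
#' @param cube A valid `hyper_cube`.
#' @param path Destination; extension is replaced per dialect.
#' @param dialect `"fixture"` or `"envi"`.
#' @param dtype `"float32"` (default) or `"float64"`. float64 round-trips
#'   arbitrary doubles bit-for-bit; float32 is exact for integer-valued counts.
#' @param interleave ENVI interleave: `"bsq"`, `"bil"` or `"bip"`.
#' @return The primary file path written (JSON sidecar or `.hdr`), invisibly.
#' @export
write_cube <- function(cube, path, dialect = guess_dialect(path),
                       dtype = c("float32", "float64"),
                       interleave = c("bsq", "bil", "bip")) {
  validate_cube(cube)
  dtype <- match.arg(dtype)
  dialect <- match.arg(dialect, c("fixture", "envi"))
  if (dialect == "fixture") {
    write_cube_fixture(cube, path, dtype)
  } else {
    write_cube_envi(cube, path, dtype, match.arg(interleave))
  }
}

#' Read a hyperspectral cube from disk
#'
#' Counterpart of [write_cube()]. The wavelength list found in the file
#' becomes the cube's grid; unevenly spaced wavelengths are an error, not
#' silently coerced. ENVI headers declaring micrometer wavelength units are
#' converted to nm (x1000) with a message.
#'
#' @param path `.json` sidecar (fixture) or `.hdr` (ENVI).
#' @param dialect `"fixture"` or `"envi"`; guessed from the extension.
#' @param pixel_size_um Override when the file carries no calibration.
#' @return A validated `hyper_cube`.
#' @export
read_cube <- function(path, dialect = guess_dialect(path),
                      pixel_size_um = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  dialect <- match.arg(dialect, c("fixture", "envi"))
  if (dialect == "fixture") {
    read_cube_fixture(path, pixel_size_um)
  } else {
    read_cube_envi(path, pixel_size_um)
  }
}

## ---- fixture dialect: JSON sidecar + raw little-endian floats -------------

size_of <- function(dtype) if (dtype == "float32") 4L else 8L

write_cube_fixture <- function(cube, path, dtype) {
  base <- sub("\\.(json|bin)$", "", path)
  d <- cube_dims(cube)
  sidecar <- list(
    height = d[1], width = d[2], bands = d[3],
    start_nm = cube$grid$start_nm, stop_nm = cube$grid$stop_nm,
    step_nm = cube$grid$step_nm,
    pixel_size_um = cube$pixel_size_um, dtype = dtype,
    metadata = if (length(cube$metadata)) cube$metadata else NULL
  )
  jsonlite::write_json(sidecar, paste0(base, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  # row-major H x W x B: band index varies fastest, then column, then row
  vec <- as.vector(aperm(cube$intensities, c(3, 2, 1)))
  con <- file(paste0(base, ".bin"), "wb")
  on.exit(close(con))
  writeBin(vec, con, size = size_of(dtype), endian = "little")
  invisible(paste0(base, ".json"))
}

read_cube_fixture <- function(path, pixel_size_um = NULL) {
  base <- sub("\\.(json|bin)$", "", path)
  side_path <- paste0(base, ".json")
  if (!file.exists(side_path)) stop("fixture sidecar missing: ", side_path)
  s <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  for (k in c("height", "width", "bands", "start_nm", "stop_nm", "step_nm")) {
    if (is.null(s[[k]])) stop("fixture sidecar missing required key '", k, "'")
  }
  grid <- make_grid(s$start_nm, s$stop_nm, s$step_nm)
  if (n_bands(grid) != s$bands) {
    stop("fixture sidecar: bands field disagrees with the wavelength grid")
  }
  dtype <- if (is.null(s$dtype)) "float32" else s$dtype
  if (!dtype %in% c("float32", "float64")) {
    stop("fixture sidecar: unsupported dtype '", dtype, "'")
  }
  n <- s$height * s$width * s$bands
  con <- file(paste0(base, ".bin"), "rb")
  on.exit(close(con))
  vec <- readBin(con, "double", n = n, size = size_of(dtype),
                 endian = "little")
  if (length(vec) != n) stop("fixture binary truncated: expected ", n,
                             " values, got ", length(vec))
  a <- aperm(array(vec, dim = c(s$bands, s$width, s$height)), c(3, 2, 1))
  ps <- if (!is.null(pixel_size_um)) pixel_size_um else s$pixel_size_um
  md <- if (is.null(s$metadata)) list() else as.list(s$metadata)
  hyper_cube(a, grid, ps, md)
}

## ---- ENVI dialect: ASCII .hdr + flat binary -------------------------------

envi_dtype_code <- function(dtype) if (dtype == "float32") 4L else 5L

write_cube_envi <- function(cube, path, dtype, interleave) {
  base <- sub("\\.(hdr|raw|img)$", "", path)
  d <- cube_dims(cube)
  hdr <- c(
    "ENVI",
    sprintf("description = {%s}",
            if (length(cube$metadata))
              paste(names(cube$metadata), unlist(cube$metadata),
                    sep = ": ", collapse = "; ")
            else "hyperspectral cube"),
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", envi_dtype_code(dtype)),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("pixel size = {%.10g, %.10g}",
            cube$pixel_size_um, cube$pixel_size_um),
    sprintf("wavelength = {%s}",
            paste(format(cube$grid$wavelengths, trim = TRUE), collapse = ", "))
  )
  writeLines(hdr, paste0(base, ".hdr"))
  # ENVI axis order (fastest first): BSQ s,l,b; BIL s,b,l; BIP b,s,l
  perm <- switch(interleave,
                 bsq = c(2, 1, 3), bil = c(2, 3, 1), bip = c(3, 2, 1))
  vec <- as.vector(aperm(cube$intensities, perm))
  con <- file(paste0(base, ".raw"), "wb")
  on.exit(close(con))
  writeBin(vec, con, size = size_of(dtype), endian = "little")
  invisible(paste0(base, ".hdr"))
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  txt <- paste(lines[-1], collapse = "\n")  # drop the "ENVI" magic line
  # join brace-delimited multi-line values, then split on key = value
  entries <- list()
  pat <- "([a-zA-Z ]+?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  if (m[1] == -1) stop("ENVI header has no key = value entries: ", hdr_path)
  for (i in seq_along(m)) {
    piece <- substr(txt, m[i], m[i] + attr(m, "match.length")[i] - 1)
    key <- tolower(trimws(sub("=.*", "", piece)))
    val <- trimws(sub("^[^=]*=", "", piece))
    entries[[key]] <- val
  }
  entries
}

envi_num_list <- function(val) {
  inner <- gsub("[{}]", "", val)
  as.numeric(trimws(strsplit(inner, ",")[[1]]))
}

read_cube_envi <- function(path, pixel_size_um = NULL) {
  base <- sub("\\.(hdr|raw|img)$", "", path)
  hdr_path <- paste0(base, ".hdr")
  if (!file.exists(hdr_path)) stop("ENVI header missing: ", hdr_path)
  h <- parse_envi_header(hdr_path)
  required <- c("samples", "lines", "bands", "data type", "interleave")
  for (k in required) {
    if (is.null(h[[k]])) stop("ENVI header missing required key '", k, "'")
  }
  if (is.null(h[["wavelength"]])) {
    stop("ENVI header has no wavelength list; cannot build the grid")
  }
  known <- c(required, "wavelength", "wavelength units", "pixel size",
             "byte order", "header offset", "file type", "description")
  extra <- setdiff(names(h), known)
  if (length(extra)) {
    message("ignoring unrecognized ENVI header keys: ",
            paste(extra, collapse = ", "))
  }
  W <- as.integer(h$samples); H <- as.integer(h$lines)
  B <- as.integer(h$bands)
  dt <- as.integer(h[["data type"]])
  if (!dt %in% c(4L, 5L)) {
    stop("unsupported ENVI data type ", dt, " (only 4=float32, 5=float64)")
  }
  byte_order <- if (is.null(h[["byte order"]])) 0L else as.integer(h[["byte order"]])
  endian <- if (byte_order == 0L) "little" else "big"
  interleave <- tolower(h$interleave)
  if (!interleave %in% c("bsq", "bil", "bip")) {
    stop("unsupported ENVI interleave '", h$interleave, "'")
  }
  wl <- envi_num_list(h$wavelength)
  if (length(wl) != B) {
    stop(sprintf("ENVI wavelength list has %d entries but bands = %d",
                 length(wl), B))
  }
  units <- if (is.null(h[["wavelength units"]])) "nanometers"
           else tolower(h[["wavelength units"]])
  if (grepl("^micro", units) || units == "um") {
    message("ENVI wavelengths declared in micrometers; converting to nm")
    wl <- wl * 1000
  }
  grid <- grid_from_wavelengths(wl)
  raw_path <- if (file.exists(paste0(base, ".raw"))) paste0(base, ".raw")
              else paste0(base, ".img")
  if (!file.exists(raw_path)) stop("ENVI binary missing for ", hdr_path)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  offset <- if (is.null(h[["header offset"]])) 0L
            else as.integer(h[["header offset"]])
  if (offset > 0) readBin(con, "raw", n = offset)
  n <- as.double(H) * W * B
  vec <- readBin(con, "double", n = n, size = if (dt == 4L) 4L else 8L,
                 endian = endian)
  if (length(vec) != n) stop("ENVI binary truncated")
  a <- switch(interleave,
              bsq = aperm(array(vec, dim = c(W, H, B)), c(2, 1, 3)),
              bil = aperm(array(vec, dim = c(W, B, H)), c(3, 1, 2)),
              bip = aperm(array(vec, dim = c(B, W, H)), c(3, 2, 1)))
  ps <- if (!is.null(pixel_size_um)) {
    pixel_size_um
  } else if (!is.null(h[["pixel size"]])) {
    envi_num_list(h[["pixel size"]])[1]
  } else {
    stop("ENVI header carries no pixel size; pass pixel_size_um explicitly")
  }
  md <- if (!is.null(h$description))
          list(description = gsub("[{}]", "", h$description)) else list()
  hyper_cube(a, grid, ps, md)
}
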