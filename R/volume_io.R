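#' OCT volume container
#'
#' An `oct_volume` holds a calibrated endoscopic OCT intensity volume as a
#' 3-D array indexed `[z, y, f]` (depth sample, pullback sample, longitudinal
#' frame), in dB, plus the acquisition metadata needed to place samples in
#' physical coordinates. Axial samples are stored on the optical path; the
#' physical (tissue) spacing is `z_spacing_optical_um / n_medium`, with water
#' (`n_medium = 1.333`) assumed by default as the immersion medium.
#'
#' @param intensity_db numeric 3-D array `[z, y, f]` of calibrated intensity
#'   in dB; all values must be finite.
#' @param y_spacing_um pullback sample spacing in micrometres (> 0).
#' @param z_spacing_optical_um axial optical-path sample spacing in
#'   micrometres (> 0).
#' @param n_medium refractive index of the immersion medium (>= 1).
#' @param frames_per_rev,pullback_speed_mm_s,rotation_hz optional acquisition
#'   metadata (frames per revolution, pullback speed in mm/s, rotation rate
#'   in Hz), carried through I/O but not used in computation.
#' @return an object of class `oct_volume`.
#' @seealso [load_volume()], [save_volume()], [rescale_isotropic()],
#'   [mean_enface()]
#' @export
oct_volume <- function(intensity_db, y_spacing_um, z_spacing_optical_um,
                       n_medium = 1.333, frames_per_rev = NA_real_,
                       pullback_speed_mm_s = NA_real_, rotation_hz = NA_real_) {
  if (!is.array(intensity_db) || length(dim(intensity_db)) != 3L)
    stop("intensity_db must be a 3-D array [z, y, frame]")
  vol <- structure(
    list(intensity_db = intensity_db,
         y_spacing_um = as.numeric(y_spacing_um),
         z_spacing_optical_um = as.numeric(z_spacing_optical_um),
         n_medium = as.numeric(n_medium),
         frames_per_rev = as.numeric(frames_per_rev),
         pullback_speed_mm_s = as.numeric(pullback_speed_mm_s),
         rotation_hz = as.numeric(rotation_hz)),
    class = "oct_volume")
  validate_oct_volume(vol)
}

#' @keywords internal
validate_oct_volume <- function(vol) {
  d <- dim(vol$intensity_db)
  if (any(d < 1L)) stop("volume dimensions must all be >= 1")
  if (!all(is.finite(vol$intensity_db))) stop("intensity values must be finite")
  if (!isTRUE(vol$y_spacing_um > 0) || !isTRUE(vol$z_spacing_optical_um > 0))
    stop("sample spacings must be > 0")
  if (!isTRUE(vol$n_medium >= 1)) stop("n_medium must be >= 1")
  vol
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensity_db)
  cat(sprintf("<oct_volume> %d frames x %d pullback x %d depth\n", d[3], d[2], d[1]))
  cat(sprintf("  y spacing %.3g um, z spacing %.3g um optical (%.3g um in tissue, n = %.4g)\n",
              x$y_spacing_um, x$z_spacing_optical_um,
              x$z_spacing_optical_um / x$n_medium, x$n_medium))
  cat(sprintf("  intensity [%.1f, %.1f] dB\n",
              min(x$intensity_db), max(x$intensity_db)))
  invisible(x)
}

#' @keywords internal
n_frames <- function(vol) dim(vol$intensity_db)[3]
#' @keywords internal
n_pullback <- function(vol) dim(vol$intensity_db)[2]
#' @keywords internal
n_depth <- function(vol) dim(vol$intensity_db)[1]

# physical (in-tissue) axial spacing in micrometres
#' @keywords internal
z_spacing_physical_um <- function(vol) vol$z_spacing_optical_um / vol$n_medium

meta_fields <- c("y_spacing_um", "z_spacing_optical_um", "n_medium",
                 "frames_per_rev", "pullback_speed_mm_s", "rotation_hz")

#' @keywords internal
sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".meta.json")

#' Save an OCT volume as multi-page TIFF with a JSON metadata sidecar
#'
#' One 32-bit float TIFF page per longitudinal frame (rows = depth z,
#' columns = pullback y). Because TIFF float storage covers `[0, 1]`, the
#' intensity is written through an affine map recorded in the sidecar
#' (`intensity_offset_db`, `intensity_scale_db`); round-trips are exact to
#' 32-bit float precision (~1e-6 of the dynamic range).
#'
#' @param vol an [oct_volume()].
#' @param path output `.tif` path; the sidecar is written next to it as
#'   `<name>.meta.json`.
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path) {
  validate_oct_volume(vol)
  rng <- range(vol$intensity_db)
  offset <- rng[1]
  scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  pages <- lapply(seq_len(n_frames(vol)), function(f)
    (vol$intensity_db[, , f, drop = TRUE] - offset) / scale)
  pages <- lapply(pages, function(p) matrix(p, n_depth(vol), n_pullback(vol)))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- vol[meta_fields]
  meta$scale <- "db"
  meta$intensity_offset_db <- offset
  meta$intensity_scale_db <- scale
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an OCT volume from multi-page TIFF plus JSON sidecar
#'
#' Reads the format written by [save_volume()]. The sidecar must declare
#' `y_spacing_um`, `z_spacing_optical_um` and `n_medium`; a `scale` field of
#' `"linear"` marks volumes stored in linear power, converted to dB on load.
#'
#' @param path path to the multi-page `.tif` volume.
#' @return an [oct_volume()].
#' @export
load_volume <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(path)) stop("volume file not found: ", path)
  if (!file.exists(sc)) stop("missing metadata sidecar: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (f in c("y_spacing_um", "z_spacing_optical_um", "n_medium"))
    if (is.null(meta[[f]]) || !is.finite(as.numeric(meta[[f]])))
      stop("sidecar is missing required field: ", f)
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("TIFF pages have inconsistent dimensions")
  if (!is.null(meta$n_frames) && as.integer(meta$n_frames) != length(pages))
    stop("sidecar declares ", meta$n_frames, " frames but TIFF has ",
         length(pages), " pages")
  arr <- array(unlist(pages, use.names = FALSE),
               dim = c(dims[1, 1], dims[2, 1], length(pages)))
  offset <- as.numeric(meta$intensity_offset_db %||% 0)
  scale <- as.numeric(meta$intensity_scale_db %||% 1)
  arr <- arr * scale + offset
  if (identical(meta$scale %||% "db", "linear")) {
    if (any(arr <= 0)) stop("linear-scale volume contains non-positive power")
    arr <- linear_to_db(arr)
  }
  if (!all(is.finite(arr))) stop("volume contains non-finite pixels")
  oct_volume(arr,
             y_spacing_um = as.numeric(meta$y_spacing_um),
             z_spacing_optical_um = as.numeric(meta$z_spacing_optical_um),
             n_medium = as.numeric(meta$n_medium),
             frames_per_rev = as.numeric(meta$frames_per_rev %||% NA),
             pullback_speed_mm_s = as.numeric(meta$pullback_speed_mm_s %||% NA),
             rotation_hz = as.numeric(meta$rotation_hz %||% NA))
}

#' Rescale a volume to square 10 um pixels in (y, z)
#'
#' Resamples every longitudinal frame so that both the pullback (y) and the
#' physical depth (z, optical spacing divided by `n_medium`) sample spacings
#' equal `pixel_um`, using separable cubic-convolution (bicubic)
#' interpolation on the stored dB values. Frame count is unchanged. Axes
#' already at the target spacing are passed through untouched.
#'
#' @param vol an [oct_volume()].
#' @param pixel_um target square pixel size in micrometres (default 10).
#' @return a new [oct_volume()] on the isotropic grid.
#' @export
rescale_isotropic <- function(vol, pixel_um = 10) {
  validate_oct_volume(vol)
  z_phys <- z_spacing_physical_um(vol)
  y_sp <- vol$y_spacing_um
  # spacings within 0.05% of the target (sub-0.01 um at 10 um pixels) are
  # taken as already on-grid: resampling them would only add interpolation
  # noise (e.g. 13.33 um optical / 1.333 is 10 um physical)
  tol <- 5e-4 * pixel_um
  same_z <- abs(z_phys - pixel_um) < tol
  same_y <- abs(y_sp - pixel_um) < tol
  if (same_z && same_y) return(vol)
  frames <- lapply(seq_len(n_frames(vol)), function(f) {
    m <- vol$intensity_db[, , f, drop = TRUE]
    m <- matrix(m, n_depth(vol), n_pullback(vol))
    if (!same_z) m <- cubic_resample_axis(m, from = z_phys, to = pixel_um, axis = 1L)
    if (!same_y) m <- cubic_resample_axis(m, from = y_sp, to = pixel_um, axis = 2L)
    m
  })
  arr <- array(unlist(frames, use.names = FALSE),
               dim = c(nrow(frames[[1]]), ncol(frames[[1]]), length(frames)))
  oct_volume(arr,
             y_spacing_um = pixel_um,
             z_spacing_optical_um = pixel_um * vol$n_medium,
             n_medium = vol$n_medium,
             frames_per_rev = vol$frames_per_rev,
             pullback_speed_mm_s = vol$pullback_speed_mm_s,
             rotation_hz = vol$rotation_hz)
}

#' Mean en face projection
#'
#' Reduces a 3-D grid to an en face map: entry `(f, y)` is the mean over
#' depth of the included pixels of that A-line. With a region mask, only
#' pixels where the mask is `TRUE` contribute; A-lines with no included
#' pixel are `NA` (missing).
#'
#' @param x an [oct_volume()] or a 3-D array `[z, y, f]`.
#' @param region optional logical array of the same dimensions as the grid.
#' @param units units label attached to the result.
#' @return an `F x Y` matrix with attribute `units`; `NA` marks missing.
#' @export
mean_enface <- function(x, region = NULL, units = "dB") {
  arr <- if (inherits(x, "oct_volume")) x$intensity_db else x
  if (!is.array(arr) || length(dim(arr)) != 3L)
    stop("x must be an oct_volume or a 3-D array [z, y, frame]")
  d <- dim(arr)
  if (!is.null(region)) {
    if (!identical(dim(region), d)) stop("region mask shape must match the grid")
    num <- apply(arr * ifelse(region, 1, 0), c(2, 3), sum)
    den <- apply(region, c(2, 3), sum)
    vals <- ifelse(den > 0, num / den, NA_real_)
  } else {
    vals <- apply(arr, c(2, 3), mean)
  }
  map <- t(vals)  # F x Y
  enface_map(map, units)
}

#' @keywords internal
enface_map <- function(values, units = "") {
  values <- as.matrix(values)
  attr(values, "units") <- units
  values
}

#' Write an en face map as 32-bit float TIFF plus CSV
#'
#' @param map an `F x Y` matrix (possibly with `NA`); `NA` is stored as the
#'   minimum finite value minus one scale unit in the TIFF and empty in the CSV.
#' @param path output `.tif` path; a `.csv` with the same stem is written too.
#' @return `path`, invisibly.
#' @export
write_enface <- function(map, path) {
  m <- as.matrix(map)
  fin <- is.finite(m)
  if (!any(fin)) stop("en face map has no defined entries")
  rng <- range(m[fin])
  scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  norm <- (m - rng[1]) / scale
  norm[!fin] <- 0
  tiff::writeTIFF(norm, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(offset = rng[1], scale = scale, units = attr(map, "units") %||% "",
         missing = "stored as 0 before offset; authoritative values in CSV"),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  utils::write.table(m, paste0(sub("\\.tiff?$", "", path), ".csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE, na = "")
  invisible(path)
}
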