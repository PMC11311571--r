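#' Per-frame layer surfaces
#'
#' A `surface_set` carries, for every (frame, pullback) A-line, the depth row
#' of the epithelium top and of the epithelial-stromal boundary, as produced
#' by an upstream segmentation (or by the phantom ground truth). Rows are
#' 1-based R indices into the depth axis; `NA` marks a missing entry. An
#' A-line with a top but no boundary is a loss-of-boundary A-line: the whole
#' visualized depth is later treated as epithelium.
#'
#' @param epi_top integer `F x Y` matrix, first epithelium row per A-line
#'   (`NA` = no tissue).
#' @param boundary integer `F x Y` matrix, first stroma row per A-line
#'   (`NA` = boundary not resolvable). Where both are present,
#'   `boundary > epi_top` is required.
#' @return an object of class `surface_set`.
#' @export
surface_set <- function(epi_top, boundary) {
  epi_top <- as.matrix(epi_top); boundary <- as.matrix(boundary)
  if (!all(dim(epi_top) == dim(boundary)))
    stop("epi_top and boundary must have the same dimensions")
  bad <- !is.na(epi_top) & !is.na(boundary) & boundary <= epi_top
  if (any(bad)) stop("boundary must lie strictly below epi_top where both present")
  if (any(!is.na(boundary) & is.na(epi_top)))
    stop("boundary present without an epithelium top")
  structure(list(epi_top = epi_top, boundary = boundary), class = "surface_set")
}

#' En face mask set (contact, artifact, lesion)
#'
#' @param contact,artifact,lesion logical `F x Y` matrices: tissue contact
#'   to retain, artifacts to remove, and the clinically labelled lesion area.
#' @return an object of class `enface_masks`.
#' @export
enface_masks <- function(contact, artifact = NULL, lesion = NULL) {
  contact <- as.matrix(contact) > 0
  d <- dim(contact)
  blank <- matrix(FALSE, d[1], d[2])
  artifact <- if (is.null(artifact)) blank else as.matrix(artifact) > 0
  lesion <- if (is.null(lesion)) blank else as.matrix(lesion) > 0
  if (!all(dim(artifact) == d) || !all(dim(lesion) == d))
    stop("all masks must share the contact mask's dimensions")
  structure(list(contact = contact, artifact = artifact, lesion = lesion),
            class = "enface_masks")
}

# ---- noise floor and visualized depth --------------------------------------

#' Frame noise floor from the bottom 25 rows
#'
#' The noise floor of a (rescaled, 10 um pixel) longitudinal frame is taken
#' from the bottom 25 rows (250 um): A-lines with no tissue (no epithelium
#' surface) are excluded first, the remaining region is smoothed with a 2-D
#' 5x5 Gaussian kernel (sigma = 1 px, reflective borders), and the floor is
#' the mean of the smoothed region.
#'
#' @param frame_db `Z x Y` matrix of intensity in dB.
#' @param epi_top length-`Y` integer vector of epithelium-top rows
#'   (`NA` = no tissue on that A-line).
#' @return the noise floor in dB (scalar).
#' @export
noise_floor <- function(frame_db, epi_top) {
  frame_db <- as.matrix(frame_db)
  if (length(epi_top) != ncol(frame_db))
    stop("epi_top must have one entry per A-line (column)")
  keep <- !is.na(epi_top)
  if (!any(keep)) stop("no A-line has an epithelium surface")
  nz <- nrow(frame_db)
  rows <- max(1L, nz - 24L):nz
  # exclusion comes first: no-tissue A-lines never enter the smoothing
  region <- frame_db[rows, keep, drop = FALSE]
  mean(gauss_smooth2d(region))
}

#' Bottom of the visualized region for one A-line
#'
#' The visualized region of an A-line starts at the epithelium top and ends
#' when the signal drops to within 6 dB of the noise floor: the bottom is the
#' first index of the first run of `k` consecutive sub-threshold pixels at or
#' below which the region ends (single-pixel speckle dips shorter than `k`
#' are ignored). The bottom is capped 25 pixels above the end of the A-line
#' so the visualized region never overlaps the noise-floor estimation window.
#' The interval is half-open: rows `[epi_top, bottom)` are visualized; a
#' return value equal to `epi_top` signals an empty visualized region.
#'
#' @param aline_db numeric depth profile in dB (ideally smoothed with the
#'   same kernel used for the noise floor).
#' @param floor_db noise floor in dB.
#' @param epi_top 1-based index of the epithelium top.
#' @param margin_db threshold above the floor (default 6 dB).
#' @param k run length that counts as a sustained drop (default 3 px).
#' @return 1-based exclusive bottom row index.
#' @export
visualized_bottom <- function(aline_db, floor_db, epi_top,
                              margin_db = 6, k = 3L) {
  m <- matrix(aline_db, ncol = 1)
  visualized_bottoms(m, floor_db, epi_top, margin_db = margin_db, k = k)[1]
}

# Vectorized bottom finder over a Z x Y frame; epi_top is a length-Y vector
# (NA = no tissue -> NA bottom).
#' @keywords internal
visualized_bottoms <- function(frame_db, floor_db, epi_top,
                               margin_db = 6, k = 3L) {
  frame_db <- as.matrix(frame_db)
  nz <- nrow(frame_db); ny <- ncol(frame_db)
  if (length(epi_top) == 1L) epi_top <- rep(epi_top, ny)
  thr <- floor_db + margin_db
  below <- frame_db < thr
  # pad with k-1 TRUE rows so a trailing partial run counts as a drop
  below <- rbind(below, matrix(TRUE, k - 1L, ny))
  run <- below[seq_len(nz), , drop = FALSE]
  if (k > 1L) for (j in seq_len(k - 1L))
    run <- run & below[seq_len(nz) + j, , drop = FALSE]
  cap <- max(nz - 24L, 1L)  # first excluded row is at most nz - 24
  out <- rep(NA_integer_, ny)
  for (y in seq_len(ny)) {
    top <- epi_top[y]
    if (is.na(top)) next
    if (top > nz) stop("epi_top outside the profile")
    hit <- which(run[top:nz, y])
    b <- if (length(hit)) top + hit[1] - 1L else nz + 1L
    out[y] <- min(b, cap)
  }
  pmax(out, epi_top)
}

# ---- region masks ----------------------------------------------------------

#' Build epithelium / stroma / half / visualized region masks
#'
#' Applies the layer rules per A-line, in half-open row intervals:
#' * boundary present: `E = [top, boundary)`, `S = [boundary, bottom)`;
#' * boundary missing (loss of the epithelial-stromal boundary): the entire
#'   visualized depth is taken to be epithelium, `E = [top, bottom)`,
#'   `S` empty, and the A-line is flagged;
#' * the upper epithelium UE is the upper `ceiling(|E|/2)` pixels of E and
#'   the lower epithelium LE the remainder (odd split favours UE).
#'
#' @param surfaces a [surface_set()].
#' @param bottoms `F x Y` matrix (or vector for one frame) of exclusive
#'   visualized-bottom rows, as from [visualized_bottom()].
#' @param n_z depth axis length (rows per frame).
#' @return an object of class `region_masks` holding per-A-line interval
#'   bounds and the loss flag; materialize masks with [region_array()].
#' @export
build_region_masks <- function(surfaces, bottoms, n_z) {
  stopifnot(inherits(surfaces, "surface_set"))
  top <- surfaces$epi_top
  bnd <- surfaces$boundary
  bottoms <- matrix(as.integer(as.matrix(bottoms)), nrow(top), ncol(top))
  tissue <- !is.na(top)
  if (any(tissue & is.na(bottoms)))
    stop("bottoms must be defined wherever tissue is present")
  if (any(tissue & bottoms < top, na.rm = TRUE))
    stop("visualized bottom above the epithelium top")
  if (any(!is.na(bnd) & bnd <= top, na.rm = TRUE))
    stop("boundary at or above the epithelium top")
  loss <- tissue & is.na(bnd)
  e_end <- ifelse(loss, bottoms, pmin(bnd, bottoms))     # exclusive end of E
  e_end <- ifelse(tissue, pmax(e_end, top), NA_integer_) # E may be empty
  s_start <- ifelse(loss, NA_integer_, e_end)
  ue_end <- top + ceiling((e_end - top) / 2)             # exclusive end of UE
  structure(list(top = top, e_end = e_end, s_start = s_start,
                 ue_end = ue_end, bottom = bottoms, loss = loss,
                 n_z = as.integer(n_z)),
            class = "region_masks")
}

#' Materialize a region as a logical array
#'
#' @param regions a [build_region_masks()] result.
#' @param which one of `"E"`, `"S"`, `"UE"`, `"LE"`, `"visualized"`.
#' @return logical array `[z, y, f]`.
#' @export
region_array <- function(regions, which = c("E", "S", "UE", "LE", "visualized")) {
  which <- match.arg(which)
  lo <- switch(which,
               E = regions$top, S = regions$s_start, UE = regions$top,
               LE = regions$ue_end, visualized = regions$top)
  hi <- switch(which,
               E = regions$e_end, S = regions$bottom, UE = regions$ue_end,
               LE = regions$e_end, visualized = regions$bottom)
  nf <- nrow(regions$top); ny <- ncol(regions$top); nz <- regions$n_z
  z <- seq_len(nz)
  out <- array(FALSE, dim = c(nz, ny, nf))
  for (f in seq_len(nf)) for (y in seq_len(ny)) {
    l <- lo[f, y]; h <- hi[f, y]
    if (!is.na(l) && !is.na(h) && h > l) out[l:(h - 1L), y, f] <- TRUE
  }
  out
}

#' Retain the central half of each azimuthal contact run
#'
#' Edge effects occur where the catheter grazes tissue tangentially at the
#' azimuthal limits of contact. For every pullback column, each maximal
#' contiguous run of contact frames of length `L` is replaced by its central
#' `floor(L/2)` frames (at least one frame is retained for `L >= 1`, so thin
#' contact strips still contribute).
#'
#' @param contact logical `F x Y` en face contact mask.
#' @return eroded logical mask of the same shape.
#' @export
erode_central <- function(contact) {
  contact <- as.matrix(contact) > 0
  out <- matrix(FALSE, nrow(contact), ncol(contact))
  for (y in seq_len(ncol(contact))) {
    r <- rle(contact[, y])
    pos <- cumsum(c(1L, r$lengths))
    for (i in seq_along(r$lengths)) {
      if (!r$values[i]) next
      L <- r$lengths[i]
      keep <- max(1L, L %/% 2L)
      s <- pos[i] + (L - keep) %/% 2L
      out[s:(s + keep - 1L), y] <- TRUE
    }
  }
  out
}

# ---- surface / mask I/O ----------------------------------------------------

#' Write surfaces to JSON
#'
#' Per frame, two integer arrays (`epi_top`, `boundary`) of 0-based depth
#' indices with `-1` as the missing sentinel.
#'
#' @param surfaces a [surface_set()].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_surfaces <- function(surfaces, path) {
  stopifnot(inherits(surfaces, "surface_set"))
  enc <- function(v) { v <- v - 1L; v[is.na(v)] <- -1L; as.integer(v) }
  frames <- lapply(seq_len(nrow(surfaces$epi_top)), function(f)
    list(epi_top = enc(surfaces$epi_top[f, ]),
         boundary = enc(surfaces$boundary[f, ])))
  jsonlite::write_json(list(n_frames = nrow(surfaces$epi_top),
                            n_y = ncol(surfaces$epi_top),
                            frames = frames),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read surfaces from JSON
#'
#' @param path path written by [write_surfaces()].
#' @return a [surface_set()].
#' @export
read_surfaces <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(v) { v <- as.integer(v); v[v < 0] <- NA_integer_; v }
  as_rows <- function(col) {
    if (is.matrix(col)) t(apply(col, 1L, dec))
    else do.call(rbind, lapply(col, dec))
  }
  top <- as_rows(x$frames$epi_top)
  bnd <- as_rows(x$frames$boundary)
  surface_set(top + 1L, bnd + 1L)
}

#' Write en face masks as 8-bit TIFFs (nonzero = set)
#'
#' @param masks an [enface_masks()] set.
#' @param dir output directory; writes `contact.tif`, `artifact.tif`,
#'   `lesion.tif`.
#' @return `dir`, invisibly.
#' @export
write_masks <- function(masks, dir) {
  stopifnot(inherits(masks, "enface_masks"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("contact", "artifact", "lesion"))
    tiff::writeTIFF(ifelse(masks[[nm]], 1, 0), file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 8L, reduce = FALSE)
  invisible(dir)
}

#' Read en face masks written by [write_masks()]
#'
#' @param dir directory holding `contact.tif` (required) and optionally
#'   `artifact.tif`, `lesion.tif`.
#' @return an [enface_masks()] set.
#' @export
read_masks <- function(dir) {
  rd <- function(nm) {
    p <- file.path(dir, paste0(nm, ".tif"))
    if (file.exists(p)) tiff::readTIFF(p) > 0 else NULL
  }
  contact <- rd("contact")
  if (is.null(contact)) stop("contact.tif not found in ", dir)
  enface_masks(contact, rd("artifact"), rd("lesion"))
}
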