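#' Epithelial depth en face map
#'
#' Depth is the height of the epithelium region per A-line, `|E|` pixels
#' times the pixel size: on loss-of-boundary A-lines the entire visualized
#' depth counts as epithelium. Missing where no tissue is present.
#'
#' @param regions a [build_region_masks()] result.
#' @param pixel_um pixel size in micrometres (default 10).
#' @return `F x Y` matrix of depth in um, `NA` = missing.
#' @export
epithelial_depth_map <- function(regions, pixel_um = 10) {
  stopifnot(inherits(regions, "region_masks"))
  enface_map((regions$e_end - regions$top) * pixel_um, "um")
}

#' Loss of the epithelial-stromal boundary, percent of volume
#'
#' The fraction of tissue A-lines (A-lines with an epithelium surface) whose
#' boundary could not be resolved, excluding artifact A-lines from both the
#' numerator and the denominator.
#'
#' @param regions a [build_region_masks()] result.
#' @param masks an [enface_masks()] set aligned with `regions`.
#' @return scalar percentage in `[0, 100]`.
#' @export
loss_of_boundary_pct <- function(regions, masks) {
  stopifnot(inherits(regions, "region_masks"), inherits(masks, "enface_masks"))
  tissue <- !is.na(regions$top) & !masks$artifact
  if (!any(tissue)) stop("no tissue A-lines outside artifacts")
  100 * sum(regions$loss & tissue) / sum(tissue)
}

#' Ratiometric stratification of two attenuation coefficients
#'
#' `(a - b) / (a + b)`: a normalized contrast in `[-1, 1]` between the mean
#' attenuation coefficients of two tissue regions on the same A-line.
#' Vectorized; missing (`NA`) where either input is missing or both are zero.
#'
#' @param a,b nonnegative attenuation coefficients (mm^-1), scalars or
#'   arrays of a common shape.
#' @return stratification value(s) in `[-1, 1]` (a.u.).
#' @export
stratification <- function(a, b) {
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE))
    stop("attenuation coefficients must be >= 0")
  s <- a + b
  out <- ifelse(is.na(a) | is.na(b) | s == 0, NA_real_, (a - b) / s)
  if (is.matrix(a)) enface_map(out, "a.u.") else out
}

#' Compute all seven biomarkers of a volume
#'
#' Orchestrates the full per-frame pipeline on a rescaled volume with given
#' layer surfaces and en face masks: 2-D Gaussian smoothing, noise floor
#' from the bottom 25 rows, visualized bottom (6 dB above the floor, with a
#' 3-px sustained-drop rule), region masks, noise-floor-subtracted
#' depth-resolved attenuation, and the seven en face biomarkers. Artifact
#' A-lines are set missing in every map.
#'
#' @param vol a rescaled [oct_volume()] (10 um square pixels).
#' @param surfaces a [surface_set()] aligned with `vol`.
#' @param masks an [enface_masks()] set aligned with `vol`.
#' @param m,compensate tail-fit controls, see [depth_resolved_mu()].
#' @param tail_trim pixels excluded at the bottom of each visualized A-line
#'   when averaging attenuation over regions (default: the tail-fit window
#'   `m`, whose estimates reflect the fitted boundary condition rather than
#'   data); see [region_mean_mu()].
#' @return an object of class `biomarker_maps`: en face matrices
#'   `depth_um`, `mu_overall`, `mu_epi`, `mu_stroma`, `es_strat`,
#'   `ie_strat`; scalar `loss_pct`; logical `loss_mask`; plus the
#'   intermediate `regions` and per-frame `floors_db`.
#' @export
compute_biomarkers <- function(vol, surfaces, masks, m = 10L, compensate = TRUE,
                               tail_trim = m) {
  stopifnot(inherits(vol, "oct_volume"), inherits(surfaces, "surface_set"),
            inherits(masks, "enface_masks"))
  px <- z_spacing_physical_um(vol)
  if (abs(px - 10) > 1e-6 || abs(vol$y_spacing_um - 10) > 1e-6)
    stop("volume must be rescaled to 10 um square pixels first; see rescale_isotropic()")
  nf <- n_frames(vol); ny <- n_pullback(vol); nz <- n_depth(vol)
  if (!all(dim(surfaces$epi_top) == c(nf, ny)))
    stop("surfaces are not aligned with the volume")
  if (!all(dim(masks$contact) == c(nf, ny)))
    stop("masks are not aligned with the volume")

  floors <- numeric(nf)
  bottoms <- matrix(NA_integer_, nf, ny)
  for (f in seq_len(nf)) {
    frame <- matrix(vol$intensity_db[, , f], nz, ny)
    keep <- !is.na(surfaces$epi_top[f, ])
    if (!any(keep)) { floors[f] <- NA_real_; next }
    floors[f] <- noise_floor(frame, surfaces$epi_top[f, ])
    sm <- gauss_smooth2d(frame)
    bottoms[f, ] <- visualized_bottoms(sm, floors[f], surfaces$epi_top[f, ])
  }
  regions <- build_region_masks(surfaces, bottoms, nz)
  att <- compute_attenuation(vol, regions, floors_db = floors, m = m,
                             compensate = compensate)

  depth <- epithelial_depth_map(regions, pixel_um = px)
  mu_overall <- region_mean_mu(att, regions, "overall", tail_trim = tail_trim)
  mu_epi <- region_mean_mu(att, regions, "epithelium", tail_trim = tail_trim)
  mu_stroma <- region_mean_mu(att, regions, "stroma", tail_trim = tail_trim)
  mu_ue <- region_mean_mu(att, regions, "upper_epithelium", tail_trim = tail_trim)
  mu_le <- region_mean_mu(att, regions, "lower_epithelium", tail_trim = tail_trim)
  es <- stratification(mu_epi, mu_stroma)
  ie <- stratification(mu_ue, mu_le)

  blank <- function(mp, units) {
    mp[masks$artifact] <- NA_real_
    enface_map(mp, units)
  }
  structure(list(depth_um = blank(depth, "um"),
                 mu_overall = blank(mu_overall, "mm^-1"),
                 mu_epi = blank(mu_epi, "mm^-1"),
                 mu_stroma = blank(mu_stroma, "mm^-1"),
                 es_strat = blank(es, "a.u."),
                 ie_strat = blank(ie, "a.u."),
                 loss_pct = loss_of_boundary_pct(regions, masks),
                 loss_mask = regions$loss & !masks$artifact,
                 regions = regions, floors_db = floors),
            class = "biomarker_maps")
}

biomarker_names <- c("depth_um", "mu_overall", "mu_epi", "mu_stroma",
                     "es_strat", "ie_strat")

#' Reduce biomarker maps to one median per biomarker
#'
#' Applies the quantitative protocol: the en face contact mask is eroded
#' azimuthally so only the central half of each contact run is retained,
#' artifact A-lines are excluded, lesion volumes are restricted to the
#' labelled lesion area, and the median of each biomarker map over the
#' retained A-lines (skipping missing entries) is reported. The
#' loss-of-boundary percentage is passed through unchanged.
#'
#' @param maps a [compute_biomarkers()] result.
#' @param masks the [enface_masks()] set used to compute `maps`.
#' @param restrict_to_lesion logical; restrict to the lesion mask.
#' @param role volume role label (`"lesion"` or `"contralateral"`).
#' @param id volume identifier carried into the output row.
#' @return a one-row `data.frame`: `id`, `role`, the seven medians
#'   (`depth_um`, `loss_pct`, `mu_overall`, `mu_epi`, `mu_stroma`,
#'   `es_strat`, `ie_strat`), and `n_alines` (retained A-line count).
#' @export
volume_summary <- function(maps, masks, restrict_to_lesion = FALSE,
                           role = c("lesion", "contralateral"), id = NA_character_) {
  stopifnot(inherits(maps, "biomarker_maps"), inherits(masks, "enface_masks"))
  role <- match.arg(role)
  retain <- erode_central(masks$contact) & !masks$artifact
  if (restrict_to_lesion) retain <- retain & masks$lesion
  if (!any(retain)) stop("no A-lines retained after erosion/artifact/lesion masking")
  med <- function(mp) stats::median(mp[retain], na.rm = TRUE)
  out <- data.frame(id = id, role = role,
                    depth_um = med(maps$depth_um),
                    loss_pct = maps$loss_pct,
                    mu_overall = med(maps$mu_overall),
                    mu_epi = med(maps$mu_epi),
                    mu_stroma = med(maps$mu_stroma),
                    es_strat = med(maps$es_strat),
                    ie_strat = med(maps$ie_strat),
                    n_alines = sum(retain),
                    stringsAsFactors = FALSE)
  out
}

#' Export biomarker maps as a TIFF stack plus CSVs
#'
#' One float TIFF page per feature plus per-feature CSVs and the loss
#' overlay mask; a simple PNG rendering with a gray loss overlay is written
#' for quick inspection.
#'
#' @param maps a [compute_biomarkers()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_biomarkers <- function(maps, dir) {
  stopifnot(inherits(maps, "biomarker_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in biomarker_names)
    write_enface(maps[[nm]], file.path(dir, paste0(nm, ".tif")))
  tiff::writeTIFF(ifelse(maps$loss_mask, 1, 0), file.path(dir, "loss_mask.tif"),
                  bits.per.sample = 8L, reduce = FALSE)
  writeLines(jsonlite::toJSON(list(loss_pct = maps$loss_pct), auto_unbox = TRUE),
             file.path(dir, "loss_pct.json"))
  render_biomarkers(maps, file.path(dir, "biomarkers.png"))
  invisible(dir)
}

# Quick-look PNG: depth and the two stratification maps with gray loss overlay.
#' @keywords internal
render_biomarkers <- function(maps, path) {
  grDevices::png(path, width = 900, height = 600)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(3, 1), mar = c(1, 1, 2, 1))
  shade <- function(mp, title) {
    m <- as.matrix(mp)
    rng <- range(m, na.rm = TRUE)
    if (!all(is.finite(rng))) rng <- c(0, 1)
    if (rng[2] <= rng[1]) rng[2] <- rng[1] + 1
    img <- t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
    graphics::image(img, zlim = rng, col = grDevices::hcl.colors(64, "YlOrBr", rev = TRUE),
                    axes = FALSE, main = title)
  }
  shade(maps$depth_um, "epithelial depth [um]")
  shade(maps$es_strat, "epithelial-stromal stratification [a.u.]")
  shade(maps$ie_strat, "intraepithelial stratification [a.u.]")
}
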