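#' Specify a synthetic two-layer mucosa phantom
#'
#' Defines a cylindrical OCT volume of layered oral mucosa: a darker
#' epithelium over a brighter stroma, each with its own attenuation
#' coefficient, on a 10 um isotropic grid. The generative law per A-line is
#' standard single-scattering round-trip decay in linear power,
#' `P(z) = B(z) * exp(-2 * integral of mu dz)`, averaged over each 10 um
#' pixel (detectors integrate the decay across the pixel), with optional
#' unit-mean exponential multiplicative speckle and an additive noise floor,
#' converted to dB. By default the backscatter amplitudes are proportional to the
#' attenuation coefficients (`backscatter_epi = backscatter_stroma *
#' mu_epi / mu_stroma`, constant backscatter efficiency), which preserves the
#' dark-over-bright layering and matches the model assumption of the
#' depth-resolved attenuation estimator.
#'
#' Scalar tissue fields are broadcast over the grid; any of them may instead
#' be a full `F x Y` matrix.
#'
#' @param n_frames,n_y,n_z grid size (frames, pullback samples, depth samples).
#' @param pixel_um isotropic pixel size in micrometres.
#' @param surface_z_um tissue-top depth per A-line (um; scalar or `F x Y`).
#' @param epi_depth_um epithelial depth per A-line (um; scalar or `F x Y`).
#' @param mu_epi_mm,mu_stroma_mm layer attenuation coefficients (mm^-1).
#' @param backscatter_epi,backscatter_stroma relative linear backscatter
#'   amplitudes; `backscatter_epi = NULL` selects the proportional default.
#' @param noise_floor_db additive noise-floor level in dB (relative to a
#'   stroma backscatter of 1 = 0 dB).
#' @param speckle logical; multiplicative unit-mean exponential speckle on
#'   the tissue signal and exponential floor noise.
#' @param loss_frac fraction of tissue A-lines with no resolvable
#'   epithelial-stromal boundary; ignored if `loss_regions` is given.
#' @param loss_regions optional logical `F x Y` matrix of loss A-lines.
#' @param contact_frames integer vector of frames in tissue contact
#'   (default: the central two-thirds of the revolution).
#' @param bubbles list of bubble artifacts, each
#'   `list(f, y, rf, ry)` (ellipse centre and radii in frames / pullback
#'   samples); bubbles carve shadowed vertical stripes.
#' @param lesion optional logical `F x Y` lesion-area mask.
#' @param taper_frames,taper_db linear dB roll-off applied over this many
#'   frames at the ends of each azimuthal contact run, emulating edge
#'   effects at grazing incidence.
#' @param seed integer RNG seed; generation is bit-reproducible per seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_frames = 64L, n_y = 512L, n_z = 200L, pixel_um = 10,
                         surface_z_um = 100, epi_depth_um = 160,
                         mu_epi_mm = 1.20, mu_stroma_mm = 3.97,
                         backscatter_epi = NULL, backscatter_stroma = 1,
                         noise_floor_db = -40, speckle = TRUE,
                         loss_frac = 0, loss_regions = NULL,
                         contact_frames = NULL, bubbles = list(),
                         lesion = NULL, taper_frames = 4L, taper_db = 10,
                         seed = 1L) {
  n_frames <- as.integer(n_frames); n_y <- as.integer(n_y); n_z <- as.integer(n_z)
  stopifnot(n_frames >= 1L, n_y >= 1L, n_z >= 1L, pixel_um > 0)
  surface_z_um <- as_field(surface_z_um, n_frames, n_y, "surface_z_um")
  epi_depth_um <- as_field(epi_depth_um, n_frames, n_y, "epi_depth_um")
  mu_epi_mm <- as_field(mu_epi_mm, n_frames, n_y, "mu_epi_mm")
  mu_stroma_mm <- as_field(mu_stroma_mm, n_frames, n_y, "mu_stroma_mm")
  if (any(surface_z_um < 0) || any(epi_depth_um < 0)) stop("depths must be >= 0")
  if (any(mu_epi_mm < 0) || any(mu_stroma_mm < 0)) stop("attenuation fields must be >= 0")
  if (is.null(contact_frames)) {
    w <- max(1L, round(n_frames * 2 / 3))
    s <- max(1L, floor((n_frames - w) / 2) + 1L)
    contact_frames <- s:(s + w - 1L)
  }
  contact_frames <- sort(unique(as.integer(contact_frames)))
  if (!length(contact_frames) || any(contact_frames < 1L | contact_frames > n_frames))
    stop("contact_frames must be a non-empty subset of the frames")
  if (!is.null(loss_regions)) {
    loss_regions <- as.matrix(loss_regions) > 0
    if (!all(dim(loss_regions) == c(n_frames, n_y)))
      stop("loss_regions must be an F x Y logical matrix")
  }
  if (!is.null(lesion)) {
    lesion <- as.matrix(lesion) > 0
    if (!all(dim(lesion) == c(n_frames, n_y))) stop("lesion must be F x Y")
  }
  for (b in bubbles)
    if (b$f < 1 || b$f > n_frames || b$y < 1 || b$y > n_y)
      stop("bubble centre outside the grid")
  structure(list(n_frames = n_frames, n_y = n_y, n_z = n_z, pixel_um = pixel_um,
                 surface_z_um = surface_z_um, epi_depth_um = epi_depth_um,
                 mu_epi_mm = mu_epi_mm, mu_stroma_mm = mu_stroma_mm,
                 backscatter_epi = backscatter_epi,
                 backscatter_stroma = backscatter_stroma,
                 noise_floor_db = noise_floor_db, speckle = isTRUE(speckle),
                 loss_frac = loss_frac, loss_regions = loss_regions,
                 contact_frames = contact_frames, bubbles = bubbles,
                 lesion = lesion, taper_frames = as.integer(taper_frames),
                 taper_db = taper_db, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Preset phantoms emulating the study's tissue groups
#'
#' `"contralateral"` reproduces the lesion-free reference medians (epithelial
#' depth 160 um, mu_epithelium 1.20 mm^-1, mu_stroma 3.97 mm^-1, no loss of
#' the epithelial-stromal boundary). `"observation_lesion"` is a thicker,
#' mildly disorganized lesion with a small loss fraction and bubble
#' artifacts. `"intervention_lesion"` emulates severe dysplasia/carcinoma
#' with a majority (77%) loss of the epithelial-stromal boundary.
#'
#' @param profile one of `"contralateral"`, `"observation_lesion"`,
#'   `"intervention_lesion"`.
#' @param seed RNG seed passed to the spec.
#' @param n_frames,n_y,n_z grid size overrides.
#' @return a [phantom_spec()].
#' @export
phantom_preset <- function(profile = c("contralateral", "observation_lesion",
                                       "intervention_lesion"),
                           seed = 1L, n_frames = 64L, n_y = 512L, n_z = 200L) {
  profile <- match.arg(profile)
  base <- list(n_frames = n_frames, n_y = n_y, n_z = n_z, seed = seed)
  lesion_center <- function(nf, ny, contact) {
    m <- matrix(FALSE, nf, ny)
    m[contact, max(1L, round(ny * 0.25)):round(ny * 0.75)] <- TRUE
    m
  }
  spec <- switch(profile,
    contralateral = do.call(phantom_spec, c(base, list(
      epi_depth_um = 160, mu_epi_mm = 1.20, mu_stroma_mm = 3.97))),
    observation_lesion = do.call(phantom_spec, c(base, list(
      epi_depth_um = 300, mu_epi_mm = 1.50, mu_stroma_mm = 4.20,
      loss_frac = 0.05,
      bubbles = list(list(f = round(n_frames * 0.45), y = round(n_y * 0.3),
                          rf = 3, ry = 12),
                     list(f = round(n_frames * 0.55), y = round(n_y * 0.62),
                          rf = 2, ry = 8))))),
    intervention_lesion = do.call(phantom_spec, c(base, list(
      epi_depth_um = 450, mu_epi_mm = 1.70, mu_stroma_mm = 3.50,
      loss_frac = 0.77))))
  if (profile != "contralateral")
    spec$lesion <- lesion_center(spec$n_frames, spec$n_y, spec$contact_frames)
  spec
}

#' Generate a phantom volume and its ground truth
#'
#' Renders the spec into an [oct_volume()] (dB, 10 um isotropic grid with
#' `n_medium = 1.333`, so [rescale_isotropic()] is the identity) plus a
#' ground-truth object: surfaces, en face masks, and per-A-line true
#' biomarker values. In loss regions the stroma backscatter step is
#' suppressed and epithelium-like decay continues to the floor; outside the
#' contact map the tissue signal is replaced by floor-level noise; bubbles
#' carve shadowed vertical stripes and are recorded as artifacts. The same
#' seed always yields a bit-identical volume.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `volume` ([oct_volume()]), `truth`
#'   (list: `surfaces` [surface_set()], `masks` [enface_masks()], `depth_um`,
#'   `mu_epi`, `mu_stroma` `F x Y` matrices, `loss` logical `F x Y`,
#'   `loss_pct` scalar), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  nf <- spec$n_frames; ny <- spec$n_y; nz <- spec$n_z
  px_mm <- spec$pixel_um / 1000
  top <- round(spec$surface_z_um / spec$pixel_um) + 1L       # 1-based row
  depth_px <- round(spec$epi_depth_um / spec$pixel_um)
  boundary <- top + depth_px
  if (any(boundary > nz))
    stop("epithelium extends deeper than the grid")
  contact <- matrix(FALSE, nf, ny)
  contact[spec$contact_frames, ] <- TRUE

  artifact <- matrix(FALSE, nf, ny)
  for (b in spec$bubbles) {
    ff <- matrix(seq_len(nf), nf, ny)
    yy <- matrix(seq_len(ny), nf, ny, byrow = TRUE)
    artifact <- artifact | (((ff - b$f) / b$rf)^2 + ((yy - b$y) / b$ry)^2 <= 1)
  }

  loss <- spec$loss_regions
  if (is.null(loss)) {
    loss <- matrix(FALSE, nf, ny)
    if (spec$loss_frac > 0) {
      eligible <- which(contact & !artifact)
      k <- round(spec$loss_frac * length(eligible))
      loss[sample(eligible, k)] <- TRUE
    }
  }
  loss <- loss & contact

  b_s <- spec$backscatter_stroma
  b_e <- spec$backscatter_epi
  B_e <- if (is.null(b_e)) b_s * spec$mu_epi_mm / spec$mu_stroma_mm
         else as_field(b_e, nf, ny, "backscatter_epi")
  B_s <- as_field(b_s, nf, ny, "backscatter_stroma")

  # azimuthal edge taper (dB attenuation ramp at contact-run ends)
  taper <- matrix(0, nf, ny)
  if (spec$taper_frames > 0L && spec$taper_db > 0) {
    tw <- spec$taper_frames
    for (y in seq_len(ny)) {
      r <- rle(contact[, y]); pos <- cumsum(c(1L, r$lengths))
      for (i in seq_along(r$lengths)) {
        if (!r$values[i]) next
        s <- pos[i]; e <- pos[i] + r$lengths[i] - 1L
        for (j in seq_len(min(tw, r$lengths[i]))) {
          ramp <- spec$taper_db * (tw - j + 1) / tw
          taper[s + j - 1L, y] <- max(taper[s + j - 1L, y], ramp)
          taper[e - j + 1L, y] <- max(taper[e - j + 1L, y], ramp)
        }
      }
    }
  }

  floor_lin <- db_to_linear(spec$noise_floor_db)
  arr <- array(0, dim = c(nz, ny, nf))
  zedge <- matrix(seq_len(nz + 1L), nz + 1L, ny)   # edge j = depth (j-1) px
  zrow <- matrix(seq_len(nz), nz, ny)
  for (f in seq_len(nf)) {
    tf1 <- matrix(top[f, ], nz + 1L, ny, byrow = TRUE)
    bf1 <- matrix(boundary[f, ], nz + 1L, ny, byrow = TRUE)
    lossf1 <- matrix(loss[f, ], nz + 1L, ny, byrow = TRUE)
    muE1 <- matrix(spec$mu_epi_mm[f, ], nz + 1L, ny, byrow = TRUE)
    muS1 <- matrix(spec$mu_stroma_mm[f, ], nz + 1L, ny, byrow = TRUE)
    # optical path to each pixel edge
    le <- pmax(zedge - tf1, 0)                     # epithelial path (px)
    ls <- pmax(zedge - bf1, 0)                     # stromal path (px)
    le_eff <- ifelse(lossf1, le, pmin(le, bf1 - tf1))
    ls_eff <- ifelse(lossf1, 0, ls)
    E <- exp(-2 * (muE1 * le_eff + muS1 * ls_eff) * px_mm)
    # per-row layer properties
    tf <- tf1[seq_len(nz), , drop = FALSE]
    bf <- bf1[seq_len(nz), , drop = FALSE]
    lossf <- lossf1[seq_len(nz), , drop = FALSE]
    instroma <- !lossf & zrow >= bf
    B <- ifelse(instroma, matrix(B_s[f, ], nz, ny, byrow = TRUE),
                matrix(B_e[f, ], nz, ny, byrow = TRUE))
    mu_row <- ifelse(instroma, muS1[seq_len(nz), , drop = FALSE],
                     muE1[seq_len(nz), , drop = FALSE])
    # pixel-integrated backscattered power: mean of B*exp(-2 integral mu)
    # over the pixel; reduces to the point sample as mu -> 0
    dE <- E[seq_len(nz), , drop = FALSE] - E[seq_len(nz) + 1L, , drop = FALSE]
    P <- ifelse(mu_row > 0, B * dE / (2 * mu_row * px_mm),
                B * E[seq_len(nz), , drop = FALSE])
    P[zrow < tf] <- 0
    P[, !contact[f, ]] <- 0
    if (any(artifact[f, ]))
      P[, artifact[f, ]] <- P[, artifact[f, ]] * 1e-3   # bubble shadow
    if (any(taper[f, ] > 0))
      P <- P * matrix(10^(-taper[f, ] / 10), nz, ny, byrow = TRUE)
    if (spec$speckle) {
      P <- P * matrix(stats::rexp(nz * ny), nz, ny)
      fl <- matrix(stats::rexp(nz * ny, rate = 1 / max(floor_lin, 1e-300)), nz, ny)
    } else {
      fl <- matrix(floor_lin, nz, ny)
    }
    arr[, , f] <- linear_to_db(pmax(P + fl, 1e-300))
  }

  topm <- ifelse(contact, top, NA_integer_)
  bndm <- ifelse(contact & !loss, boundary, NA_integer_)
  truth_depth <- ifelse(contact, depth_px * spec$pixel_um, NA_real_)
  tissue_ok <- contact & !artifact
  loss_pct <- 100 * sum(loss & tissue_ok) / sum(tissue_ok)
  list(volume = oct_volume(arr, y_spacing_um = spec$pixel_um,
                           z_spacing_optical_um = spec$pixel_um * 1.333,
                           n_medium = 1.333,
                           frames_per_rev = nf,
                           rotation_hz = 100, pullback_speed_mm_s = 2),
       truth = list(surfaces = surface_set(topm, bndm),
                    masks = enface_masks(contact, artifact, spec$lesion),
                    depth_um = truth_depth,
                    mu_epi = ifelse(contact, spec$mu_epi_mm, NA_real_),
                    mu_stroma = ifelse(contact & !loss, spec$mu_stroma_mm, NA_real_),
                    loss = loss, loss_pct = loss_pct),
       spec = spec)
}

#' Read a phantom spec from YAML or JSON
#'
#' Scalar fields may be given as constants; `loss_regions` and `lesion` may
#' be given as nested arrays. Field names match [phantom_spec()] arguments.
#'
#' @param path `.yaml`/`.yml` or `.json` spec file.
#' @return a [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("loss_regions", "lesion"))
    if (!is.null(x[[f]])) x[[f]] <- do.call(rbind, lapply(x[[f]], as.numeric))
  do.call(phantom_spec, x)
}
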