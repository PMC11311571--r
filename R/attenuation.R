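#' Depth-resolved attenuation coefficient of one A-line
#'
#' Estimates the attenuation coefficient mu (mm^-1, round-trip decay
#' `exp(-2 mu z)`) at every pixel of a linear-power A-line from the
#' single-scattering relation between local signal and the energy remaining
#' below it, in its exact discrete form:
#'
#' `mu[i] = log(1 + I[i] / S[i]) / (2 * delta)`,
#'
#' where `S[i]` is the sum of the power below pixel `i` plus a tail
#' compensation for the energy beyond the last measured pixel. The tail is
#' the summed geometric continuation of an exponential fitted by log-linear
#' least squares to the last `m` pixels:
#' `tail = I[N] * r / (1 - r)`, `r = exp(-2 * mu_tail * delta)` (equivalent
#' to the boundary estimate `I[N] / (2 mu_tail)` in the small-pixel limit).
#' On a noiseless exponential the estimate is exact at every pixel. The
#' estimator is invariant to rescaling the profile by any positive constant.
#'
#' If the tail fit is degenerate (non-decaying) or the profile is shorter
#' than `m`, the uncompensated sum is used and the result carries
#' `attr(, "quality") = "uncompensated"`; the last pixel is then undefined
#' (`NA`).
#'
#' @param aline_power linear power profile over the N visualized pixels
#'   (all values > 0).
#' @param delta_mm pixel size in mm (default 0.01 = 10 um).
#' @param m tail-fit window length in pixels (default 10).
#' @param compensate logical; apply the tail compensation.
#' @return numeric vector of mu (mm^-1) with attribute `quality`
#'   (`"compensated"` or `"uncompensated"`).
#' @export
depth_resolved_mu <- function(aline_power, delta_mm = 0.01, m = 10L,
                              compensate = TRUE) {
  if (any(!is.finite(aline_power)) || any(aline_power <= 0))
    stop("aline_power must be finite and > 0")
  n <- length(aline_power)
  power <- matrix(aline_power, ncol = 1)
  res <- mu_engine(power, top = 1L, bottom = n + 1L, delta_mm = delta_mm,
                   m = m, compensate = compensate)
  mu <- res$mu[, 1]
  attr(mu, "quality") <- res$quality[1]
  mu
}

# Vectorized estimator over the columns of a Z x Y linear-power matrix.
# top/bottom are per-column 1-based visualized intervals [top, bottom);
# NA top = no tissue. Returns mu matrix (NA outside intervals) and a
# per-column quality string.
#' @keywords internal
mu_engine <- function(power, top, bottom, delta_mm = 0.01, m = 10L,
                      compensate = TRUE) {
  nz <- nrow(power); ny <- ncol(power)
  if (length(top) == 1L) top <- rep(top, ny)
  if (length(bottom) == 1L) bottom <- rep(bottom, ny)
  vis <- matrix(FALSE, nz, ny)
  for (y in seq_len(ny))
    if (!is.na(top[y]) && bottom[y] > top[y])
      vis[top[y]:min(bottom[y] - 1L, nz), y] <- TRUE
  pm <- ifelse(vis, power, 0)
  cs <- apply(pm, 2L, cumsum)
  cs <- matrix(cs, nz, ny)
  totals <- cs[nz, ]
  below <- sweep(-cs, 2L, totals, `+`)          # sum of power strictly below

  quality <- ifelse(is.na(top), NA_character_, "compensated")
  tail_add <- numeric(ny)
  if (compensate) {
    nvis <- ifelse(is.na(top), 0L, pmax(bottom - top, 0L))
    fit <- which(!is.na(top) & nvis >= m)
    if (length(fit)) {
      x <- seq_len(m) - (m + 1) / 2             # centred abscissa
      sxx <- sum(x^2)
      idx_last <- pmin(bottom[fit] - 1L, nz)
      win <- outer(seq.int(-m + 1L, 0L), idx_last, `+`)   # m x |fit| row idx
      flat <- cbind(as.vector(win), rep(fit, each = m))
      logw <- matrix(log(power[flat]), m, length(fit))
      slope <- as.numeric(crossprod(x, sweep(logw, 2L, colMeans(logw))) / sxx)
      ok <- is.finite(slope) & slope < 0
      last_p <- power[cbind(idx_last, fit)]
      r <- exp(slope)
      tail_add[fit[ok]] <- (last_p * r / (1 - r))[ok]
      quality[fit[!ok]] <- "uncompensated"
    }
    short <- which(!is.na(top) & nvis > 0L & nvis < m)
    quality[short] <- "uncompensated"
  } else {
    quality[!is.na(top)] <- "uncompensated"
  }
  denom <- below + matrix(tail_add, nz, ny, byrow = TRUE)
  mu <- log1p(ifelse(vis & denom > 0, power, NA) / denom) / (2 * delta_mm)
  mu[!vis] <- NA_real_
  mu <- pmax(mu, 0)
  list(mu = mu, quality = quality)
}

#' Attenuation-coefficient volume from a rescaled OCT volume
#'
#' Converts dB intensity to linear power, subtracts the per-frame noise
#' floor (mean level, in linear power), and runs the depth-resolved
#' estimator over the visualized region of every A-line. Pixels outside the
#' visualized region are `NA`.
#'
#' @param vol a rescaled [oct_volume()] (10 um pixels).
#' @param regions a [build_region_masks()] result aligned with `vol`.
#' @param floors_db per-frame noise floor in dB (length F), as from
#'   [noise_floor()]; `NULL` disables floor subtraction.
#' @param m,compensate tail-fit controls, see [depth_resolved_mu()].
#' @return an `attenuation_volume`: list with `mu` (`[z, y, f]` array,
#'   mm^-1, `NA` outside the visualized region), `delta_mm`, and `quality`
#'   (`F x Y` matrix).
#' @export
compute_attenuation <- function(vol, regions, floors_db = NULL, m = 10L,
                                compensate = TRUE) {
  stopifnot(inherits(vol, "oct_volume"), inherits(regions, "region_masks"))
  delta_mm <- z_spacing_physical_um(vol) / 1000
  nf <- n_frames(vol)
  mu <- array(NA_real_, dim = dim(vol$intensity_db))
  quality <- matrix(NA_character_, nf, n_pullback(vol))
  for (f in seq_len(nf)) {
    p <- db_to_linear(vol$intensity_db[, , f, drop = TRUE])
    p <- matrix(p, n_depth(vol), n_pullback(vol))
    if (!is.null(floors_db)) {
      fl <- db_to_linear(floors_db[f])
      p <- pmax(p - fl, fl * 1e-6)
    }
    res <- mu_engine(p, regions$top[f, ], regions$bottom[f, ],
                     delta_mm = delta_mm, m = m, compensate = compensate)
    mu[, , f] <- res$mu
    quality[f, ] <- res$quality
  }
  structure(list(mu = mu, delta_mm = delta_mm, quality = quality),
            class = "attenuation_volume")
}

#' Region-wise mean attenuation en face map
#'
#' Per-A-line mean of the attenuation coefficient over the chosen region
#' (`overall` = full visualized depth, or the epithelium / stroma /
#' upper-epithelium / lower-epithelium mask). Entries are missing where the
#' region is empty on that A-line (e.g. the stroma under a loss flag).
#'
#' @param att an [compute_attenuation()] result, or a `[z, y, f]` mu array.
#' @param regions a [build_region_masks()] result.
#' @param which region name: `"overall"`, `"epithelium"`, `"stroma"`,
#'   `"upper_epithelium"`, `"lower_epithelium"`.
#' @param tail_trim pixels to exclude at the bottom of each A-line's
#'   visualized region before averaging. Estimates inside the
#'   tail-compensation window are dominated by the fitted boundary
#'   condition rather than by data, so the pipeline excludes them
#'   (`tail_trim = m`); the default 0 averages the full region.
#' @return an `F x Y` en face matrix (mm^-1), `NA` = missing.
#' @export
region_mean_mu <- function(att, regions,
                           which = c("overall", "epithelium", "stroma",
                                     "upper_epithelium", "lower_epithelium"),
                           tail_trim = 0L) {
  which <- match.arg(which)
  mu <- if (inherits(att, "attenuation_volume")) att$mu else att
  lo <- switch(which, overall = regions$top, epithelium = regions$top,
               stroma = regions$s_start, upper_epithelium = regions$top,
               lower_epithelium = regions$ue_end)
  hi <- switch(which, overall = regions$bottom, epithelium = regions$e_end,
               stroma = regions$bottom, upper_epithelium = regions$ue_end,
               lower_epithelium = regions$e_end)
  if (tail_trim > 0L) hi <- pmin(hi, regions$bottom - as.integer(tail_trim))
  nf <- dim(mu)[3]
  out <- matrix(NA_real_, nf, dim(mu)[2])
  for (f in seq_len(nf))
    out[f, ] <- interval_col_means(matrix(mu[, , f], dim(mu)[1], dim(mu)[2]),
                                   lo[f, ], hi[f, ])
  enface_map(out, "mm^-1")
}

# Mean of mat[lo:(hi-1), y] per column, NA-aware; empty/NA interval -> NA.
#' @keywords internal
interval_col_means <- function(mat, lo, hi) {
  vals <- ifelse(is.na(mat), 0, mat)
  cnt <- !is.na(mat)
  cs_v <- apply(vals, 2L, cumsum); cs_n <- apply(cnt, 2L, cumsum)
  cs_v <- rbind(0, matrix(cs_v, nrow(mat))); cs_n <- rbind(0, matrix(cs_n, nrow(mat)))
  ny <- ncol(mat)
  out <- rep(NA_real_, ny)
  ok <- !is.na(lo) & !is.na(hi) & hi > lo
  if (any(ok)) {
    yy <- which(ok)
    s <- cs_v[cbind(hi[yy], yy)] - cs_v[cbind(lo[yy], yy)]
    n <- cs_n[cbind(hi[yy], yy)] - cs_n[cbind(lo[yy], yy)]
    out[yy] <- ifelse(n > 0, s / n, NA_real_)
  }
  out
}
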