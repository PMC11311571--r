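# Shared fixture builders; all fixtures are generated in code.

# Small volume with arbitrary values, already on the 10 um isotropic grid.
tiny_volume <- function(nz = 30, ny = 8, nf = 2, fill = NULL, seed = 1) {
  set.seed(seed)
  arr <- array(if (is.null(fill)) stats::rnorm(nz * ny * nf, -50, 8)
               else fill, dim = c(nz, ny, nf))
  oct_volume(arr, y_spacing_um = 10, z_spacing_optical_um = 13.33,
             n_medium = 1.333, frames_per_rev = nf,
             pullback_speed_mm_s = 2, rotation_hz = 100)
}

# Surfaces with constant top/boundary over an F x Y grid (NA allowed).
flat_surfaces <- function(nf, ny, top = 11L, boundary = 27L) {
  surface_set(matrix(as.integer(top), nf, ny),
              matrix(as.integer(boundary), nf, ny))
}

# All-contact masks of a given grid size.
full_masks <- function(nf, ny) enface_masks(matrix(TRUE, nf, ny))
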