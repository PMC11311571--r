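# Separable cubic-convolution (Keys, a = -0.5) resampling on regular grids.
# Used by rescale_isotropic(); linear in the sample values, reproduces
# polynomials up to degree 2 exactly, replicate borders.

# Keys kernel weight for offsets t in [0, 2)
keys_weights <- function(t, a = -0.5) {
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at <= 1
  w[i1] <- (a + 2) * at[i1]^3 - (a + 3) * at[i1]^2 + 1
  i2 <- at > 1 & at < 2
  w[i2] <- a * at[i2]^3 - 5 * a * at[i2]^2 + 8 * a * at[i2] - 4 * a
  w
}

# Interpolate samples y (at integer coordinates 0..n-1) at coordinates u.
#' @keywords internal
cubic_interp1 <- function(y, u) {
  n <- length(y)
  if (n == 1L) return(rep(y, length(u)))
  i0 <- floor(u)
  t <- u - i0
  idx <- function(k) pmin(pmax(i0 + k, 0), n - 1) + 1L  # replicate borders
  keys_weights(t + 1) * y[idx(-1L)] +
    keys_weights(t)     * y[idx(0L)] +
    keys_weights(t - 1) * y[idx(1L)] +
    keys_weights(t - 2) * y[idx(2L)]
}

# Resample each column (axis = 1) or row (axis = 2) of a matrix from sample
# spacing `from` to `to` (same units), keeping the physical origin at sample 0.
#' @keywords internal
cubic_resample_axis <- function(m, from, to, axis = 1L) {
  n <- if (axis == 1L) nrow(m) else ncol(m)
  n_out <- floor((n - 1) * from / to) + 1L
  u <- (seq_len(n_out) - 1L) * to / from
  if (axis == 1L) {
    out <- apply(m, 2L, cubic_interp1, u = u)
    matrix(out, n_out, ncol(m))
  } else {
    out <- t(apply(m, 1L, cubic_interp1, u = u))
    matrix(out, nrow(m), n_out)
  }
}
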