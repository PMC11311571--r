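# Internal numeric helpers shared across modules.

#' @keywords internal
db_to_linear <- function(x) 10^(x / 10)

#' @keywords internal
linear_to_db <- function(x) 10 * log10(x)

# 2-D Gaussian smoothing with a (2r+1)x(2r+1) kernel and reflective borders.
# Default: 5x5 support, sigma = 1 px (~99% of kernel mass inside the support).
#' @keywords internal
gauss_smooth2d <- function(m, radius = 2L, sigma = 1) {
  stopifnot(is.matrix(m), radius >= 1L, sigma > 0)
  k1 <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  nr <- nrow(m); nc <- ncol(m)
  # reflect-pad then run the separable kernel along each axis
  refl <- function(n, r) c(pmin(r + 1L - seq_len(r), n), seq_len(n), n + 1L - pmin(seq_len(r), n))
  mp <- m[refl(nr, radius), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (j in seq_along(k1)) out <- out + k1[j] * mp[j:(j + nr - 1L), , drop = FALSE]
  mp <- out[, refl(nc, radius), drop = FALSE]
  out <- matrix(0, nr, nc)
  for (j in seq_along(k1)) out <- out + k1[j] * mp[, j:(j + nc - 1L), drop = FALSE]
  out
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Broadcast a scalar or matrix field to an F x Y matrix.
#' @keywords internal
as_field <- function(x, n_frames, n_y, what = "field") {
  if (is.null(dim(x))) {
    if (length(x) != 1L) stop(what, " must be a scalar or an F x Y matrix")
    return(matrix(as.numeric(x), n_frames, n_y))
  }
  x <- as.matrix(x)
  if (!all(dim(x) == c(n_frames, n_y)))
    stop(what, " has dimensions ", paste(dim(x), collapse = "x"),
         " but the grid is ", n_frames, "x", n_y)
  x
}
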