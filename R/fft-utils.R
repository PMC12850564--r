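# Centered discrete Fourier conventions shared by every module.
#
# All k-space arrays in this package use a centered grid: the DC sample sits
# at 0-based index floor(N/2) on each axis (1-based index floor(N/2) + 1).
# A single convention everywhere avoids half-pixel phase ramps between the
# simulator, the calibration matrices and the per-pixel operators.

#' Centered grid coordinates
#'
#' Integer coordinates of a length-`n` centered grid, running from
#' `-floor(n/2)` to `ceiling(n/2) - 1` so that coordinate 0 falls at 0-based
#' index `floor(n/2)`.
#'
#' @param n Grid length (positive integer).
#' @return Integer vector of length `n`.
#' @keywords internal
centered_coords <- function(n) {
  seq_len(n) - 1L - n %/% 2L
}

#' @keywords internal
dc_index <- function(n) n %/% 2L + 1L

# Circular shift of a matrix along both axes.
circshift2 <- function(x, by) {
  ny <- nrow(x); nx <- ncol(x)
  i <- ((seq_len(ny) - 1L - by[1L]) %% ny) + 1L
  j <- ((seq_len(nx) - 1L - by[2L]) %% nx) + 1L
  x[i, j, drop = FALSE]
}

#' @keywords internal
fftshift2 <- function(x) circshift2(x, c(nrow(x) %/% 2L, ncol(x) %/% 2L))

#' @keywords internal
ifftshift2 <- function(x) circshift2(x, -c(nrow(x) %/% 2L, ncol(x) %/% 2L))

#' Centered 2D discrete Fourier transforms
#'
#' `kspace_forward()` maps a centered image to centered k-space,
#' `kspace_inverse()` is its inverse.  The forward transform is unnormalized
#' (`sum |K|^2 = N^2 sum |m|^2`); the inverse carries the `1/N^2` factor, so
#' `kspace_inverse(kspace_forward(m))` is the identity.
#'
#' @param x Complex (or numeric) matrix on the centered grid.
#' @return Complex matrix of the same dimensions.
#' @examples
#' m <- matrix(rnorm(16 * 16), 16, 16)
#' max(Mod(kspace_inverse(kspace_forward(m)) - m)) < 1e-12
#' @export
kspace_forward <- function(x) {
  fftshift2(stats::fft(ifftshift2(x)))
}

#' @rdname kspace_forward
#' @export
kspace_inverse <- function(x) {
  fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / length(x)
}

# Evaluate a seeded expression without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
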