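#' Ground-truth shot-to-shot phase fluctuation maps
#'
#' Simulates the smooth, nonlinear image-space phase that differs between
#' shots of a diffusion-weighted multi-shot EPI acquisition (e.g., from bulk
#' or physiological motion during diffusion encoding).  Shot 0 is the phase
#' reference and is identically zero; every other shot receives a random
#' polynomial of order `poly_order` mixed with a band-limited random field,
#' and the whole set is rescaled so the maximum absolute phase over all shots
#' and pixels equals `amplitude_rad` exactly.
#'
#' @param n_shots Number of shots (>= 2).
#' @param grid_size Pixels per axis.
#' @param poly_order Polynomial order of the smooth component (0..4).
#' @param amplitude_rad Peak absolute phase in radians (>= 0).
#' @param random_fraction Mixing weight in \[0, 1\] of the band-limited random
#'   field relative to the polynomial component.
#' @param seed Integer seed.
#' @param amplitude_maps Optional per-shot nonnegative magnitude-fluctuation
#'   array (`grid x grid x n_shots`); default all ones.
#' @return Object of class `epi_phases`: list with `phase` (array
#'   `grid x grid x n_shots`, radians), `amplitude` (same shape), `n_shots`,
#'   `grid_size`.
#' @export
make_shot_phase_maps <- function(n_shots, grid_size, poly_order = 2L,
                                 amplitude_rad = 1.5, random_fraction = 0.2,
                                 seed = 1L, amplitude_maps = NULL) {
  if (n_shots < 2) stop("n_shots must be at least 2", call. = FALSE)
  if (poly_order > 4) stop("poly_order must be at most 4", call. = FALSE)
  if (amplitude_rad < 0) stop("amplitude_rad must be nonnegative", call. = FALSE)
  n <- as.integer(grid_size)
  cx <- centered_coords(n) / (n / 2)
  X <- matrix(cx, n, n, byrow = TRUE)
  Y <- matrix(cx, n, n)

  phase <- with_local_seed(seed, {
    out <- array(0, dim = c(n, n, n_shots))
    for (s in seq_len(n_shots)[-1]) {
      poly <- matrix(0, n, n)
      for (px in 0:poly_order) for (py in 0:(poly_order - px)) {
        if (px == 0 && py == 0) next
        poly <- poly + stats::runif(1, -1, 1) * X^px * Y^py
      }
      # band-limited field: random k-space coefficients within radius 3
      field <- matrix(0, n, n)
      if (random_fraction > 0) {
        K <- matrix(0 + 0i, n, n)
        kc <- dc_index(n)
        for (dy in -3:3) for (dx in -3:3) {
          if (dy^2 + dx^2 > 9) next
          K[kc + dy, kc + dx] <- complex(real = stats::rnorm(1),
                                         imaginary = stats::rnorm(1))
        }
        field <- Re(kspace_inverse(K)) * n^2
        field <- field / max(abs(field))
      }
      if (max(abs(poly)) > 0) poly <- poly / max(abs(poly))
      out[, , s] <- (1 - random_fraction) * poly + random_fraction * field
    }
    out
  })

  mx <- max(abs(phase))
  if (mx > 0) phase <- phase * (amplitude_rad / mx)

  if (is.null(amplitude_maps)) {
    amplitude_maps <- array(1, dim = c(n, n, n_shots))
  } else {
    stopifnot(all(dim(amplitude_maps) == c(n, n, n_shots)), all(amplitude_maps >= 0))
  }

  structure(
    list(phase = phase, amplitude = amplitude_maps,
         n_shots = as.integer(n_shots), grid_size = n),
    class = "epi_phases"
  )
}
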