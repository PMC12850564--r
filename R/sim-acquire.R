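#' Simulate a multi-shot, multi-coil EPI acquisition
#'
#' For every shot `s` and coil `c`, samples the centered 2D DFT of
#' `coil_c * amplitude_s * exp(i phase_s) * object` on the shot's coordinate
#' set, optionally applies a per-shot fractional k-space shift (a surrogate
#' for shot-dependent eddy currents, implemented as a coordinate-linear
#' phase), and adds i.i.d. complex Gaussian noise of standard deviation
#' `noise_sigma` per real/imaginary part on the sampled entries.
#'
#' @param phantom An `epi_phantom`.
#' @param coils An `epi_coils` on the same grid.
#' @param phases An `epi_phases` with one map per shot.
#' @param trajectory An `epi_trajectory` with the same shot count and grid.
#' @param noise_sigma Complex-noise standard deviation per component.
#' @param eddy_shift_px Optional `n_shots x 2` matrix of per-shot `(dx, dy)`
#'   image-space shifts in fractional pixels (default none).
#' @param seed Integer seed for the noise stream.
#' @return Object of class `epi_acquisition`: list with `kspace` (complex
#'   array `ky x kx x coil x shot`, zero where unsampled), `mask`
#'   (logical `ky x kx x shot`), `trajectory`, `noise_sigma`, `seed`, and
#'   `truth` (the generating phantom, coils, phases and eddy shifts).
#' @export
simulate_acquisition <- function(phantom, coils, phases, trajectory,
                                 noise_sigma = 0, eddy_shift_px = NULL,
                                 seed = 1L) {
  n <- phantom$grid_size
  S <- trajectory$n_shots
  C <- coils$n_coils
  if (coils$grid_size != n || phases$grid_size != n || trajectory$grid_size != n)
    stop("grid sizes of phantom, coils, phases and trajectory must agree",
         call. = FALSE)
  if (phases$n_shots != S)
    stop("phase set and trajectory disagree on the number of shots",
         call. = FALSE)
  if (is.null(eddy_shift_px)) eddy_shift_px <- matrix(0, S, 2)
  eddy_shift_px <- matrix(eddy_shift_px, nrow = S, ncol = 2)

  kx <- matrix(centered_coords(n), n, n, byrow = TRUE)
  ky <- matrix(centered_coords(n), n, n)

  kspace <- array(0 + 0i, dim = c(n, n, C, S))
  for (s in seq_len(S)) {
    mod_s <- phases$amplitude[, , s] * exp(1i * phases$phase[, , s])
    shift_phase <- exp(-2i * pi * (kx * eddy_shift_px[s, 1] +
                                   ky * eddy_shift_px[s, 2]) / n)
    m <- trajectory$masks[, , s]
    for (c in seq_len(C)) {
      K <- kspace_forward(coils$maps[, , c] * mod_s * phantom$values) * shift_phase
      K[!m] <- 0 + 0i
      kspace[, , c, s] <- K
    }
  }

  if (noise_sigma > 0) {
    kspace <- with_local_seed(seed, {
      for (s in seq_len(S)) {
        idx <- which(trajectory$masks[, , s])
        for (c in seq_len(C)) {
          nz <- complex(real = stats::rnorm(length(idx), sd = noise_sigma),
                        imaginary = stats::rnorm(length(idx), sd = noise_sigma))
          plane <- kspace[, , c, s]
          plane[idx] <- plane[idx] + nz
          kspace[, , c, s] <- plane
        }
      }
      kspace
    })
  }

  structure(
    list(kspace = kspace, mask = trajectory$masks, trajectory = trajectory,
         noise_sigma = noise_sigma, seed = as.integer(seed),
         truth = list(phantom = phantom, coils = coils, phases = phases,
                      eddy_shift_px = eddy_shift_px)),
    class = "epi_acquisition"
  )
}

#' k-space noise level for a target image-domain SNR
#'
#' Converts a target signal-to-noise ratio into the per-component k-space
#' noise standard deviation used by [simulate_acquisition()].  SNR is defined
#' in image space as the mean object magnitude over the support divided by
#' the per-pixel complex-noise standard deviation of a single coil image
#' (for a centered unnormalized forward DFT, image-domain noise per component
#' is `sigma_k / N` for an `N x N` grid, so the complex magnitude noise scale
#' is `sqrt(2) * sigma_k / N`).
#'
#' @param phantom An `epi_phantom`.
#' @param snr Target SNR (> 0).
#' @return Per-component k-space noise standard deviation.
#' @export
noise_sigma_for_snr <- function(phantom, snr) {
  if (snr <= 0) stop("snr must be positive", call. = FALSE)
  sig <- mean(Mod(phantom$values[phantom$support]))
  n <- phantom$grid_size
  (sig / snr) * n / sqrt(2)
}
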