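# Multi-shot Cartesian segmentation schemes.  Each shot's sampled set is a
# logical mask on the centered k-space grid; consecutive shots share a small
# rectangular overlap band that serves as the shot-dependent auto-calibration
# region downstream.

#' Multi-shot k-space segmentation trajectory
#'
#' Builds per-shot sampled-coordinate masks for one of four segmentation
#' schemes:
#' \describe{
#'   \item{`mosaic2`}{top/bottom half-planes sharing `overlap_px` rows about
#'     the DC row (2 shots).}
#'   \item{`mosaic4`}{quadrant bands; each consecutive shot pair shares an
#'     `overlap_px`-wide band through the k-space center (4 shots).}
#'   \item{`readout_segmented`}{full-height vertical bands tiled along kx,
#'     consecutive bands sharing `overlap_px` columns (2..8 shots).}
#'   \item{`phase_interleaved`}{shot `s` samples every `R * n_shots`-th ky row
#'     offset by `s * R`; shots share no raw coordinates, and a designated
#'     central calibration block (side `max(overlap_px, min(50, N/2))`) is
#'     recorded for calibration on intermediate per-shot reconstructions.}
#' }
#'
#' @param scheme One of `"mosaic2"`, `"mosaic4"`, `"readout_segmented"`,
#'   `"phase_interleaved"`.
#' @param grid_size Pixels per axis.
#' @param n_shots Number of shots, consistent with the scheme.
#' @param overlap_px Requested overlap width in pixels (>= 7, so the default
#'   7x7 calibration window fits).
#' @param undersample_R Integer parallel-imaging factor (phase_interleaved
#'   only; total undersampling per shot is `undersample_R * n_shots`).
#' @return Object of class `epi_trajectory`: list with `scheme`, `grid_size`,
#'   `n_shots`, `overlap_px`, `undersample_R`, `masks` (logical
#'   `grid x grid x n_shots`), and `calib_block` (inclusive index ranges of
#'   the central calibration block, `phase_interleaved` only).
#' @export
make_trajectory <- function(scheme = c("mosaic2", "mosaic4",
                                       "readout_segmented", "phase_interleaved"),
                            grid_size, n_shots, overlap_px = 15L,
                            undersample_R = 1L) {
  scheme <- match.arg(scheme)
  n <- as.integer(grid_size)
  S <- as.integer(n_shots)
  ov <- as.integer(overlap_px)
  ok_shots <- switch(scheme,
    mosaic2 = S == 2L, mosaic4 = S == 4L,
    readout_segmented = S >= 2L && S <= 8L,
    phase_interleaved = S >= 2L && S <= 8L)
  if (!ok_shots) stop("n_shots = ", S, " is not valid for scheme '", scheme, "'",
                      call. = FALSE)
  if (ov < 7L) stop("overlap_px must be at least 7 (calibration window width)",
                    call. = FALSE)
  if (ov >= n) stop("overlap_px must be smaller than the grid", call. = FALSE)

  masks <- array(FALSE, dim = c(n, n, S))
  calib_block <- NULL
  dc <- dc_index(n)
  # inclusive overlap band containing the DC index
  band_lo <- dc - (ov - 1L) %/% 2L
  band_hi <- band_lo + ov - 1L
  if (band_lo < 1L || band_hi > n)
    stop("overlap band does not fit inside the grid", call. = FALSE)

  if (scheme == "mosaic2") {
    masks[1:band_hi, , 1L] <- TRUE
    masks[band_lo:n, , 2L] <- TRUE
  } else if (scheme == "mosaic4") {
    masks[1:band_hi, 1:band_hi, 1L] <- TRUE        # top-left
    masks[1:band_hi, band_lo:n, 2L] <- TRUE        # top-right
    masks[band_lo:n, band_lo:n, 3L] <- TRUE        # bottom-right
    masks[band_lo:n, 1:band_hi, 4L] <- TRUE        # bottom-left
  } else if (scheme == "readout_segmented") {
    total <- n + (S - 1L) * ov
    w <- rep(total %/% S, S)
    extra <- total - sum(w)
    if (extra > 0) w[seq_len(extra)] <- w[seq_len(extra)] + 1L
    if (any(w <= ov))
      stop("overlap_px too large: bands would be contained in their neighbors",
           call. = FALSE)
    x0 <- 1L
    for (s in seq_len(S)) {
      masks[, x0:(x0 + w[s] - 1L), s] <- TRUE
      x0 <- x0 + w[s] - ov
    }
  } else { # phase_interleaved
    R <- as.integer(undersample_R)
    if (R < 1L) stop("undersample_R must be a positive integer", call. = FALSE)
    step <- R * S
    for (s in seq_len(S)) {
      rows <- which(((seq_len(n) - 1L) %% step) == (s - 1L) * R)
      masks[rows, , s] <- TRUE
    }
    side <- max(ov, min(50L, n %/% 2L))
    lo <- dc - (side - 1L) %/% 2L
    hi <- lo + side - 1L
    calib_block <- list(ky = c(lo, hi), kx = c(lo, hi))
  }

  structure(
    list(scheme = scheme, grid_size = n, n_shots = S, overlap_px = ov,
         undersample_R = as.integer(undersample_R), masks = masks,
         calib_block = calib_block),
    class = "epi_trajectory"
  )
}
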