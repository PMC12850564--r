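# Combining all shots into a final image: (1) conjugate-phase mosaic
# combination with optional apodization and an inverse modulation-transfer
# (MTF) filter over the summed segment windows; (2) an iterative SENSE-type
# forward-model reconstruction that includes phase-fluctuation encoding.

#' Coil-combine each shot's k-space segment
#'
#' Per shot: inverse-DFT each coil's zero-filled segment, combine pixelwise
#' with the matched filter `conj(coil) / sum |coil|^2` (guarded against zero
#' sensitivity), forward-DFT, and restrict to the segment's support.  In the
#' fully-sampled synthetic case this stands in for the per-segment parallel
#' imaging reconstruction of a scanner pipeline.
#'
#' @param bundle An `epi_acquisition`.
#' @param coils Coil maps used for the combination.
#' @return List with `kspace` (complex array `ky x kx x shot`, zero off the
#'   segment support) and `mask` (the per-shot supports).
#' @export
coil_combine_segments <- function(bundle, coils) {
  dm <- dim(bundle$kspace)
  n <- dm[1]; C <- dm[3]; S <- dm[4]
  if (coils$grid_size != n)
    stop("coil map grid does not match the acquisition", call. = FALSE)
  rss2 <- apply(abs(coils$maps)^2, c(1, 2), sum)
  denom <- pmax(rss2, 1e-12)
  out <- array(0 + 0i, dim = c(n, n, S))
  for (s in seq_len(S)) {
    img <- matrix(0 + 0i, n, n)
    for (c in seq_len(C))
      img <- img + Conj(coils$maps[, , c]) * kspace_inverse(bundle$kspace[, , c, s])
    img <- img / denom
    K <- kspace_forward(img)
    K[!bundle$mask[, , s]] <- 0 + 0i
    out[, , s] <- K
  }
  list(kspace = out, mask = bundle$mask)
}

#' Mosaic combination settings
#'
#' @param apodization Cosine-taper ramp width in pixels applied to each
#'   segment window before combination; 0 disables apodization.  The taper
#'   is removed again by the inverse MTF filter wherever the summed window
#'   is above the floor.
#' @param mtf_floor Relative floor for the inverse-filter division (caps
#'   noise amplification where the summed window tapers toward zero).
#' @param reference_shot Kept for bookkeeping.
#' @return List of class `combine_config`.
#' @export
combine_config <- function(apodization = 0L, mtf_floor = 0.05,
                           reference_shot = 1L) {
  if (mtf_floor <= 0 || mtf_floor >= 1)
    stop("mtf_floor must lie strictly between 0 and 1", call. = FALSE)
  structure(list(apodization = as.integer(apodization), mtf_floor = mtf_floor,
                 reference_shot = as.integer(reference_shot)),
            class = "combine_config")
}

# Apodized indicator window of a shot's (rectangular) support.
segment_window <- function(mask, ramp) {
  if (ramp <= 0) return(mask * 1)
  rows <- which(apply(mask, 1, any))
  cols <- which(apply(mask, 2, any))
  taper1d <- function(len, ramp) {
    r <- min(ramp, (len - 1) %/% 2)
    t <- rep(1, len)
    if (r > 0) {
      ramp_vals <- 0.5 * (1 - cos(pi * seq_len(r) / (r + 1)))
      t[seq_len(r)] <- ramp_vals
      t[len + 1 - seq_len(r)] <- ramp_vals
    }
    t
  }
  win <- matrix(0, nrow(mask), ncol(mask))
  win[rows, cols] <- outer(taper1d(length(rows), ramp),
                           taper1d(length(cols), ramp))
  win * mask
}

#' Conjugate-phase mosaic combination with inverse MTF filter
#'
#' Each shot's zero-filled segment is inverse-DFT'd, multiplied by the
#' complex conjugate of that shot's estimated phase map, transformed back
#' and re-windowed on its support (optionally apodized); the windowed
#' k-space segments are accumulated and the sum divided by the summed window
#' weights (inverse MTF filter, floored at `mtf_floor` of the peak weight
#' and zeroed where no shot sampled).
#'
#' @param segments Output of [coil_combine_segments()] (or a list with
#'   `kspace` `ky x kx x shot` and `mask`).
#' @param phase_maps An `epi_phases` or a phase array `ky x kx x shot`
#'   (radians).
#' @param config A [combine_config()].
#' @return Complex image matrix.
#' @export
combine_mosaic <- function(segments, phase_maps, config = combine_config()) {
  K3 <- segments$kspace
  dm <- dim(K3)
  n <- dm[1]; S <- dm[3]
  ph <- if (inherits(phase_maps, "epi_phases")) phase_maps$phase else phase_maps
  if (!all(dim(ph) == c(n, n, S)))
    stop("phase map dimensions do not match the segments", call. = FALSE)
  Ksum <- matrix(0 + 0i, n, n)
  Wt <- matrix(0, n, n)
  for (s in seq_len(S)) {
    win <- segment_window(segments$mask[, , s], config$apodization)
    img <- kspace_inverse(K3[, , s])
    corrected <- img * exp(-1i * ph[, , s])
    Ksum <- Ksum + kspace_forward(corrected) * win
    Wt <- Wt + win
  }
  denom <- pmax(Wt, config$mtf_floor * max(Wt))
  K <- Ksum / denom
  K[Wt == 0] <- 0 + 0i
  kspace_inverse(K)
}

#' SENSE-type forward model with phase-fluctuation encoding
#'
#' @param coils Coil maps (`epi_coils`).
#' @param phases Optional `epi_phases` (zero phases if `NULL`).
#' @param tol Relative residual tolerance of the conjugate-gradient solver.
#' @param max_iter Iteration cap.
#' @return List of class `forward_model`.
#' @export
forward_model <- function(coils, phases = NULL, tol = 1e-8, max_iter = 200L) {
  structure(list(coils = coils, phases = phases, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "forward_model")
}

#' Forward and adjoint encoding operators
#'
#' Builds the multi-shot, multi-coil encoding operator
#' `y[s, c] = Sample_s DFT Coil_c Phase_s m` and its exact adjoint for a
#' given acquisition geometry (the adjoint of the unnormalized centered DFT
#' is `N^2` times the centered inverse DFT).
#'
#' @param bundle An `epi_acquisition` (provides masks and dimensions).
#' @param model A [forward_model()].
#' @param shots Optional subset of shots to include (default all).
#' @return List with closures `forward(m)` (image to k-space array
#'   `ky x kx x coil x shot_subset`) and `adjoint(y)`.
#' @export
sense_operators <- function(bundle, model, shots = NULL) {
  dm <- dim(bundle$kspace)
  n <- dm[1]; C <- dm[3]
  if (is.null(shots)) shots <- seq_len(dm[4])
  masks <- bundle$mask[, , shots, drop = FALSE]
  cmaps <- model$coils$maps
  if (dim(cmaps)[3] != C)
    stop("coil count of model and acquisition disagree", call. = FALSE)
  S <- length(shots)
  P <- array(1 + 0i, dim = c(n, n, S))
  if (!is.null(model$phases)) {
    for (i in seq_len(S)) {
      s <- shots[i]
      P[, , i] <- model$phases$amplitude[, , s] *
        exp(1i * model$phases$phase[, , s])
    }
  }
  forward <- function(m) {
    y <- array(0 + 0i, dim = c(n, n, C, S))
    for (i in seq_len(S)) {
      ms <- P[, , i] * m
      msk <- masks[, , i]
      for (c in seq_len(C)) {
        K <- kspace_forward(cmaps[, , c] * ms)
        K[!msk] <- 0 + 0i
        y[, , c, i] <- K
      }
    }
    y
  }
  adjoint <- function(y) {
    m <- matrix(0 + 0i, n, n)
    for (i in seq_len(S)) {
      msk <- masks[, , i]
      acc <- matrix(0 + 0i, n, n)
      for (c in seq_len(C)) {
        K <- y[, , c, i]
        K[!msk] <- 0 + 0i
        acc <- acc + Conj(cmaps[, , c]) * (kspace_inverse(K) * n^2)
      }
      m <- m + Conj(P[, , i]) * acc
    }
    m
  }
  list(forward = forward, adjoint = adjoint, shots = shots)
}

#' Iterative multi-shot SENSE reconstruction with phase encoding
#'
#' Solves the normal equations of the multi-shot forward model by conjugate
#' gradients from a zero initial guess, stopping at relative residual
#' `model$tol` or `model$max_iter` iterations (the best iterate is returned
#' with a warning if unconverged).
#'
#' @param bundle An `epi_acquisition`.
#' @param model A [forward_model()].
#' @param shots Optional subset of shots to reconstruct from.
#' @return Complex image matrix with attributes `iterations` and
#'   `converged`.
#' @export
cg_sense <- function(bundle, model, shots = NULL) {
  ops <- sense_operators(bundle, model, shots = shots)
  dm <- dim(bundle$kspace)
  y <- bundle$kspace[, , , ops$shots, drop = FALSE]
  n <- dm[1]
  x <- matrix(0 + 0i, n, n)
  r <- ops$adjoint(y)
  p <- r
  rs <- Re(sum(Conj(r) * r))
  rs0 <- rs
  converged <- FALSE
  it <- 0L
  while (it < model$max_iter) {
    if (sqrt(rs / rs0) <= model$tol) { converged <- TRUE; break }
    it <- it + 1L
    Ap <- ops$adjoint(ops$forward(p))
    alpha <- rs / Re(sum(Conj(p) * Ap))
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- Re(sum(Conj(r) * r))
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  if (!converged && sqrt(rs / rs0) <= model$tol) converged <- TRUE
  if (!converged)
    warning("cg_sense reached the iteration cap before the residual ",
            "tolerance; returning the final iterate", call. = FALSE)
  attr(x, "iterations") <- it
  attr(x, "converged") <- converged
  x
}

#' Normalized root-mean-square error against a reference image
#'
#' `sqrt(sum |x - ref|^2 / sum |ref|^2)` after removing one global complex
#' scale (the magnitude-weighted projection of `x` onto `ref`), so that
#' reconstructions defined up to a constant phase compare fairly.
#'
#' @param x Complex (or numeric) image.
#' @param ref Reference image of the same size.
#' @param align Remove the global complex scale first (default `TRUE`).
#' @return Scalar NRMSE.
#' @export
nrmse <- function(x, ref, align = TRUE) {
  if (align) {
    sc <- sum(Conj(ref) * x) / sum(Mod(ref)^2)
    x <- x / sc
  }
  sqrt(sum(Mod(x - ref)^2) / sum(Mod(ref)^2))
}
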