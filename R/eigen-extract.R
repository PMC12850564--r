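# Eigenvalue (ESPIRiT-type) route: SVD of the symmetric calibration matrix,
# subspace truncation, per-pixel operators from the kept singular vectors,
# and a pixelwise eigen decomposition whose top eigenvector is the vector of
# shot-to-shot signal modulations at that pixel.
#
# Derivation used throughout.  A sliding-window row at position t decomposes
# exactly as row_t = sum_x c_x(t) b_x with per-pixel signal vectors
# b_x[(s,d)] = P_s(x) exp(-2i pi d.x / N) (P_s the shot modulation at pixel
# x).  With A = U S V^H, the rows live in the span of the CONJUGATED kept
# right singular vectors conj(v_k) (the kernel null-space relation A u = 0
# is bilinear, not Hermitian), so conj(b_x) lies in span{v_k}.  Defining per
# shot s the correlation transform
#   g_k^s(x) = sum_d v_k^s(d) exp(-2i pi d.x / N)
# (the centered *forward* DFT of the zero-filled patch, equivalently the
# inverse DFT of the conjugate-reversed patch) and M_x[k, s] = g_k^s(x) / w,
# the Hermitian form u^H (M_x^H M_x) u = (1/w^2) sum_k |<v_k, conj(b_x(u))>|^2
# is maximized over unit u exactly by the vector of shot modulations, with
# maximum 1 when conj(b_x) is contained in the kept subspace and never more
# than 1 (Bessel, since the v_k are orthonormal).  M_x^H M_x also equals the
# per-pixel block of F^-1 W F for W = M^-1 sum_t R_t^H P R_t built with the
# projection P onto the row space and M = w^2 I (all window positions,
# circular); the dense-operator oracle in the tests pins this equality.

#' SVD and subspace split of a symmetric calibration matrix
#'
#' Economy SVD of the calibration matrix with a kept/discarded split of the
#' right singular vectors: either the `keep_fraction` leading columns
#' (default half the subspace) or all columns with singular value at least
#' `sigma_cut * sigma_max`.
#'
#' @param calib A `calib_matrix` with `layout = "symmetric"` (or any
#'   `calib_matrix`).
#' @param keep_fraction Fraction of columns to keep (used when `sigma_cut`
#'   is `NULL`); kept count is `round(fraction * ncol)`, at least 1.
#' @param sigma_cut Optional relative singular-value threshold.
#' @return Object of class `subspace_basis`: list with `singular_values`
#'   (descending), `kept`, `V_par` (columns = kept right singular vectors),
#'   `window`, `n_shots_row`, `n_col`.
#' @export
calib_svd <- function(calib, keep_fraction = 0.5, sigma_cut = NULL) {
  if (!inherits(calib, "calib_matrix"))
    stop("calib_svd needs a calib_matrix", call. = FALSE)
  A <- calib$A
  if (length(A) == 0 || nrow(A) == 0)
    stop("empty calibration matrix", call. = FALSE)
  sv <- svd(A)
  kept <- if (is.null(sigma_cut)) round(keep_fraction * ncol(A))
          else sum(sv$d >= sigma_cut * sv$d[1])
  kept <- max(1L, min(as.integer(kept), ncol(A)))
  structure(
    list(singular_values = sv$d, kept = kept,
         V_par = sv$v[, seq_len(kept), drop = FALSE],
         window = calib$window, n_shots_row = calib$n_shots_row,
         n_col = ncol(A), shot_pair = calib$shot_pair),
    class = "subspace_basis"
  )
}

#' Per-pixel operators from the kept calibration subspace
#'
#' Reshapes each kept right singular vector shot-major into `w x w` k-space
#' patches (inverting the calibration column ordering), zero-fills each patch
#' at the center of the full grid and applies the centered *forward* DFT --
#' the conjugate-reversed (correlation) form required because the calibration
#' rows span the conjugates of the right singular vectors -- scaled by `1/w`
#' so that noiseless identical-shot data yields a top per-pixel eigenvalue of
#' exactly 1.  The stack entry `M[x][k, s]` is the (k, s) element of the
#' per-pixel matrix whose Gram matrix `M^H M` is the pixel block of the
#' image-space projection operator.
#'
#' @param basis A `subspace_basis`.
#' @param grid_size Output grid size.
#' @return Object of class `pixel_operator_stack`: list with `M` (complex
#'   array `grid x grid x kept x n_shots_row`), `window`, `kept`,
#'   `n_shots_row`, `grid_size`.
#' @export
build_pixel_operators <- function(basis, grid_size) {
  w <- basis$window
  S <- basis$n_shots_row
  if (nrow(basis$V_par) != S * w * w)
    stop("subspace column length inconsistent with shot count and window",
         call. = FALSE)
  n <- as.integer(grid_size)
  h <- (w - 1L) %/% 2L
  dc <- dc_index(n)
  kept <- basis$kept
  M <- array(0 + 0i, dim = c(n, n, kept, S))
  for (k in seq_len(kept)) {
    for (s in seq_len(S)) {
      u <- basis$V_par[((s - 1L) * w * w + 1L):(s * w * w), k]
      patch <- t(matrix(u, w, w))  # offset (dy, dx), dy was the outer index
      K <- matrix(0 + 0i, n, n)
      K[(dc - h):(dc + h), (dc - h):(dc + h)] <- patch
      gimg <- kspace_forward(K)         # sum_d v(d) exp(-2i pi d.x / N)
      M[, , k, s] <- gimg / w
    }
  }
  structure(
    list(M = M, window = w, kept = kept, n_shots_row = S, grid_size = n,
         shot_pair = basis$shot_pair),
    class = "pixel_operator_stack"
  )
}

#' Pixelwise eigen decomposition of the calibrated operator
#'
#' At every pixel, takes the top eigenvector of the Hermitian `S x S` matrix
#' `M^H M` from the operator stack, unit-normalized and phase-referenced so
#' the reference-shot component is real-nonnegative.  The top eigenvalue is
#' close to 1 wherever the truncated subspace explains the local data and
#' never exceeds 1 (up to numerical tolerance); degenerate (zero-signal)
#' pixels return eigenvalue 0 and the canonical reference basis vector.
#'
#' @param stack A `pixel_operator_stack`.
#' @param reference_shot Index (within the row group, 1-based) whose
#'   component fixes the per-pixel phase gauge.
#' @return Object of class `eigen_result`: list with `vectors` (complex
#'   array `grid x grid x S`, unit norm per pixel), `eigenvalue` (real
#'   matrix), `reference_shot`, `shot_pair`.
#' @export
eigen_phase_maps <- function(stack, reference_shot = 1L) {
  n <- stack$grid_size
  S <- stack$n_shots_row
  kept <- stack$kept
  vecs <- array(0 + 0i, dim = c(n, n, S))
  if (S == 2L) {
    a <- apply(Mod(stack$M[, , , 1, drop = FALSE])^2, c(1, 2), sum)
    d <- apply(Mod(stack$M[, , , 2, drop = FALSE])^2, c(1, 2), sum)
    b <- matrix(0 + 0i, n, n)
    for (k in seq_len(kept))
      b <- b + Conj(stack$M[, , k, 1]) * stack$M[, , k, 2]
    lam <- (a + d) / 2 + sqrt(((a - d) / 2)^2 + Mod(b)^2)
    v1 <- b; v2 <- lam - a
    deg <- (Mod(v1) + abs(v2)) < 1e-14
    v1[deg] <- ifelse(a[deg] >= d[deg], 1 + 0i, 0 + 0i)
    v2[deg] <- ifelse(a[deg] >= d[deg], 0, 1)
    nrm <- sqrt(Mod(v1)^2 + Mod(v2)^2)
    vecs[, , 1] <- v1 / nrm
    vecs[, , 2] <- v2 / nrm
    eigval <- lam
  } else {
    eigval <- matrix(0, n, n)
    for (iy in seq_len(n)) for (ix in seq_len(n)) {
      Mq <- matrix(stack$M[iy, ix, , ], kept, S)
      G <- crossprod(Conj(Mq), Mq)
      ev <- eigen(G, symmetric = TRUE)
      eigval[iy, ix] <- ev$values[1]
      vecs[iy, ix, ] <- ev$vectors[, 1]
    }
  }
  # degenerate pixels: zero operator -> eigenvalue 0, canonical basis vector
  zero <- eigval < 1e-14
  if (any(zero)) {
    eigval[zero] <- 0
    for (s in seq_len(S)) {
      plane <- vecs[, , s]
      plane[zero] <- if (s == reference_shot) 1 + 0i else 0 + 0i
      vecs[, , s] <- plane
    }
  }
  # gauge: reference-shot component real-nonnegative
  ref <- vecs[, , reference_shot]
  rot <- ifelse(Mod(ref) > 0, Conj(ref) / Mod(ref), 1 + 0i)
  for (s in seq_len(S)) vecs[, , s] <- vecs[, , s] * rot

  structure(
    list(vectors = vecs, eigenvalue = eigval,
         reference_shot = as.integer(reference_shot),
         shot_pair = stack$shot_pair),
    class = "eigen_result"
  )
}

#' Relative phase between the two shots of an eigen result
#'
#' @param x An `eigen_result`.
#' @param shot Component index within the row group (default 2).
#' @return Matrix of wrapped phases (radians) of the given component
#'   relative to the reference component.
#' @export
relative_phase <- function(x, shot = 2L) {
  Arg(x$vectors[, , shot] * Conj(x$vectors[, , x$reference_shot]))
}

#' Chain pairwise relative maps into per-shot phase maps
#'
#' Composes pairwise relative phases (from [eigen_phase_maps()] or
#' [kernel_to_relative_map()]) along the connected chain of shot pairs into
#' per-shot phase maps referenced to `reference_shot` (whose map is
#' identically zero).  All composition is carried out on unit phasors; no
#' unwrapping is performed.
#'
#' @param pairwise List of `eigen_result` or `relative_map` objects, each
#'   carrying the shot pair it relates.
#' @param n_shots Total number of shots.
#' @param reference_shot Index of the zero-phase reference shot.
#' @param grid_size Grid size (taken from the first element if missing).
#' @return An `epi_phases` object with the composed phase maps.
#' @export
align_shots <- function(pairwise, n_shots, reference_shot = 1L,
                        grid_size = NULL) {
  get_pair <- function(p) {
    pr <- if (inherits(p, "eigen_result")) p$shot_pair else p$pair
    if (is.null(pr) || any(is.na(pr))) stop("pair ids missing", call. = FALSE)
    pr
  }
  get_phasor <- function(p) {
    # unit phasor of (second shot of the pair) relative to (first)
    if (inherits(p, "eigen_result")) {
      z <- p$vectors[, , 2] * Conj(p$vectors[, , 1])
    } else {
      z <- p$values
    }
    m <- Mod(z)
    ifelse(m > 0, z / m, 1 + 0i)
  }
  if (is.null(grid_size)) {
    z0 <- get_phasor(pairwise[[1]])
    grid_size <- nrow(z0)
  }
  n <- as.integer(grid_size)
  S <- as.integer(n_shots)
  phasor <- vector("list", S)
  phasor[[reference_shot]] <- matrix(1 + 0i, n, n)
  done <- reference_shot
  pending <- pairwise
  repeat {
    progressed <- FALSE
    keep <- logical(length(pending))
    for (i in seq_along(pending)) {
      pr <- get_pair(pending[[i]])
      if (pr[1] %in% done && !(pr[2] %in% done)) {
        phasor[[pr[2]]] <- phasor[[pr[1]]] * get_phasor(pending[[i]])
        done <- c(done, pr[2]); progressed <- TRUE
      } else if (pr[2] %in% done && !(pr[1] %in% done)) {
        phasor[[pr[1]]] <- phasor[[pr[2]]] * Conj(get_phasor(pending[[i]]))
        done <- c(done, pr[1]); progressed <- TRUE
      } else {
        keep[i] <- !(pr[1] %in% done && pr[2] %in% done)
      }
    }
    pending <- pending[keep]
    if (length(done) == S) break
    if (!progressed)
      stop("shot pairs do not form a connected chain covering all shots",
           call. = FALSE)
  }
  phase <- array(0, dim = c(n, n, S))
  for (s in seq_len(S)) phase[, , s] <- Arg(phasor[[s]])
  structure(
    list(phase = phase, amplitude = array(1, dim = c(n, n, S)),
         n_shots = S, grid_size = n),
    class = "epi_phases"
  )
}

#' Fill low-confidence phase estimates from confident neighbors
#'
#' Pixels whose top eigenvalue falls below `threshold` are flagged
#' low-confidence and their phase replaced by propagating the complex phasor
#' of the nearest confident neighbors (iterative 4-neighbor averaging),
#' which avoids propagating unreliable estimates or NaNs into the
#' reconstruction.
#'
#' @param phase Matrix of wrapped phases (radians).
#' @param confidence Matrix of per-pixel eigenvalues (same size).
#' @param threshold Confidence cutoff (default 0.7).
#' @return Matrix of phases with low-confidence pixels filled in.
#' @export
fill_low_confidence <- function(phase, confidence, threshold = 0.7) {
  good <- confidence >= threshold
  if (all(good) || !any(good)) return(phase)
  z <- exp(1i * phase)
  z[!good] <- 0 + 0i
  filled <- good
  n <- nrow(phase)
  while (!all(filled)) {
    zn <- matrix(0 + 0i, n, ncol(phase))
    zn[-1, ] <- zn[-1, ] + z[-n, ]
    zn[-n, ] <- zn[-n, ] + z[-1, ]
    zn[, -1] <- zn[, -1] + z[, -ncol(phase)]
    zn[, -ncol(phase)] <- zn[, -ncol(phase)] + z[, -1]
    newly <- !filled & Mod(zn) > 0
    if (!any(newly)) break
    z[newly] <- zn[newly] / Mod(zn[newly])
    filled <- filled | newly
  }
  out <- phase
  out[!good] <- Arg(z[!good])
  out
}

#' Self-navigated phase extraction for phase-interleaved EPI
#'
#' Phase-interleaved shots share no raw k-space coordinates, so the
#' calibration region is built from intermediate per-shot parallel-imaging
#' reconstructions: each shot is reconstructed alone by [cg_sense()] with
#' zero phase, transformed back to k-space, and cropped to the central
#' calibration block.  The cropped blocks act as the shot-dependent ACS and
#' feed the eigenvalue route jointly over all shots.
#'
#' @param bundle An `epi_acquisition` with a `phase_interleaved` trajectory.
#' @param coils The coil maps used for the intermediate reconstructions.
#' @param central_block Side of the central calibration block in pixels
#'   (default: the block recorded in the trajectory).
#' @param keep_fraction Subspace fraction kept in the SVD split.
#' @param window_w Calibration window width (odd, default 7).
#' @param reference_shot Zero-phase reference shot.
#' @return An `epi_phases` object with per-shot phase maps; attributes
#'   `eigenvalue` (per-pixel top eigenvalue) and `singular_values`.
#' @export
muse_kernel_extract <- function(bundle, coils, central_block = NULL,
                                keep_fraction = 0.5, window_w = 7L,
                                reference_shot = 1L) {
  traj <- bundle$trajectory
  if (traj$scheme != "phase_interleaved")
    stop("muse_kernel_extract needs a phase_interleaved acquisition",
         call. = FALSE)
  n <- traj$grid_size
  S <- traj$n_shots
  if (is.null(central_block)) {
    blk <- traj$calib_block
  } else {
    side <- as.integer(central_block)
    if (side < window_w)
      stop("central_block must be at least the window width", call. = FALSE)
    dc <- dc_index(n)
    lo <- dc - (side - 1L) %/% 2L
    blk <- list(ky = c(lo, lo + side - 1L), kx = c(lo, lo + side - 1L))
  }
  per_shot_R <- traj$undersample_R * S
  if (per_shot_R > coils$n_coils)
    warning("per-shot undersampling factor ", per_shot_R,
            " exceeds the coil count; intermediate reconstructions and the ",
            "extracted phase maps may be unreliable", call. = FALSE)

  model <- forward_model(coils)
  blocks <- array(0 + 0i, dim = c(blk$ky[2] - blk$ky[1] + 1L,
                                  blk$kx[2] - blk$kx[1] + 1L, 1L, S))
  for (s in seq_len(S)) {
    img <- cg_sense(bundle, model, shots = s)
    K <- kspace_forward(img)
    blocks[, , 1L, s] <- K[blk$ky[1]:blk$ky[2], blk$kx[1]:blk$kx[2]]
  }

  A <- calib_rows(blocks, as.integer(window_w), reverse = FALSE)
  calib <- structure(
    list(A = A, target = NULL, window = as.integer(window_w),
         layout = "symmetric", region = blk, n_coils = 1L,
         n_shots_row = S, shot_pair = seq_len(S)),
    class = "calib_matrix"
  )
  basis <- calib_svd(calib, keep_fraction = keep_fraction)
  stack <- build_pixel_operators(basis, n)
  res <- eigen_phase_maps(stack, reference_shot = reference_shot)

  phase <- array(0, dim = c(n, n, S))
  for (s in seq_len(S))
    phase[, , s] <- Arg(res$vectors[, , s] * Conj(res$vectors[, , reference_shot]))
  out <- structure(
    list(phase = phase, amplitude = array(1, dim = c(n, n, S)),
         n_shots = S, grid_size = n),
    class = "epi_phases"
  )
  attr(out, "eigenvalue") <- res$eigenvalue
  attr(out, "singular_values") <- basis$singular_values
  out
}
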