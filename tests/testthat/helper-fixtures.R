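# Shared fixtures, built once per test run.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

fix_phantom <- function() fixture("phantom64", function() make_phantom(64))
fix_coils <- function() fixture("coils64", function() make_coil_maps(4, 64, 7))

# the reference two-shot mosaic study: 64^2, 4 coils, overlap 15 rows,
# polynomial order 2, amplitude 1.5 rad, noiseless
fix_mosaic_acq <- function() fixture("mosaic_acq", function() {
  simulate_acquisition(fix_phantom(), fix_coils(),
                       make_shot_phase_maps(2, 64, 2, 1.5, 0.2, 11),
                       make_trajectory("mosaic2", 64, 2, 15), 0)
})

# a trajectory-shaped object with full sampling for every shot
full_trajectory <- function(grid_size, n_shots) {
  structure(
    list(scheme = "mosaic2", grid_size = as.integer(grid_size),
         n_shots = as.integer(n_shots), overlap_px = as.integer(grid_size),
         undersample_R = 1L,
         masks = array(TRUE, dim = c(grid_size, grid_size, n_shots)),
         calib_block = NULL),
    class = "epi_trajectory"
  )
}

# unit coil set (single coil identically 1)
unit_coils <- function(grid_size) {
  structure(list(maps = array(1 + 0i, dim = c(grid_size, grid_size, 1L)),
                 n_coils = 1L, grid_size = as.integer(grid_size)),
            class = "epi_coils")
}

# phase set from an explicit array
phases_from_array <- function(phase) {
  dm <- dim(phase)
  structure(list(phase = phase, amplitude = array(1, dim = dm),
                 n_shots = dm[3], grid_size = dm[1]),
            class = "epi_phases")
}

# weighted phase RMSE of a single relative map against truth
rel_rmse <- function(est, truth, weight) {
  n <- nrow(est)
  phase_rmse(array(est, c(n, n, 1)), array(truth, c(n, n, 1)), weight)
}

# Dense-operator oracle: explicitly assemble the subspace projection operator
# over all (circular) window positions, conjugate it into image space with
# per-shot centered DFT matrices, and return the per-pixel shot blocks.
dense_pixel_blocks <- function(basis, n) {
  w <- basis$window; h <- (w - 1L) %/% 2L
  S <- basis$n_shots_row
  V <- basis$V_par
  N2 <- n * n
  # projection onto the row space (rows span the conjugated singular vectors)
  P <- Conj(V) %*% t(V)
  offs <- expand.grid(dx = -h:h, dy = -h:h)
  offs <- offs[order(offs$dy, offs$dx), ]
  W <- matrix(0 + 0i, S * N2, S * N2)
  for (ty in seq_len(n)) for (tx in seq_len(n)) {
    idx <- integer(S * w * w)
    pos <- 1L
    for (s in seq_len(S)) for (l in seq_len(w * w)) {
      iy <- ((ty - 1L + offs$dy[l]) %% n) + 1L
      ix <- ((tx - 1L + offs$dx[l]) %% n) + 1L
      idx[pos] <- (s - 1L) * N2 + (ix - 1L) * n + iy
      pos <- pos + 1L
    }
    W[idx, idx] <- W[idx, idx] + P
  }
  W <- W / (w * w)
  x <- shotphase:::centered_coords(n)
  F1 <- exp(-2i * pi * outer(x, x) / n)
  F2 <- kronecker(F1, F1)
  Fb <- kronecker(diag(S), F2)
  Fbi <- kronecker(diag(S), Conj(F2) / N2)
  T_img <- Fbi %*% W %*% Fb
  blocks <- array(0 + 0i, dim = c(N2, S, S))
  for (q in seq_len(N2))
    blocks[q, , ] <- T_img[q + (seq_len(S) - 1L) * N2,
                           q + (seq_len(S) - 1L) * N2]
  blocks
}
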