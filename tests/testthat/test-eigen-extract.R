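test_that("subspace split keeps the requested dimension and normalizes profiles", {
  acq <- fix_mosaic_acq()
  cal <- build_calibration_matrix(acq, find_overlap(acq$trajectory, 1, 2),
                                  7, "symmetric")
  bas <- calib_svd(cal, 0.5)
  expect_equal(bas$kept, 49)
  expect_equal(ncol(bas$V_par), 49)
  expect_true(all(diff(bas$singular_values) <= 1e-12))
  # kept columns are orthonormal
  G <- Conj(t(bas$V_par)) %*% bas$V_par
  expect_lt(max(Mod(G - diag(49))), 1e-10)

  bas2 <- calib_svd(cal, sigma_cut = 0.5)
  expect_true(bas2$kept >= 1 &&
                all(bas$singular_values[seq_len(bas2$kept)] >=
                      0.5 * bas$singular_values[1]))
})

test_that("a single center-delta kernel gives a constant one-shot operator", {
  w <- 7
  V <- matrix(0 + 0i, 2 * w * w, 1)
  V[(w * w - 1) / 2 + 1, 1] <- 1  # center of shot-1 patch
  bas <- structure(list(singular_values = 1, kept = 1L, V_par = V,
                        window = w, n_shots_row = 2L, n_col = 2 * w * w,
                        shot_pair = c(1, 2)),
                   class = "subspace_basis")
  stk <- build_pixel_operators(bas, 32)
  expect_lt(max(abs(Mod(stk$M[, , 1, 1]) - 1 / w)), 1e-12)
  expect_lt(max(Mod(stk$M[, , 1, 2])), 1e-14)
})

test_that("pixel operators match the dense projection operator oracle", {
  n <- 16; w <- 3
  ph <- make_phantom(n)
  pp <- make_shot_phase_maps(2, n, 2, 1.0, 0, 5)
  acq <- simulate_acquisition(ph, make_coil_maps(2, n, 3), pp,
                              make_trajectory("mosaic2", n, 2, 9), 0)
  cal <- build_calibration_matrix(acq, find_overlap(acq$trajectory, 1, 2, w),
                                  w, "symmetric")
  bas <- calib_svd(cal, 0.5)
  blocks <- dense_pixel_blocks(bas, n)
  stk <- build_pixel_operators(bas, n)
  worst <- 0
  for (q in seq_len(n * n)) {
    iy <- ((q - 1) %% n) + 1; ix <- ((q - 1) %/% n) + 1
    Mq <- matrix(stk$M[iy, ix, , ], bas$kept, 2)
    worst <- max(worst, max(Mod(blocks[q, , ] - crossprod(Conj(Mq), Mq))))
  }
  expect_lt(worst, 1e-10)
})

test_that("identical shots give unit eigenvalues and the symmetric eigenvector", {
  ph <- fix_phantom()
  zero <- make_shot_phase_maps(2, 64, 0, 0, 0, 1)
  acq <- simulate_acquisition(ph, fix_coils(), zero,
                              make_trajectory("mosaic2", 64, 2, 15), 0)
  cal <- build_calibration_matrix(acq, find_overlap(acq$trajectory, 1, 2),
                                  7, "symmetric")
  res <- eigen_phase_maps(build_pixel_operators(calib_svd(cal, 0.5), 64))
  supp <- Mod(ph$values) > 0.1 * max(Mod(ph$values))
  expect_lt(max(abs(res$eigenvalue[supp] - 1)), 0.02)
  # per-pixel vector proportional to (1,1)/sqrt(2)
  ip <- Mod(res$vectors[, , 1] + res$vectors[, , 2]) / sqrt(2)
  expect_true(all(ip[supp] > 0.999))
  expect_lt(max(abs(relative_phase(res)[supp])), 1e-3)
})

test_that("the eigen route recovers smooth phase maps and agrees with the kernel route", {
  acq <- fix_mosaic_acq()
  truth <- acq$truth$phases$phase[, , 2]
  wmag <- Mod(acq$truth$phantom$values)
  ov <- find_overlap(acq$trajectory, 1, 2)
  cal <- build_calibration_matrix(acq, ov, 7, "symmetric")
  res <- eigen_phase_maps(build_pixel_operators(calib_svd(cal, 0.5), 64))
  eig_phase <- relative_phase(res)
  expect_lt(rel_rmse(eig_phase, truth, wmag), 0.05)
  expect_true(all(res$eigenvalue <= 1 + 1e-6))

  ker <- solve_interp_kernel(build_calibration_matrix(acq, ov, 7, "oneway"))
  gra_phase <- Arg(kernel_to_relative_map(ker, 64)$values)
  expect_lt(rel_rmse(gra_phase, eig_phase, wmag), 0.05)
})

test_that("a global phase on one shot shifts its recovered phase uniformly", {
  acq <- fix_mosaic_acq()
  theta <- 0.8
  acq2 <- acq
  acq2$kspace[, , , 2] <- acq2$kspace[, , , 2] * exp(1i * theta)
  ov <- find_overlap(acq$trajectory, 1, 2)
  get_phase <- function(a) {
    cal <- build_calibration_matrix(a, ov, 7, "symmetric")
    relative_phase(eigen_phase_maps(build_pixel_operators(calib_svd(cal, 0.5), 64)))
  }
  d <- Arg(exp(1i * (get_phase(acq2) - get_phase(acq) - theta)))
  supp <- acq$truth$phantom$support
  expect_lt(max(abs(d[supp])), 1e-6)
})

test_that("pairwise maps chain into per-shot maps referenced to shot one", {
  n <- 16
  f1 <- matrix(0.4, n, n); f2 <- matrix(-0.9, n, n)
  mk <- function(phi, pair) structure(list(values = exp(1i * phi), pair = pair,
                                           method = "grappa"),
                                      class = "relative_map")
  al <- align_shots(list(mk(f1, c(1, 2)), mk(f2, c(2, 3))), 3)
  expect_true(all(al$phase[, , 1] == 0))
  expect_equal(al$phase[, , 2], f1, tolerance = 1e-12)
  expect_equal(al$phase[, , 3], f1 + f2, tolerance = 1e-12)

  single <- align_shots(list(mk(f1, c(1, 2))), 2)
  expect_equal(single$phase[, , 2], f1, tolerance = 1e-12)

  expect_error(align_shots(list(mk(f1, c(1, 2)), mk(f2, c(3, 4))), 4),
               "connected")
})

test_that("chained eigen extraction recovers a three-shot acquisition", {
  ph <- fix_phantom()
  pp3 <- make_shot_phase_maps(3, 64, 2, 1.5, 0.2, 8)
  acq3 <- simulate_acquisition(ph, fix_coils(), pp3,
                               make_trajectory("readout_segmented", 64, 3, 15), 0)
  prs <- lapply(1:2, function(i) {
    cal <- build_calibration_matrix(
      acq3, find_overlap(acq3$trajectory, i, i + 1), 7, "symmetric")
    eigen_phase_maps(build_pixel_operators(calib_svd(cal, 0.5), 64))
  })
  al <- align_shots(prs, 3)
  err <- phase_rmse(al, pp3, Mod(ph$values))
  expect_true(all(err < 0.07))
})

test_that("interleaved extraction works through intermediate reconstructions", {
  ph <- fix_phantom()
  co <- fix_coils()
  pp <- make_shot_phase_maps(2, 64, 2, 1.0, 0.2, 6)
  acq <- simulate_acquisition(ph, co,  pp,
                              make_trajectory("phase_interleaved", 64, 2, 15, 1), 0)
  mu <- muse_kernel_extract(acq, co)
  expect_lt(phase_rmse(mu, pp, Mod(ph$values))[2], 0.05)

  zero <- make_shot_phase_maps(2, 64, 0, 0, 0, 1)
  acq0 <- simulate_acquisition(ph, co, zero,
                               make_trajectory("phase_interleaved", 64, 2, 15, 1), 0)
  mu0 <- muse_kernel_extract(acq0, co)
  supp <- ph$support
  expect_lt(max(abs(mu0$phase[, , 2][supp])), 1e-3)

  # beyond the parallel-imaging limit the extraction warns
  pp4 <- make_shot_phase_maps(4, 64, 2, 1.0, 0.2, 6)
  acq4 <- simulate_acquisition(ph, co, pp4,
                               make_trajectory("phase_interleaved", 64, 4, 15, 2), 0)
  expect_warning(muse_kernel_extract(acq4, co), "undersampling")
})

test_that("low-confidence pixels are filled from confident neighbors", {
  phase <- matrix(0.5, 8, 8)
  phase[4:5, 4:5] <- 3  # junk inside a low-confidence hole
  conf <- matrix(1, 8, 8)
  conf[4:5, 4:5] <- 0.1
  filled <- fill_low_confidence(phase, conf, threshold = 0.7)
  expect_equal(filled[4, 4], 0.5, tolerance = 1e-12)
  expect_equal(filled[1, 1], 0.5)
})
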