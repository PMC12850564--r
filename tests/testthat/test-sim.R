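test_that("phantoms are deterministic, bounded and supported consistently", {
  ph <- make_phantom(64, "ellipses")
  expect_gt(mean(ph$support), 0.2)
  expect_lt(mean(ph$support), 0.8)
  expect_true(all(Mod(ph$values) <= 1))
  expect_identical(ph$values, make_phantom(64, "ellipses")$values)

  blocks <- make_phantom(16, "blocks")
  expect_identical(blocks$support, Mod(blocks$values) > 0)
  expect_true(all(Mod(blocks$values)[!blocks$support] == 0))

  expect_error(make_phantom(8), "grid_size")
})

test_that("coil maps are seeded, smooth and RSS-normalized", {
  one <- make_coil_maps(1, 64, 3)
  expect_true(all(abs(Mod(one$maps[, , 1]) - 1) < 1e-6))

  co <- make_coil_maps(4, 64, 7)
  expect_identical(co$maps, make_coil_maps(4, 64, 7)$maps)
  rss <- sqrt(apply(abs(co$maps)^2, c(1, 2), sum))
  expect_true(all(rss >= 0.9 & rss <= 1.1))
  expect_error(make_coil_maps(0, 64), "n_coils")
})

test_that("phase maps honor the reference shot, scaling and smooth structure", {
  zero <- make_shot_phase_maps(2, 64, 0, 0.0, 0, 5)
  expect_true(all(zero$phase == 0))

  affine <- make_shot_phase_maps(2, 64, 1, 1.0, 0, 5)
  expect_true(all(affine$phase[, , 1] == 0))
  expect_equal(max(abs(affine$phase)), 1.0, tolerance = 1e-9)
  # shot-1 map is an affine plane: second differences vanish
  p <- affine$phase[, , 2]
  expect_lt(max(abs(diff(diff(p)))), 1e-9)
  expect_lt(max(abs(t(diff(diff(t(p)))))), 1e-9)

  mixed <- make_shot_phase_maps(4, 64, 2, 2.0, 0.3, 11)
  expect_equal(max(abs(mixed$phase)), 2.0, tolerance = 1e-9)
  expect_identical(mixed$phase, make_shot_phase_maps(4, 64, 2, 2.0, 0.3, 11)$phase)

  expect_error(make_shot_phase_maps(2, 64, 2, -1), "amplitude_rad")
})

test_that("trajectories produce the advertised overlap geometry and coverage", {
  rs <- make_trajectory("readout_segmented", 64, 3, 15)
  for (i in 1:2) {
    inter <- rs$masks[, , i] & rs$masks[, , i + 1]
    cols <- which(apply(inter, 2, any))
    expect_length(cols, 15)
    expect_true(all(inter[, cols]))
  }
  expect_true(all(rs$masks[, , 1] | rs$masks[, , 2] | rs$masks[, , 3]))

  mo <- make_trajectory("mosaic2", 64, 2, 13)
  inter <- mo$masks[, , 1] & mo$masks[, , 2]
  rows <- which(apply(inter, 1, any))
  expect_length(rows, 13)
  expect_true(all(inter[rows, ]))
  expect_true((64 %/% 2 + 1) %in% rows)  # DC row inside the band

  m4 <- make_trajectory("mosaic4", 64, 4, 13)
  expect_true(all(m4$masks[, , 1] | m4$masks[, , 2] | m4$masks[, , 3] | m4$masks[, , 4]))
  for (i in 1:3) {
    inter <- m4$masks[, , i] & m4$masks[, , i + 1]
    expect_gte(min(dim(largest <- which(inter, arr.ind = TRUE))), 1)
    short_axis <- min(diff(range(largest[, 1])), diff(range(largest[, 2]))) + 1
    expect_gte(short_axis, 13)
  }

  pi4 <- make_trajectory("phase_interleaved", 64, 4, 15, 1)
  # raw interleaves are disjoint and tile every R-th row
  expect_true(all(apply(pi4$masks, c(1, 2), sum) <= 1))
  expect_true(all(apply(pi4$masks, 1, any)))
  expect_false(is.null(pi4$calib_block))

  expect_error(make_trajectory("mosaic2", 64, 3, 13), "n_shots")
  expect_error(make_trajectory("mosaic2", 64, 2, 5), "overlap_px")
})

test_that("simulation matches the centered-DFT model exactly", {
  ph <- fix_phantom()
  n <- 64
  zero2 <- make_shot_phase_maps(2, n, 0, 0, 0, 1)
  acq <- simulate_acquisition(ph, unit_coils(n), zero2, full_trajectory(n, 2))
  K <- acq$kspace[, , 1, 1]
  expect_lt(max(Mod(K - kspace_forward(ph$values))), 1e-10)
  parseval <- sum(Mod(K)^2) / n^2 / sum(Mod(ph$values)^2)
  expect_equal(parseval, 1, tolerance = 1e-10)

  # identical modulation: shots agree exactly on shared coordinates
  tr <- make_trajectory("mosaic2", n, 2, 13)
  acq2 <- simulate_acquisition(ph, fix_coils(), zero2, tr, 0)
  shared <- tr$masks[, , 1] & tr$masks[, , 2]
  for (c in 1:4)
    expect_identical(acq2$kspace[, , c, 1][shared], acq2$kspace[, , c, 2][shared])
})

test_that("a linear shot phase translates k-space per the shift theorem", {
  ph <- fix_phantom()
  n <- 64
  k0 <- 3
  xc <- matrix(shotphase:::centered_coords(n), n, n, byrow = TRUE)
  phase <- array(0, dim = c(n, n, 2))
  phase[, , 2] <- 2 * pi * k0 * xc / n
  acq <- simulate_acquisition(ph, unit_coils(n), phases_from_array(phase),
                              full_trajectory(n, 2))
  K0 <- acq$kspace[, , 1, 1]
  K1 <- acq$kspace[, , 1, 2]
  interior <- (k0 + 1):(n - k0)
  expect_lt(max(Mod(K1[, interior + k0] - K0[, interior])), 1e-8)
})

test_that("noise is seeded, confined to sampled coordinates, and eddy shifts act", {
  ph <- fix_phantom()
  tr <- make_trajectory("mosaic2", 64, 2, 13)
  pp <- make_shot_phase_maps(2, 64, 2, 1.0, 0, 2)
  a1 <- simulate_acquisition(ph, fix_coils(), pp, tr, 0.05, seed = 42)
  a2 <- simulate_acquisition(ph, fix_coils(), pp, tr, 0.05, seed = 42)
  a3 <- simulate_acquisition(ph, fix_coils(), pp, tr, 0.05, seed = 43)
  expect_identical(a1$kspace, a2$kspace)
  expect_false(identical(a1$kspace, a3$kspace))
  expect_true(all(a1$kspace[, , 1, 1][!tr$masks[, , 1]] == 0))

  # an integer eddy shift translates the sampled k-space phase ramp linearly
  ae <- simulate_acquisition(ph, unit_coils(64), pp, full_trajectory(64, 2),
                             0, eddy_shift_px = rbind(c(0, 0), c(1.5, -0.5)))
  a0 <- simulate_acquisition(ph, unit_coils(64), pp, full_trajectory(64, 2), 0)
  cc <- shotphase:::centered_coords(64)
  ramp <- exp(-2i * pi * (matrix(cc, 64, 64, byrow = TRUE) * 1.5 +
                          matrix(cc, 64, 64) * (-0.5)) / 64)
  expect_lt(max(Mod(ae$kspace[, , 1, 2] - a0$kspace[, , 1, 2] * ramp)), 1e-8)
  expect_identical(ae$kspace[, , 1, 1], a0$kspace[, , 1, 1])
})
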