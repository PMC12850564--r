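# shotphase

Self-navigated shot-to-shot phase calibration for multi-shot EPI, from small
k-space overlap bands at arbitrary k-space locations.

## What problem this solves

Multi-shot EPI acquires k-space over several excitations. In
diffusion-weighted imaging, motion during the diffusion encoding gives every
shot its own smooth image-space phase map; combining the shots without
correcting these maps produces ghosting. The classical fixes — navigator
echoes, or oversampling the k-space center in every shot — cost scan time or
constrain the trajectory.

`shotphase` implements the overlap-band alternative. If consecutive shots
share a small band of k-space (a dozen lines, anywhere in k-space), that band
is a shot-dependent auto-calibration region. Writing shot *i*'s data as
`f_i = S_i F P_i m` (object `m`, DFT `F`, shot phase modulation `P_i`,
sampling `S_i`), the image-space ratio `P_j P_i^{-1}` is a *convolution with
a small kernel* in k-space, shift-invariant across k-space positions and
receive coils. The band therefore supports the same two calibrations used
for coil sensitivities in parallel imaging, with shots in place of coils:

* **direct kernel solve (GRAPPA-type)** — a sliding window over the band
  builds a calibration matrix `A`; solving `A u = f_j` gives the
  interpolation kernel `u`, whose zero-filled inverse DFT is the relative
  map;
* **eigenvalue approach (ESPIRiT-type)** — the SVD of the symmetric
  calibration matrix is truncated to a signal subspace; per-pixel operators
  `G_q` built from the kept singular vectors have the vector of shot
  modulations as their top eigenvector, with eigenvalue 1 where the model
  explains the data (and never above 1).

The package also provides the two shot-combination reconstructions
(conjugate-phase mosaic combination with an inverse-MTF filter, and a
CG-SENSE forward model with phase encoding), a fully controlled multi-shot
acquisition simulator with known ground truth (four segmentation schemes:
two- and four-shot mosaic, readout-segmented, phase-interleaved), and
diagnostics (CV maps, singular-value profiles, weighted phase-error
metrics). Everything runs on synthetic data; no downloads are needed.

## Worked example

```r
library(shotphase)

n <- 64
phantom <- make_phantom(n)
coils   <- make_coil_maps(4, n, seed = 7)
phases  <- make_shot_phase_maps(2, n, poly_order = 2, amplitude_rad = 1.5,
                                random_fraction = 0.2, seed = 11)
traj    <- make_trajectory("mosaic2", n, 2, overlap_px = 15)
acq     <- simulate_acquisition(phantom, coils, phases, traj)

region <- find_overlap(traj, 1, 2)
calib  <- build_calibration_matrix(acq, region, window_w = 7, "symmetric")
res    <- eigen_phase_maps(build_pixel_operators(calib_svd(calib, 0.5), n))

est <- array(0, c(n, n, 2)); est[, , 2] <- relative_phase(res)
seg <- coil_combine_segments(acq, coils)
rec  <- combine_mosaic(seg, est)                      # corrected
rec0 <- combine_mosaic(seg, array(0, c(n, n, 2)))     # uncorrected
```

The same pipeline is wired into the command line demo,
`Rscript inst/cli/shotphase.R demo`, which prints:

```
median top eigenvalue on support : 0.9999
max top eigenvalue               : 0.999996
phase RMSE vs truth [rad]        : 0.0106
NRMSE corrected / uncorrected    : 0.0087 / 0.0672
```

Reading: the per-pixel top eigenvalue of the calibrated operator is 1 on the
object (the subspace model explains the overlap data) and bounded by 1
everywhere; the extracted relative phase map matches the simulator's ground
truth to ~0.01 rad; and feeding the estimated map into the mosaic
combination removes almost all of the shot-inconsistency error (NRMSE drops
about 8-fold versus ignoring the phase maps).

Other entry points: `solve_interp_kernel()`/`kernel_to_relative_map()` for
the direct kernel route, `align_shots()` to chain pairwise maps across more
than two shots, `muse_kernel_extract()` for phase-interleaved trajectories,
`cg_sense()` for the forward-model reconstruction, and `cv_map()`,
`sv_profile()`, `phase_rmse()` for diagnostics. The
`vignettes/overlap-kernel-phase-calibration.Rmd` vignette documents the
model, conventions and limitations.

## Command line

```sh
Rscript inst/cli/shotphase.R simulate --scheme readout_segmented --shots 3 \
    --grid 64 --coils 4 --overlap 15 --phase-amp 1.5 --seed 1 --out acq.rds
Rscript inst/cli/shotphase.R extract --method espirit --kernel-size 7 \
    --keep 0.5 --pair 1,2 acq.rds --out maps.rds
Rscript inst/cli/shotphase.R recon --mode mosaic --maps maps.rds acq.rds --out img
Rscript inst/cli/shotphase.R diagnose acq.rds
```

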