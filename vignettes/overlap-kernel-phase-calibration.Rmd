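---
title: "Shot-to-shot phase calibration from k-space overlap bands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shot-to-shot phase calibration from k-space overlap bands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shotphase)
```

## The problem

Multi-shot EPI splits k-space over several excitations to gain resolution or
reduce distortion.  In diffusion-weighted scans, microscopic motion during
the diffusion encoding imprints a smooth, nonlinear image-space phase that
differs from shot to shot.  Writing the object seen by the receive chain as
$m$ and the phase modulation of shot $i$ as the diagonal operator $P_i$, the
acquired samples of shot $i$ are

$$ f_i = S_i \, F \, P_i \, m, $$

with $F$ the 2D DFT and $S_i$ the shot's sampling mask.  If the shots are
combined while the $P_i$ are ignored, the inconsistencies alias into
ghosting.  Navigator acquisitions measure $P_i$ at the cost of scan time and
only at the k-space center; this package implements the self-navigated
alternative: design the trajectory so that consecutive shots share a *small
overlap band*, anywhere in k-space, and extract the relative maps
$P_j P_i^{-1}$ directly from that band.

The key observation is the Fourier dual of the modulation: multiplying the
image by the smooth ratio $\mu_{ij}(x) = e^{i(\phi_j(x) - \phi_i(x))}$ is
convolving k-space with a small kernel $u_{ij}$.  The overlap band therefore
plays exactly the role that the auto-calibration (ACS) region plays in
parallel imaging, with shots in place of coils: the kernel is shift-invariant
across k-space positions and receive channels, so every sliding window over
the band is one more equation constraining it.

## Calibration matrix

A $w\times w$ window ($w = 7$ by default; the kernel support of smooth
in-vivo-like phase maps spans a few pixels) slides with stride 1 over the
overlap region; each neighborhood is reshaped into a row.  Two layouts are
built (`build_calibration_matrix()`):

* **one-way**: rows hold the source shot's neighborhood in convolution
  order, and a target vector holds the other shot's sample at each window
  center.  $A u = f_j$ is an ordinary least-squares problem for the kernel.
* **symmetric**: rows hold both shots' neighborhoods side by side
  (shot-major).  Its row space encodes every interpolation relation at once
  and feeds the eigenvalue route.

Coils only ever add rows, never columns: the modulation kernel does not
depend on the receive channel.  With an $H \times W$ region and $C$ coils
the matrix has $C\,(H-w+1)(W-w+1)$ rows — the closed form the tests pin.

## Direct (GRAPPA-type) route

`solve_interp_kernel()` solves $A u = f_j$ by truncated SVD (default),
Tikhonov-damped pseudo-inverse, or conjugate gradients on the normal
equations.  `kernel_to_relative_map()` zero-fills the kernel at the center
of the full grid and applies the centered inverse DFT, scaled so that a pure
center delta maps to the all-ones image; the result approximates
$\mu_{ij}$ on the object support.  Only the phase of the map is used
downstream; the magnitude is retained for inspection but discarded by the
reconstructions, matching how amplitude fluctuations are normally treated.

## Eigenvalue (ESPIRiT-type) route

The symmetric matrix is decomposed as $A = U\Sigma V^H$ and split into a
kept signal subspace $V_\parallel$ (default: half the columns) and a
discarded one.  Each kept vector is reshaped shot-major into $w\times w$
patches, zero-filled, and transformed to image space; at every pixel $q$
this yields a small matrix $M_q$ (kept $\times$ shots) whose Gram matrix
$G_q = M_q^H M_q$ is the pixel block of the image-space operator
$F^{-1} W F$, where $W$ averages the subspace projection over all window
positions.  The per-pixel top eigenvector of $G_q$ is the vector of
relative shot modulations; its eigenvalue is 1 where the subspace explains
the data and lies in $[0, 1]$ everywhere — the average-of-projections bound
that the acceptance checks measure.

One convention deserves a warning, because exactly one choice is correct
and the wrong one fails in a deceptively structured way.  The null-space
relation $A u = 0$ is bilinear, so the calibration **rows span the
conjugates of the right singular vectors**.  The per-pixel operators must
therefore be built from the centered *forward* DFT of the kept patches
(the conjugate-reversed, correlation form).  With the other sign the
machinery still satisfies every self-consistency test — eigenvalues are
still 1 on support, and a dense operator assembled with the same wrong
convention still matches — but the recovered map is the complex conjugate
of the true map evaluated at the point-reflected position,
$\overline{\mu(-x)}$.  The package pins the correct choice twice: a dense
assembly of the projection operator over all circular window positions,
conjugated into image space with explicit DFT matrices, must match the
per-pixel operators to $10^{-10}$; and recovered maps must match the
simulator's ground truth, which the flipped convention cannot.

Per-pixel eigenvectors are defined up to a phase; the gauge is fixed by
making the reference-shot component real-nonnegative, and pixels with zero
operator return eigenvalue 0 with the canonical reference vector.  Pixels
whose eigenvalue falls below 0.7 are flagged low-confidence and can be
filled from their nearest confident neighbors (`fill_low_confidence()`)
before reconstruction — estimation there is unreliable (usually outside the
object) and unfilled junk would propagate through the conjugate-phase
combination.

For phase-interleaved trajectories the shots share no raw coordinates, so
`muse_kernel_extract()` first reconstructs each shot alone with the
SENSE-type solver (zero phase), returns to k-space, and crops a central
calibration block that then acts as the shot-dependent ACS for the joint
eigen decomposition over all shots.  When the per-shot undersampling factor
exceeds the coil count the intermediate reconstructions are themselves
underdetermined; the function warns and degraded maps must be expected —
this is a documented failure mode of the approach, not of the
implementation.

## Shot combination

Two reconstructions close the loop:

* `combine_mosaic()`: each segment is inverse-transformed, multiplied by
  the conjugate of its shot's phase map, re-windowed on its support
  (optionally cosine-tapered to reduce ringing), accumulated in k-space and
  divided by the summed window weights — the inverse modulation-transfer
  filter.  The division floor (`mtf_floor`, default 0.05 of the peak
  weight) caps noise amplification where tapers fall toward zero; with a
  negligible floor the taper is removed exactly, which the tests verify to
  machine precision.  The conjugate multiply is performed in image space on
  the zero-filled segment — equivalent to, and cheaper than, k-space
  convolution with the conjugate kernel.
* `cg_sense()`: conjugate gradients on the normal equations of the full
  forward model $y_{s,c} = S_s F C_c P_s m$, with the phase maps included
  as encoding.  The adjoint is exact (inner-product test to $10^{-10}$);
  the solver starts from zero, stops at relative residual $10^{-8}$ or 200
  iterations, and returns the final iterate with a warning if unconverged.

Phase maps are never unwrapped anywhere in the package: all composition and
comparison arithmetic uses complex phasors, so wrapping is harmless.

## The simulator and what it does (not) emulate

All tests run on a fully controlled synthetic acquisition
(`simulate_acquisition()`): an analytic piecewise-smooth complex phantom,
smooth randomized coil maps normalized to unit root-sum-of-squares, per-shot
phase maps (random polynomial plus band-limited random field, reference
shot zero, peak amplitude exactly the requested radians), four segmentation
schemes with configurable overlap, optional per-shot fractional k-space
shifts as an eddy-current surrogate, and i.i.d. complex Gaussian noise
(pre-whitened-coil assumption).  The default study conditions used by the
acceptance script are a $64^2$ grid, 4 coils, two-shot mosaic with a 15-row
band about DC (mirroring the central-band mosaic protocols this method
targets), polynomial order 2 with 1.5 rad amplitude and a 20% random-field
component; SNR 20 is defined in image space as mean support magnitude over
per-pixel complex noise deviation.  The dense-operator oracle runs on a
$16^2$ grid with $w = 3$, where the explicit $F^{-1} W F$ assembly is a
512-square matrix; these sizes keep the whole suite in the tens of seconds
while leaving every contract sharp.

Deliberately not modeled: T2/T2* decay along the echo train, B0
off-resonance distortion, partial-Fourier sampling, intra-shot (continuous)
eddy currents, readout oversampling, and gradient-polarity effects beyond
their net absence in an ideal simulator.  Passing tests therefore
demonstrate the correctness of the calibration and reconstruction
machinery under the stated signal model, not robustness to those scanner
effects; on real data the method additionally relies on the preprocessing
(regridding, ghost correction, per-segment parallel-imaging
reconstruction) that sits outside this package's scope.

## Numerical conventions and edge cases

* Centered DFT everywhere, DC at 0-based index $\lfloor N/2\rfloor$; the
  forward transform is unnormalized, the inverse carries $1/N^2$.
* Overlap search returns the maximal axis-aligned rectangle of the
  intersection; ties break toward the rectangle nearest DC.
* The sliding-window stride is 1 (maximal averaging).
* `calib_svd()` enforces at least one kept vector; degenerate (all-zero)
  pixels yield eigenvalue 0, not NaN; zero-RSS coil pixels and zero-weight
  inverse-filter pixels are guarded.
* Seeded operations save and restore the caller's RNG state.

## Containers

Acquisitions and extracted maps round-trip through a single-file serialized
container (`write_acquisition()` / `read_acquisition()`) holding the
k-space array, sampling masks, trajectory metadata and optional ground
truth; magnitude images export to NIfTI via `export_nifti()` when RNifti is
available.

## A short worked run

```{r pipeline}
n <- 64
phantom <- make_phantom(n)
coils <- make_coil_maps(4, n, 7)
phases <- make_shot_phase_maps(2, n, poly_order = 2, amplitude_rad = 1.5,
                               random_fraction = 0.2, seed = 11)
acq <- simulate_acquisition(phantom, coils, phases,
                            make_trajectory("mosaic2", n, 2, 15))
region <- find_overlap(acq$trajectory, 1, 2)
calib <- build_calibration_matrix(acq, region, 7, "symmetric")
result <- eigen_phase_maps(build_pixel_operators(calib_svd(calib, 0.5), n))
support <- Mod(phantom$values) > 0.1 * max(Mod(phantom$values))
median(result$eigenvalue[support])
phase_rmse(array(relative_phase(result), c(n, n, 1)),
           array(phases$phase[, , 2], c(n, n, 1)), Mod(phantom$values))
```

## Known limitations

* Estimation accuracy degrades with the SNR of the overlap band; bands far
  from DC under strong diffusion weighting are the hard regime, and the
  singular-value tail mass (`sv_profile()`, `sv_tail_mass()`) is the
  corresponding diagnostic.
* Kernels wider than the window (very strong or rough phase) leave residual
  error in both routes; the window is exposed (`window_w`) but large
  windows raise cost and weaken the averaging.
* Only chains of pairwise overlaps are composed (`align_shots()`);
  least-squares closure of redundant overlap graphs is noted as an
  extension.
* Multiple eigenvector sets ("soft" models) and null-space residue images
  have no natural analog here, since the shots overlap only in small bands.
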