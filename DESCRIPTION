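Package: shotphase
Title: Shot-to-Shot Phase Calibration for Multi-Shot EPI from k-Space Overlap Bands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Self-navigated estimation and correction of shot-to-shot phase
    fluctuations in multi-shot echo-planar imaging (EPI). Consecutive shots are
    designed to share a small k-space overlap band at an arbitrary location;
    the band is treated as a shot-dependent auto-calibration region from which
    the relative inter-shot phase map is extracted in one step, either by
    directly solving a shift-invariant k-space interpolation kernel
    (GRAPPA-type operation) or by an eigenvalue decomposition of per-pixel
    operators built from the truncated subspace of a sliding-window
    calibration matrix (ESPIRiT-type operation). Includes a fully controlled
    multi-shot, multi-coil acquisition simulator with known ground-truth phase
    maps, conjugate-phase mosaic combination with inverse modulation-transfer
    filtering, an iterative SENSE-type forward-model reconstruction with phase
    encoding, and diagnostics (coefficient-of-variation maps, singular-value
    subspace profiles, weighted phase error metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
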