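# On-disk containers and exports.  The acquisition container is a single
# RDS serialization with a versioned layout (kspace / mask / truth plus
# scheme, overlap and noise metadata); magnitude and phase images can be
# exported to NIfTI when the RNifti package is available.

#' Write / read an acquisition container
#'
#' Serializes an `epi_acquisition` (k-space, sampling masks, trajectory
#' metadata and optional ground truth) to a single file and reads it back
#' bit-exactly.
#'
#' @param bundle An `epi_acquisition`.
#' @param path Output file path (conventionally `.rds`).
#' @return `write_acquisition` returns `path` invisibly; `read_acquisition`
#'   returns the `epi_acquisition`.
#' @export
write_acquisition <- function(bundle, path) {
  if (!inherits(bundle, "epi_acquisition"))
    stop("bundle must be an epi_acquisition", call. = FALSE)
  payload <- list(format = "shotphase-acquisition", version = 1L,
                  bundle = bundle)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_acquisition
#' @export
read_acquisition <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "shotphase-acquisition"))
    stop("not a shotphase acquisition container: ", path, call. = FALSE)
  payload$bundle
}

#' Write / read extracted phase maps
#'
#' @param phases An `epi_phases` (attributes such as the eigenvalue map are
#'   preserved).
#' @param path File path.
#' @export
write_phase_maps <- function(phases, path) {
  saveRDS(list(format = "shotphase-maps", version = 1L, phases = phases), path)
  invisible(path)
}

#' @rdname write_phase_maps
#' @export
read_phase_maps <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "shotphase-maps"))
    stop("not a shotphase phase-map container: ", path, call. = FALSE)
  payload$phases
}

#' Export an image to NIfTI
#'
#' Writes a real image (or the magnitude of a complex one) to a NIfTI file
#' via the RNifti package.
#'
#' @param image Numeric or complex matrix / 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
export_nifti <- function(image, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI export requires the RNifti package", call. = FALSE)
  if (is.complex(image)) image <- Mod(image)
  RNifti::writeNifti(RNifti::asNifti(image), path)
  invisible(path)
}

#' @export
print.epi_acquisition <- function(x, ...) {
  dm <- dim(x$kspace)
  cat("Multi-shot EPI acquisition:", dm[4], "shots,", dm[3], "coils,",
      dm[1], "x", dm[2], "grid\n")
  cat("  scheme:", x$trajectory$scheme,
      "| overlap:", x$trajectory$overlap_px, "px",
      "| noise sigma:", format(x$noise_sigma), "\n")
  invisible(x)
}

#' @export
print.calib_matrix <- function(x, ...) {
  cat("Calibration matrix (", x$layout, "): ", nrow(x$A), " x ", ncol(x$A),
      ", window ", x$window, "x", x$window, ", ", x$n_coils, " coil(s)\n",
      sep = "")
  invisible(x)
}

#' @export
print.eigen_result <- function(x, ...) {
  cat("Pixelwise eigen decomposition over", dim(x$vectors)[3], "shots;",
      "median top eigenvalue", format(stats::median(x$eigenvalue), digits = 4), "\n")
  invisible(x)
}
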