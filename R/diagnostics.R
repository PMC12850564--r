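# Quantitative diagnostics: coefficient-of-variation maps over repetitions,
# singular-value subspace profiles, and weighted wrapped-phase error metrics.

#' Coefficient-of-variation map over repetitions
#'
#' Pixelwise standard deviation divided by mean of the magnitude images over
#' repetitions (the inverse of temporal SNR).  Pixels with zero temporal
#' mean are set to 0 rather than dividing by zero.
#'
#' @param magnitude_stack Real array `ny x nx x repetitions` (>= 2
#'   repetitions); complex input is reduced to magnitudes.
#' @return Object of class `cv_map`: list with `values` (nonnegative
#'   matrix) and `n_repetitions`.
#' @export
cv_map <- function(magnitude_stack) {
  if (is.complex(magnitude_stack)) magnitude_stack <- Mod(magnitude_stack)
  dm <- dim(magnitude_stack)
  if (length(dm) != 3 || dm[3] < 2)
    stop("cv_map needs at least 2 repetitions", call. = FALSE)
  mu <- apply(magnitude_stack, c(1, 2), mean)
  sd_ <- apply(magnitude_stack, c(1, 2), stats::sd)
  values <- ifelse(mu > 0, sd_ / mu, 0)
  structure(list(values = values, n_repetitions = dm[3]), class = "cv_map")
}

#' Magnitude-weighted RMSE of wrapped phase differences
#'
#' Per shot, removes one global phase (the weighted circular mean of the
#' difference) and returns the weighted root-mean-square of the wrapped
#' phase difference in radians.  All arithmetic uses complex phasors; no
#' unwrapping is performed.
#'
#' @param estimated,truth `epi_phases` objects or phase arrays
#'   `ny x nx x n_shots` (radians), same shapes.
#' @param weight Nonnegative weight image (e.g. object magnitude).
#' @return Numeric vector of per-shot RMSE values (radians).
#' @export
phase_rmse <- function(estimated, truth, weight) {
  est <- if (inherits(estimated, "epi_phases")) estimated$phase else estimated
  tru <- if (inherits(truth, "epi_phases")) truth$phase else truth
  if (!all(dim(est) == dim(tru)))
    stop("estimated and truth phase arrays differ in shape", call. = FALSE)
  wsum <- sum(weight)
  if (wsum <= 0) stop("total weight is zero", call. = FALSE)
  S <- dim(est)[3]
  out <- numeric(S)
  for (s in seq_len(S)) {
    z <- exp(1i * (est[, , s] - tru[, , s]))
    gm <- sum(weight * z)
    if (Mod(gm) > 0) z <- z * Conj(gm / Mod(gm))
    out[s] <- sqrt(sum(weight * Arg(z)^2) / wsum)
  }
  out
}

#' Normalized singular-value profile
#'
#' Singular values divided by the largest one, in descending order, with the
#' kept-subspace size annotated.  The area in the profile's tail is the
#' standard diagnostic of calibration quality: a more left-concentrated
#' (low-rank) profile indicates kernels representable by fewer singular
#' vectors and hence more reliable extraction.
#'
#' @param x A `calib_matrix`, a `subspace_basis`, or a numeric vector of
#'   singular values.
#' @return Object of class `sv_profile`: list with `values` (first entry 1,
#'   non-increasing) and `kept` (may be `NA`).
#' @export
sv_profile <- function(x) {
  if (inherits(x, "subspace_basis")) {
    d <- x$singular_values; kept <- x$kept
  } else if (inherits(x, "calib_matrix")) {
    if (length(x$A) == 0) stop("empty calibration matrix", call. = FALSE)
    d <- svd(x$A, nu = 0, nv = 0)$d; kept <- NA_integer_
  } else {
    d <- sort(as.numeric(x), decreasing = TRUE); kept <- NA_integer_
  }
  if (!length(d) || max(d) == 0)
    stop("all singular values are zero", call. = FALSE)
  structure(list(values = d / d[1], kept = kept), class = "sv_profile")
}

#' Tail mass of a singular-value profile
#'
#' Sum of the normalized singular values beyond index `after`; grows with
#' the noise level of the calibration data.
#'
#' @param profile An `sv_profile`.
#' @param after Last index counted as head.
#' @return Scalar tail mass.
#' @export
sv_tail_mass <- function(profile, after) {
  v <- profile$values
  if (after >= length(v)) return(0)
  sum(v[(after + 1):length(v)])
}
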