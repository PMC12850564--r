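# Synthetic objects: deterministic analytic compositions standing in for the
# in vivo object in controlled experiments.

#' Analytic test phantom
#'
#' Builds a deterministic complex-valued object on a square centered grid.
#' `"ellipses"` is a head-like composition of nested ellipses with distinct
#' intensities; `"blocks"` is a piecewise-constant rectangle composition.
#' Both carry a smooth, low-amplitude intrinsic phase so that the object is
#' genuinely complex; magnitudes lie in \[0, 1\] and are exactly zero outside
#' the support.
#'
#' @param grid_size Pixels per axis (square grid), at least 16.
#' @param kind `"ellipses"` or `"blocks"`.
#' @return An object of class `epi_phantom`: list with `values` (complex
#'   matrix), `support` (logical matrix), `grid_size`, `kind`.
#' @examples
#' ph <- make_phantom(64, "ellipses")
#' mean(ph$support)   # support fraction
#' @export
make_phantom <- function(grid_size, kind = c("ellipses", "blocks")) {
  kind <- match.arg(kind)
  if (grid_size < 16) stop("grid_size must be at least 16", call. = FALSE)
  n <- as.integer(grid_size)
  cx <- centered_coords(n) / (n / 2)         # normalized [-1, 1) coordinates
  X <- matrix(cx, n, n, byrow = TRUE)        # column (kx / x) coordinate
  Y <- matrix(cx, n, n)                      # row (ky / y) coordinate

  mag <- matrix(0, n, n)
  if (kind == "ellipses") {
    add_ellipse <- function(mag, x0, y0, a, b, theta, val) {
      ct <- cos(theta); st <- sin(theta)
      xr <- (X - x0) * ct + (Y - y0) * st
      yr <- -(X - x0) * st + (Y - y0) * ct
      inside <- (xr / a)^2 + (yr / b)^2 <= 1
      mag[inside] <- val
      mag
    }
    mag <- add_ellipse(mag, 0, 0, 0.72, 0.58, 0, 0.8)
    mag <- add_ellipse(mag, 0, 0, 0.62, 0.48, 0, 0.55)
    mag <- add_ellipse(mag, -0.22, -0.05, 0.22, 0.28, 0.35, 0.9)
    mag <- add_ellipse(mag, 0.22, -0.05, 0.20, 0.26, -0.35, 0.35)
    mag <- add_ellipse(mag, 0.00, 0.28, 0.12, 0.10, 0, 1.0)
    mag <- add_ellipse(mag, 0.05, -0.30, 0.08, 0.08, 0, 0.15)
  } else {
    add_rect <- function(mag, x0, x1, y0, y1, val) {
      inside <- X >= x0 & X <= x1 & Y >= y0 & Y <= y1
      mag[inside] <- val
      mag
    }
    mag <- add_rect(mag, -0.7, 0.7, -0.7, 0.7, 0.6)
    mag <- add_rect(mag, -0.45, -0.05, -0.45, 0.2, 1.0)
    mag <- add_rect(mag, 0.1, 0.5, -0.2, 0.5, 0.3)
    mag <- add_rect(mag, -0.2, 0.2, -0.6, -0.35, 0.8)
  }

  support <- mag > 0
  # Smooth deterministic intrinsic phase, zero outside the support.
  phs <- 0.4 * (X + 0.5 * Y + 0.6 * X * Y - 0.3 * X^2)
  values <- mag * exp(1i * phs)
  values[!support] <- 0 + 0i

  structure(
    list(values = values, support = support, grid_size = n, kind = kind),
    class = "epi_phantom"
  )
}
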