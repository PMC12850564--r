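# Direct (GRAPPA-type) route: solve the one-way interpolation kernel between
# two shots from the overlap band, then read off the relative image-space
# modulation as the kernel's zero-filled inverse DFT.

#' Solve the shot-to-shot interpolation kernel
#'
#' Least-squares solution of `A u = target` for a `oneway` calibration
#' matrix.  The kernel `u` is the k-space face of the smooth image-space
#' modulation relating the two shots: multiplying the source image by the
#' relative map is convolving the source k-space with `u`.
#'
#' Solvers:
#' \describe{
#'   \item{`tsvd`}{truncated SVD, discarding singular values below
#'     `reg * sigma_max` (default `reg = 0.05`); the default, mirroring the
#'     subspace-truncation robustness of the eigenvalue route.}
#'   \item{`pinv`}{Tikhonov-regularized pseudo-inverse with damping
#'     `reg * sigma_max` (default `reg = 1e-3`); `reg = 0` gives the plain
#'     minimum-norm least-squares solution.}
#'   \item{`lsqr`}{conjugate-gradient iteration on the normal equations to
#'     relative residual `reg` (default `1e-8`), capped at 500 iterations.}
#' }
#'
#' @param calib A `calib_matrix` with `layout = "oneway"`.
#' @param solver `"tsvd"`, `"pinv"` or `"lsqr"`.
#' @param reg Solver-specific regularization (see above); `NULL` for the
#'   solver default.
#' @return Object of class `interp_kernel`: list with `values` (`w x w`
#'   complex matrix indexed by window offset, row = ky offset), `window`,
#'   `source_shot`, `target_shot`, `solver`, `reg`, `residual` (relative).
#' @export
solve_interp_kernel <- function(calib, solver = c("tsvd", "pinv", "lsqr"),
                                reg = NULL) {
  solver <- match.arg(solver)
  if (!inherits(calib, "calib_matrix") || calib$layout != "oneway")
    stop("solve_interp_kernel needs a oneway calibration matrix", call. = FALSE)
  A <- calib$A; b <- calib$target
  if (length(A) == 0 || nrow(A) == 0)
    stop("empty calibration matrix", call. = FALSE)
  if (!all(is.finite(Re(A))) || !all(is.finite(Im(A))) ||
      !all(is.finite(Re(b))) || !all(is.finite(Im(b))))
    stop("non-finite calibration data", call. = FALSE)
  if (is.null(reg))
    reg <- switch(solver, tsvd = 0.05, pinv = 1e-3, lsqr = 1e-8)

  u <- switch(solver,
    pinv = {
      sv <- svd(A)
      smax <- sv$d[1]
      lam <- reg * smax
      filt <- sv$d / (sv$d^2 + lam^2)
      filt[sv$d < smax * 1e-12] <- 0
      sv$v %*% (filt * (Conj(t(sv$u)) %*% b))
    },
    tsvd = {
      sv <- svd(A)
      keep <- sv$d >= reg * sv$d[1]
      keep[1] <- TRUE
      sv$v[, keep, drop = FALSE] %*%
        ((Conj(t(sv$u[, keep, drop = FALSE])) %*% b) / sv$d[keep])
    },
    lsqr = cg_normal(A, b, tol = reg, max_iter = 500L)
  )
  u <- drop(u)
  resid <- sqrt(sum(Mod(A %*% u - b)^2)) / max(sqrt(sum(Mod(b)^2)), .Machine$double.eps)

  w <- calib$window
  # u index = (dy + h) * w + (dx + h) + 1 (ky offset outer): transpose of
  # R's column-major fill
  values <- t(matrix(u, w, w))

  structure(
    list(values = values, window = w,
         source_shot = calib$source_shot, target_shot = calib$target_shot,
         solver = solver, reg = reg, residual = resid),
    class = "interp_kernel"
  )
}

# Conjugate gradients on the normal equations A^H A x = A^H b.
cg_normal <- function(A, b, tol = 1e-8, max_iter = 500L) {
  Ah <- Conj(t(A))
  x <- rep(0 + 0i, ncol(A))
  r <- Ah %*% b
  p <- r
  rs <- Re(sum(Conj(r) * r))
  rs0 <- rs
  for (it in seq_len(max_iter)) {
    if (sqrt(rs / rs0) <= tol) break
    Ap <- Ah %*% (A %*% p)
    alpha <- rs / Re(sum(Conj(p) * Ap))
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- Re(sum(Conj(r) * r))
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  x
}

#' Convert an interpolation kernel to a relative image-space map
#'
#' Embeds the `w x w` kernel at the center of a `grid_size` square zero
#' array and applies the centered inverse DFT, scaled so that a pure
#' center-delta kernel maps to the all-ones image.  The result approximates
#' the target-over-source modulation (relative phase map) on the object
#' support.  If `support` is supplied, a global phase is removed by rotating
#' the map so its magnitude-weighted mean over the support is real-positive.
#'
#' @param kernel An `interp_kernel` (or bare `w x w` complex matrix).
#' @param grid_size Output grid (>= kernel width).
#' @param support Optional logical matrix for the gauge fix.
#' @return Object of class `relative_map`: list with `values` (complex
#'   `grid x grid`), `pair`, `method`.
#' @export
kernel_to_relative_map <- function(kernel, grid_size, support = NULL) {
  vals <- if (inherits(kernel, "interp_kernel")) kernel$values else kernel
  w <- nrow(vals)
  n <- as.integer(grid_size)
  if (w > n) stop("kernel larger than the output grid", call. = FALSE)
  h <- (w - 1L) %/% 2L
  K <- matrix(0 + 0i, n, n)
  dc <- dc_index(n)
  K[(dc - h):(dc + h), (dc - h):(dc + h)] <- vals
  map <- kspace_inverse(K) * n^2
  if (!is.null(support)) {
    wmean <- sum(map[support] * Mod(map[support]))
    if (Mod(wmean) > 0) map <- map * Conj(wmean / Mod(wmean))
  }
  pair <- if (inherits(kernel, "interp_kernel"))
    c(kernel$source_shot, kernel$target_shot) else c(NA_integer_, NA_integer_)
  structure(
    list(values = map, pair = pair, method = "grappa"),
    class = "relative_map"
  )
}
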