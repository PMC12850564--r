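#' Smooth synthetic receive-coil sensitivity maps
#'
#' Generates spatially smooth complex coil sensitivities: per coil, a broad
#' Gaussian envelope centered near the image edge (randomized by `seed`)
#' multiplied by a low-order complex polynomial, then pixelwise normalized so
#' the root-sum-of-squares over coils is exactly 1 everywhere (in particular
#' within \[0.9, 1.1\] on any object support).
#'
#' @param n_coils Number of receive channels (>= 1).
#' @param grid_size Pixels per axis.
#' @param seed Integer seed; the map set is bit-reproducible.
#' @return Object of class `epi_coils`: list with `maps` (complex array
#'   `grid_size x grid_size x n_coils`), `n_coils`, `grid_size`.
#' @export
make_coil_maps <- function(n_coils, grid_size, seed = 1L) {
  if (n_coils < 1) stop("n_coils must be at least 1", call. = FALSE)
  n <- as.integer(grid_size)
  cx <- centered_coords(n) / (n / 2)
  X <- matrix(cx, n, n, byrow = TRUE)
  Y <- matrix(cx, n, n)

  maps <- with_local_seed(seed, {
    out <- array(0 + 0i, dim = c(n, n, n_coils))
    ang0 <- stats::runif(1, 0, 2 * pi)
    for (c in seq_len(n_coils)) {
      # coil centers on a ring just outside the FOV, jittered
      ang <- ang0 + 2 * pi * (c - 1) / n_coils + stats::runif(1, -0.2, 0.2)
      x0 <- 1.25 * cos(ang); y0 <- 1.25 * sin(ang)
      sigma <- stats::runif(1, 1.2, 1.8)
      env <- 0.25 + exp(-((X - x0)^2 + (Y - y0)^2) / (2 * sigma^2))
      a <- stats::runif(3, -0.3, 0.3)
      b <- stats::runif(3, -0.4, 0.4)
      poly <- (1 + a[1] * X + a[2] * Y + a[3] * X * Y) *
        exp(1i * (b[1] * X + b[2] * Y + b[3] * (X^2 - Y^2)))
      out[, , c] <- env * poly
    }
    out
  })

  rss <- sqrt(apply(abs(maps)^2, c(1, 2), sum))
  rss[rss == 0] <- 1
  for (c in seq_len(n_coils)) maps[, , c] <- maps[, , c] / rss

  structure(
    list(maps = maps, n_coils = as.integer(n_coils), grid_size = n),
    class = "epi_coils"
  )
}
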