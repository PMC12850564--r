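# Inter-shot overlap regions and the sliding-window calibration matrix.
#
# The overlap band shared by two shots plays the role of an auto-calibrating
# signal (ACS) region: within it, both shots observe the same k-space
# neighborhoods up to the shot-to-shot phase modulation, so a sliding window
# over the band yields the rows of a calibration matrix from which the
# modulation kernel (or its image-space eigenvector) can be extracted.

#' Locate the calibration region shared by two shots
#'
#' Returns the maximal axis-aligned rectangle contained in the intersection
#' of the two shots' sampled-coordinate sets.  Area ties are broken toward
#' the rectangle whose center is nearest the k-space origin.
#'
#' @param trajectory An `epi_trajectory`.
#' @param shot_i,shot_j Shot indices (1-based).
#' @param window_w Minimum admissible extent (the calibration window width).
#' @return Object of class `overlap_region`: list with `shot_pair`, `ky` and
#'   `kx` (inclusive index ranges).
#' @export
find_overlap <- function(trajectory, shot_i, shot_j, window_w = 7L) {
  S <- trajectory$n_shots
  if (shot_i < 1 || shot_i > S || shot_j < 1 || shot_j > S || shot_i == shot_j)
    stop("shot indices must be distinct and within 1..", S, call. = FALSE)
  inter <- trajectory$masks[, , shot_i] & trajectory$masks[, , shot_j]
  if (!any(inter))
    stop("shots ", shot_i, " and ", shot_j, " share no k-space coordinates",
         call. = FALSE)
  rect <- largest_rectangle(inter, trajectory$grid_size)
  if ((rect$ky[2] - rect$ky[1] + 1) < window_w ||
      (rect$kx[2] - rect$kx[1] + 1) < window_w)
    stop("overlap of shots ", shot_i, " and ", shot_j,
         " is smaller than the calibration window on one axis", call. = FALSE)
  structure(
    list(shot_pair = c(shot_i, shot_j), ky = rect$ky, kx = rect$kx),
    class = "overlap_region"
  )
}

# Maximal all-TRUE axis-aligned rectangle of a logical matrix (histogram
# method), ties broken toward the rectangle center nearest the DC index.
largest_rectangle <- function(mask, grid_size) {
  ny <- nrow(mask); nx <- ncol(mask)
  dc <- dc_index(grid_size)
  heights <- integer(nx)
  best <- list(area = -1, dist = Inf, ky = c(1L, 1L), kx = c(1L, 1L))
  consider <- function(best, y1, y0, x0, x1) {
    area <- (y1 - y0 + 1) * (x1 - x0 + 1)
    d <- ((y0 + y1) / 2 - dc)^2 + ((x0 + x1) / 2 - dc)^2
    if (area > best$area || (area == best$area && d < best$dist))
      list(area = area, dist = d, ky = c(y0, y1), kx = c(x0, x1))
    else best
  }
  for (y in seq_len(ny)) {
    heights <- ifelse(mask[y, ], heights + 1L, 0L)
    # largest rectangle in histogram, O(nx) stack sweep
    stack_pos <- integer(0); stack_h <- integer(0)
    for (x in seq_len(nx + 1L)) {
      h <- if (x <= nx) heights[x] else 0L
      start <- x
      while (length(stack_h) && stack_h[length(stack_h)] > h) {
        ph <- stack_h[length(stack_h)]; pp <- stack_pos[length(stack_pos)]
        stack_h <- stack_h[-length(stack_h)]
        stack_pos <- stack_pos[-length(stack_pos)]
        best <- consider(best, y, y - ph + 1L, pp, x - 1L)
        start <- pp
      }
      if (h > 0 && (!length(stack_h) || stack_h[length(stack_h)] < h)) {
        stack_pos <- c(stack_pos, start); stack_h <- c(stack_h, h)
      }
    }
  }
  best
}

#' Sliding-window calibration matrix over an overlap region
#'
#' Applies a `window_w` x `window_w` sliding window (stride 1, windows fully
#' inside the region) to the overlap band and reshapes each neighborhood into
#' a matrix row.  Coils contribute additional rows (the kernel is
#' shift-invariant across k-space locations and receive channels), never
#' columns.  Two layouts are produced:
#' \describe{
#'   \item{`oneway`}{columns hold the source shot's neighborhood read in
#'     convolution order (entry for window offset `d` is the source sample at
#'     `center - d`); the `target` vector holds the target shot's sample at
#'     each window center.  `A u = target` is the interpolation system whose
#'     solution `u` is the shot-to-shot modulation kernel.}
#'   \item{`symmetric`}{columns hold both shots' neighborhoods read directly
#'     (entry for offset `d` is the sample at `center + d`), concatenated
#'     shot-major; this is the form whose right singular vectors feed the
#'     eigenvalue approach.}
#' }
#' Row count is `n_coils * (H - w + 1) * (W - w + 1)` for an `H x W` region;
#' column count is `w^2` (oneway) or `n_shots * w^2` (symmetric).
#'
#' @param bundle An `epi_acquisition`.
#' @param region An `overlap_region` (or any list with `shot_pair`, `ky`,
#'   `kx`).
#' @param window_w Odd window width (default 7).
#' @param layout `"oneway"` or `"symmetric"`.
#' @param source_shot,target_shot Shot roles for the `oneway` layout; default
#'   the first and second element of `region$shot_pair`.
#' @return Object of class `calib_matrix`: list with `A`, `target` (oneway
#'   only), `window`, `layout`, `region`, `n_coils`, `n_shots_row`,
#'   `shot_pair`.
#' @export
build_calibration_matrix <- function(bundle, region, window_w = 7L,
                                     layout = c("oneway", "symmetric"),
                                     source_shot = NULL, target_shot = NULL) {
  layout <- match.arg(layout)
  w <- as.integer(window_w)
  if (w %% 2L == 0L) stop("window_w must be odd", call. = FALSE)
  if (is.null(source_shot)) source_shot <- region$shot_pair[1]
  if (is.null(target_shot)) target_shot <- region$shot_pair[2]
  ky <- region$ky; kx <- region$kx
  H <- ky[2] - ky[1] + 1L; W <- kx[2] - kx[1] + 1L
  if (H < w || W < w)
    stop("calibration window larger than the overlap region", call. = FALSE)
  C <- dim(bundle$kspace)[3]
  shots <- if (layout == "oneway") source_shot else region$shot_pair
  blocks <- bundle$kspace[ky[1]:ky[2], kx[1]:kx[2], , shots, drop = FALSE]

  A <- calib_rows(blocks, w, reverse = (layout == "oneway"))
  target <- NULL
  if (layout == "oneway") {
    h <- (w - 1L) %/% 2L
    ctr <- bundle$kspace[(ky[1] + h):(ky[2] - h), (kx[1] + h):(kx[2] - h),
                         , target_shot, drop = FALSE]
    target <- as.vector(ctr)
  }

  structure(
    list(A = A, target = target, window = w, layout = layout, region = region,
         n_coils = C, n_shots_row = length(shots),
         shot_pair = region$shot_pair,
         source_shot = source_shot, target_shot = target_shot),
    class = "calib_matrix"
  )
}

# Core row assembly.  `blocks` is a complex array [H, W, C, S_sel] already
# cropped to the region.  Rows are ordered window-row fastest, then
# window-column, then coil; columns are shot-major, and within a shot the
# window offsets run row-major from (-h, -h) to (+h, +h).  With
# reverse = TRUE the entry for offset d is the sample at center - d
# (convolution order); otherwise at center + d (direct order).
calib_rows <- function(blocks, w, reverse = FALSE) {
  dm <- dim(blocks)
  H <- dm[1]; W <- dm[2]; C <- dm[3]; S <- dm[4]
  h <- (w - 1L) %/% 2L
  nwy <- H - w + 1L; nwx <- W - w + 1L
  cy <- (h + 1L):(h + nwy); cx <- (h + 1L):(h + nwx)
  nrows <- nwy * nwx * C
  A <- matrix(0 + 0i, nrows, S * w * w)
  col <- 0L
  for (s in seq_len(S)) {
    for (dy in -h:h) for (dx in -h:h) {
      col <- col + 1L
      sgn <- if (reverse) -1L else 1L
      A[, col] <- as.vector(blocks[cy + sgn * dy, cx + sgn * dx, , s])
    }
  }
  A
}
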