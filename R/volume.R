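#' Regular-grid volume container
#'
#' A `volume3d` stores samples of a 3D function on a centered regular grid.
#' Voxel centers lie at `(i - (n - 1)/2) * delta` for `i = 0, ..., n - 1`
#' on each axis, so the grid is symmetric about the world origin for both
#' odd and even `n`. Spacing is isotropic.
#'
#' @param values numeric 3D array `(nx, ny, nz)`; all values must be finite.
#' @param extent world half-width of the x-axis; the voxel spacing is
#'   `2 * extent / nx` and is shared by all axes.
#' @return an object of class `volume3d` with fields `values`, `spacing`,
#'   `extent`.
#' @export
volume3d <- function(values, extent = 1) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!all(is.finite(values))) stop("volume values must all be finite")
  if (extent <= 0) stop("`extent` must be positive")
  spacing <- 2 * extent / dim(values)[1]
  structure(list(values = values, spacing = spacing, extent = extent),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume3d> %d x %d x %d, spacing %.4g, extent %.4g, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$spacing, x$extent,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$values)

#' Centered grid coordinates
#'
#' @param n number of samples.
#' @param delta sample spacing.
#' @return numeric vector of length `n`, symmetric about 0.
#' @export
grid_coords <- function(n, delta) (seq_len(n) - 1 - (n - 1) / 2) * delta

#' Multi-angle projection stack
#'
#' Per-angle 2D detector images `P_theta f(u, v)` sharing one detector grid.
#' The detector `u` axis is the in-plane axis perpendicular to the ray
#' direction; `v` coincides with the volume's z axis.
#'
#' @param data numeric 3D array `(nu, nv, n_angles)`.
#' @param angles numeric vector of projection angles in radians, in `[0, 2*pi)`.
#' @param spacing detector sample spacing (same for u and v).
#' @return an object of class `projection_stack`.
#' @export
projection_stack <- function(data, angles, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (nu, nv, n_angles)")
  if (dim(data)[3] != length(angles))
    stop("number of images must equal number of angles")
  if (length(angles) < 1L) stop("at least one angle is required")
  if (any(angles < 0 | angles >= 2 * pi))
    stop("angles must lie in [0, 2*pi)")
  if (spacing <= 0) stop("`spacing` must be positive")
  structure(list(data = data, angles = as.numeric(angles), spacing = spacing),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<projection_stack> %d angle(s), detector %d x %d, spacing %.4g\n",
              d[3], d[1], d[2], x$spacing))
  invisible(x)
}

# Bilinear interpolation of every z-slice of a flattened volume at a common
# set of in-plane points. `V` is (nx*ny, nz); xq, yq are world coordinates.
# Points outside the grid contribute 0. Returns (length(xq), nz).
bilinear_slices <- function(V, nx, ny, delta, xq, yq) {
  c0 <- (nx - 1) / 2
  gx <- xq / delta + c0          # fractional index, 0-based
  gy <- yq / delta + (ny - 1) / 2
  i0 <- floor(gx); j0 <- floor(gy)
  fx <- gx - i0;  fy <- gy - j0
  inside <- i0 >= 0 & i0 <= nx - 2 & j0 >= 0 & j0 <= ny - 2
  # clamp so indexing is valid; weights of outside points are zeroed
  i0c <- pmin(pmax(i0, 0), nx - 2)
  j0c <- pmin(pmax(j0, 0), ny - 2)
  w00 <- ifelse(inside, (1 - fx) * (1 - fy), 0)
  w10 <- ifelse(inside, fx * (1 - fy), 0)
  w01 <- ifelse(inside, (1 - fx) * fy, 0)
  w11 <- ifelse(inside, fx * fy, 0)
  k00 <- i0c + 1 + j0c * nx
  out <- w00 * V[k00, , drop = FALSE] + w10 * V[k00 + 1, , drop = FALSE] +
    w01 * V[k00 + nx, , drop = FALSE] + w11 * V[k00 + nx + 1, , drop = FALSE]
  out
}

# Keys cubic-convolution kernel (a = -1/2), vectorized over |t| <= 2
keys_weight <- function(t) {
  at <- abs(t)
  ifelse(at <= 1, 1.5 * at^3 - 2.5 * at^2 + 1,
         ifelse(at < 2, -0.5 * at^3 + 2.5 * at^2 - 4 * at + 2, 0))
}

# Bicubic (cubic-convolution) analogue of bilinear_slices: third-order
# accurate in-plane resampling, zero outside the grid. Needs a 4x4 tap
# neighborhood; points whose neighborhood leaves the grid fall back to 0
# (the supported objects vanish at the boundary by construction).
bicubic_slices <- function(V, nx, ny, delta, xq, yq) {
  gx <- xq / delta + (nx - 1) / 2
  gy <- yq / delta + (ny - 1) / 2
  i0 <- floor(gx); j0 <- floor(gy)
  fx <- gx - i0;  fy <- gy - j0
  inside <- i0 >= 1 & i0 <= nx - 3 & j0 >= 1 & j0 <= ny - 3
  i0c <- pmin(pmax(i0, 1), nx - 3)
  j0c <- pmin(pmax(j0, 1), ny - 3)
  wx <- lapply(-1:2, function(o) ifelse(inside, keys_weight(fx - o), 0))
  wy <- lapply(-1:2, function(o) keys_weight(fy - o))
  out <- matrix(0, length(xq), ncol(V))
  for (oy in 1:4) {
    rowbase <- i0c + 1 + (j0c + oy - 2) * nx
    acc <- wx[[1]] * V[rowbase - 1, , drop = FALSE] +
      wx[[2]] * V[rowbase, , drop = FALSE] +
      wx[[3]] * V[rowbase + 1, , drop = FALSE] +
      wx[[4]] * V[rowbase + 2, , drop = FALSE]
    out <- out + wy[[oy]] * acc
  }
  out
}
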