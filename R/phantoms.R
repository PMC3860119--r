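#' Ellipsoid primitive
#'
#' Axis-aligned ellipsoid optionally rotated about the z axis, with a
#' (possibly negative) constant density. The building block of the
#' Shepp-Logan-style head phantom.
#'
#' @param center numeric length-3 world-coordinate center `(x0, y0, z0)`.
#' @param semiaxes numeric length-3 strictly positive semi-axes `(a, b, c)`.
#' @param angle rotation about z, radians.
#' @param density constant density inside the ellipsoid; may be negative.
#' @return object of class `ellipsoid`.
#' @export
ellipsoid <- function(center, semiaxes, angle = 0, density = 1) {
  stopifnot(length(center) == 3L, length(semiaxes) == 3L)
  if (any(semiaxes <= 0)) stop("semi-axes must be strictly positive")
  if (!is.finite(density)) stop("density must be finite")
  structure(list(center = as.numeric(center), semiaxes = as.numeric(semiaxes),
                 angle = as.numeric(angle), density = as.numeric(density)),
            class = "ellipsoid")
}

# Versioned 3D Shepp-Logan parameter table (v1).
# Kak-Slaney-style 10-ellipsoid extension of the classic head phantom with the
# "modified" high-contrast densities; rotations restricted to the z axis
# (the small third-Euler-angle tilts of some published tables are dropped,
# consistent with a rotation-about-z-only geometry).
# Columns: density, a, b, c, x0, y0, z0, angle_deg (about z).
.shepp_logan_table_v1 <- matrix(c(
   1.0, 0.6900, 0.9200, 0.810,  0.00,  0.0000,  0.00,   0,
  -0.8, 0.6624, 0.8740, 0.780,  0.00, -0.0184,  0.00,   0,
  -0.2, 0.1100, 0.3100, 0.220,  0.22,  0.0000,  0.00, -18,
  -0.2, 0.1600, 0.4100, 0.280, -0.22,  0.0000,  0.00,  18,
   0.1, 0.2100, 0.2500, 0.410,  0.00,  0.3500, -0.15,   0,
   0.1, 0.0460, 0.0460, 0.050,  0.00,  0.1000,  0.25,   0,
   0.1, 0.0460, 0.0460, 0.050,  0.00, -0.1000,  0.25,   0,
   0.1, 0.0460, 0.0230, 0.050, -0.08, -0.6050,  0.00,   0,
   0.1, 0.0230, 0.0230, 0.020,  0.00, -0.6060,  0.00,   0,
   0.1, 0.0230, 0.0460, 0.020,  0.06, -0.6050,  0.00,   0),
  ncol = 8, byrow = TRUE)

#' Shepp-Logan ellipsoid list
#'
#' The 10-ellipsoid 3D head phantom parameter table used by
#' [make_shepp_logan_3d()], as a list of [ellipsoid()] objects.
#'
#' @return list of 10 `ellipsoid` objects.
#' @export
shepp_logan_ellipsoids <- function() {
  tab <- .shepp_logan_table_v1
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    ellipsoid(center = r[5:7], semiaxes = r[2:4],
              angle = r[8] * pi / 180, density = r[1])
  })
}

#' Rasterize a list of ellipsoids onto a centered grid
#'
#' Pointwise evaluation: each voxel center receives the sum of the densities
#' of the ellipsoids containing it. Voxels outside every ellipsoid are
#' exactly zero.
#'
#' @param ells list of [ellipsoid()] objects.
#' @param n grid size per axis.
#' @param extent world half-width.
#' @return a [volume3d()].
#' @export
rasterize_ellipsoids <- function(ells, n, extent = 1) {
  delta <- 2 * extent / n
  g <- grid_coords(n, delta)
  xs <- rep(g, times = n * n)
  ys <- rep(rep(g, each = n), times = n)
  zs <- rep(g, each = n * n)
  vals <- numeric(n^3)
  for (e in ells) {
    ca <- cos(e$angle); sa <- sin(e$angle)
    dx <- xs - e$center[1]; dy <- ys - e$center[2]; dz <- zs - e$center[3]
    # rotate world offset into the ellipsoid frame (inverse z-rotation)
    px <- ca * dx + sa * dy
    py <- -sa * dx + ca * dy
    q <- (px / e$semiaxes[1])^2 + (py / e$semiaxes[2])^2 +
      (dz / e$semiaxes[3])^2
    vals <- vals + e$density * (q <= 1)
  }
  volume3d(array(vals, c(n, n, n)), extent = extent)
}

#' 3D Shepp-Logan phantom
#'
#' Rasterizes the standard 10-ellipsoid head phantom on an `n^3` centered
#' grid spanning `[-extent, extent]^3`. Deterministic.
#'
#' @param n grid size per axis, at least 8.
#' @param extent world half-width, default 1.
#' @return a [volume3d()].
#' @export
make_shepp_logan_3d <- function(n, extent = 1) {
  if (n < 8) stop("`n` must be at least 8")
  rasterize_ellipsoids(shepp_logan_ellipsoids(), n, extent)
}

#' Analytic X-ray projection of ellipsoids
#'
#' Exact closed-form parallel-beam line integrals: for each ray the chord
#' length through each ellipsoid times its density, summed over ellipsoids.
#' Rays run along `w = (-sin(theta), cos(theta), 0)` through the detector
#' point `u * (cos(theta), sin(theta), 0) + v * (0, 0, 1)`. Serves as ground
#' truth for the numeric projector.
#'
#' @param ells list of [ellipsoid()] objects.
#' @param theta projection angle, radians.
#' @param u,v detector coordinate vectors (finite).
#' @return matrix `(length(u), length(v))` of line integrals.
#' @export
analytic_xray_ellipsoids <- function(ells, theta, u, v) {
  if (!all(is.finite(u), is.finite(v))) stop("detector grids must be finite")
  uu <- rep(u, times = length(v))
  vv <- rep(v, each = length(u))
  p0x <- uu * cos(theta); p0y <- uu * sin(theta); p0z <- vv
  dx <- -sin(theta); dy <- cos(theta)  # dz = 0
  out <- numeric(length(uu))
  for (e in ells) {
    ca <- cos(e$angle); sa <- sin(e$angle)
    ax <- e$semiaxes[1]; ay <- e$semiaxes[2]; az <- e$semiaxes[3]
    # ray origin and direction in the ellipsoid frame
    ox <- p0x - e$center[1]; oy <- p0y - e$center[2]; oz <- p0z - e$center[3]
    px <- ca * ox + sa * oy
    py <- -sa * ox + ca * oy
    ddx <- ca * dx + sa * dy
    ddy <- -sa * dx + ca * dy
    A <- (ddx / ax)^2 + (ddy / ay)^2
    B <- 2 * (px * ddx / ax^2 + py * ddy / ay^2)
    C <- (px / ax)^2 + (py / ay)^2 + (oz / az)^2 - 1
    disc <- B^2 - 4 * A * C
    out <- out + e$density * sqrt(pmax(disc, 0)) / A
  }
  matrix(out, length(u), length(v))
}

#' Gaussian blob primitive
#'
#' Isotropic Gaussian `amplitude * exp(-|x - center|^2 / (2 sigma^2))`: a
#' smooth compactly-concentrated test object whose X-ray projection has a
#' closed form at every angle.
#'
#' @param center length-3 world center.
#' @param sigma isotropic width, strictly positive.
#' @param amplitude peak value.
#' @return object of class `gaussian_blob`.
#' @export
gaussian_blob <- function(center = c(0, 0, 0), sigma = 1, amplitude = 1) {
  stopifnot(length(center) == 3L)
  if (sigma <= 0) stop("`sigma` must be strictly positive")
  structure(list(center = as.numeric(center), sigma = sigma,
                 amplitude = amplitude), class = "gaussian_blob")
}

#' Rasterize a Gaussian blob
#'
#' @param blob a [gaussian_blob()].
#' @param n grid size per axis.
#' @param extent world half-width.
#' @return a [volume3d()].
#' @export
rasterize_blob <- function(blob, n, extent = 1) {
  delta <- 2 * extent / n
  g <- grid_coords(n, delta)
  ex <- exp(-(g - blob$center[1])^2 / (2 * blob$sigma^2))
  ey <- exp(-(g - blob$center[2])^2 / (2 * blob$sigma^2))
  ez <- exp(-(g - blob$center[3])^2 / (2 * blob$sigma^2))
  vals <- blob$amplitude * outer(outer(ex, ey), ez)
  volume3d(array(vals, c(n, n, n)), extent = extent)
}

#' Analytic X-ray projection of a Gaussian blob
#'
#' The line integral of an isotropic Gaussian is again Gaussian:
#' `amplitude * sigma * sqrt(2*pi) * exp(-((u-u0)^2+(v-v0)^2)/(2 sigma^2))`,
#' where `(u0, v0)` is the projected center. For a blob centered at the
#' origin this is independent of the angle.
#'
#' @inheritParams analytic_xray_ellipsoids
#' @param blob a [gaussian_blob()].
#' @return matrix `(length(u), length(v))`.
#' @export
analytic_xray_blob <- function(blob, theta, u, v) {
  u0 <- blob$center[1] * cos(theta) + blob$center[2] * sin(theta)
  v0 <- blob$center[3]
  amp <- blob$amplitude * blob$sigma * sqrt(2 * pi)
  eu <- exp(-(u - u0)^2 / (2 * blob$sigma^2))
  ev <- exp(-(v - v0)^2 / (2 * blob$sigma^2))
  amp * outer(eu, ev)
}

#' Add seeded Gaussian noise
#'
#' Adds i.i.d. zero-mean Gaussian noise of the given variance to an array,
#' a [volume3d()] or a [projection_stack()]. With the same seed the output
#' is bit-for-bit reproducible.
#'
#' @param x numeric array, `volume3d` or `projection_stack`.
#' @param variance noise variance, non-negative.
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @return object of the same class and shape as `x`.
#' @export
add_gaussian_noise <- function(x, variance, seed = NULL) {
  if (variance < 0) stop("`variance` must be non-negative")
  if (inherits(x, "volume3d")) {
    x$values <- add_gaussian_noise(x$values, variance, seed)
    return(x)
  }
  if (inherits(x, "projection_stack")) {
    x$data <- add_gaussian_noise(x$data, variance, seed)
    return(x)
  }
  if (variance == 0) return(x)
  if (!is.null(seed)) set.seed(seed)
  x + array(stats::rnorm(length(x), mean = 0, sd = sqrt(variance)),
            dim = dim(x) %||% length(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
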