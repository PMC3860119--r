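#' View geometry for rotation about z
#'
#' Unit vectors of the rotating detector frame at angle `theta` (measured
#' anticlockwise from +x): `u = (cos, sin, 0)` is the in-plane detector
#' axis, `w = (-sin, cos, 0)` the ray direction, `v = (0, 0, 1)` the
#' rotation axis (identical to z).
#'
#' @param theta angle in radians.
#' @return list with unit vectors `u`, `w`, `v` and `theta`.
#' @export
view_geometry <- function(theta) {
  list(u = c(cos(theta), sin(theta), 0),
       w = c(-sin(theta), cos(theta), 0),
       v = c(0, 0, 1), theta = theta)
}

# index-unit DFT frequencies (numpy fftfreq convention, as fractions of fs)
fftfreq_idx <- function(n) {
  k <- 0:(n - 1)
  ifelse(k < (n + 1) %/% 2, k, k - n)
}

# Continuous-Fourier-transform approximation of an array sampled on a
# centered grid: Delta^d-scaled DFT with per-axis phase correction for the
# grid origin, reordered to ascending frequencies. Returns values + freqs.
ctft_nd <- function(arr, delta) {
  d <- dim(arr); nd <- length(d)
  f <- stats::fft(arr)
  freqs <- vector("list", nd)
  for (ax in seq_len(nd)) {
    n <- d[ax]
    w <- 2 * pi * fftfreq_idx(n) / (n * delta)
    ph <- exp(1i * w * (n - 1) / 2 * delta)  # grid starts at -(n-1)/2*delta
    shp <- rep(1L, nd); shp[ax] <- n
    f <- f * array(rep(ph, each = prod(d[seq_len(ax - 1L)])), dim = d)
    ord <- order(fftfreq_idx(n))
    idx <- rep(list(quote(expr = )), nd)
    idx[[ax]] <- ord
    f <- do.call(`[`, c(list(f), idx, list(drop = FALSE)))
    freqs[[ax]] <- sort(w)
  }
  list(values = f * delta^nd, freqs = freqs)
}

#' Parallel-beam X-ray projection
#'
#' Forward projector for rotation about the z axis. For each angle the
#' volume is resampled into the rotated frame by bilinear interpolation in
#' the (x, y) plane (the detector v axis coincides with z, so every v row
#' is a 2D Radon projection of the matching z-slice), values outside the
#' grid are zero, and the line integral is a Riemann sum along the ray with
#' step equal to the voxel spacing. The detector grid equals the volume's
#' (x, z) grid.
#'
#' @param vol a [volume3d()].
#' @param angles numeric vector of angles in radians, in `[0, 2*pi)`.
#' @param interp in-plane resampling scheme: `"cubic"` (cubic-convolution,
#'   third-order accurate; the default) or `"linear"` (bilinear).
#' @return a [projection_stack()].
#' @export
xray_project <- function(vol, angles, interp = c("cubic", "linear")) {
  interp <- match.arg(interp)
  sampler <- if (interp == "cubic") bicubic_slices else bilinear_slices
  if (length(angles) == 0L) stop("`angles` must contain at least one angle")
  if (any(angles < 0 | angles >= 2 * pi))
    stop("angles must lie in [0, 2*pi)")
  d <- dim(vol$values); nx <- d[1]; ny <- d[2]; nz <- d[3]
  delta <- vol$spacing
  u <- grid_coords(nx, delta)
  tmax <- sqrt(2) * max(abs(range(grid_coords(nx, delta)))) + delta
  tgrid <- seq(-tmax, tmax, by = delta)
  nt <- length(tgrid)
  V <- matrix(vol$values, nx * ny, nz)
  out <- array(0, c(nx, nz, length(angles)))
  for (k in seq_along(angles)) {
    th <- angles[k]
    xq <- rep(u, times = nt) * cos(th) - rep(tgrid, each = nx) * sin(th)
    yq <- rep(u, times = nt) * sin(th) + rep(tgrid, each = nx) * cos(th)
    samp <- sampler(V, nx, ny, delta, xq, yq)  # (nx*nt, nz)
    dim(samp) <- c(nx, nt, nz)
    out[, , k] <- colSums(aperm(samp, c(2, 1, 3))) * delta
  }
  projection_stack(out, angles, delta)
}

#' Fourier slice theorem discrepancy
#'
#' Computes the 2D Fourier transform of the numeric projection at angle
#' `theta` and compares it against the central slice of the volume's 3D
#' Fourier transform through the plane with normal along the ray direction
#' (interpolated from the 3D DFT grid). Both sides use the same
#' non-unitary, phase-corrected continuous-transform approximation, so
#' their relative L2 discrepancy measures how well the slice theorem holds
#' at the grid's resolution.
#'
#' @param vol a cubic [volume3d()].
#' @param theta angle in radians.
#' @param pad zero-padding factor before the transforms; padding refines
#'   the frequency grid (band-limited interpolation), which controls the
#'   in-plane interpolation error of the central slice for spectra that
#'   decay slowly (discontinuous phantoms).
#' @return scalar relative L2 discrepancy.
#' @export
fourier_slice_check <- function(vol, theta, pad = 2) {
  d <- dim(vol$values)
  if (length(unique(d)) != 1L) stop("`vol` must be cubic")
  n0 <- d[1]; delta <- vol$spacing
  proj <- xray_project(vol, theta)$data[, , 1]
  n <- pad * n0
  # center the data in the padded box: pad - 1 times n0 extra zeros split
  # evenly keeps samples on the centered-grid positions of the larger box
  j0 <- (n - n0) / 2
  pp <- matrix(0, n, n); pp[j0 + seq_len(n0), j0 + seq_len(n0)] <- proj
  pv <- array(0, c(n, n, n))
  pv[j0 + seq_len(n0), j0 + seq_len(n0), j0 + seq_len(n0)] <- vol$values
  lhs <- ctft_nd(pp, delta)
  f3 <- ctft_nd(pv, delta)
  wgrid <- f3$freqs[[1]]
  dw <- wgrid[2] - wgrid[1]
  # sample F3 at (wu*cos, wu*sin, wz): interpolation in the (wx, wy) plane
  wu <- lhs$freqs[[1]]
  xq <- wu * cos(theta)
  yq <- wu * sin(theta)
  # the DFT frequency grid of an even-length axis is asymmetric (extra
  # negative Nyquist bin); recenter queries on the grid midpoint before
  # using the centered-grid interpolator
  wmid <- (wgrid[1] + wgrid[n]) / 2
  Vr <- matrix(Re(f3$values), n * n, n)
  Vi <- matrix(Im(f3$values), n * n, n)
  rhs <- bicubic_slices(Vr, n, n, dw, xq - wmid, yq - wmid) +
    1i * bicubic_slices(Vi, n, n, dw, xq - wmid, yq - wmid)
  diffn <- sqrt(sum(Mod(lhs$values - rhs)^2))
  refn <- sqrt(sum(Mod(rhs)^2))
  diffn / refn
}

#' Filtered backprojection inverse
#'
#' Per-slice 2D filtered backprojection: each projection's u-profiles are
#' ramp-filtered in the frequency domain (Ram-Lak, DC term zero, optional
#' Hann apodization), then backprojected over angles with linear
#' interpolation. Because the detector v axis equals z, each v row
#' reconstructs the corresponding z-slice. Angles are assumed to cover
#' `[0, pi)` or `[0, 2*pi)` approximately uniformly.
#'
#' @param stack a [projection_stack()] with at least 2 angles.
#' @param hann logical; apply a Hann window to the ramp filter.
#' @return a [volume3d()] on the grid implied by the detector grid.
#' @export
fbp_inverse <- function(stack, hann = FALSE) {
  d <- dim(stack$data); nu <- d[1]; nv <- d[2]; na <- d[3]
  if (na < 2L) stop("filtered backprojection needs at least 2 angles")
  delta <- stack$spacing
  L <- 2^ceiling(log2(2 * nu))
  cfrac <- fftfreq_idx(L) / L
  filt <- abs(cfrac) / delta
  if (hann) filt <- filt * (0.5 * (1 + cos(2 * pi * cfrac)))
  M <- matrix(0, L, nv * na)
  M[seq_len(nu), ] <- stack$data
  Q <- Re(stats::mvfft(stats::mvfft(M) * filt, inverse = TRUE)) / L
  Q <- array(Q[seq_len(nu), ], c(nu, nv, na))
  g <- grid_coords(nu, delta)
  xs <- rep(g, times = nu)
  ys <- rep(g, each = nu)
  c0 <- (nu - 1) / 2
  acc <- matrix(0, nu * nu, nv)
  for (k in seq_len(na)) {
    th <- stack$angles[k]
    gi <- (xs * cos(th) + ys * sin(th)) / delta + c0
    i0 <- floor(gi)
    fx <- gi - i0
    inside <- i0 >= 0 & i0 <= nu - 2
    i0c <- pmin(pmax(i0, 0), nu - 2) + 1
    w0 <- ifelse(inside, 1 - fx, 0)
    w1 <- ifelse(inside, fx, 0)
    Qk <- Q[, , k]
    acc <- acc + w0 * Qk[i0c, , drop = FALSE] + w1 * Qk[i0c + 1, , drop = FALSE]
  }
  vals <- array(acc * (pi / na), c(nu, nu, nv))
  volume3d(vals, extent = nu * delta / 2)
}
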