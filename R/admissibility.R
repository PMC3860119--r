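#' Zero-mean residual of a wavelet
#'
#' Grid quadrature of the wavelet over its support cube; returns the mean
#' integral relative to the L1 norm. A mother wavelet must have (numerically)
#' zero mean — equivalently a vanishing Fourier transform at the origin.
#'
#' @param wavelet a `mother_wavelet3d` or `projected_wavelet2d`.
#' @param theta angle at which to evaluate a projected wavelet; ignored for
#'   3D wavelets.
#' @param n quadrature points per axis.
#' @param tol pass threshold on `|mean| / L1`.
#' @return list with `residual`, `mean`, `l1` and logical `pass`.
#' @export
zero_mean_residual <- function(wavelet, theta = 0, n = 81, tol = 1e-8) {
  if (inherits(wavelet, "mother_wavelet3d")) {
    m <- wavelet_moments3d(wavelet, n)
  } else {
    r <- 1.5 * wavelet$support_radius
    g <- seq(-r, r, length.out = n)
    dd <- (g[2] - g[1])^2
    v <- wavelet$evaluate(outer(g, rep(1, n)), outer(rep(1, n), g), theta)
    m <- list(mean = sum(v) * dd, l1 = sum(abs(v)) * dd)
  }
  res <- if (m$l1 > 0) abs(m$mean) / m$l1 else 0
  list(residual = res, mean = m$mean, l1 = m$l1, pass = res <= tol)
}

# Fourier modulus-squared of a wavelet at frequency points; dispatches on
# analytic forms (3D) or the projected 2D form at an angle.
.fourier_mod2 <- function(wavelet, theta = 0) {
  if (inherits(wavelet, "mother_wavelet3d")) {
    if (is.null(wavelet$fourier))
      stop("wavelet has no analytic Fourier form; rasterized checks only")
    function(wx, wy, wz) Mod(wavelet$fourier(wx, wy, wz))^2
  } else {
    if (is.null(wavelet$fourier2d))
      stop("projected wavelet has no analytic Fourier form")
    function(wu, wv) Mod(wavelet$fourier2d(wu, wv, theta))^2
  }
}

#' Admissibility integral certificate
#'
#' Numerically certifies the admissibility condition
#' `integral |psihat(w)|^2 / |w|^n dw < infinity` by quadrature in
#' spherical (n = 3) or polar (n = 2) coordinates, where the `|w|^(n-1)`
#' Jacobian cancels the singularity when `psihat(0) = 0`. "Finite" is
#' operationalized as convergence: the estimate at doubled radial
#' resolution and doubled domain radius must agree with the base estimate
#' within `tol` relative (default 1%). Functions with nonzero mean (for
#' which the integral diverges logarithmically, e.g. the plain Gaussian)
#' fail the gate.
#'
#' @param wavelet a `mother_wavelet3d` or `projected_wavelet2d` with an
#'   analytic Fourier form.
#' @param n dimensionality of the condition (2 or 3); defaults to the
#'   wavelet's own.
#' @param theta angle for projected wavelets.
#' @param rmax radial truncation; default `10 / sigma` (the Gaussian forms
#'   decay like `exp(-sigma^2 rho^2 / 2)`).
#' @param nr radial quadrature cells at base resolution.
#' @param nang angular points per angular coordinate.
#' @param tol relative convergence tolerance.
#' @return list with `value` (finer estimate), `coarse`, `rel_change`,
#'   logical `converged`, and `pass` (converged and zero-mean holds).
#' @export
check_admissibility_nd <- function(wavelet, n = wavelet$ndim, theta = 0,
                                   rmax = NULL, nr = 200, nang = 90,
                                   tol = 0.01) {
  stopifnot(n %in% c(2L, 3L))
  mod2 <- .fourier_mod2(wavelet, theta)
  if (is.null(rmax)) rmax <- 10 / wavelet$sigma
  quad <- function(R, ncell) {
    h <- R / ncell
    rho <- (seq_len(ncell) - 0.5) * h
    if (n == 3L) {
      lam <- seq(0, 2 * pi, length.out = nang + 1)[-(nang + 1)]
      phi <- (seq_len(nang) - 0.5) * pi / nang
      dlam <- 2 * pi / nang; dphi <- pi / nang
      tot <- 0
      for (p in phi) {
        sx <- outer(rho * sin(p), cos(lam))
        sy <- outer(rho * sin(p), sin(lam))
        sz <- matrix(rho * cos(p), length(rho), nang)
        # |w|^(n-1) Jacobian / |w|^n = 1/rho (rho^2 sin(phi) volume element)
        tot <- tot + sum(mod2(sx, sy, sz) / rho) * sin(p) * h * dlam * dphi
      }
      tot
    } else {
      alp <- seq(0, 2 * pi, length.out = nang + 1)[-(nang + 1)]
      dalp <- 2 * pi / nang
      su <- outer(rho, cos(alp))
      sv <- outer(rho, sin(alp))
      sum(mod2(su, sv) / rho) * h * dalp
    }
  }
  coarse <- quad(rmax, nr)
  fine <- quad(2 * rmax, 4 * nr)
  rel <- if (fine != 0) abs(fine - coarse) / abs(fine) else 0
  zm <- if (inherits(wavelet, "mother_wavelet3d") && !wavelet$admissible)
    FALSE else TRUE
  list(value = fine, coarse = coarse, rel_change = rel,
       converged = rel <= tol, pass = (rel <= tol) && zm)
}

#' Uniform Fourier energy bound over low in-plane frequencies
#'
#' Approximates `max over theta, |w_u| <= 1` of
#' `integral |F2 P_theta psi(w_u, w_v)|^2 dw_v` on a grid of angles and
#' in-plane frequencies (midpoint quadrature in `w_v`). Finiteness of this
#' supremum is the condition under which the projection of a
#' square-integrable 3D wavelet remains square-integrable.
#'
#' @param pw a `projected_wavelet2d` with analytic 2D Fourier form.
#' @param n_theta angle grid size over `[0, 2*pi)`.
#' @param n_wu grid size over `w_u` in `[-1, 1]`.
#' @param wv_max truncation for the `w_v` quadrature; default `10 / sigma`.
#' @param n_wv quadrature cells in `w_v`.
#' @return list with `k` (the max), `theta_at`, `wu_at`, and the integral
#'   matrix `values` (`n_theta` by `n_wu`).
#' @export
theorem3_bound <- function(pw, n_theta = 360, n_wu = 201, wv_max = NULL,
                           n_wv = 400) {
  if (is.null(wv_max)) wv_max <- 10 / pw$sigma
  thetas <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  wu <- seq(-1, 1, length.out = n_wu)
  h <- 2 * wv_max / n_wv
  wv <- -wv_max + (seq_len(n_wv) - 0.5) * h
  WU <- outer(wu, rep(1, n_wv))
  WV <- outer(rep(1, n_wu), wv)
  vals <- matrix(0, n_theta, n_wu)
  for (i in seq_along(thetas)) {
    vals[i, ] <- rowSums(Mod(pw$fourier2d(WU, WV, thetas[i]))^2) * h
  }
  idx <- which(vals == max(vals), arr.ind = TRUE)[1, ]
  list(k = max(vals), theta_at = thetas[idx[1]], wu_at = wu[idx[2]],
       values = vals, thetas = thetas, wu = wu)
}

#' Per-angle 2D admissibility integral of a projected wavelet
#'
#' Polar quadrature of
#' `integral |F2 P_theta psi|^2 (w_u^2 + w_v^2)^(-1) dw_u dw_v` at one
#' angle, with the same convergence gate as [check_admissibility_nd()].
#'
#' @inheritParams check_admissibility_nd
#' @param pw a `projected_wavelet2d`.
#' @return list as in [check_admissibility_nd()].
#' @export
eq19_integral <- function(pw, theta, rmax = NULL, nr = 200, nang = 180,
                          tol = 0.01) {
  check_admissibility_nd(pw, n = 2L, theta = theta, rmax = rmax, nr = nr,
                         nang = nang, tol = tol)
}

#' Full 2D mother-wavelet certificate for a projected wavelet
#'
#' Combines the per-angle 2D admissibility integral and the uniform Fourier
#' energy bound; the projected wavelet is certified as a 2D mother wavelet
#' when both are finite (convergent) at every angle on the grid. Angles at
#' which the direction factor vanishes give an identically zero projection
#' whose integrals are zero; these count as (trivially) convergent.
#'
#' @param pw a `projected_wavelet2d`.
#' @param thetas angle grid; default 36 uniform angles over `[0, 2*pi)`.
#' @param ... passed to [eq19_integral()] and [theorem3_bound()].
#' @return an `admissibility_report` with fields `eq19` (per-angle values),
#'   `k_sup`, per-condition flags and overall `pass`.
#' @export
theorem4_certificate <- function(pw,
                                 thetas = seq(0, 2 * pi,
                                              length.out = 37)[-37],
                                 ...) {
  eq19 <- vapply(thetas, function(th) {
    r <- eq19_integral(pw, th)
    c(r$value, r$converged)
  }, numeric(2))
  t3 <- theorem3_bound(pw)
  zm <- zero_mean_residual(pw, theta = thetas[which.max(eq19[1, ])])
  flags <- list(
    eq19_converged = all(as.logical(eq19[2, ])),
    k_finite = is.finite(t3$k),
    zero_mean = zm$pass)
  structure(list(wavelet = pw$name, thetas = thetas,
                 eq19_integral = eq19[1, ], k_sup = t3$k,
                 k_theta_at = t3$theta_at, k_wu_at = t3$wu_at,
                 zero_mean = zm, flags = flags,
                 pass = all(unlist(flags))),
            class = "admissibility_report")
}

#' @export
print.admissibility_report <- function(x, ...) {
  cat(sprintf("<admissibility_report> %s: %s\n", x$wavelet,
              if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  k_sup = %.6g at theta = %.3f, wu = %.3f\n",
              x$k_sup, x$k_theta_at, x$k_wu_at))
  cat(sprintf("  eq19 integral over %d angles: range [%.3g, %.3g]\n",
              length(x$thetas), min(x$eq19_integral), max(x$eq19_integral)))
  for (nm in names(x$flags))
    cat(sprintf("  %-16s %s\n", nm, if (x$flags[[nm]]) "ok" else "FAIL"))
  invisible(x)
}

#' Compact-support energy inequality
#'
#' For a compactly supported wavelet vanishing outside the ball of radius
#' `r`, the Cauchy-Schwarz bound
#' `integral (P_theta psi)^2 du dv <= 2 r * integral psi^2 dx` guarantees
#' square-integrability of every projection. Both sides are evaluated on
#' rasters (numeric projection for the left side) over a grid of angles.
#'
#' @param wavelet a compactly supported `mother_wavelet3d` (see
#'   [truncate_wavelet()]).
#' @param thetas angle grid; default 36 uniform angles in `[0, 2*pi)`.
#' @param n raster size per axis.
#' @param tol relative slack in the flag.
#' @return list with per-angle `lhs`, scalar `rhs`, radius `r` and logical
#'   `pass`.
#' @export
theorem6_energy_bound <- function(wavelet,
                                  thetas = seq(0, 2 * pi,
                                               length.out = 37)[-37],
                                  n = 97, tol = 1e-6) {
  if (!inherits(wavelet, "mother_wavelet3d") || !wavelet$compact)
    stop("`wavelet` must be a compactly supported 3D wavelet")
  r <- wavelet$support_radius
  delta <- 2 * r / n
  g <- grid_coords(n, delta)
  xs <- rep(g, times = n * n)
  ys <- rep(rep(g, each = n), times = n)
  zs <- rep(g, each = n * n)
  vol <- volume3d(array(wavelet$evaluate(xs, ys, zs), c(n, n, n)), extent = r)
  rhs <- 2 * r * sum(vol$values^2) * delta^3
  st <- xray_project(vol, thetas)
  lhs <- apply(st$data, 3, function(p) sum(p^2) * delta^2)
  list(lhs = lhs, rhs = rhs, r = r, thetas = thetas,
       pass = all(lhs <= rhs * (1 + tol)))
}

#' Parseval (Plancherel) discrepancy of a raster
#'
#' Compares the spatial L2 norm of a sampled function with its
#' `(2*pi)^(-n/2)`-scaled frequency-domain L2 norm under the package's
#' non-unitary Fourier convention. The discrete transform satisfies the
#' relation exactly up to floating-point error, so the discrepancy measures
#' only numerical conditioning.
#'
#' @param arr numeric array (any dimensionality).
#' @param delta sample spacing.
#' @return scalar relative discrepancy.
#' @export
parseval_check <- function(arr, delta) {
  d <- dim(arr) %||% length(arr)
  nd <- length(d)
  spatial <- sqrt(sum(arr^2) * delta^nd)
  fhat <- stats::fft(arr) * delta^nd
  dw <- 2 * pi / (d * delta)
  freq <- (2 * pi)^(-nd / 2) * sqrt(sum(Mod(fhat)^2) * prod(dw))
  abs(spatial - freq) / spatial
}
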