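#' Mother wavelet objects
#'
#' A `mother_wavelet3d` packages a pointwise evaluation rule
#' `psi(x, y, z)`, its analytic 3D Fourier transform when known (non-unitary
#' angular-frequency convention, forward kernel `exp(-1i * w . x)`), an
#' effective support radius, and flags for compact support and expected
#' admissibility. A `projected_wavelet2d` represents the X-ray projection of
#' a 3D wavelet as `kappa * d(theta) * profile(u, v)`: a theta-independent
#' base profile times an angle-dependent direction factor `d(theta)` in
#' `{cos, sin, 1}` and an exact line-integral constant `kappa`.
#'
#' @name wavelet-objects
#' @keywords internal
NULL

new_mother_wavelet3d <- function(name, sigma, evaluate, fourier = NULL,
                                 support_radius, compact = FALSE,
                                 admissible = TRUE) {
  structure(list(name = name, sigma = sigma, evaluate = evaluate,
                 fourier = fourier, support_radius = support_radius,
                 compact = compact, admissible = admissible, ndim = 3L),
            class = "mother_wavelet3d")
}

new_projected_wavelet2d <- function(name, sigma, kappa, profile, dirfactor,
                                    fourier2d = NULL, support_radius) {
  evaluate <- function(u, v, theta) kappa * dirfactor(theta) * profile(u, v)
  structure(list(name = name, sigma = sigma, kappa = kappa, profile = profile,
                 dirfactor = dirfactor, evaluate = evaluate,
                 fourier2d = fourier2d, support_radius = support_radius,
                 compact = FALSE, ndim = 2L),
            class = "projected_wavelet2d")
}

#' @export
print.mother_wavelet3d <- function(x, ...) {
  cat(sprintf("<mother_wavelet3d> %s (sigma = %g, support %g%s%s)\n",
              x$name, x$sigma, x$support_radius,
              if (x$compact) ", compact" else "",
              if (x$admissible) "" else ", NOT admissible"))
  invisible(x)
}

#' @export
print.projected_wavelet2d <- function(x, ...) {
  cat(sprintf("<projected_wavelet2d> %s (sigma = %g, kappa = %g)\n",
              x$name, x$sigma, x$kappa))
  invisible(x)
}

#' Isotropic 3D Gaussian (smoothing kernel, not a wavelet)
#'
#' `g(x, y, z) = exp(-(x^2+y^2+z^2)/(2 sigma^2))`. Its mean is nonzero, so
#' it fails the zero-mean admissibility requirement and is flagged
#' `admissible = FALSE`; it exists as the smoothing kernel whose partial
#' derivatives are the admissible wavelets.
#'
#' @param sigma width, strictly positive; default 1.
#' @return a `mother_wavelet3d` with `admissible = FALSE`.
#' @export
gaussian_3d <- function(sigma = 1) {
  stopifnot(sigma > 0)
  s2 <- sigma^2
  new_mother_wavelet3d(
    name = "gauss", sigma = sigma,
    evaluate = function(x, y, z) exp(-(x^2 + y^2 + z^2) / (2 * s2)),
    fourier = function(wx, wy, wz)
      (2 * pi)^(3 / 2) * sigma^3 * exp(-s2 * (wx^2 + wy^2 + wz^2) / 2),
    support_radius = 6 * sigma, admissible = FALSE)
}

#' First x- and y-derivative-of-Gaussian 3D wavelets
#'
#' `psi1 = d g / d x = -(x / sigma^2) g` and `psi2 = d g / d y`. Both have
#' zero mean by odd symmetry and finite admissibility integrals, so they are
#' mother wavelets; their X-ray projections carry a `cos(theta)` (resp.
#' `sin(theta)`) direction factor.
#'
#' @inheritParams gaussian_3d
#' @return a `mother_wavelet3d`.
#' @export
psi1 <- function(sigma = 1) {
  stopifnot(sigma > 0)
  s2 <- sigma^2
  new_mother_wavelet3d(
    name = "dgauss-x", sigma = sigma,
    evaluate = function(x, y, z)
      -(x / s2) * exp(-(x^2 + y^2 + z^2) / (2 * s2)),
    fourier = function(wx, wy, wz)
      1i * wx * (2 * pi)^(3 / 2) * sigma^3 *
        exp(-s2 * (wx^2 + wy^2 + wz^2) / 2),
    support_radius = 6 * sigma)
}

#' @rdname psi1
#' @export
psi2 <- function(sigma = 1) {
  stopifnot(sigma > 0)
  s2 <- sigma^2
  new_mother_wavelet3d(
    name = "dgauss-y", sigma = sigma,
    evaluate = function(x, y, z)
      -(y / s2) * exp(-(x^2 + y^2 + z^2) / (2 * s2)),
    fourier = function(wx, wy, wz)
      1i * wy * (2 * pi)^(3 / 2) * sigma^3 *
        exp(-s2 * (wx^2 + wy^2 + wz^2) / 2),
    support_radius = 6 * sigma)
}

#' @rdname psi1
#' @export
psi3 <- function(sigma = 1) {
  stopifnot(sigma > 0)
  s2 <- sigma^2
  new_mother_wavelet3d(
    name = "dgauss-z", sigma = sigma,
    evaluate = function(x, y, z)
      -(z / s2) * exp(-(x^2 + y^2 + z^2) / (2 * s2)),
    fourier = function(wx, wy, wz)
      1i * wz * (2 * pi)^(3 / 2) * sigma^3 *
        exp(-s2 * (wx^2 + wy^2 + wz^2) / 2),
    support_radius = 6 * sigma)
}

#' 3D Mexican-hat wavelet
#'
#' Negative Laplacian of the Gaussian,
#' `(3/sigma^2 - r^2/sigma^4) * exp(-r^2/(2 sigma^2))`, with the sign fixed
#' so the value at the origin is positive. Zero mean holds analytically.
#'
#' @inheritParams gaussian_3d
#' @return a `mother_wavelet3d`.
#' @export
mexican_hat_3d <- function(sigma = 1) {
  stopifnot(sigma > 0)
  s2 <- sigma^2
  new_mother_wavelet3d(
    name = "mexican3d", sigma = sigma,
    evaluate = function(x, y, z) {
      r2 <- x^2 + y^2 + z^2
      (3 / s2 - r2 / s2^2) * exp(-r2 / (2 * s2))
    },
    fourier = function(wx, wy, wz) {
      w2 <- wx^2 + wy^2 + wz^2
      w2 * (2 * pi)^(3 / 2) * sigma^3 * exp(-s2 * w2 / 2)
    },
    support_radius = 6 * sigma)
}

#' Projected derivative-of-Gaussian wavelets
#'
#' Closed-form X-ray projections of [psi1()] / [psi2()]:
#' `P_theta psi1(u, v) = kappa * cos(theta) * (-u/sigma^2) *
#' exp(-(u^2+v^2)/(2 sigma^2))` with the exact line-integral constant
#' `kappa = sigma * sqrt(2*pi)` (and `sin(theta)` for `psi2`). At angles
#' where the direction factor vanishes the projection is identically zero.
#' Setting `kappa = 1` reproduces the constant-free normalization some
#' treatments use.
#'
#' @inheritParams gaussian_3d
#' @param kappa multiplicative constant; default the exact line integral
#'   `sigma * sqrt(2*pi)`.
#' @return a `projected_wavelet2d`.
#' @export
projected_psi1 <- function(sigma = 1, kappa = sigma * sqrt(2 * pi)) {
  stopifnot(sigma > 0)
  s2 <- sigma^2
  new_projected_wavelet2d(
    name = "proj-dgauss-x", sigma = sigma, kappa = kappa,
    profile = function(u, v) -(u / s2) * exp(-(u^2 + v^2) / (2 * s2)),
    dirfactor = function(theta) cos(theta),
    fourier2d = function(wu, wv, theta)
      kappa * cos(theta) * 1i * wu * 2 * pi * s2 *
        exp(-s2 * (wu^2 + wv^2) / 2),
    support_radius = 6 * sigma)
}

#' @rdname projected_psi1
#' @export
projected_psi2 <- function(sigma = 1, kappa = sigma * sqrt(2 * pi)) {
  stopifnot(sigma > 0)
  s2 <- sigma^2
  new_projected_wavelet2d(
    name = "proj-dgauss-y", sigma = sigma, kappa = kappa,
    profile = function(u, v) -(u / s2) * exp(-(u^2 + v^2) / (2 * s2)),
    dirfactor = function(theta) sin(theta),
    fourier2d = function(wu, wv, theta)
      kappa * sin(theta) * 1i * wu * 2 * pi * s2 *
        exp(-s2 * (wu^2 + wv^2) / 2),
    support_radius = 6 * sigma)
}

#' Projected 3D Mexican hat
#'
#' The X-ray projection of the 3D Mexican hat is the 2D Mexican hat scaled
#' by the line-integral constant: projecting the negative 3D Laplacian of a
#' Gaussian integrates out the along-ray second derivative (its integral
#' vanishes) and leaves the negative 2D Laplacian of the projected Gaussian.
#' Direction factor is identically 1 (isotropy).
#'
#' @inheritParams projected_psi1
#' @return a `projected_wavelet2d`.
#' @export
projected_mexican_hat <- function(sigma = 1, kappa = sigma * sqrt(2 * pi)) {
  stopifnot(sigma > 0)
  s2 <- sigma^2
  new_projected_wavelet2d(
    name = "proj-mexican", sigma = sigma, kappa = kappa,
    profile = function(u, v) {
      r2 <- u^2 + v^2
      (2 / s2 - r2 / s2^2) * exp(-r2 / (2 * s2))
    },
    dirfactor = function(theta) rep(1, length(theta)),
    fourier2d = function(wu, wv, theta) {
      w2 <- wu^2 + wv^2
      kappa * w2 * 2 * pi * s2 * exp(-s2 * w2 / 2)
    },
    support_radius = 6 * sigma)
}

#' Scale and translate a wavelet
#'
#' The L2-norm-preserving wavelet family
#' `psi_{a,b}(x) = a^{-n/2} psi((x - b)/a)`, where `n` is the wavelet's
#' dimensionality (3 for volume wavelets, 2 for projected ones).
#'
#' @param wavelet a `mother_wavelet3d` or `projected_wavelet2d`.
#' @param a scale, strictly positive.
#' @param b translation vector (length 3 or 2 to match); default origin.
#' @return same kind of object as `wavelet`.
#' @export
family_scale_translate <- function(wavelet, a, b = NULL) {
  if (a <= 0) stop("scale `a` must be strictly positive")
  n <- wavelet$ndim
  if (is.null(b)) b <- numeric(n)
  stopifnot(length(b) == n)
  w <- wavelet
  norm <- a^(-n / 2)
  if (n == 3L) {
    ev <- wavelet$evaluate
    w$evaluate <- function(x, y, z)
      norm * ev((x - b[1]) / a, (y - b[2]) / a, (z - b[3]) / a)
    if (!is.null(wavelet$fourier)) {
      fo <- wavelet$fourier
      w$fourier <- function(wx, wy, wz)
        a^(n / 2) * fo(a * wx, a * wy, a * wz) *
          exp(-1i * (wx * b[1] + wy * b[2] + wz * b[3]))
    }
  } else {
    pr <- wavelet$profile
    w$profile <- function(u, v) norm * pr((u - b[1]) / a, (v - b[2]) / a)
    kap <- wavelet$kappa; dirf <- wavelet$dirfactor; prof <- w$profile
    w$evaluate <- function(u, v, theta) kap * dirf(theta) * prof(u, v)
    if (!is.null(wavelet$fourier2d)) {
      fo <- wavelet$fourier2d
      w$fourier2d <- function(wu, wv, theta)
        a^(n / 2) * fo(a * wu, a * wv, theta) *
          exp(-1i * (wu * b[1] + wv * b[2]))
    }
  }
  w$support_radius <- wavelet$support_radius * a
  w$scale <- a
  w$shift <- b
  w
}

#' Truncate a wavelet to compact support
#'
#' Multiplies the evaluation rule by the indicator of the ball of radius
#' `r`, producing a compactly supported wavelet (as required by the
#' compact-support energy inequality). The analytic Fourier form is dropped
#' (truncation has no elementary transform); numeric routes are used
#' instead.
#'
#' @param wavelet a `mother_wavelet3d`.
#' @param r truncation radius, world units.
#' @return a compactly supported `mother_wavelet3d`.
#' @export
truncate_wavelet <- function(wavelet, r) {
  stopifnot(inherits(wavelet, "mother_wavelet3d"), r > 0)
  w <- wavelet
  ev <- wavelet$evaluate
  w$evaluate <- function(x, y, z)
    ev(x, y, z) * ((x^2 + y^2 + z^2) <= r^2)
  w$fourier <- NULL
  w$support_radius <- r
  w$compact <- TRUE
  w$name <- sprintf("%s-trunc%g", wavelet$name, r)
  w
}

#' Look up a wavelet by name
#'
#' Names usable from the command line and config files: `"dgauss-x"`,
#' `"dgauss-y"`, `"dgauss-z"`, `"mexican3d"`, `"gauss"`.
#'
#' @param name wavelet name.
#' @param sigma width parameter.
#' @return a `mother_wavelet3d`.
#' @export
wavelet_by_name <- function(name, sigma = 1) {
  known <- c("dgauss-x", "dgauss-y", "dgauss-z", "mexican3d", "gauss")
  switch(name,
    "dgauss-x" = psi1(sigma),
    "dgauss-y" = psi2(sigma),
    "dgauss-z" = psi3(sigma),
    "mexican3d" = mexican_hat_3d(sigma),
    "gauss" = gaussian_3d(sigma),
    stop(sprintf("unknown wavelet '%s'; known names: %s",
                 name, paste(known, collapse = ", "))))
}

#' Rasterize a 3D wavelet kernel
#'
#' Samples `a^{-3/2} psi(x/a)` on an odd-sized cube with the given spacing,
#' truncated at `trunc_mult * sigma * a` (default 4), center tap at the
#' origin. Values only; convolution routines supply the volume element.
#'
#' @param wavelet a `mother_wavelet3d`.
#' @param delta grid spacing.
#' @param a scale, strictly positive.
#' @param trunc_mult truncation radius in units of `sigma * a`.
#' @return odd-sized numeric 3D array.
#' @export
rasterize_wavelet3d <- function(wavelet, delta, a = 1, trunc_mult = 4) {
  stopifnot(a > 0)
  h <- max(1L, ceiling(trunc_mult * wavelet$sigma * a / delta))
  g <- (-h:h) * delta
  m <- length(g)
  xs <- rep(g, times = m * m)
  ys <- rep(rep(g, each = m), times = m)
  zs <- rep(g, each = m * m)
  vals <- a^(-3 / 2) * wavelet$evaluate(xs / a, ys / a, zs / a)
  array(vals, c(m, m, m))
}

#' Rasterize a projected 2D wavelet kernel
#'
#' Samples the projected wavelet at angle `theta` on an odd-sized square.
#' Two normalizations: `"xray"` (default) rasterizes the X-ray projection of
#' the 3D family member `a^{-3/2} psi(x/a)`, which scales as
#' `a^{-1/2} P psi((u,v)/a)` and is what the projection-domain realization
#' of the 3D transform needs; `"family"` uses the intrinsic 2D family
#' normalization `a^{-1}`.
#'
#' @param pw a `projected_wavelet2d`.
#' @param theta angle, radians.
#' @param delta grid spacing.
#' @param a scale, strictly positive.
#' @param trunc_mult truncation radius in units of `sigma * a`.
#' @param norm `"xray"` or `"family"`.
#' @return odd-sized numeric matrix.
#' @export
rasterize_projected2d <- function(pw, theta, delta, a = 1, trunc_mult = 4,
                                  norm = c("xray", "family")) {
  stopifnot(a > 0)
  norm <- match.arg(norm)
  h <- max(1L, ceiling(trunc_mult * pw$sigma * a / delta))
  g <- (-h:h) * delta
  fac <- if (norm == "xray") a^(-1 / 2) else a^(-1)
  fac * pw$evaluate(outer(g, rep(1, length(g))) / a,
                    outer(rep(1, length(g)), g) / a, theta)
}

# Grid-quadrature moments of a 3D wavelet: mean integral, L1 and L2
# norms. Integrates over 1.5x the support radius so that truncation tails
# of polynomially weighted Gaussians stay below the zero-mean tolerance.
wavelet_moments3d <- function(wavelet, n = 81) {
  r <- 1.5 * wavelet$support_radius
  g <- seq(-r, r, length.out = n)
  dd <- (g[2] - g[1])^3
  xs <- rep(g, times = n * n)
  ys <- rep(rep(g, each = n), times = n)
  zs <- rep(g, each = n * n)
  v <- wavelet$evaluate(xs, ys, zs)
  list(mean = sum(v) * dd, l1 = sum(abs(v)) * dd, l2sq = sum(v^2) * dd)
}
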