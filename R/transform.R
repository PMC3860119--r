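# n-D linear convolution via zero-padded FFT, cropped to "same" size
# centered on the kernel's center. True convolution: the FFT product
# implements the flipped-kernel sum, so odd kernels keep their sign.
# `scale` supplies the cell area/volume so discrete results approximate
# the continuous convolution integral. For odd kernel sizes the center tap
# sits on the grid and the crop is exact; for even sizes (e.g. convolving
# two whole volumes on a centered even grid) the continuous result lives
# half a sample off the grid, and a band-limited Fourier half-sample shift
# brings it back before cropping.
conv_fft_same <- function(x, k, scale = 1) {
  dx <- dim(x); dk <- dim(k)
  if (any(dk > dx)) stop("kernel must not be larger than the data")
  nd <- length(dx)
  np <- vapply(dx + dk - 1, stats::nextn, integer(1), factors = c(2, 3, 5))
  px <- array(0, np); pk <- array(0, np)
  ix <- lapply(seq_len(nd), function(i) seq_len(dx[i]))
  ik <- lapply(seq_len(nd), function(i) seq_len(dk[i]))
  px <- do.call(`[<-`, c(list(px), ix, list(x)))
  pk <- do.call(`[<-`, c(list(pk), ik, list(k)))
  prod_f <- stats::fft(px) * stats::fft(pk)
  off <- (dk - 1) / 2
  ci <- floor(off)
  frac <- off - ci
  for (ax in seq_len(nd)) {
    if (frac[ax] > 0) {
      ph <- exp(1i * 2 * pi * fftfreq_idx(np[ax]) * frac[ax] / np[ax])
      prod_f <- prod_f * array(rep(ph, each = prod(np[seq_len(ax - 1L)])),
                               dim = np)
    }
  }
  full <- Re(stats::fft(prod_f, inverse = TRUE)) / prod(np)
  icrop <- lapply(seq_len(nd), function(i) ci[i] + seq_len(dx[i]))
  do.call(`[`, c(list(full), icrop)) * scale
}

#' 3D continuous wavelet transform by direct convolution
#'
#' Convolves the volume with the rasterized, scaled wavelet
#' `a^{-3/2} psi(x/a)` (odd kernel, truncated at `4 * sigma * a`,
#' zero-padded boundaries), multiplying by the voxel volume so the result
#' approximates the continuous transform `f *** psi_a`. Also records the
#' multiply-add count of the direct sliding-window scheme
#' (`prod(dim(volume)) * prod(dim(kernel))`), the cost model under which
#' the volume and projection routes are compared.
#'
#' @param vol a [volume3d()].
#' @param wavelet a `mother_wavelet3d`.
#' @param a scale, strictly positive.
#' @param trunc_mult kernel truncation radius in units of `sigma * a`.
#' @return a `cwt_result` with fields `wavelet`, `component`, `scale`,
#'   `domain = "volume"`, `payload` (a `volume3d`), `kernel_size`, `macs`.
#' @export
cwt3d <- function(vol, wavelet, a = 1, trunc_mult = 4) {
  kern <- rasterize_wavelet3d(wavelet, vol$spacing, a, trunc_mult)
  if (any(dim(kern) > dim(vol$values)))
    stop("wavelet kernel is larger than the volume")
  out <- conv_fft_same(vol$values, kern, scale = vol$spacing^3)
  comp <- switch(wavelet$name, "dgauss-x" = "x", "dgauss-y" = "y",
                 "dgauss-z" = "z", wavelet$name)
  structure(list(wavelet = wavelet$name, component = comp, scale = a,
                 domain = "volume",
                 payload = volume3d(out, extent = vol$extent),
                 kernel_size = dim(kern)[1],
                 macs = prod(dim(vol$values)) * prod(dim(kern))),
            class = "cwt_result")
}

#' @export
print.cwt_result <- function(x, ...) {
  cat(sprintf("<cwt_result> %s (component %s, scale %g, %s domain, kernel %d, %.3g MACs)\n",
              x$wavelet, x$component, x$scale, x$domain, x$kernel_size,
              x$macs))
  invisible(x)
}

#' 2D wavelet transform of one projection
#'
#' Convolves a single projection image with the projected wavelet evaluated
#' at that projection's own angle (the angle-matched kernel is what makes
#' the projection-domain route equal the projection of the volume-domain
#' transform). Multiplied by the detector cell area; boundary zero-padded.
#' Records the direct-scheme multiply-add count.
#'
#' @param proj numeric matrix `(nu, nv)`.
#' @param pw a `projected_wavelet2d`.
#' @param theta the projection's angle, radians.
#' @param delta detector spacing.
#' @param a scale, strictly positive.
#' @param trunc_mult kernel truncation radius in units of `sigma * a`.
#' @param norm kernel normalization, see [rasterize_projected2d()].
#' @return matrix the size of `proj`, with attributes `macs` and
#'   `kernel_size`.
#' @export
cwt2d <- function(proj, pw, theta, delta, a = 1, trunc_mult = 4,
                  norm = "xray") {
  kern <- rasterize_projected2d(pw, theta, delta, a, trunc_mult, norm)
  if (any(dim(kern) > dim(proj)))
    stop("wavelet kernel is larger than the projection")
  out <- conv_fft_same(proj, kern, scale = delta^2)
  attr(out, "macs") <- prod(dim(proj)) * prod(dim(kern))
  attr(out, "kernel_size") <- dim(kern)[1]
  out
}

#' 2D wavelet transform of a whole projection stack
#'
#' Applies [cwt2d()] to every projection at its own angle.
#'
#' @param stack a [projection_stack()].
#' @param pw a `projected_wavelet2d`.
#' @inheritParams cwt2d
#' @return a [projection_stack()] with attributes `macs` (total) and
#'   `macs_per_angle`.
#' @export
cwt2d_stack <- function(stack, pw, a = 1, trunc_mult = 4, norm = "xray") {
  d <- dim(stack$data)
  out <- array(0, d)
  macs <- 0
  for (k in seq_len(d[3])) {
    fk <- cwt2d(stack$data[, , k], pw, stack$angles[k], stack$spacing, a,
                trunc_mult, norm)
    macs <- macs + attr(fk, "macs")
    out[, , k] <- fk
  }
  res <- projection_stack(out, stack$angles, stack$spacing)
  attr(res, "macs") <- macs
  attr(res, "macs_per_angle") <- macs / d[3]
  attr(res, "kernel_size") <- attr(fk, "kernel_size")
  res
}

#' Projection-convolution identity discrepancy
#'
#' The X-ray transform of a 3D convolution equals the 2D convolution of the
#' factors' X-ray transforms at the same angle. Computes both sides
#' numerically — left: 3D convolve (times voxel volume) then project;
#' right: project each factor then 2D convolve (times detector cell area) —
#' and returns their relative L2 discrepancy.
#'
#' @param f_vol,h_vol volumes on the same grid.
#' @param theta angle, radians.
#' @return scalar relative L2 error.
#' @export
projection_convolution_identity <- function(f_vol, h_vol, theta) {
  stopifnot(all(dim(f_vol$values) == dim(h_vol$values)),
            abs(f_vol$spacing - h_vol$spacing) < 1e-12)
  s <- conv_fft_same(f_vol$values, h_vol$values, scale = f_vol$spacing^3)
  lhs <- xray_project(volume3d(s, f_vol$extent), theta)$data[, , 1]
  pf <- xray_project(f_vol, theta)$data[, , 1]
  ph <- xray_project(h_vol, theta)$data[, , 1]
  rhs <- conv_fft_same(pf, ph, scale = f_vol$spacing^2)
  sqrt(sum((lhs - rhs)^2) / sum(lhs^2))
}

#' Realize the 3D wavelet transform through 2D projections
#'
#' The package's core pipeline: project the volume at all angles, apply the
#' 2D wavelet transform to each projection with the projected x- and
#' y-derivative wavelets at the projection's own angle, then invert each
#' filtered stack by filtered backprojection. The two outputs approximate
#' the direct 3D convolutions `f *** psi1_a` and `f *** psi2_a`.
#'
#' @param vol a [volume3d()].
#' @param angles projection angles (adequate for filtered backprojection).
#' @param sigma wavelet width in world units.
#' @param a scale, strictly positive.
#' @param hann apply Hann apodization in the backprojection filter.
#' @return list with `w1`, `w2` (two `cwt_result`s, `domain =
#'   "projection"`), the filtered stacks `stack1`, `stack2`, and counters
#'   `macs_per_angle`, `macs_total`.
#' @export
realize_wf_via_projections <- function(vol, angles, sigma = 1, a = 1,
                                       hann = FALSE) {
  st <- xray_project(vol, angles)
  pw1 <- projected_psi1(sigma)
  pw2 <- projected_psi2(sigma)
  f1 <- cwt2d_stack(st, pw1, a)
  f2 <- cwt2d_stack(st, pw2, a)
  w1 <- fbp_inverse(f1, hann = hann)
  w2 <- fbp_inverse(f2, hann = hann)
  mk <- function(v, nm, comp) structure(
    list(wavelet = nm, component = comp, scale = a, domain = "projection",
         payload = v, kernel_size = attr(f1, "kernel_size"),
         macs = attr(f1, "macs")), class = "cwt_result")
  list(w1 = mk(w1, "dgauss-x", "x"), w2 = mk(w2, "dgauss-y", "y"),
       stack1 = f1, stack2 = f2,
       macs_per_angle = attr(f1, "macs_per_angle") +
         attr(f2, "macs_per_angle"),
       macs_total = attr(f1, "macs") + attr(f2, "macs"))
}

#' Complexity comparison of the two routes
#'
#' Compares recorded multiply-add counts of the direct 3D convolution and
#' the per-angle 2D convolution against the asymptotic cost model
#' `O(S * N^2 * M^3)` (3D route, `S` slices of an `N x N` image, kernel
#' size `M`) versus `O(N^2 * M * (M + 1))` per angle (2D route). The
#' measured ratio should agree with the predicted ratio
#' `S * M^3 / (M * (M + 1))` within a factor of 2.
#'
#' @param N image size.
#' @param M kernel size.
#' @param S number of slices.
#' @param macs3d recorded 3D multiply-add count.
#' @param macs2d_per_angle recorded per-angle 2D multiply-add count.
#' @return list with measured and predicted counts, their ratios, and a
#'   logical `within_factor2`.
#' @export
complexity_report <- function(N, M, S, macs3d, macs2d_per_angle) {
  pred3d <- S * N^2 * M^3
  pred2d <- N^2 * M * (M + 1)
  ratio_measured <- macs3d / macs2d_per_angle
  ratio_predicted <- S * M^3 / (M * (M + 1))
  list(N = N, M = M, S = S,
       macs3d = macs3d, macs2d_per_angle = macs2d_per_angle,
       predicted3d = pred3d, predicted2d = pred2d,
       ratio_measured = ratio_measured, ratio_predicted = ratio_predicted,
       within_factor2 = ratio_measured / ratio_predicted <= 2 &&
         ratio_predicted / ratio_measured <= 2)
}
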