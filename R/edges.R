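# zero-padded shift of an array along its first two (in-plane) axes
shift2 <- function(a, dx, dy) {
  d <- dim(a)
  out <- array(0, d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2])
  fx <- sx - dx; fy <- sy - dy
  okx <- fx >= 1 & fx <= d[1]; oky <- fy >= 1 & fy <= d[2]
  if (length(d) == 3L)
    out[sx[okx], sy[oky], ] <- a[fx[okx], fy[oky], , drop = FALSE]
  else out[sx[okx], sy[oky]] <- a[fx[okx], fy[oky], drop = FALSE]
  out
}

# In-plane modulus-maxima stage shared by all edge routes: modulus of the
# wavelet-gradient pair, 8-neighbor non-maximum suppression along the
# quantized gradient direction (strict inequality against both neighbors;
# ties suppressed), then a quantile threshold on the modulus. A border of
# `margin` voxels (where the zero-padded convolution is not valid and a
# constant input would spuriously respond) is excluded from both the
# threshold statistics and the map.
# `floor` is an absolute modulus floor (callers reference it to the input
# scale) so that pure floating-point noise from constant inputs never
# survives the relative quantile threshold.
modulus_maxima <- function(w1, w2, quantile = 0.9, w3 = NULL, margin = 0L,
                           floor = 0) {
  m <- sqrt(w1^2 + w2^2 + if (is.null(w3)) 0 else w3^2)
  if (margin > 0) {
    d <- dim(m)
    if (2 * margin >= min(d)) stop("margin leaves no interior voxels")
    border <- array(TRUE, d)
    ii <- lapply(d, function(nn) (margin + 1):(nn - margin))
    border <- do.call(`[<-`, c(list(border), ii, list(FALSE)))
    m[border] <- 0
  }
  phi <- atan2(w2, w1)
  # quantize direction to {0, 45, 90, 135} degrees in-plane
  q <- (round(phi / (pi / 4)) %% 4)
  dxs <- c(1, 1, 0, -1)
  dys <- c(0, 1, 1, 1)
  is_max <- array(FALSE, dim(m))
  for (k in 0:3) {
    sel <- q == k
    if (!any(sel)) next
    n1 <- shift2(m, dxs[k + 1], dys[k + 1])
    n2 <- shift2(m, -dxs[k + 1], -dys[k + 1])
    is_max <- is_max | (sel & m > n1 & m > n2)
  }
  thr <- max(stats::quantile(m, quantile, names = FALSE), floor)
  list(mask = is_max & m > thr, modulus = m, threshold = thr,
       margin = margin)
}

new_edge_map <- function(mask, modulus, method, quantile, threshold, a,
                         sigma) {
  structure(list(mask = mask, modulus = modulus, method = method,
                 threshold_policy = sprintf("quantile %.3g", quantile),
                 quantile = quantile, threshold = threshold,
                 scale = a, sigma = sigma),
            class = "edge_map")
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf("<edge_map> method %s, %s (value %.4g), scale %g: %d edge voxels\n",
              x$method, x$threshold_policy, x$threshold, x$scale,
              sum(x$mask)))
  invisible(x)
}

#' Edge detection by 3D wavelet modulus maxima
#'
#' Computes the x- and y-derivative-of-Gaussian wavelet transforms of the
#' volume by direct 3D convolution, forms the in-plane gradient modulus
#' `sqrt(W1^2 + W2^2)` and direction `atan2(W2, W1)`, and marks voxels that
#' are strict local maxima of the modulus along the quantized direction and
#' exceed a quantile threshold. The wavelet pair spans only the in-plane
#' derivatives — the rotation-about-z geometry transports exactly these two
#' through the projection route, keeping the routes comparable; an optional
#' z-derivative channel can be added to the modulus for the direct route.
#'
#' @param vol a [volume3d()].
#' @param a wavelet scale.
#' @param sigma wavelet width, world units; default two voxels.
#' @param quantile modulus quantile for the threshold, in (0, 1).
#' @param include_z also include a z-derivative-of-Gaussian channel in the
#'   modulus (direct route only; off by default).
#' @return an `edge_map`.
#' @export
edges_3d <- function(vol, a = 1, sigma = 2 * vol$spacing, quantile = 0.9,
                     include_z = FALSE) {
  stopifnot(quantile > 0, quantile < 1)
  r1 <- cwt3d(vol, psi1(sigma), a)
  w1 <- r1$payload$values
  w2 <- cwt3d(vol, psi2(sigma), a)$payload$values
  w3 <- if (include_z) cwt3d(vol, psi3(sigma), a)$payload$values else NULL
  mm <- modulus_maxima(w1, w2, quantile, w3 = w3,
                       margin = (r1$kernel_size - 1) %/% 2,
                       floor = 1e-8 * max(abs(vol$values)))
  new_edge_map(mm$mask, mm$modulus, "3d", quantile, mm$threshold, a, sigma)
}

#' Edge detection through the projection route
#'
#' Runs the projection-domain realization of the 3D wavelet transform
#' ([realize_wf_via_projections()]) and applies the same modulus-maxima and
#' threshold stage as [edges_3d()].
#'
#' @inheritParams edges_3d
#' @param angles projection angles, adequate for filtered backprojection.
#' @return an `edge_map`.
#' @export
edges_via_projections <- function(vol, angles, a = 1,
                                  sigma = 2 * vol$spacing, quantile = 0.9) {
  stopifnot(quantile > 0, quantile < 1)
  rw <- realize_wf_via_projections(vol, angles, sigma = sigma, a = a)
  mm <- modulus_maxima(rw$w1$payload$values, rw$w2$payload$values, quantile,
                       margin = (rw$w1$kernel_size - 1) %/% 2,
                       floor = 1e-8 * max(abs(vol$values)))
  new_edge_map(mm$mask, mm$modulus, "projection", quantile, mm$threshold, a,
               sigma)
}

#' Per-slice 2D baseline edge detector
#'
#' Classic per-z-slice multiscale edge detection: each slice is convolved
#' with the 2D derivative-of-Gaussian pair and passed through the same
#' modulus-maxima stage. Serves as the simple 2D baseline against which the
#' volumetric routes are compared.
#'
#' @inheritParams edges_3d
#' @return an `edge_map`.
#' @export
edges_slice2d_baseline <- function(vol, a = 1, sigma = 2 * vol$spacing,
                                   quantile = 0.9) {
  stopifnot(quantile > 0, quantile < 1)
  delta <- vol$spacing
  h <- max(1L, ceiling(4 * sigma * a / delta))
  g <- (-h:h) * delta
  m <- length(g)
  s2 <- sigma^2
  gx <- outer(g, rep(1, m)); gy <- outer(rep(1, m), g)
  base <- exp(-(gx^2 + gy^2) / (2 * s2 * a^2))
  kx <- array(a^(-1) * (-(gx / a) / s2) * base, c(m, m, 1))
  ky <- array(a^(-1) * (-(gy / a) / s2) * base, c(m, m, 1))
  w1 <- conv_fft_same(vol$values, kx, scale = delta^2)
  w2 <- conv_fft_same(vol$values, ky, scale = delta^2)
  mm <- modulus_maxima(w1, w2, quantile, margin = h,
                       floor = 1e-8 * max(abs(vol$values)))
  new_edge_map(mm$mask, mm$modulus, "slice2d", quantile, mm$threshold, a,
               sigma)
}

#' Overlap metrics between two edge maps
#'
#' Dice coefficient, precision and recall of `map` against `ref`, computed
#' on the binary voxel masks.
#'
#' @param map,ref `edge_map`s (or logical arrays) on the same grid.
#' @return list with `dice`, `precision`, `recall`, `n_map`, `n_ref`.
#' @export
edge_metrics <- function(map, ref) {
  a <- if (inherits(map, "edge_map")) map$mask else map
  b <- if (inherits(ref, "edge_map")) ref$mask else ref
  stopifnot(all(dim(a) == dim(b)))
  inter <- sum(a & b)
  list(dice = if (sum(a) + sum(b) > 0) 2 * inter / (sum(a) + sum(b)) else 1,
       precision = if (sum(a) > 0) inter / sum(a) else 1,
       recall = if (sum(b) > 0) inter / sum(b) else 1,
       n_map = sum(a), n_ref = sum(b))
}

#' Projection-noise edge-detection experiment
#'
#' Adds seeded zero-mean Gaussian noise to the projections of a clean
#' volume and compares two processing orders against the clean-volume
#' reference edge map: arm A reconstructs the noisy projections by filtered
#' backprojection and edge-detects the reconstruction; arm B applies the 2D
#' wavelet filters to the noisy projections first and reconstructs the
#' already-filtered stacks, so reconstruction noise is never sharpened by a
#' volume-domain derivative. Replicates use consecutive seeds, making the
#' whole table bit-reproducible.
#'
#' @param vol clean [volume3d()].
#' @param variance projection-noise variance (the study condition is 0.1).
#' @param seed base RNG seed; replicate `r` uses `seed + r - 1`.
#' @param angles projection angles.
#' @param replicates number of noise replicates.
#' @param a,sigma,quantile edge-detector parameters as in [edges_3d()].
#' @return data.frame with one row per replicate and arm: columns
#'   `replicate`, `arm` ("reconstruct_then_detect" or
#'   "filter_projections"), `dice`, `precision`, `recall`.
#' @export
noise_experiment <- function(vol, variance = 0.1, seed = 0, angles,
                             replicates = 10, a = 1,
                             sigma = 2 * vol$spacing, quantile = 0.9) {
  if (variance < 0) stop("`variance` must be non-negative")
  ref <- edges_3d(vol, a = a, sigma = sigma, quantile = quantile)
  clean <- xray_project(vol, angles)
  pw1 <- projected_psi1(sigma)
  pw2 <- projected_psi2(sigma)
  rows <- vector("list", 2 * replicates)
  for (r in seq_len(replicates)) {
    noisy <- add_gaussian_noise(clean, variance, seed = seed + r - 1)
    # arm A: reconstruct, then detect in the volume domain
    rec <- fbp_inverse(noisy)
    ea <- edges_3d(rec, a = a, sigma = sigma, quantile = quantile)
    ma <- edge_metrics(ea, ref)
    # arm B: wavelet-filter the projections, then reconstruct
    f1 <- cwt2d_stack(noisy, pw1, a)
    w1 <- fbp_inverse(f1)
    w2 <- fbp_inverse(cwt2d_stack(noisy, pw2, a))
    mm <- modulus_maxima(w1$values, w2$values, quantile,
                         margin = (attr(f1, "kernel_size") - 1) %/% 2,
                         floor = 1e-8 * max(abs(vol$values)))
    mb <- edge_metrics(mm$mask, ref)
    rows[[2 * r - 1]] <- data.frame(replicate = r,
                                    arm = "reconstruct_then_detect",
                                    dice = ma$dice, precision = ma$precision,
                                    recall = ma$recall)
    rows[[2 * r]] <- data.frame(replicate = r, arm = "filter_projections",
                                dice = mb$dice, precision = mb$precision,
                                recall = mb$recall)
  }
  do.call(rbind, rows)
}
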