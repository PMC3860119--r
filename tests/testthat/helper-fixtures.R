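# Shared fixtures and small numeric helpers; everything is generated in
# code, no stored data.

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

# coordinate arrays of an n^3 centered grid
grid_arrays <- function(n, extent = 1) {
  g <- grid_coords(n, 2 * extent / n)
  list(x = array(rep(g, times = n * n), c(n, n, n)),
       y = array(rep(rep(g, each = n), times = n), c(n, n, n)),
       z = array(rep(g, each = n * n), c(n, n, n)),
       g = g)
}

# outer-ellipsoid support mask of the Shepp-Logan phantom
sl_support_mask <- function(n, extent = 1) {
  co <- grid_arrays(n, extent)
  (co$x / 0.69)^2 + (co$y / 0.92)^2 + (co$z / 0.81)^2 <= 1
}

# rasterize a 3D wavelet onto a full volume (for projector tests)
wavelet_volume <- function(w, n, extent) {
  co <- grid_arrays(n, extent)
  volume3d(array(w$evaluate(co$x, co$y, co$z), c(n, n, n)), extent = extent)
}

# binary dilation of a 3D mask by r voxels (Chebyshev ball), via shifts
dilate_mask <- function(mask, r) {
  d <- dim(mask)
  out <- mask
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sx <- pmin(pmax(seq_len(d[1]) - dx, 1), d[1])
    sy <- pmin(pmax(seq_len(d[2]) - dy, 1), d[2])
    sz <- pmin(pmax(seq_len(d[3]) - dz, 1), d[3])
    out <- out | mask[sx, sy, sz]
  }
  out
}

# brute-force direct true convolution ("same", zero padded) — independent
# oracle for the FFT convolution path, usable at tiny sizes only
direct_conv3_same <- function(x, k) {
  dx <- dim(x); dk <- dim(k); h <- (dk - 1) / 2
  out <- array(0, dx)
  for (i in seq_len(dx[1])) for (j in seq_len(dx[2])) for (l in seq_len(dx[3])) {
    acc <- 0
    for (a in seq_len(dk[1])) for (b in seq_len(dk[2])) for (cc in seq_len(dk[3])) {
      ii <- i - (a - 1 - h[1]); jj <- j - (b - 1 - h[2]); ll <- l - (cc - 1 - h[3])
      if (ii >= 1 && ii <= dx[1] && jj >= 1 && jj <= dx[2] &&
          ll >= 1 && ll <= dx[3])
        acc <- acc + x[ii, jj, ll] * k[a, b, cc]
    }
    out[i, j, l] <- acc
  }
  out
}
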