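test_that("FFT convolution agrees with the brute-force flipped-kernel sum", {
  set.seed(11)
  x <- array(rnorm(9 * 9 * 9), c(9, 9, 9))
  k <- array(rnorm(3 * 3 * 3), c(3, 3, 3))
  expect_equal(tomowave:::conv_fft_same(x, k), direct_conv3_same(x, k),
               tolerance = 1e-12)
  # an odd (antisymmetric) kernel keeps its sign under true convolution
  kx <- array(0, c(3, 1, 1)); kx[1, 1, 1] <- 1; kx[3, 1, 1] <- -1
  x1 <- array(0, c(9, 9, 9)); x1[5, 5, 5] <- 1
  out <- tomowave:::conv_fft_same(x1, kx)
  expect_equal(out[4, 5, 5], 1)   # impulse at i responds at i-1 with +1
  expect_equal(out[6, 5, 5], -1)
})

test_that("3D CWT of an impulse reproduces the rasterized kernel", {
  n <- 33
  vol <- volume3d(array(0, c(n, n, n)), extent = 1)
  vol$values[17, 17, 17] <- 1
  res <- cwt3d(vol, psi1(0.2))
  expect_s3_class(res, "cwt_result")
  kern <- rasterize_wavelet3d(psi1(0.2), vol$spacing)
  h <- (dim(kern)[1] - 1) / 2
  sub <- res$payload$values[17 + (-h:h), 17 + (-h:h), 17 + (-h:h)]
  expect_equal(sub, kern * vol$spacing^3, tolerance = 1e-12)
  expect_equal(res$macs, prod(dim(vol$values)) * prod(dim(kern)))
  expect_error(cwt3d(volume3d(array(0, c(8, 8, 8)), 1), psi1(2)), "larger")
})

test_that("constant volumes are annihilated by the zero-mean kernel", {
  vol <- volume3d(array(5, c(32, 32, 32)), extent = 1)
  res <- cwt3d(vol, psi1(0.15))
  h <- (res$kernel_size - 1) / 2
  core <- res$payload$values[(h + 1):(32 - h), (h + 1):(32 - h),
                             (h + 1):(32 - h)]
  kern <- rasterize_wavelet3d(psi1(0.15), vol$spacing)
  expect_lt(max(abs(core)), 1e-6 * 5 * sum(abs(kern)) * vol$spacing^3)
})

test_that("Gaussian blob CWT matches the Gaussian convolution algebra", {
  sf <- 0.5; sw <- 0.3
  vol <- rasterize_blob(gaussian_blob(sigma = sf), 64, extent = 2)
  res <- cwt3d(vol, psi1(sw))
  s2 <- sf^2 + sw^2
  cc <- (2 * pi * sf^2)^1.5 * (2 * pi * sw^2)^1.5 / (2 * pi * s2)^1.5
  co <- grid_arrays(64, 2)
  ref <- -co$x / s2 * cc * exp(-(co$x^2 + co$y^2 + co$z^2) / (2 * s2))
  expect_lt(max(abs(res$payload$values - ref)), 1e-3 * max(abs(ref)))
})

test_that("2D CWT respects the angle-dependent direction factor", {
  pw <- projected_psi1(0.3)
  proj <- matrix(rnorm(48 * 48), 48)
  out <- cwt2d(proj, pw, pi / 2, delta = 1 / 12)
  expect_lt(max(abs(out)), 1e-14)
  # impulse projection returns the centered kernel raster
  imp <- matrix(0, 49, 49); imp[25, 25] <- 1
  out <- cwt2d(imp, pw, 0.7, delta = 1 / 12)
  kern <- rasterize_projected2d(pw, 0.7, 1 / 12)
  h <- (dim(kern)[1] - 1) / 2
  expect_equal(out[25 + (-h:h), 25 + (-h:h)], kern * (1 / 12)^2,
               tolerance = 1e-12)
  # theta-independent input (exact analytic blob projection):
  # output at theta = cos(theta) x output at 0
  g <- grid_coords(48, 1 / 12)
  proj <- analytic_xray_blob(gaussian_blob(sigma = 0.4), 0, g, g)
  o0 <- cwt2d(proj, pw, 0, 1 / 12)
  o1 <- cwt2d(proj, pw, 1.1, 1 / 12)
  expect_lt(max(abs(o1 - cos(1.1) * o0)), 1e-12 * max(abs(o0)))
})

test_that("projection of a convolution equals convolution of projections", {
  f <- rasterize_blob(gaussian_blob(c(0.1, 0, 0), 0.5), 64, extent = 3)
  h <- rasterize_blob(gaussian_blob(c(0, -0.1, 0.05), 0.5), 64, extent = 3)
  errs <- vapply(c(0, pi / 4, pi / 2, 3 * pi / 4),
                 function(th) projection_convolution_identity(f, h, th),
                 numeric(1))
  expect_true(all(errs < 1e-2))
  expect_lt(max(errs), 2 * min(errs))  # no preferred direction
  # an axis-aligned impulse factor reduces the identity to projector linearity
  fo <- rasterize_blob(gaussian_blob(sigma = 0.5), 65, extent = 2)
  dv <- volume3d(array(0, c(65, 65, 65)), extent = 2)
  dv$values[33, 33, 33] <- 1 / fo$spacing^3
  expect_lt(projection_convolution_identity(fo, dv, 0), 1e-6)
})

test_that("the projection route reproduces the volume-domain transform", {
  b <- gaussian_blob(sigma = 0.4)
  vol <- rasterize_blob(b, 48, extent = 2)
  sw <- 0.2
  ang <- seq(0, pi, length.out = 61)[-61]
  rw <- realize_wf_via_projections(vol, ang, sigma = sw)
  s2 <- 0.4^2 + sw^2
  cc <- (2 * pi * 0.4^2)^1.5 * (2 * pi * sw^2)^1.5 / (2 * pi * s2)^1.5
  co <- grid_arrays(48, 2)
  ref <- -co$x / s2 * cc * exp(-(co$x^2 + co$y^2 + co$z^2) / (2 * s2))
  expect_lt(rel_l2(rw$w1$payload$values, ref), 0.05)
  # the y-component is the same field rotated a quarter turn
  refy <- -co$y / s2 * cc * exp(-(co$x^2 + co$y^2 + co$z^2) / (2 * s2))
  expect_lt(rel_l2(rw$w2$payload$values, refy), 0.05)
  # zero volume in, zero fields out
  zv <- volume3d(array(0, c(16, 16, 16)), 1)
  rz <- realize_wf_via_projections(zv, seq(0, pi, length.out = 13)[-13],
                                   sigma = 3 / 16)
  expect_true(all(rz$w1$payload$values == 0))
  expect_true(all(rz$w2$payload$values == 0))
})

test_that("operation counters scale as M^3 (3D) and M^2 (2D per angle)", {
  vol <- make_shepp_logan_3d(32)
  delta <- vol$spacing
  Ms <- c(5, 9, 13)
  macs3 <- numeric(3); macs2 <- numeric(3)
  for (i in seq_along(Ms)) {
    sig <- (Ms[i] - 1) / 2 / 4 * delta  # truncation at 4 sigma gives size M
    r3 <- cwt3d(vol, psi1(sig))
    expect_equal(r3$kernel_size, Ms[i])
    macs3[i] <- r3$macs
    st <- xray_project(vol, c(0, pi / 3))
    f <- cwt2d_stack(st, projected_psi1(sig))
    macs2[i] <- attr(f, "macs_per_angle")
  }
  s3 <- stats::coef(stats::lm(log(macs3) ~ log(Ms)))[2]
  s2 <- stats::coef(stats::lm(log(macs2) ~ log(Ms)))[2]
  expect_lt(abs(s3 - 3), 0.3)
  expect_lt(abs(s2 - 2), 0.3)
  # measured ratio consistent with the S M^3 / (M (M+1)) cost model
  rep9 <- complexity_report(N = 32, M = 9, S = 32, macs3d = macs3[2],
                            macs2d_per_angle = macs2[2])
  expect_true(rep9$within_factor2)
  # degenerate single-tap kernel: both routes cost about S x N^2
  r1 <- cwt3d(vol, psi1(0.1 * delta))
  expect_equal(r1$kernel_size, 3)  # smallest odd kernel
})
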