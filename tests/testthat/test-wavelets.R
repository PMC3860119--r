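test_that("Gaussian kernel: unit peak, known integral, flagged inadmissible", {
  g <- gaussian_3d(1)
  expect_equal(g$evaluate(0, 0, 0), 1)
  m <- tomowave:::wavelet_moments3d(g, n = 101)
  expect_equal(m$mean, (2 * pi)^(3 / 2), tolerance = 1e-6)
  expect_false(g$admissible)
  expect_false(zero_mean_residual(g)$pass)
})

test_that("derivative-of-Gaussian wavelets match their pointwise closed forms", {
  p1 <- psi1(1)
  # odd in x: vanishes on the x = 0 plane
  expect_equal(p1$evaluate(0, c(-1, 0, 2), c(0.5, 1, -3)), c(0, 0, 0))
  # -x exp(-(x^2+y^2+z^2)/2) at (1,0,0)
  expect_equal(p1$evaluate(1, 0, 0), -exp(-0.5), tolerance = 1e-12)
  expect_true(zero_mean_residual(p1)$pass)
  p2 <- psi2(1)
  expect_equal(p2$evaluate(0.3, 1, 0), -exp(-(0.09 + 1) / 2), tolerance = 1e-12)
  expect_equal(p1$evaluate(0.7, 0.2, -0.4), p2$evaluate(0.2, 0.7, -0.4))
  # general sigma: psi1 = d/dx exp(-r^2/(2 s^2))
  expect_equal(psi1(2)$evaluate(1, 1, 1), -(1 / 4) * exp(-3 / 8),
               tolerance = 1e-12)
  expect_true(zero_mean_residual(psi3(0.7))$pass)
})

test_that("Mexican hat is positive at the origin, zero-mean, projects to the 2D hat", {
  mh <- mexican_hat_3d(1)
  expect_gt(mh$evaluate(0, 0, 0), 0)
  expect_true(zero_mean_residual(mh)$pass)
  # numeric projection equals kappa x (2D Mexican hat), any angle
  vol <- wavelet_volume(mh, 81, 5)
  g <- grid_coords(81, vol$spacing)
  pm <- projected_mexican_hat(1)
  ref <- pm$evaluate(outer(g, rep(1, 81)), outer(rep(1, 81), g), 2.2)
  P <- xray_project(vol, 2.2)$data[, , 1]
  expect_lt(max(abs(P - ref)), 5e-3 * max(abs(ref)))
})

test_that("projected wavelets factor into profile x direction factor", {
  pw <- projected_psi1(1)
  g <- seq(-4, 4, length.out = 33)
  U <- outer(g, rep(1, 33)); V <- outer(rep(1, 33), g)
  # at theta = pi/2 the x-derivative wavelet projects to exactly zero
  expect_true(all(pw$evaluate(U, V, pi / 2) ==
                    cos(pi / 2) * pw$kappa * pw$profile(U, V)))
  expect_lt(max(abs(pw$evaluate(U, V, pi / 2))), 1e-15)
  # exact line-integral constant: value at (1, 0), theta = 0
  expect_equal(pw$evaluate(1, 0, 0), -sqrt(2 * pi) * exp(-0.5),
               tolerance = 1e-12)
  # pointwise cos(theta) factorization
  for (th in c(0.3, 2.5, 4.4))
    expect_equal(pw$evaluate(U, V, th), cos(th) * pw$evaluate(U, V, 0),
                 tolerance = 1e-12)
  # y-derivative partner uses sin(theta)
  pw2 <- projected_psi2(1)
  expect_equal(pw2$evaluate(U, V, 1.2), sin(1.2) * pw$evaluate(U, V, 0),
               tolerance = 1e-12)
})

test_that("scaling and translation preserve L2 norm and zero mean", {
  p1 <- psi1(1)
  # a = 1, b = 0 is the identity
  w0 <- family_scale_translate(p1, 1)
  expect_equal(w0$evaluate(0.3, -0.2, 0.9), p1$evaluate(0.3, -0.2, 0.9))
  l2 <- function(w, r) {
    g <- seq(-r, r, length.out = 141)
    co <- expand.grid(x = g, y = g, z = g)
    sum(w$evaluate(co$x, co$y, co$z)^2) * (g[2] - g[1])^3
  }
  base <- l2(p1, 16)
  for (a in c(0.5, 2)) {
    wa <- family_scale_translate(p1, a, b = c(0.2, 0, -0.1))
    expect_equal(l2(wa, 16), base, tolerance = 1e-3)
    # zero mean survives scaling and translation
    g <- seq(-16, 16, length.out = 161)
    co <- expand.grid(x = g, y = g, z = g)
    s <- sum(wa$evaluate(co$x, co$y, co$z)) * (g[2] - g[1])^3
    expect_lt(abs(s), 1e-8)
  }
  expect_error(family_scale_translate(p1, 0), "positive")
  expect_error(family_scale_translate(p1, -2), "positive")
  # 2D family normalization: a^{-1}
  pw <- family_scale_translate(projected_psi1(1), 2)
  expect_equal(pw$profile(0.6, 0.4), 0.5 * projected_psi1(1)$profile(0.3, 0.2),
               tolerance = 1e-12)
})

test_that("analytic Fourier forms agree with the DFT of rasters", {
  for (wname in c("dgauss-x", "mexican3d", "gauss")) {
    w <- wavelet_by_name(wname, 1)
    n <- 65
    vol <- wavelet_volume(w, n, 6)
    ft <- tomowave:::ctft_nd(vol$values, vol$spacing)
    wg <- ft$freqs[[1]]
    keep <- which(abs(wg) <= 3)  # where the transform has appreciable mass
    ref <- w$fourier(
      array(rep(wg[keep], length(keep)^2), rep(length(keep), 3)),
      array(rep(rep(wg[keep], each = length(keep)), length(keep)),
            rep(length(keep), 3)),
      array(rep(wg[keep], each = length(keep)^2), rep(length(keep), 3)))
    num <- ft$values[keep, keep, keep]
    expect_lt(max(Mod(num - ref)) / max(Mod(ref)), 1e-4)
  }
})

test_that("wavelets are addressable by name and unknown names are rejected", {
  expect_identical(wavelet_by_name("mexican3d", 2)$name, "mexican3d")
  expect_equal(wavelet_by_name("dgauss-y", 1.5)$sigma, 1.5)
  err <- tryCatch(wavelet_by_name("daub4"), error = conditionMessage)
  expect_match(err, "unknown wavelet")
  expect_match(err, "dgauss-x")  # message lists known names
  expect_match(err, "mexican3d")
})

test_that("truncation produces a compact wavelet that vanishes outside its radius", {
  tw <- truncate_wavelet(psi1(1), 3)
  expect_true(tw$compact)
  expect_equal(tw$support_radius, 3)
  expect_equal(tw$evaluate(3.1, 0, 0), 0)
  expect_equal(tw$evaluate(1, 0.5, -0.5), psi1(1)$evaluate(1, 0.5, -0.5))
})
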