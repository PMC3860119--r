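test_that("3D admissibility integral matches the spherical closed form", {
  # for psi1 (sigma = 1): integral (2 pi)^3 wx^2 e^{-|w|^2} / |w|^3 dw
  #   = (2 pi)^3 * (1/2) * (4 pi / 3)    [radial x angular factorization]
  adm <- check_admissibility_nd(psi1(1), 3)
  expect_true(adm$converged)
  expect_true(adm$pass)
  expect_equal(adm$value, (2 * pi)^3 * 2 * pi / 3, tolerance = 0.01)
  # y-derivative has the same integral by symmetry
  expect_equal(check_admissibility_nd(psi2(1), 3)$value, adm$value,
               tolerance = 1e-6)
  expect_true(check_admissibility_nd(mexican_hat_3d(1), 3)$pass)
})

test_that("the plain Gaussian fails the admissibility gates", {
  g <- gaussian_3d(1)
  expect_false(zero_mean_residual(g)$pass)
  adm <- check_admissibility_nd(g, 3)
  # log-divergent integral: the refinement gate cannot converge
  expect_false(adm$converged)
  expect_false(adm$pass)
})

test_that("2D admissibility integral of the projected wavelet matches polar closed form", {
  # Fourier-side constant-free normalization (F = j wu e^{-rho^2/2} cos t):
  # integral wu^2 e^{-rho^2} / rho^2 dw = (pi/2) cos^2(theta)
  pw <- projected_psi1(1, kappa = 1 / (2 * pi))
  expect_equal(eq19_integral(pw, 0)$value, pi / 2, tolerance = 0.01)
  expect_equal(eq19_integral(pw, pi / 3)$value, (pi / 2) * cos(pi / 3)^2,
               tolerance = 0.01)
  expect_equal(eq19_integral(pw, pi / 2)$value, 0, tolerance = 1e-10)
  # general kappa scales the integral by kappa^2 (x (2 pi)^2 Fourier factor)
  full <- projected_psi1(1)
  expect_equal(eq19_integral(full, 0.4)$value,
               (2 * pi)^3 * eq19_integral(pw, 0.4)$value, tolerance = 1e-6)
})

test_that("uniform Fourier bound attains its max at the closed-form location", {
  # constant-free normalization: k = max wu^2 e^{-wu^2} * integral e^{-wv^2}
  #   = e^{-1} sqrt(pi), attained at theta = 0 (mod pi), |wu| = 1
  pw <- projected_psi1(1, kappa = 1 / (2 * pi))
  t3 <- theorem3_bound(pw, n_theta = 72, n_wu = 101)
  expect_equal(t3$k, sqrt(pi) * exp(-1), tolerance = 1e-3)
  expect_equal(abs(t3$wu_at), 1)
  expect_equal(min(t3$theta_at %% pi, pi - t3$theta_at %% pi), 0,
               tolerance = 1e-10)
  # the y-derivative attains the same max a quarter turn later
  pw2 <- projected_psi2(1, kappa = 1 / (2 * pi))
  t32 <- theorem3_bound(pw2, n_theta = 72, n_wu = 101)
  expect_equal(t32$k, t3$k, tolerance = 1e-10)
  expect_equal(min(abs(t32$theta_at - c(pi / 2, 3 * pi / 2))), 0,
               tolerance = 1e-10)
  # zero wavelet: k = 0
  pz <- projected_psi1(1, kappa = 0)
  expect_equal(theorem3_bound(pz, n_theta = 8, n_wu = 11)$k, 0)
})

test_that("full 2D certificate passes for projections of admissible wavelets", {
  cert <- theorem4_certificate(projected_psi1(1))
  expect_s3_class(cert, "admissibility_report")
  expect_true(cert$pass)
  # angular structure: eq19(theta) proportional to cos^2(theta)
  fit <- stats::lm(cert$eq19_integral ~ I(cos(cert$thetas)^2))
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((cert$eq19_integral - mean(cert$eq19_integral))^2)
  expect_gt(r2, 0.999)
  expect_true(theorem4_certificate(projected_mexican_hat(1))$pass)
  # a projected function with nonzero mean diverges at the frequency origin
  fake <- tomowave:::new_projected_wavelet2d(
    name = "proj-gauss", sigma = 1, kappa = 1,
    profile = function(u, v) exp(-(u^2 + v^2) / 2),
    dirfactor = function(theta) rep(1, length(theta)),
    fourier2d = function(wu, wv, theta) 2 * pi * exp(-(wu^2 + wv^2) / 2),
    support_radius = 6)
  expect_false(eq19_integral(fake, 0)$converged)
})

test_that("compact-support energy inequality holds with slack growing in r", {
  slack <- vapply(c(3, 4, 6), function(r) {
    t6 <- theorem6_energy_bound(truncate_wavelet(psi1(1), r), n = 61)
    expect_true(t6$pass)
    t6$rhs - max(t6$lhs)
  }, numeric(1))
  expect_true(all(diff(slack) > 0))  # monotone slack in the radius
  # the inequality is an equality-free bound even for a non-wavelet:
  # indicator of the ball, where both sides have closed forms
  ball <- tomowave:::new_mother_wavelet3d(
    name = "ball", sigma = 1,
    evaluate = function(x, y, z) as.numeric(x^2 + y^2 + z^2 <= 1),
    support_radius = 1, compact = TRUE, admissible = FALSE)
  t6 <- theorem6_energy_bound(ball, thetas = c(0, 1), n = 121)
  expect_equal(max(t6$lhs), 2 * pi, tolerance = 0.05)     # 2 pi r^4
  expect_equal(t6$rhs, 8 * pi / 3, tolerance = 0.05)      # 2r x (4/3) pi r^3
  expect_true(t6$pass)
  expect_error(theorem6_energy_bound(psi1(1)), "compact")
})

test_that("Parseval relation holds for rasters under the stated convention", {
  blob <- rasterize_blob(gaussian_blob(sigma = 1), 64, extent = 6)
  expect_lt(parseval_check(blob$values, blob$spacing), 1e-6)
  # modulus invariance: a translate has the same discrepancy
  sh <- blob$values[c(5:64, 1:4), , ]
  expect_equal(parseval_check(sh, blob$spacing),
               parseval_check(blob$values, blob$spacing), tolerance = 1e-10)
  sl <- make_shepp_logan_3d(64)
  expect_lt(parseval_check(sl$values, sl$spacing), 1e-3)
  # 2D raster path
  m <- matrix(rnorm(32 * 32), 32)
  expect_lt(parseval_check(m, 0.1), 1e-10)
})
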