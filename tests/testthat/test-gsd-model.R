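# Generalized Saffman-Delbruck law: worked values, limits, inversion,
# viscosity conversions.

test_that("reduced radius reproduces the worked micrometre-domain value", {
  # d = 1 um, h = 5 nm, eta = 0.5 Pa s, eta3d = 1e-3 Pa s -> epsilon = 0.4
  beta <- beta_from_viscosity(0.5, u = 1, h = 5, eta3d = 1e-3)
  p <- hydro_params(A = 1, beta = beta)
  expect_equal(reduced_radius(1, p), 0.4)
  expect_equal(reduced_radius(0, p), 0)
  # two routes to epsilon agree to machine precision
  p2 <- hydro_params(A = 1, beta = 0.4)
  eta <- viscosity_from_beta(p2)
  eps_direct <- p2$beta * 1 / p2$u
  eps_phys <- 1e-6 * p2$eta3d / ((p2$h * 1e-9) * eta)
  expect_equal(eps_direct, eps_phys)
})

test_that("reduced radius warns outside the validity window and rejects d < 0", {
  p <- hydro_params(A = 1, beta = 0.33)
  expect_warning(eps <- reduced_radius(0.9e-3, p), "validity window")
  expect_equal(eps, 0.33 * 0.9e-3)
  expect_error(reduced_radius(-1, p), "non-negative")
})

test_that("single-lipid extrapolation matches the fitted-parameter predictions", {
  suppressWarnings({
    D_lod <- gsd_diffusion(0.9e-3, ref_params_lod())
    D_ldd <- gsd_diffusion(0.9e-3, ref_params_ldd())
  })
  expect_equal(D_lod, 6.2, tolerance = 0.05)
  expect_equal(D_ldd, 1.6, tolerance = 0.05)
})

test_that("small-epsilon limit recovers the classical Saffman-Delbruck form", {
  p <- hydro_params(A = 0.76, beta = 0.33)
  for (eps in c(1e-6, 1e-4, 9e-4)) {
    d <- eps / p$beta
    D <- gsd_diffusion(d, p)
    D_classic <- p$A * (log(2 / eps) - 0.5772 + 4 * eps / pi)
    expect_lt(abs(D - D_classic) / D, 1e-3)
  }
})

test_that("diffusion law is strictly decreasing in diameter and rejects d <= 0", {
  for (p in list(ref_params_lod(), ref_params_ldd(),
                 hydro_params(A = 2, beta = 1.5))) {
    d <- 10^seq(-4, 3, length.out = 400)
    D <- gsd_diffusion(d, p)
    expect_true(all(diff(D) < 0))
    expect_true(all(D > 0))
  }
  expect_error(gsd_diffusion(0, ref_params_lod()), "positive")
  expect_error(gsd_diffusion(-0.1, ref_params_lod()), "positive")
})

test_that("diameter inversion round-trips across the full size range", {
  p <- ref_params_lod()
  d <- 10^seq(-4, 3, length.out = 25)
  D <- gsd_diffusion(d, p)
  d_hat <- invert_diameter(D, p)
  expect_equal(d_hat, d, tolerance = 1e-6)
})

test_that("diameter inversion rejects unattainable diffusion coefficients", {
  p <- ref_params_lod()
  expect_error(invert_diameter(0, p), "attainable range")
  expect_error(invert_diameter(1e6, p), "attainable range")
})

test_that("gsd constants are fixed literals unless overridden", {
  expect_error(gsd_constants(p = 3), "override")
  cs <- gsd_constants(p = 3, override = TRUE)
  expect_equal(cs$p, 3)
})

test_that("viscosity conversions reproduce the hand-computed values", {
  # from A: eta = kBT / (4 pi h A)
  expect_equal(viscosity_from_A(ref_params_lod()), 0.0853, tolerance = 1e-3)
  expect_equal(viscosity_from_A(ref_params_ldd()), 0.3601, tolerance = 1e-3)
  # halving A doubles eta
  p2 <- hydro_params(A = 2 * 0.76, beta = 0.33)
  expect_equal(viscosity_from_A(p2) * 2, viscosity_from_A(ref_params_lod()))
  # from beta: eta = eta3d u / (h beta)
  expect_equal(viscosity_from_beta(hydro_params(A = 1, beta = 0.4)), 0.5)
  expect_equal(viscosity_from_beta(hydro_params(A = 1, beta = 0.33)),
               0.606, tolerance = 1e-3)
  expect_equal(viscosity_from_beta(hydro_params(A = 1, beta = 0.8)) * 2,
               viscosity_from_beta(hydro_params(A = 1, beta = 0.4)) * 1,
               tolerance = 1e-12)
})

test_that("implied bulk viscosity links the jointly fitted A and beta", {
  expect_equal(eta3d_consistency(ref_params_lod()), 1.4e-4, tolerance = 0.01)
  expect_equal(eta3d_consistency(ref_params_ldd()), 3.6e-4, tolerance = 0.01)
  # constructing beta from the identity reproduces eta3d exactly
  A <- 0.5
  eta3d <- 1e-3
  beta <- 4 * pi * (1e-6) * (A * 1e-12) * eta3d / thermal_energy(295)
  p <- hydro_params(A = A, beta = beta, eta3d = eta3d)
  expect_equal(eta3d_consistency(p), eta3d)
  # and then both viscosity conversions agree exactly
  expect_equal(viscosity_from_A(p), viscosity_from_beta(p))
})

test_that("true diameter subtracts the offset with quadrature errors and flags", {
  td <- true_diameter(1.0, 0.46, sigma_da = 0.03, sigma_delta = 0.02)
  expect_equal(td$d, 0.54)
  expect_equal(td$sigma_d, sqrt(0.03^2 + 0.02^2))
  expect_true(td$physical)
  # boundary: d_a == delta is flagged non-physical, not clipped
  td0 <- true_diameter(0.57, 0.57)
  expect_equal(td0$d, 0)
  expect_false(td0$physical)
  # the smallest-domain scale: 0.50 - 0.46 = 0.04 um
  expect_equal(true_diameter(0.50, 0.46)$d, 0.04)
})
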