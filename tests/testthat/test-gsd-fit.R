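# Fitting (A, beta, delta) of the offset diffusion law.

test_that("noise-free data recover all three parameters to 1e-3 relative", {
  d <- 10^seq(log10(0.7), log10(20), length.out = 40)
  obs <- gsd_obs_fixture(ref_params_lod(), d)
  f <- fit_gsd(obs)
  expect_equal(unname(f$estimates[["A"]]), 0.76, tolerance = 1e-3)
  expect_equal(unname(f$estimates[["beta"]]), 0.33, tolerance = 1e-3)
  expect_equal(unname(f$estimates[["delta"]]), 0.57, tolerance = 1e-3)
  expect_true(f$converged)
  expect_false(f$degenerate_delta)
  # tidy/glance accessors
  td <- tidy(f)
  expect_setequal(td$term, c("A", "beta", "delta"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  expect_equal(glance(f)$n_obs, 40)
})

test_that("underdetermined and malformed observation sets are rejected", {
  obs <- gsd_obs_fixture(ref_params_lod(), c(1, 2, 5))
  expect_error(fit_gsd(obs), "at least 4")
  expect_error(fit_gsd(tibble::tibble(d_a = 1:4)), "missing required|missing column")
  bad <- tibble::tibble(d_a = c(1, 2, 3, 4), D = c(1, -1, 1, 1))
  expect_error(fit_gsd(bad), "D > 0")
})

test_that("noisy fits keep the truth inside profile confidence intervals", {
  # moderate replication here; the full coverage study runs in acceptance
  truth <- ref_params_lod()
  tr <- c(0.76, 0.33, 0.57)
  cover <- vapply(1:10, function(r) {
    withr::with_seed(300 + r, {
      d <- exp(runif(29, log(0.04), log(20)))
    })
    obs <- gsd_obs_fixture(truth, d, noise_sd = 0.1, seed = 300 + r)
    f <- fit_gsd(obs, loss = "log", n_starts = 3, seed = r)
    ci <- profile_ci(f)
    all(ci$conf.low <= tr & tr <= ci$conf.high)
  }, logical(1))
  expect_gte(mean(cover), 0.8)
})

test_that("bootstrap intervals are tight on clean data and reject n_boot = 0", {
  d <- 10^seq(log10(0.7), log10(20), length.out = 30)
  obs <- gsd_obs_fixture(ref_params_lod(), d)
  f <- fit_gsd(obs)
  ci <- bootstrap_fit(f, n_boot = 60, seed = 4)
  expect_true(all(ci$conf.high - ci$conf.low < 1e-4))
  expect_error(bootstrap_fit(f, n_boot = 0), "positive")
})

test_that("bootstrap constrains delta more tightly than beta on size-spanning noisy data", {
  withr::with_seed(17, d <- exp(runif(29, log(0.04), log(20))))
  obs <- gsd_obs_fixture(ref_params_lod(), d, noise_sd = 0.1, seed = 17)
  f <- fit_gsd(obs, loss = "log", n_starts = 3)
  ci <- bootstrap_fit(f, n_boot = 100, seed = 5)
  rel_width <- (ci$conf.high - ci$conf.low) / f$estimates[ci$term]
  expect_lt(rel_width[ci$term == "delta"], rel_width[ci$term == "beta"])
})

test_that("missing small domains inflate the delta uncertainty", {
  truth <- ref_params_lod()
  withr::with_seed(23, {
    d_small <- exp(runif(29, log(0.04), log(20)))
    d_large <- exp(runif(29, log(4), log(20)))  # every d_a >> delta
  })
  obs_small <- gsd_obs_fixture(truth, d_small, noise_sd = 0.05, seed = 23)
  obs_large <- gsd_obs_fixture(truth, d_large, noise_sd = 0.05, seed = 24)
  f_small <- fit_gsd(obs_small, loss = "log", n_starts = 3)
  f_large <- fit_gsd(obs_large, loss = "log", n_starts = 3)
  ci_small <- profile_ci(f_small)
  ci_large <- profile_ci(f_large)
  w <- function(ci) ci$conf.high[ci$term == "delta"] - ci$conf.low[ci$term == "delta"]
  expect_gt(w(ci_large), 3 * w(ci_small))
})

test_that("corrected curve reproduces the single-lipid extrapolations", {
  d <- 10^seq(log10(0.7), log10(20), length.out = 40)
  f <- fit_gsd(gsd_obs_fixture(ref_params_lod(), d))
  cc <- corrected_curve(f, d_grid = 0.9e-3)
  expect_equal(nrow(cc), 1)
  expect_equal(cc$D_model, 6.26, tolerance = 0.01)
  f2 <- fit_gsd(gsd_obs_fixture(ref_params_ldd(), d))
  expect_equal(corrected_curve(f2, d_grid = 0.9e-3)$D_model, 1.57,
               tolerance = 0.01)
  # observations are carried along offset-corrected
  obs_att <- attr(cc, "observations")
  expect_equal(obs_att$d, d, tolerance = 1e-3)
})

test_that("zero offset leaves the model curve identical to the raw-diameter law", {
  truth <- hydro_params(A = 0.5, beta = 0.3, delta = 0)
  d <- 10^seq(log10(0.5), log10(10), length.out = 20)
  obs <- tibble::tibble(d_a = d, D = gsd_diffusion(d, truth))
  f <- fit_gsd(obs)
  cc <- corrected_curve(f, d_grid = d)
  expect_equal(cc$D_model, obs$D, tolerance = 1e-4)
})

test_that("smallest-domain estimate propagates uncertainty and flags boundaries", {
  d <- 10^seq(log10(0.04), log10(20), length.out = 40)
  f <- fit_gsd(gsd_obs_fixture(ref_params_ldd(), d))
  sm <- smallest_domain(f)
  expect_equal(sm$d_min, 0.04, tolerance = 1e-3)
  expect_gte(sm$sigma, 0)
  expect_true(sm$physical)
  # with an explicit apparent-size uncertainty the error grows in quadrature
  obs2 <- f$data
  obs2$sigma_da <- 0.02
  sm2 <- smallest_domain(f, obs2)
  expect_gte(sm2$sigma, 0.02)
})

test_that("predict and autoplot work on fitted objects", {
  d <- 10^seq(log10(0.7), log10(20), length.out = 20)
  f <- fit_gsd(gsd_obs_fixture(ref_params_lod(), d))
  pr <- predict(f, tibble::tibble(d_a = c(1, 2)))
  expect_length(pr, 2)
  expect_true(all(pr > 0))
  p <- ggplot2::autoplot(f)
  expect_s3_class(p, "ggplot")
})
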