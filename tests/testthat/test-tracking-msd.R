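# MSD computation, diffusion fitting, and the simple-diffusion filter.

test_that("MSD matches a brute-force pair enumeration exactly", {
  # hand-checkable 4-point track
  tr <- make_track(c(0, 1, 1, 2), c(0, 0, 1, 1))
  m <- compute_msd(tr)
  expect_equal(m$msd, c(1, 2))
  expect_equal(m$n_pairs, c(3L, 2L))
  # random tracks vs the double-loop oracle
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- sample(10:50, 1)
      tr <- make_track(cumsum(rnorm(n)), cumsum(rnorm(n)), dt = 0.5)
    })
    m <- compute_msd(tr, max_lag_fraction = 0.5)
    expect_equal(m$msd, msd_bruteforce(tr$x, tr$y, max(m$lag)), tolerance = 1e-12)
  }
})

test_that("MSD handles degenerate and deterministic tracks", {
  stat <- make_track(rep(1, 20), rep(-2, 20))
  expect_true(all(compute_msd(stat)$msd == 0))
  # ballistic motion: msd(tau) = v^2 tau^2
  t <- 0:49
  ball <- make_track(1 * t, 0 * t, dt = 1)
  m <- compute_msd(ball)
  expect_equal(m$msd, m$tau^2)
  expect_error(compute_msd(make_track(c(0, 1), c(0, 0))), "2 usable lags")
  expect_error(compute_msd(make_track(c(0, 1, NA), c(0, 0, 0))), "finite")
  bad <- tibble::tibble(time = c(0, 1, 3), x = 0:2, y = 0:2)
  expect_error(compute_msd(bad), "uniform")
})

test_that("diffusion fit recovers slope and intercept on exact lines", {
  lags <- 1:12
  m <- tibble::tibble(lag = lags, tau = lags * 0.1,
                      msd = 4 * 0.5 * lags * 0.1, n_pairs = 100L - lags)
  f <- fit_diffusion(m, lags = 2:10)
  expect_equal(f$D, 0.5)
  expect_equal(f$intercept, 0)
  expect_false(f$flagged)
  # localization-noise offset is identified separately from the slope
  m$msd <- m$msd + 0.01
  f2 <- fit_diffusion(m, lags = 2:10)
  expect_equal(f2$D, 0.5)
  expect_equal(f2$intercept, 0.01)
  expect_error(fit_diffusion(m[1:2, ], lags = 1:2), "at least 3")
})

test_that("diffusion fit is accurate on a long simulated Brownian track", {
  tr <- brownian_fixture(10000, D = 1, dt = 0.1, seed = 42)
  f <- fit_diffusion(compute_msd(tr, max_lag_fraction = 0.01), lags = 1:10)
  expect_gt(f$D, 0.95)
  expect_lt(f$D, 1.05)
})

test_that("diffusion fit is unbiased over an ensemble of tracks", {
  Ds <- vapply(1:200, function(s) {
    tr <- brownian_fixture(400, D = 1, dt = 0.1, seed = s)
    fit_diffusion(compute_msd(tr), lags = 2:10)$D
  }, numeric(1))
  expect_equal(mean(Ds), 1, tolerance = 0.02)
})

test_that("simple-diffusion filter separates Brownian, ballistic and confined", {
  lags <- 1:12
  lin <- tibble::tibble(lag = lags, tau = lags * 0.1, msd = 4 * 0.3 * lags * 0.1,
                        n_pairs = 200L - lags)
  c1 <- classify_simple_diffusion(lin)
  expect_true(c1$is_simple)
  expect_equal(c1$alpha, 1, tolerance = 1e-8)

  ball <- tibble::tibble(lag = lags, tau = lags * 0.1, msd = (lags * 0.1)^2,
                         n_pairs = 200L - lags)
  c2 <- classify_simple_diffusion(ball)
  expect_false(c2$is_simple)
  expect_equal(c2$alpha, 2, tolerance = 1e-8)

  # confinement saturates the MSD: alpha well below 1 at long observation
  conf <- confined_fixture(3000, D = 1, R = 0.5, dt = 0.1, seed = 7)
  c3 <- classify_simple_diffusion(compute_msd(conf), lags = 2:30)
  expect_lt(c3$alpha, 0.8)
  expect_false(c3$is_simple)

  zero <- tibble::tibble(lag = lags, tau = lags * 0.1, msd = rep(0, 12),
                         n_pairs = 200L - lags)
  expect_false(classify_simple_diffusion(zero)$is_simple)
})

test_that("simple-diffusion filter passes almost all genuine Brownian tracks", {
  pass <- vapply(1:60, function(s) {
    tr <- brownian_fixture(500, D = 0.5, dt = 0.1, seed = 100 + s)
    classify_simple_diffusion(compute_msd(tr))$is_simple
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("observation estimation filters tracks and reports exclusions", {
  mk <- function(id, tr, d_a, phase) {
    dplyr::mutate(tr, track_id = id, frame = seq_len(nrow(tr)) - 1L,
                  d_a = d_a, phase = phase)
  }
  simple <- purrr::map(1:5, function(i)
    mk(paste0("s", i), brownian_fixture(400, D = 0.5, dt = 0.1, seed = i),
       d_a = 1 + i / 10, phase = "LOD"))
  t <- (0:399) * 0.1
  ballistic <- purrr::map(1:5, function(i)
    mk(paste0("b", i), make_track(0.5 * t, 0.1 * t, dt = 0.1),
       d_a = 2, phase = "LOD"))
  tracks <- dplyr::bind_rows(c(simple, ballistic))
  obs <- estimate_observations(tracks, n_boot = 20, seed = 9)
  expect_equal(nrow(obs), 5)
  expect_setequal(obs$track_id, paste0("s", 1:5))
  excl <- attr(obs, "exclusions")
  expect_equal(nrow(excl), 5)
  expect_true(all(excl$reason == "not_simple_diffusion"))
  expect_true(all(is.finite(obs$sigma_D) & obs$sigma_D > 0))

  expect_error(estimate_observations(tracks[0, ]), "no trajectories")
  expect_error(estimate_observations(dplyr::bind_rows(ballistic)),
               "no track passed")
})
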