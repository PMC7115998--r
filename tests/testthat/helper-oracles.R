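# Independent oracles and small fixture builders used across the suite.

# brute-force time-averaged MSD: explicit double loop over ordered pairs
msd_bruteforce <- function(x, y, max_lag) {
  n <- length(x)
  vapply(seq_len(max_lag), function(k) {
    acc <- 0
    for (i in seq_len(n - k)) {
      acc <- acc + (x[i + k] - x[i])^2 + (y[i + k] - y[i])^2
    }
    acc / (n - k)
  }, numeric(1))
}

make_track <- function(x, y, dt = 1) {
  tibble::tibble(time = (seq_along(x) - 1) * dt, x = x, y = y)
}

# seeded Brownian track with known diffusion coefficient
brownian_fixture <- function(n, D, dt = 0.1, sigma_loc = 0, seed = 1) {
  withr::with_seed(seed, {
    sd_step <- sqrt(2 * D * dt)
    x <- cumsum(c(0, rnorm(n - 1, 0, sd_step))) + rnorm(n, 0, sigma_loc)
    y <- cumsum(c(0, rnorm(n - 1, 0, sd_step))) + rnorm(n, 0, sigma_loc)
    make_track(x, y, dt)
  })
}

# random walk reflected inside a disk of radius R (confined diffusion)
confined_fixture <- function(n, D, R, dt = 0.1, seed = 1) {
  withr::with_seed(seed, {
    sd_step <- sqrt(2 * D * dt)
    x <- numeric(n); y <- numeric(n)
    for (i in 2:n) {
      repeat {
        xn <- x[i - 1] + rnorm(1, 0, sd_step)
        yn <- y[i - 1] + rnorm(1, 0, sd_step)
        if (xn^2 + yn^2 <= R^2) break
      }
      x[i] <- xn; y[i] <- yn
    }
    make_track(x, y, dt)
  })
}

# noise-free observation set from known hydrodynamic truth
gsd_obs_fixture <- function(truth, d, noise_sd = 0, seed = 1) {
  D <- gsd_diffusion(d, truth)
  if (noise_sd > 0) {
    D <- withr::with_seed(seed, D * (1 + rnorm(length(d), 0, noise_sd)))
  }
  tibble::tibble(d_a = d + truth$delta, D = D)
}

ref_params_lod <- function() hydro_params(A = 0.76, beta = 0.33, delta = 0.57)
ref_params_ldd <- function() hydro_params(A = 0.18, beta = 0.20, delta = 0.46)

disk_mask_fixture <- function(side, cx, cy, r) {
  xs <- matrix(seq_len(side), side, side)
  ys <- matrix(seq_len(side), side, side, byrow = TRUE)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}
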