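# Synthetic data generator: trajectories, two-channel images, and FCS
# curves with the statistical structure the analysis assumes, so every
# pipeline stage is testable without microscopy data.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' experimental study conditions: 29 tracked ordered domains (LODs, moving
#' through the disordered phase) and 31 tracked disordered domains (LDDs,
#' moving through the ordered phase), true diameters log-uniform over
#' 0.04-20 um, diffusion following the generalized Saffman-Delbruck law
#' with the fitted hydrodynamic parameters of each phase as generator
#' truth, and a constant per-phase apparent-diameter offset.
#'
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param n_lod,n_ldd number of tracked domains per phase.
#' @param d_range true-diameter range, um (log-uniform draw).
#' @param params_lod,params_ldd generator-truth [hydro_params()] per phase
#'   (`delta` is the injected apparent-diameter offset).
#' @param dt frame interval, s.
#' @param n_frames frames per track.
#' @param sigma_loc localization noise sd per coordinate, um.
#' @param field image side length, px.
#' @param pixel_size image pixel size, um/px.
#' @param psf_sigma point-spread-function sigma, um.
#' @param photons mean photon count of the bright phase (Poisson
#'   scaling); `Inf` disables photon noise.
#' @param n_domains_img number of disks per synthetic image.
#' @param d_range_img disk diameter range for images, um.
#' @param antiregistered_fraction fraction of disks present in only one
#'   channel (0 = fully registered leaflets, 1 = fully antiregistered).
#' @param fcs_G0,fcs_r0 FCS amplitude and beam waist (um).
#' @param fcs_noise multiplicative noise sd on simulated G values.
#' @param fcs_n_tau number of log-spaced lags.
#' @param fcs_tau_range lag range, s.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_lod = 29, n_ldd = 31,
                       d_range = c(0.04, 20),
                       params_lod = hydro_params(A = 0.76, beta = 0.33, delta = 0.57),
                       params_ldd = hydro_params(A = 0.18, beta = 0.20, delta = 0.46),
                       dt = 0.1, n_frames = 500, sigma_loc = 0.02,
                       field = 192, pixel_size = 0.1, psf_sigma = 0.15,
                       photons = 200, n_domains_img = 12,
                       d_range_img = c(0.8, 3),
                       antiregistered_fraction = 0,
                       fcs_G0 = 0.1, fcs_r0 = 0.2, fcs_noise = 0.02,
                       fcs_n_tau = 64, fcs_tau_range = c(1e-5, 1)) {
  stopifnot(d_range[1] > 0, d_range[2] >= d_range[1], dt > 0, n_frames >= 2,
            sigma_loc >= 0, field > 0, pixel_size > 0, psf_sigma >= 0,
            photons > 0 || is.infinite(photons), antiregistered_fraction >= 0,
            antiregistered_fraction <= 1,
            inherits(params_lod, "hydro_params"),
            inherits(params_ldd, "hydro_params"))
  structure(as.list(environment()), class = "sim_config")
}

# one Brownian track with localization noise; pure function of the RNG state
.brownian_track <- function(n_frames, dt, D, sigma_loc) {
  step_sd <- sqrt(2 * D * dt)
  x <- cumsum(c(0, stats::rnorm(n_frames - 1, 0, step_sd)))
  y <- cumsum(c(0, stats::rnorm(n_frames - 1, 0, step_sd)))
  if (sigma_loc > 0) {
    x <- x + stats::rnorm(n_frames, 0, sigma_loc)
    y <- y + stats::rnorm(n_frames, 0, sigma_loc)
  }
  list(x = x, y = y)
}

#' Simulate domain trajectories under the generalized Saffman-Delbruck law
#'
#' For each domain a true diameter is drawn log-uniformly, its diffusion
#' coefficient is computed from the GSD law with the phase's generator-truth
#' parameters, a 2D Gaussian random walk with per-axis step variance
#' `2 D dt` is integrated, localization noise is added to the positions,
#' and the apparent diameter is set to `d + delta` (the constant-offset
#' observation model; the offset does not depend on domain size).
#'
#' @param config a [sim_config()] object.
#' @return A list with `tracks` (tibble: `track_id`, `frame`, `time`, `x`,
#'   `y`, `d_a`, `phase`) and `truth` (tibble: `track_id`, `phase`, `d`,
#'   `D_true`, `delta`, `d_a`).
#' @export
simulate_tracks <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    domains <- tibble::tibble(
      phase = c(rep("LOD", config$n_lod), rep("LDD", config$n_ldd))
    )
    domains$track_id <- sprintf("%s_%02d", domains$phase,
                             c(seq_len(config$n_lod), seq_len(config$n_ldd)))
    lr <- log(config$d_range)
    domains$d <- exp(stats::runif(nrow(domains), lr[1], lr[2]))
    domains$delta <- ifelse(domains$phase == "LOD", config$params_lod$delta,
                         config$params_ldd$delta)
    domains$d_a <- domains$d + domains$delta
    domains$D_true <- NA_real_
    domains$D_true[domains$phase == "LOD"] <-
      gsd_diffusion(domains$d[domains$phase == "LOD"], config$params_lod)
    domains$D_true[domains$phase == "LDD"] <-
      gsd_diffusion(domains$d[domains$phase == "LDD"], config$params_ldd)

    tracks <- purrr::pmap_dfr(
      list(domains$track_id, domains$d_a, domains$phase, domains$D_true),
      function(id, d_a, phase, D) {
        tr <- .brownian_track(config$n_frames, config$dt, D, config$sigma_loc)
        tibble::tibble(
          track_id = id,
          frame = seq_len(config$n_frames) - 1L,
          time = (seq_len(config$n_frames) - 1L) * config$dt,
          x = tr$x, y = tr$y, d_a = d_a, phase = phase
        )
      }
    )
    list(tracks = tracks,
         truth = domains[, c("track_id", "phase", "d", "D_true", "delta", "d_a")])
  })
}

# rejection-sample non-overlapping disk centres on a field of `side` px
.place_disks <- function(n, radii_px, side, max_attempts = 1e4) {
  centers <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      cx <- stats::runif(1, radii_px[i] + 1, side - radii_px[i] - 1)
      cy <- stats::runif(1, radii_px[i] + 1, side - radii_px[i] - 1)
      if (i == 1) { ok <- TRUE } else {
        j <- seq_len(i - 1)
        dist2 <- (centers[j, 1] - cx)^2 + (centers[j, 2] - cy)^2
        ok <- all(dist2 > (radii_px[j] + radii_px[i] + 2)^2)
      }
      if (ok) { centers[i, ] <- c(cx, cy); break }
    }
    if (!ok) stop("could not place non-overlapping domains after 1e4 attempts",
                  call. = FALSE)
  }
  centers
}

.disk_mask <- function(side, cx, cy, r) {
  xs <- matrix(seq_len(side), side, side)
  ys <- matrix(seq_len(side), side, side, byrow = TRUE)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

#' Simulate a registered (or antiregistered) two-channel image pair
#'
#' Ordered domains are dark disks on a bright disordered background in both
#' dye channels. A configurable fraction of the disks is placed in only one
#' channel (alternating channels), providing an antiregistration control.
#' Each channel is blurred with a Gaussian point-spread function and
#' corrupted with Poisson photon noise. The pre-noise true masks are
#' returned for oracle comparisons.
#'
#' @param config a [sim_config()] object.
#' @return A list: `channel1`, `channel2` (numeric matrices), `mask1`,
#'   `mask2` (true logical LOD masks per channel), `pixel_size`.
#' @export
simulate_images <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, {
    side <- config$field
    n <- config$n_domains_img
    d_px <- stats::runif(n, config$d_range_img[1], config$d_range_img[2]) /
      config$pixel_size
    r_px <- d_px / 2
    if (sum(pi * r_px^2) > 0.5 * side^2) {
      stop("requested domain area exceeds 50% of the field", call. = FALSE)
    }
    centers <- .place_disks(n, r_px, side)
    n_anti <- round(config$antiregistered_fraction * n)
    # antiregistered disks alternate between the two channels
    anti_ch <- rep(0L, n)
    if (n_anti > 0) anti_ch[seq_len(n_anti)] <- rep_len(c(1L, 2L), n_anti)

    mask1 <- matrix(FALSE, side, side)
    mask2 <- matrix(FALSE, side, side)
    for (i in seq_len(n)) {
      dm <- .disk_mask(side, centers[i, 1], centers[i, 2], r_px[i])
      if (anti_ch[i] != 2L) mask1 <- mask1 | dm
      if (anti_ch[i] != 1L) mask2 <- mask2 | dm
    }
    render <- function(mask) {
      img <- matrix(1, side, side)
      img[mask] <- 0.2
      if (config$psf_sigma > 0) {
        img <- EBImage::imageData(
          EBImage::gblur(EBImage::Image(img),
                         sigma = config$psf_sigma / config$pixel_size)
        )
      }
      if (!is.finite(config$photons)) return(matrix(img, side, side))
      matrix(stats::rpois(length(img), lambda = pmax(img, 0) * config$photons) /
               config$photons, side, side)
    }
    list(channel1 = render(mask1), channel2 = render(mask2),
         mask1 = mask1, mask2 = mask2, pixel_size = config$pixel_size)
  })
}

#' Simulate an FCS autocorrelation curve
#'
#' Evaluates the 2D diffusion model at log-spaced lags for a given
#' generator-truth diffusion coefficient and adds multiplicative Gaussian
#' noise. The diffusion time embedded in the curve is
#' `tau_D = r0^2 / (4 D)`.
#'
#' @param D_truth diffusion coefficient, um^2/s.
#' @param config a [sim_config()] object (supplies `fcs_G0`, `fcs_r0`,
#'   `fcs_noise`, lag grid, and the seed).
#' @return A tibble: `tau`, `G`, `sigma_G`, with the truth in attributes
#'   `G0`, `tau_D`.
#' @export
simulate_fcs <- function(D_truth, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"), D_truth > 0)
  tau_D <- config$fcs_r0^2 / (4 * D_truth)
  taus <- 10^seq(log10(config$fcs_tau_range[1]), log10(config$fcs_tau_range[2]),
                 length.out = config$fcs_n_tau)
  G <- fcs_model(taus, config$fcs_G0, tau_D)
  withr::with_seed(config$seed + 2L, {
    noisy <- G * (1 + stats::rnorm(length(G), 0, config$fcs_noise))
  })
  out <- tibble::tibble(tau = taus, G = noisy,
                        sigma_G = config$fcs_noise * G)
  attr(out, "G0") <- config$fcs_G0
  attr(out, "tau_D") <- tau_D
  out
}
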