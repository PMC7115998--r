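# Per-domain diffusion estimation from 2D trajectories:
# time-averaged MSD, linear fit, simple-diffusion filter.

.validate_track <- function(traj) {
  need <- c("time", "x", "y")
  miss <- setdiff(need, names(traj))
  if (length(miss)) {
    stop("trajectory is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(traj) < 2) stop("trajectory needs at least 2 points", call. = FALSE)
  if (!all(is.finite(traj$x)) || !all(is.finite(traj$y))) {
    stop("trajectory coordinates must be finite", call. = FALSE)
  }
  dt <- diff(traj$time)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  if (diff(range(dt)) > 1e-9 * mean(dt)) {
    stop("frame interval must be uniform (resampling is out of scope)",
         call. = FALSE)
  }
  invisible(traj)
}

#' Time-averaged mean squared displacement of one trajectory
#'
#' For each integer lag `k` up to `floor(N * max_lag_fraction)` the MSD is
#' averaged over all ordered pairs of points `k` frames apart (the
#' time-averaged, overlapping-pair estimator standard in single-particle
#' tracking). The number of pairs entering each lag is recorded; it is the
#' natural weight for the subsequent linear fit.
#'
#' @param traj a data frame with columns `time` (s, uniform spacing), `x`,
#'   `y` (um). One track only.
#' @param max_lag_fraction largest lag as a fraction of track length.
#' @return A tibble with columns `lag` (frames), `tau` (s), `msd` (um^2),
#'   `n_pairs`.
#' @export
compute_msd <- function(traj, max_lag_fraction = 0.25) {
  .validate_track(traj)
  stopifnot(max_lag_fraction > 0, max_lag_fraction <= 1)
  n <- nrow(traj)
  dt <- mean(diff(traj$time))
  # at least two lags whenever the track permits, so short tracks stay usable
  max_lag <- min(n - 1L, max(2L, floor(n * max_lag_fraction)))
  lags <- seq_len(max_lag)
  if (length(lags) < 2L) stop("fewer than 2 usable lags", call. = FALSE)
  msd <- vapply(lags, function(k) {
    dx <- traj$x[(k + 1):n] - traj$x[1:(n - k)]
    dy <- traj$y[(k + 1):n] - traj$y[1:(n - k)]
    mean(dx^2 + dy^2)
  }, numeric(1))
  tibble::tibble(lag = lags, tau = lags * dt, msd = msd, n_pairs = n - lags)
}

#' Fit a diffusion coefficient to an MSD curve
#'
#' Weighted least squares of `msd = 4 * D * tau + b`, weights equal to the
#' pair counts. The intercept `b` absorbs static localization noise
#' (`b = 4 sigma_loc^2` for uncorrelated Gaussian errors). A negative slope
#' is reported as a negative `D` with `flagged = TRUE`, never clipped, so
#' ensemble averages of the estimator stay unbiased.
#'
#' @param msd an MSD tibble from [compute_msd()].
#' @param lags integer lags to include (intersected with those available).
#' @return A one-row tibble: `D` (um^2/s), `intercept` (um^2), `se_D`, `r2`,
#'   `n_lags`, `flagged`.
#' @export
fit_diffusion <- function(msd, lags = 2:10) {
  use <- msd[msd$lag %in% lags, , drop = FALSE]
  if (nrow(use) < 3) stop("need at least 3 MSD points in the fit window",
                          call. = FALSE)
  fit <- stats::lm(msd ~ tau, data = use, weights = use$n_pairs)
  co <- stats::coef(fit)
  # vcov on an exactly collinear (noise-free) fit warns; the se is 0 there
  se <- tryCatch(suppressWarnings(sqrt(diag(stats::vcov(fit)))[["tau"]] / 4),
                 error = function(e) NA_real_)
  ss_tot <- sum(use$n_pairs * (use$msd - stats::weighted.mean(use$msd, use$n_pairs))^2)
  r2 <- if (ss_tot > 0) 1 - sum(use$n_pairs * stats::resid(fit)^2) / ss_tot else 1
  D <- unname(co[["tau"]]) / 4
  tibble::tibble(
    D = D,
    intercept = unname(co[["(Intercept)"]]),
    se_D = se,
    r2 = r2,
    n_lags = nrow(use),
    flagged = D <= 0
  )
}

#' Classify an MSD curve as simple (Brownian) diffusion or not
#'
#' Fits `log(msd)` against `log(tau)` over the lag window; the slope is the
#' anomalous exponent `alpha` (1 for free diffusion, <1 subdiffusive or
#' confined, 2 ballistic). The curve is accepted as simple diffusion when
#' `|alpha - 1| <= alpha_tol` and the linear-in-tau fit quality `r2` is at
#' least `r2_min`. Zero-MSD lags are excluded from the log fit; an all-zero
#' curve is classified not simple.
#'
#' @param msd an MSD tibble from [compute_msd()].
#' @param alpha_tol tolerance on the anomalous exponent.
#' @param r2_min minimum weighted r-squared of the linear MSD fit.
#' @param lags lag window (as in [fit_diffusion()]).
#' @return A one-row tibble: `is_simple`, `alpha`, `r2`.
#' @export
classify_simple_diffusion <- function(msd, alpha_tol = 0.2, r2_min = 0.9,
                                      lags = 2:10) {
  use <- msd[msd$lag %in% lags & msd$msd > 0, , drop = FALSE]
  if (nrow(use) < 4) {
    return(tibble::tibble(is_simple = FALSE, alpha = NA_real_, r2 = NA_real_))
  }
  lf <- stats::lm(log(msd) ~ log(tau), data = use)
  alpha <- unname(stats::coef(lf)[["log(tau)"]])
  r2 <- fit_diffusion(msd, lags = lags)$r2
  tibble::tibble(
    is_simple = abs(alpha - 1) <= alpha_tol && r2 >= r2_min,
    alpha = alpha,
    r2 = r2
  )
}

# Block bootstrap over displacement blocks: resample contiguous blocks of
# step vectors, rebuild a track, re-estimate D. Returns sd of the resampled
# estimates.
.bootstrap_sigma_D <- function(traj, lags, n_boot, block, seed) {
  dx <- diff(traj$x)
  dy <- diff(traj$y)
  n_steps <- length(dx)
  n_blocks <- floor(n_steps / block)
  if (n_blocks < 2 || n_boot < 2) return(NA_real_)
  dt <- mean(diff(traj$time))
  starts <- (seq_len(n_blocks) - 1L) * block + 1L
  withr::with_seed(seed, {
    est <- vapply(seq_len(n_boot), function(b) {
      pick <- sample(starts, n_blocks, replace = TRUE)
      idx <- as.vector(outer(0:(block - 1L), pick, "+"))
      bx <- cumsum(c(0, dx[idx]))
      by <- cumsum(c(0, dy[idx]))
      bt <- tibble::tibble(time = dt * seq_along(bx), x = bx, y = by)
      m <- compute_msd(bt, max_lag_fraction = min(1, (max(lags) + 1) / length(bx)))
      fit_diffusion(m, lags = lags)$D
    }, numeric(1))
    stats::sd(est)
  })
}

#' Estimate per-domain observations from a table of trajectories
#'
#' Applies the single-particle-tracking pipeline to every track in a tidy
#' trajectory table: compute the time-averaged MSD, keep only tracks
#' compatible with simple diffusion, fit `D`, and attach a block-bootstrap
#' uncertainty. Tracks are dropped (with a recorded reason) when they fail
#' the simple-diffusion filter or yield a non-positive `D`.
#'
#' @param tracks a data frame with columns `track_id`, `time`, `x`, `y` and
#'   (carried through) `d_a`, `phase`.
#' @param alpha_tol,r2_min simple-diffusion thresholds, see
#'   [classify_simple_diffusion()].
#' @param lags lag window for the MSD fit.
#' @param max_lag_fraction see [compute_msd()].
#' @param n_boot,block block-bootstrap settings for `sigma_D` (`n_boot = 0`
#'   skips the bootstrap).
#' @param seed integer seed for the bootstrap resampling.
#' @return A tibble of surviving observations (`track_id`, `d_a`, `phase`,
#'   `D`, `sigma_D`, `intercept`, `alpha`, `r2`), with an `exclusions`
#'   attribute tabulating dropped tracks and reasons.
#' @export
estimate_observations <- function(tracks, alpha_tol = 0.2, r2_min = 0.9,
                                  lags = 2:10, max_lag_fraction = 0.25,
                                  n_boot = 200, block = 10, seed = 1) {
  if (is.null(tracks) || nrow(tracks) == 0) {
    stop("no trajectories supplied", call. = FALSE)
  }
  ids <- unique(tracks$track_id)
  rows <- vector("list", length(ids))
  excl <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    tr <- dplyr::filter(tracks, .data$track_id == ids[[i]])
    msd <- compute_msd(tr, max_lag_fraction = max_lag_fraction)
    cls <- classify_simple_diffusion(msd, alpha_tol, r2_min, lags)
    if (!isTRUE(cls$is_simple)) {
      excl[[i]] <- tibble::tibble(track_id = ids[[i]], reason = "not_simple_diffusion")
      next
    }
    fd <- fit_diffusion(msd, lags = lags)
    if (fd$flagged) {
      excl[[i]] <- tibble::tibble(track_id = ids[[i]], reason = "non_positive_D")
      next
    }
    sD <- if (n_boot > 0) {
      .bootstrap_sigma_D(tr, lags, n_boot, block, seed + i)
    } else NA_real_
    rows[[i]] <- tibble::tibble(
      track_id = ids[[i]],
      d_a = if ("d_a" %in% names(tr)) tr$d_a[[1]] else NA_real_,
      phase = if ("phase" %in% names(tr)) tr$phase[[1]] else "unknown",
      D = fd$D, sigma_D = sD, intercept = fd$intercept,
      alpha = cls$alpha, r2 = cls$r2
    )
  }
  out <- dplyr::bind_rows(rows)
  exclusions <- dplyr::bind_rows(excl)
  if (nrow(out) == 0) {
    stop("no track passed the simple-diffusion filter; exclusions: ",
         paste(sprintf("%s (%s)", exclusions$track_id, exclusions$reason),
               collapse = ", "),
         call. = FALSE)
  }
  attr(out, "exclusions") <- exclusions
  out
}
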