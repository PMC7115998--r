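# Fit (A, beta, delta) of the offset generalized Saffman-Delbruck law to
# observed (apparent diameter, diffusion coefficient) pairs.

.gsd_model_da <- function(d_a, A, beta, delta, u, consts) {
  p <- structure(list(A = A, beta = beta, delta = 0, u = u, h = 5,
                      eta3d = 1e-3, T = 295), class = "hydro_params")
  gsd_diffusion(pmax(d_a - delta, 1e-12), p, consts)
}

.validate_obs <- function(obs) {
  need <- c("d_a", "D")
  miss <- setdiff(need, names(obs))
  if (length(miss)) {
    stop("observations are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(obs$d_a <= 0) || any(obs$D <= 0)) {
    stop("observations require d_a > 0 and D > 0", call. = FALSE)
  }
  invisible(obs)
}

#' Fit the offset generalized Saffman-Delbruck law to domain observations
#'
#' Estimates the diffusivity scale `A`, the mobility ratio `beta`, and the
#' apparent-diameter offset `delta` by bounded nonlinear least squares of
#' `D_i = gsd(d_a_i - delta; A, beta)`. `A` and `beta` are treated as
#' independent parameters. When per-observation uncertainties `sigma_D` are
#' present the objective is weighted by `1/sigma_D^2`, otherwise unweighted.
#' Because the three parameters share a correlation valley, the optimizer is
#' restarted from several jittered initial points and the best final
#' objective wins (ties broken by the smaller `delta`).
#'
#' @param obs a data frame with columns `d_a` (um), `D` (um^2/s) and
#'   optionally `sigma_D`. At least 4 rows.
#' @param init optional [hydro_params()] carrying starting values; by
#'   default `A = median(D)/5`, `beta = 0.3`, `delta = 0.8 * min(d_a)`.
#' @param lower,upper bounds on `(A, beta, delta)`; `delta` is always kept
#'   below `min(d_a)` so every corrected diameter stays positive.
#' @param loss `"linear"` (residuals on D, default) or `"log"` (residuals on
#'   log D).
#' @param n_starts number of jittered restarts.
#' @param seed seed for the restart jitter.
#' @param u,consts fixed reference length and formula constants.
#' @return An object of class `gsd_fit` with [tidy()], [glance()],
#'   [predict()][predict.gsd_fit] and [ggplot2::autoplot()] methods.
#' @export
fit_gsd <- function(obs, init = NULL, lower = c(A = 1e-8, beta = 1e-8, delta = 0),
                    upper = c(A = Inf, beta = Inf, delta = NA),
                    loss = c("linear", "log"), n_starts = 5, seed = 1,
                    u = 1, consts = gsd_constants()) {
  .validate_obs(obs)
  loss <- match.arg(loss)
  if (nrow(obs) < 4) {
    stop("need at least 4 observations to identify (A, beta, delta)",
         call. = FALSE)
  }
  d_a <- obs$d_a
  D <- obs$D
  delta_max <- min(d_a) * (1 - 1e-9)
  if (is.na(upper[["delta"]])) upper[["delta"]] <- delta_max
  upper[["delta"]] <- min(upper[["delta"]], delta_max)

  w <- if ("sigma_D" %in% names(obs) && all(is.finite(obs$sigma_D)) &&
           all(obs$sigma_D > 0)) 1 / obs$sigma_D^2 else rep(1, length(D))
  weighted <- !all(w == w[[1]]) || ("sigma_D" %in% names(obs) &&
                                      all(is.finite(obs$sigma_D)) &&
                                      all(obs$sigma_D > 0))

  start0 <- if (is.null(init)) {
    c(A = stats::median(D) / 5, beta = 0.3, delta = 0.8 * min(d_a))
  } else {
    c(A = init$A, beta = init$beta, delta = init$delta)
  }
  start0 <- pmin(pmax(start0, lower + 1e-12), c(upper[1:2], delta_max))

  resp <- if (loss == "log") log(D) else D
  fn <- if (loss == "log") {
    function(d_a, A, beta, delta) log(.gsd_model_da(d_a, A, beta, delta, u, consts))
  } else {
    function(d_a, A, beta, delta) .gsd_model_da(d_a, A, beta, delta, u, consts)
  }

  dat <- data.frame(d_a = d_a, resp = resp)
  fits <- withr::with_seed(seed, {
    lapply(seq_len(n_starts), function(k) {
      st <- if (k == 1) start0 else {
        s <- start0 * stats::runif(3, 0.5, 1.5)
        pmin(pmax(s, lower + 1e-12), c(upper[["A"]], upper[["beta"]], delta_max))
      }
      tryCatch(
        minpack.lm::nlsLM(
          resp ~ fn(d_a, A, beta, delta),
          data = dat,
          start = as.list(st),
          lower = lower, upper = upper, weights = w,
          control = minpack.lm::nls.lm.control(maxiter = 500)
        ),
        error = function(e) NULL
      )
    })
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    stop("nonlinear least squares failed to converge from any start",
         call. = FALSE)
  }
  objs <- vapply(fits, function(f) sum(w * stats::resid(f)^2), numeric(1))
  deltas <- vapply(fits, function(f) stats::coef(f)[["delta"]], numeric(1))
  best <- order(objs, deltas)[[1]]
  fit <- fits[[best]]

  est <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 3, 3))
  se <- sqrt(pmax(diag(vc), 0))
  dfree <- length(D) - 3L
  tq <- stats::qt(0.975, dfree)
  ci <- cbind(lower = est - tq * se, upper = est + tq * se)
  degenerate_delta <- est[["delta"]] >= delta_max * (1 - 1e-6)

  structure(list(
    estimates = est,
    se = se,
    vcov = vc,
    ci95 = ci,
    params = hydro_params(A = est[["A"]], beta = est[["beta"]],
                          delta = est[["delta"]], u = u),
    consts = consts,
    n_obs = length(D),
    objective = objs[[best]],
    converged = TRUE,
    degenerate_delta = degenerate_delta,
    weighted = weighted,
    weights = w,
    loss = loss,
    data = tibble::as_tibble(obs),
    fitted = as.numeric(.gsd_model_da(d_a, est[["A"]], est[["beta"]],
                                      est[["delta"]], u, consts)),
    nls = fit
  ), class = "gsd_fit")
}

#' @export
print.gsd_fit <- function(x, ...) {
  cat("<gsd_fit> offset generalized Saffman-Delbruck fit\n")
  cat(sprintf("  n = %d observations, %s loss%s\n", x$n_obs, x$loss,
              if (x$weighted) ", 1/sigma^2 weights" else ""))
  est <- x$estimates
  for (nm in names(est)) {
    cat(sprintf("  %-5s = %8.4g +/- %.3g  [%.4g, %.4g]\n", nm, est[[nm]],
                x$se[[nm]], x$ci95[nm, "lower"], x$ci95[nm, "upper"]))
  }
  if (x$degenerate_delta) {
    cat("  warning: delta sits on its upper bound min(d_a); fit is degenerate\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the parameters of a GSD fit
#'
#' @param x a `gsd_fit` object.
#' @param ... unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @method tidy gsd_fit
#' @export
tidy.gsd_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = unname(x$se),
    conf.low = unname(x$ci95[, "lower"]),
    conf.high = unname(x$ci95[, "upper"])
  )
}

#' One-row summary of a GSD fit
#'
#' @param x a `gsd_fit` object.
#' @param ... unused.
#' @return A one-row tibble: `n_obs`, `objective`, `converged`, `weighted`,
#'   `loss`, `degenerate_delta`.
#' @method glance gsd_fit
#' @export
glance.gsd_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    objective = x$objective,
    converged = x$converged,
    weighted = x$weighted,
    loss = x$loss,
    degenerate_delta = x$degenerate_delta
  )
}

#' Predict diffusion coefficients from a GSD fit
#'
#' @param object a `gsd_fit` object.
#' @param newdata optional data frame with a `d_a` column; defaults to the
#'   fitted data.
#' @param ... unused.
#' @return Numeric vector of model diffusion coefficients, um^2/s.
#' @export
predict.gsd_fit <- function(object, newdata = NULL, ...) {
  d_a <- if (is.null(newdata)) object$data$d_a else newdata$d_a
  est <- object$estimates
  as.numeric(.gsd_model_da(d_a, est[["A"]], est[["beta"]], est[["delta"]],
                           object$params$u, object$consts))
}

#' Case-resampling bootstrap confidence intervals for a GSD fit
#'
#' Refits the model to `n_boot` case resamples of the observations and
#' returns percentile 95% intervals per parameter. Errors if more than 20%
#' of the refits fail.
#'
#' @param fit a `gsd_fit` object.
#' @param n_boot number of bootstrap resamples (must be positive).
#' @param seed integer seed.
#' @return A tibble: `term`, `conf.low`, `conf.high`, `n_ok`.
#' @export
bootstrap_fit <- function(fit, n_boot = 200, seed = 1) {
  stopifnot(inherits(fit, "gsd_fit"))
  if (n_boot <= 0) stop("n_boot must be positive", call. = FALSE)
  obs <- fit$data
  n <- nrow(obs)
  est <- withr::with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(obs$d_a[idx])) < 4) return(NULL)
      f <- tryCatch(
        fit_gsd(obs[idx, , drop = FALSE],
                init = fit$params, loss = fit$loss, n_starts = 1,
                u = fit$params$u, consts = fit$consts),
        error = function(e) NULL
      )
      if (is.null(f)) NULL else f$estimates
    })
  })
  ok <- Filter(Negate(is.null), est)
  if (length(ok) < 0.8 * n_boot) {
    stop(sprintf("bootstrap unstable: only %d of %d refits succeeded",
                 length(ok), n_boot), call. = FALSE)
  }
  m <- do.call(rbind, ok)
  tibble::tibble(
    term = colnames(m),
    conf.low = apply(m, 2, stats::quantile, probs = 0.025),
    conf.high = apply(m, 2, stats::quantile, probs = 0.975),
    n_ok = length(ok)
  )
}

#' Model curve over true diameters, with offset-corrected observations
#'
#' Evaluates the fitted law on a grid of true diameters `d` and attaches the
#' observations replotted as `d = d_a - delta` (the offset-corrected view in
#' which the smallest domains reveal their actual size).
#'
#' @param fit a `gsd_fit` object.
#' @param d_grid true-diameter grid, um.
#' @return A tibble `(d, D_model)`; the corrected observations are in the
#'   `observations` attribute.
#' @export
corrected_curve <- function(fit, d_grid = 10^seq(-3, log10(25), length.out = 200)) {
  stopifnot(inherits(fit, "gsd_fit"))
  curve <- tibble::tibble(
    d = d_grid,
    D_model = gsd_diffusion(d_grid, fit$params, fit$consts)
  )
  obs <- true_diameter(fit$data$d_a, fit$estimates[["delta"]],
                       sigma_delta = fit$se[["delta"]])
  obs$D <- fit$data$D
  attr(curve, "observations") <- obs
  curve
}

#' Smallest true domain diameter in an observation set
#'
#' `min(d_a) - delta` with quadrature-propagated uncertainty from the
#' apparent-diameter uncertainty (when available) and the fitted offset's
#' standard error. A non-positive estimate is flagged, not clipped.
#'
#' @param fit a `gsd_fit` object.
#' @param obs observation table; defaults to the fitted data. An optional
#'   `sigma_da` column feeds the error propagation.
#' @return One-row tibble: `d_a_min`, `d_min`, `sigma`, `physical`.
#' @export
smallest_domain <- function(fit, obs = fit$data) {
  stopifnot(inherits(fit, "gsd_fit"))
  if (nrow(obs) == 0) stop("no observations", call. = FALSE)
  i <- which.min(obs$d_a)
  s_da <- if ("sigma_da" %in% names(obs)) obs$sigma_da[[i]] else 0
  td <- true_diameter(obs$d_a[[i]], fit$estimates[["delta"]],
                      sigma_da = s_da, sigma_delta = fit$se[["delta"]])
  tibble::tibble(
    d_a_min = td$d_a, d_min = td$d, sigma = td$sigma_d, physical = td$physical
  )
}

#' Plot a GSD fit: observed D against apparent diameter with the model curve
#'
#' @param object a `gsd_fit` object.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot gsd_fit
#' @export
autoplot.gsd_fit <- function(object, ...) {
  grid <- tibble::tibble(
    d_a = 10^seq(log10(min(object$data$d_a)), log10(max(object$data$d_a)),
                 length.out = 200)
  )
  grid$D <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$d_a, y = .data$D)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = expression(d[a] ~ (mu * m)),
      y = expression(D ~ (mu * m^2 / s)),
      title = "Offset generalized Saffman-Delbrück fit"
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Profile-likelihood confidence intervals for a GSD fit
#'
#' Profiles the (weighted) residual sum of squares over each parameter with
#' the other two re-optimized, and returns the interval where the profiled
#' objective stays below the F-based threshold
#' `SSE_min * (1 + qf(level, 1, n - 3) / (n - 3))`. Profile intervals follow
#' the curved valley that the three parameters share, which plain Wald
#' intervals understate badly on noisy data; endpoints are clamped to the
#' parameter bounds (`delta < min(d_a)`).
#'
#' @param fit a `gsd_fit` object.
#' @param level confidence level.
#' @return A tibble: `term`, `estimate`, `conf.low`, `conf.high`.
#' @export
profile_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "gsd_fit"), level > 0, level < 1)
  obs <- fit$data
  n <- fit$n_obs
  u <- fit$params$u
  consts <- fit$consts
  w <- fit$weights
  resp <- if (fit$loss == "log") log(obs$D) else obs$D
  sse_at <- function(par) {
    mu <- .gsd_model_da(obs$d_a, par[1], par[2], par[3], u, consts)
    if (fit$loss == "log") mu <- log(mu)
    val <- sum(w * (resp - mu)^2)
    # keep the objective finite so box-constrained optim never sees NA/Inf
    if (!is.finite(val) || val > 1e30) 1e30 else val
  }
  lob <- c(1e-10, 1e-10, 0)
  hib <- c(Inf, Inf, min(obs$d_a) * (1 - 1e-9))
  prof_sse <- function(j, value) {
    free <- setdiff(1:3, j)
    fn <- function(th) {
      par <- numeric(3)
      par[j] <- value
      par[free] <- th
      sse_at(par)
    }
    # L-BFGS-B warns when it patches a non-finite trial value; that patching
    # is the intended fallback here, so the warning carries no information
    o <- tryCatch(
      suppressWarnings(
        stats::optim(fit$estimates[free], fn, method = "L-BFGS-B",
                     lower = lob[free], upper = hib[free])
      ),
      error = function(e) NULL
    )
    # finite sentinel: uniroot warns on non-finite objective values
    if (is.null(o)) 1e30 else o$value
  }
  sse0 <- sse_at(fit$estimates)
  thr <- sse0 * (1 + stats::qf(level, 1, n - 3) / (n - 3))
  ci <- vapply(1:3, function(j) {
    est <- fit$estimates[j]
    g <- function(v) prof_sse(j, v) - thr
    find_end <- function(dir) {
      step0 <- max(abs(est) * 0.1, 2 * fit$se[j], 0.01, na.rm = TRUE)
      step <- step0
      v_in <- est
      v_out <- NA_real_
      for (k in 1:60) {
        v <- if (dir < 0) max(est - step, lob[j]) else min(est + step, hib[j])
        if (g(v) > 0) { v_out <- v; break }
        v_in <- v
        if ((dir < 0 && v <= lob[j]) || (dir > 0 && v >= hib[j])) return(v)
        step <- step * 1.6
      }
      if (is.na(v_out)) return(v_in)
      stats::uniroot(g, c(min(v_in, v_out), max(v_in, v_out)), tol = 1e-6)$root
    }
    c(find_end(-1), find_end(1))
  }, numeric(2))
  tibble::tibble(
    term = names(fit$estimates),
    estimate = unname(fit$estimates),
    conf.low = ci[1, ],
    conf.high = ci[2, ]
  )
}
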