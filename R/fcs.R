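# Two-dimensional fluorescence correlation spectroscopy model fitting,
# used to cross-validate single-lipid diffusion coefficients.

#' Two-dimensional single-component FCS autocorrelation model
#'
#' `G(tau) = G0 / (1 + tau / tau_D)`: the autocorrelation of fluorescence
#' fluctuations for free 2D diffusion through a Gaussian focal spot. `tau_D`
#' is the lag at which the correlation has decayed to half its amplitude.
#'
#' @param tau lag time(s), s.
#' @param G0 amplitude at zero lag.
#' @param tau_D diffusion time, s.
#' @return Autocorrelation value(s).
#' @examples
#' fcs_model(1.28e-3, G0 = 0.1, tau_D = 1.28e-3)  # G0 / 2
#' @export
fcs_model <- function(tau, G0, tau_D) {
  stopifnot(G0 > 0, tau_D > 0, all(tau >= 0))
  G0 / (1 + tau / tau_D)
}

#' Fit the 2D diffusion model to an FCS autocorrelation curve
#'
#' Least-squares fit of [fcs_model()] (weighted by `1/sigma_G^2` when
#' uncertainties are present), then conversion of the diffusion time to a
#' diffusion coefficient via `D = r0^2 / (4 tau_D)`. The beam waist `r0` is
#' not identifiable from the curve itself and must be supplied; `D` is only
#' as accurate as `r0`.
#'
#' @param curve a data frame with columns `tau` (s, strictly increasing and
#'   positive), `G`, optionally `sigma_G`. At least 5 points spanning the
#'   decay.
#' @param r0 beam waist (1/e^2 radius) of the focal spot, um.
#' @return An object of class `fcs_fit` with fields `G0`, `tau_D`, `D`,
#'   `r0`, `tau_D_in_span`, plus [tidy()] and [glance()] methods.
#' @export
fit_fcs <- function(curve, r0 = 0.2) {
  need <- setdiff(c("tau", "G"), names(curve))
  if (length(need)) {
    stop("FCS curve missing column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(r0 > 0)
  if (nrow(curve) < 5) {
    stop("need at least 5 autocorrelation points spanning the decay",
         call. = FALSE)
  }
  if (any(curve$tau <= 0) || any(diff(curve$tau) <= 0)) {
    stop("tau must be positive and strictly increasing", call. = FALSE)
  }
  w <- if ("sigma_G" %in% names(curve) && all(is.finite(curve$sigma_G)) &&
           all(curve$sigma_G > 0)) 1 / curve$sigma_G^2 else rep(1, nrow(curve))
  G0_start <- max(curve$G)
  tau_D_start <- curve$tau[[which.min(abs(curve$G - G0_start / 2))]]
  fit <- minpack.lm::nlsLM(
    G ~ G0 / (1 + tau / tau_D),
    data = curve,
    start = list(G0 = G0_start, tau_D = tau_D_start),
    lower = c(G0 = 1e-12, tau_D = 1e-12),
    weights = w,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, 2))
  tau_D <- est[["tau_D"]]
  in_span <- tau_D >= min(curve$tau) && tau_D <= max(curve$tau)
  if (!in_span) {
    warning("fitted tau_D lies outside the measured lag span; D is an extrapolation",
            call. = FALSE)
  }
  structure(list(
    G0 = est[["G0"]], tau_D = tau_D,
    D = r0^2 / (4 * tau_D),
    r0 = r0,
    se = c(G0 = unname(se[[1]]), tau_D = unname(se[[2]])),
    tau_D_in_span = in_span,
    n = nrow(curve),
    rss = sum(w * stats::resid(fit)^2),
    data = tibble::as_tibble(curve)
  ), class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat("<fcs_fit> 2D diffusion autocorrelation fit\n")
  cat(sprintf("  G0 = %.4g, tau_D = %.4g s, r0 = %g um\n", x$G0, x$tau_D, x$r0))
  cat(sprintf("  D = r0^2/(4 tau_D) = %.4g um^2/s\n", x$D))
  invisible(x)
}

#' Tidy the parameters of an FCS fit
#'
#' @param x an `fcs_fit` object.
#' @param ... unused.
#' @return A tibble: `term`, `estimate`, `std.error`.
#' @method tidy fcs_fit
#' @export
tidy.fcs_fit <- function(x, ...) {
  tibble::tibble(
    term = c("G0", "tau_D", "D"),
    estimate = c(x$G0, x$tau_D, x$D),
    std.error = c(x$se[["G0"]], x$se[["tau_D"]],
                  x$D * x$se[["tau_D"]] / x$tau_D)
  )
}

#' One-row summary of an FCS fit
#'
#' @param x an `fcs_fit` object.
#' @param ... unused.
#' @return A one-row tibble: `n`, `rss`, `tau_D_in_span`, `r0`.
#' @method glance fcs_fit
#' @export
glance.fcs_fit <- function(x, ...) {
  tibble::tibble(n = x$n, rss = x$rss, tau_D_in_span = x$tau_D_in_span,
                 r0 = x$r0)
}

#' Plot an FCS curve with its fitted model
#'
#' @param object an `fcs_fit` object.
#' @param ... unused.
#' @return A ggplot object (log-scaled lag axis).
#' @method autoplot fcs_fit
#' @export
autoplot.fcs_fit <- function(object, ...) {
  grid <- tibble::tibble(
    tau = 10^seq(log10(min(object$data$tau)), log10(max(object$data$tau)),
                 length.out = 200)
  )
  grid$G <- fcs_model(grid$tau, object$G0, object$tau_D)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$tau, y = .data$G)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau ~ (s)), y = expression(G(tau)))
}
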