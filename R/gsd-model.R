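# Generalized Saffman-Delbruck (GSD) diffusion law and viscosity conversions.

.kB <- 1.380649e-23  # Boltzmann constant, J/K

#' Thermal energy
#'
#' @param T temperature in kelvin.
#' @return `k_B * T` in joules.
#' @export
thermal_energy <- function(T) {
  stopifnot(is.numeric(T), T > 0)
  .kB * T
}

#' Hydrodynamic parameter set for the generalized Saffman-Delbruck law
#'
#' Bundles the parameters that govern lateral diffusion of a disk-shaped
#' inclusion (here: a lipid domain) in a thin viscous membrane sheet bathed
#' in bulk water: the diffusivity scale `A = k_B T / (4 pi h eta)`, the
#' dimensionless mobility ratio `beta = eta3d * u / (h * eta)`, and the
#' apparent-diameter offset `delta` by which optical measurements
#' overestimate the true domain diameter (scan-time motion blur plus
#' diffraction).
#'
#' @param A diffusivity scale, um^2/s. Must be positive.
#' @param beta dimensionless mobility ratio. Must be positive.
#' @param delta apparent-diameter offset, um. Non-negative.
#' @param u reference length, um (the length at which `epsilon = beta`).
#' @param h bilayer thickness, nm.
#' @param eta3d bulk (water) viscosity, Pa s.
#' @param T temperature, K.
#' @return An object of class `hydro_params`.
#' @examples
#' hydro_params(A = 0.76, beta = 0.33, delta = 0.57)
#' @export
hydro_params <- function(A, beta, delta = 0, u = 1, h = 5, eta3d = 1e-3,
                         T = 295) {
  stopifnot(
    is.numeric(A), length(A) == 1, A > 0,
    is.numeric(beta), length(beta) == 1, beta > 0,
    is.numeric(delta), length(delta) == 1, delta >= 0,
    u > 0, h > 0, eta3d > 0, T > 0
  )
  structure(
    list(A = A, beta = beta, delta = delta, u = u, h = h, eta3d = eta3d,
         T = T),
    class = "hydro_params"
  )
}

#' @export
print.hydro_params <- function(x, ...) {
  cat("<hydro_params>\n")
  cat(sprintf("  A      = %g um^2/s\n", x$A))
  cat(sprintf("  beta   = %g\n", x$beta))
  cat(sprintf("  delta  = %g um\n", x$delta))
  cat(sprintf("  u = %g um, h = %g nm, eta3d = %g Pa s, T = %g K\n",
              x$u, x$h, x$eta3d, x$T))
  invisible(x)
}

#' Numerical constants of the generalized Saffman-Delbruck formula
#'
#' The five constants of the large-inclusion interpolation formula. They are
#' fixed literals of the published formula; overriding them requires
#' `override = TRUE`.
#'
#' @param gamma_e Euler-Mascheroni constant.
#' @param p,q,v,w_c interpolation constants (`w_c` named to avoid collision
#'   with the rim energy `w` used in the energetics module).
#' @param override set `TRUE` to permit non-standard values.
#' @return An object of class `gsd_constants`.
#' @export
gsd_constants <- function(gamma_e = 0.5772, p = 2.74819, q = 0.61465,
                          v = 0.73761, w_c = 0.52119, override = FALSE) {
  std <- c(gamma_e = 0.5772, p = 2.74819, q = 0.61465, v = 0.73761,
           w_c = 0.52119)
  got <- c(gamma_e = gamma_e, p = p, q = q, v = v, w_c = w_c)
  if (!override && !isTRUE(all.equal(std, got))) {
    stop("gsd_constants are fixed literals; pass override = TRUE to change them",
         call. = FALSE)
  }
  structure(as.list(got), class = "gsd_constants")
}

#' Reduced radius of a membrane inclusion
#'
#' Computes the dimensionless reduced radius `epsilon = beta * d / u`
#' (equivalently `d * eta3d / (h * eta)`), the parameter that decides whether
#' membrane or bulk dissipation dominates the drag on the inclusion. The
#' interpolation formula is quoted as valid for `1e-3 < epsilon < 1e3`;
#' values outside that window trigger a warning but are still returned.
#'
#' @param d true domain diameter, um. Vectorized; must be non-negative.
#' @param params a [hydro_params()] object.
#' @return Numeric vector of reduced radii.
#' @examples
#' p <- hydro_params(A = 1, beta = 0.4)
#' reduced_radius(1, p)  # 0.4
#' @export
reduced_radius <- function(d, params) {
  stopifnot(inherits(params, "hydro_params"), is.numeric(d))
  if (any(d < 0)) stop("diameter d must be non-negative", call. = FALSE)
  eps <- params$beta * d / params$u
  out <- eps > 0 & (eps < 1e-3 | eps > 1e3)
  if (any(out)) {
    warning(sprintf(
      "%d reduced radius value(s) outside the validity window [1e-3, 1e3]",
      sum(out)), call. = FALSE)
  }
  eps
}

# epsilon without the range warning, for internal hot paths
.reduced_radius <- function(d, params) params$beta * d / params$u

#' Diffusion coefficient of a domain from the generalized Saffman-Delbruck law
#'
#' Evaluates
#' \deqn{D = A \frac{\ln(2/\epsilon) - \gamma_e + 4\epsilon/\pi -
#'   (\epsilon^2/2)\ln(2/\epsilon)}{1 - (\epsilon^3/\pi)\ln(2/\epsilon) +
#'   v\,\epsilon^p / (1 + w_c\,\epsilon^q)}}
#' with `epsilon = beta * d / u`. This interpolation reproduces the classical
#' Saffman-Delbruck logarithm for small inclusions and remains accurate up to
#' micrometre-scale domains (`1e-3 < epsilon < 1e3`).
#'
#' @param d true domain diameter, um. Vectorized; must be positive.
#' @param params a [hydro_params()] object.
#' @param consts a [gsd_constants()] object.
#' @return Diffusion coefficient(s), um^2/s.
#' @examples
#' gsd_diffusion(0.9e-3, hydro_params(A = 0.76, beta = 0.33))  # ~6.26
#' @export
gsd_diffusion <- function(d, params, consts = gsd_constants()) {
  stopifnot(inherits(params, "hydro_params"), inherits(consts, "gsd_constants"),
            is.numeric(d))
  if (any(d <= 0)) stop("diameter d must be positive", call. = FALSE)
  eps <- .reduced_radius(d, params)
  L <- log(2 / eps)
  num <- L - consts$gamma_e + 4 * eps / pi - eps^2 / 2 * L
  den <- 1 - eps^3 / pi * L + consts$v * eps^consts$p /
    (1 + consts$w_c * eps^consts$q)
  params$A * num / den
}

#' Invert the diffusion law: diameter from a measured diffusion coefficient
#'
#' Solves `gsd_diffusion(d) = D` for `d` by bisection on the search interval
#' `[1e-4, 1e3]` um, over which the law is strictly monotone decreasing so
#' the root is unique.
#'
#' @param D measured diffusion coefficient, um^2/s. Vectorized.
#' @param params a [hydro_params()] object.
#' @param consts a [gsd_constants()] object.
#' @param interval diameter search interval, um.
#' @return Diameter(s) `d` in um with relative residual below 1e-9.
#' @examples
#' p <- hydro_params(A = 0.76, beta = 0.33)
#' invert_diameter(gsd_diffusion(0.1, p), p)  # 0.1
#' @export
invert_diameter <- function(D, params, consts = gsd_constants(),
                            interval = c(1e-4, 1e3)) {
  stopifnot(inherits(params, "hydro_params"), is.numeric(D))
  D_hi <- gsd_diffusion(interval[1], params, consts)
  D_lo <- gsd_diffusion(interval[2], params, consts)
  one <- function(Di) {
    if (!is.finite(Di) || Di < D_lo || Di > D_hi) {
      stop(sprintf(
        "D = %g um^2/s is outside the attainable range [%g, %g] um^2/s for d in [%g, %g] um",
        Di, D_lo, D_hi, interval[1], interval[2]), call. = FALSE)
    }
    # bisection in log-diameter keeps relative precision uniform across scales
    root <- stats::uniroot(
      function(ld) gsd_diffusion(10^ld, params, consts) - Di,
      interval = log10(interval), tol = 1e-13
    )
    d_hat <- 10^root$root
    resid <- abs(gsd_diffusion(d_hat, params, consts) - Di) / Di
    if (resid > 1e-9) {
      stop(sprintf("inversion did not converge (relative residual %g)", resid),
           call. = FALSE)
    }
    d_hat
  }
  vapply(D, one, numeric(1))
}

#' Membrane viscosity from the diffusivity scale A
#'
#' Inverts the prefactor definition `A = k_B T / (4 pi h eta)`.
#'
#' @param params a [hydro_params()] object.
#' @return Membrane viscosity, Pa s.
#' @examples
#' viscosity_from_A(hydro_params(A = 0.76, beta = 0.33))  # ~0.085 Pa s
#' @export
viscosity_from_A <- function(params) {
  stopifnot(inherits(params, "hydro_params"))
  thermal_energy(params$T) /
    (4 * pi * (params$h * 1e-9) * (params$A * 1e-12))
}

#' Membrane viscosity from the mobility ratio beta
#'
#' Inverts `beta = eta3d * u / (h * eta)`.
#'
#' @param params a [hydro_params()] object.
#' @return Membrane viscosity, Pa s.
#' @examples
#' viscosity_from_beta(hydro_params(A = 1, beta = 0.4))  # 0.5 Pa s
#' @export
viscosity_from_beta <- function(params) {
  stopifnot(inherits(params, "hydro_params"))
  params$eta3d * (params$u * 1e-6) / ((params$h * 1e-9) * params$beta)
}

#' Mobility ratio implied by a membrane viscosity
#'
#' The inverse of [viscosity_from_beta()]: `beta = eta3d * u / (h * eta)`.
#'
#' @param eta membrane viscosity, Pa s.
#' @param u reference length, um.
#' @param h bilayer thickness, nm.
#' @param eta3d bulk viscosity, Pa s.
#' @return Dimensionless `beta`.
#' @export
beta_from_viscosity <- function(eta, u = 1, h = 5, eta3d = 1e-3) {
  stopifnot(eta > 0, u > 0, h > 0, eta3d > 0)
  eta3d * (u * 1e-6) / ((h * 1e-9) * eta)
}

#' Bulk viscosity implied by jointly fitted A and beta
#'
#' When `A` and `beta` are estimated independently they are still linked
#' through the water viscosity: `beta * k_B T / (4 pi u A) = eta3d`. This
#' returns the implied value for comparison with the nominal `params$eta3d`;
#' agreement is a consistency check on the fit.
#'
#' @param params a [hydro_params()] object.
#' @return Implied bulk viscosity, Pa s.
#' @export
eta3d_consistency <- function(params) {
  stopifnot(inherits(params, "hydro_params"))
  params$beta * thermal_energy(params$T) /
    (4 * pi * (params$u * 1e-6) * (params$A * 1e-12))
}

#' True diameter from apparent diameter and offset
#'
#' Optical measurements overestimate the domain diameter by a constant
#' offset `delta` (motion blur during the scan plus diffraction), so the
#' true diameter is `d = d_a - delta`. Uncertainties combine in quadrature.
#' A non-positive result is returned flagged (`physical = FALSE`) rather
#' than clipped.
#'
#' @param d_a apparent diameter(s), um.
#' @param delta offset, um (scalar).
#' @param sigma_da,sigma_delta standard uncertainties of `d_a` and `delta`.
#' @return A tibble with columns `d_a`, `d`, `sigma_d`, `physical`.
#' @examples
#' true_diameter(1.0, 0.46, sigma_da = 0.03, sigma_delta = 0.02)
#' @export
true_diameter <- function(d_a, delta, sigma_da = 0, sigma_delta = 0) {
  stopifnot(is.numeric(d_a), is.numeric(delta), length(delta) == 1,
            delta >= 0, all(sigma_da >= 0), sigma_delta >= 0)
  d <- d_a - delta
  tibble::tibble(
    d_a = d_a,
    d = d,
    sigma_d = sqrt(sigma_da^2 + sigma_delta^2),
    physical = d > 0
  )
}
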