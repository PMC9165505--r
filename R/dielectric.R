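#' Dielectric parameters of a dual-frequency nematic
#'
#' Bundles the constants of the single-relaxation (Debye-type) model for the
#' permittivity along the long molecular axis,
#' \deqn{\varepsilon_\parallel(\omega) = \varepsilon_{\parallel,\infty} +
#'   \frac{\varepsilon_{\parallel,0} - \varepsilon_{\parallel,\infty}}
#'        {1 + (\omega\tau)^2},}
#' while the short-axis permittivity \eqn{\varepsilon_\perp} is frequency
#' independent.  The anisotropy \eqn{\Delta\varepsilon(\omega) =
#' \varepsilon_\parallel(\omega) - \varepsilon_\perp} changes sign at the
#' zero-crossing frequency \eqn{\omega_0} provided
#' \eqn{\varepsilon_{\parallel,\infty} < \varepsilon_\perp <
#' \varepsilon_{\parallel,0}}.
#'
#' Defaults are the model constants used throughout the package:
#' \eqn{\varepsilon_{\parallel,0} = 0.5}, \eqn{\varepsilon_{\parallel,\infty}
#' = 0.01}, \eqn{\varepsilon_\perp = 0.2}, \eqn{\tau = 0.6} s, which place
#' the zero-crossing at \eqn{\omega_0 \approx 2.094\ \mathrm{s}^{-1}}.
#'
#' @param eps_par_0 static (\eqn{\omega = 0}) long-axis relative permittivity.
#' @param eps_par_inf high-frequency limit of the long-axis permittivity.
#' @param eps_perp short-axis relative permittivity (frequency independent).
#' @param tau dipole relaxation time in seconds; must be positive.
#' @return An object of class `dielectric_params`.
#' @examples
#' p <- dielectric_params()
#' delta_eps(p, 1.1) # > 0: parallel alignment regime
#' delta_eps(p, 6.3) # < 0: perpendicular alignment regime
#' zero_crossing(p)
#' @export
dielectric_params <- function(eps_par_0 = 0.5, eps_par_inf = 0.01,
                              eps_perp = 0.2, tau = 0.6) {
  stopifnot(is.numeric(eps_par_0), is.numeric(eps_par_inf),
            is.numeric(eps_perp), is.numeric(tau),
            length(eps_par_0) == 1, length(eps_par_inf) == 1,
            length(eps_perp) == 1, length(tau) == 1)
  if (!is.finite(tau) || tau <= 0)
    stop("'tau' must be a positive relaxation time (seconds)")
  if (eps_par_0 <= eps_par_inf)
    stop("'eps_par_0' must exceed 'eps_par_inf' (relaxation lowers eps_par)")
  structure(
    list(eps_par_0 = eps_par_0, eps_par_inf = eps_par_inf,
         eps_perp = eps_perp, tau = tau),
    class = "dielectric_params")
}

#' @export
print.dielectric_params <- function(x, ...) {
  cat("Dual-frequency dielectric parameters\n")
  cat(sprintf("  eps_par_0 = %g, eps_par_inf = %g, eps_perp = %g, tau = %g s\n",
              x$eps_par_0, x$eps_par_inf, x$eps_perp, x$tau))
  w0 <- tryCatch(zero_crossing(x), error = function(e) NA_real_)
  if (is.finite(w0))
    cat(sprintf("  zero-crossing omega_0 = %.4f s^-1\n", w0))
  else cat("  no finite zero-crossing\n")
  invisible(x)
}

#' Debye relaxation parameters
#'
#' Constants of the classical Debye dielectric relaxation with a Lorentz
#' local-field correction; see [debye_eps()].
#'
#' @param eps_0 static permittivity.
#' @param eps_inf high-frequency permittivity; must be below `eps_0`.
#' @param tau relaxation time (seconds), positive.
#' @return An object of class `debye_params`.
#' @export
debye_params <- function(eps_0, eps_inf, tau) {
  if (!is.finite(tau) || tau <= 0) stop("'tau' must be positive")
  if (!(eps_0 > eps_inf)) stop("'eps_0' must exceed 'eps_inf'")
  structure(list(eps_0 = eps_0, eps_inf = eps_inf, tau = tau),
            class = "debye_params")
}

check_omega <- function(omega) {
  if (!is.numeric(omega) || any(!is.nan(omega) & omega < 0))
    stop("'omega' must be a non-negative angular frequency (s^-1)")
  omega
}

#' Long-axis permittivity of the dual-frequency nematic
#'
#' Evaluates \eqn{\varepsilon_\parallel(\omega)}; strictly decreasing in
#' \eqn{\omega}, from `eps_par_0` at \eqn{\omega = 0} towards `eps_par_inf`.
#'
#' @param params a [dielectric_params()] object.
#' @param omega angular frequency in \eqn{s^{-1}} (vectorised, must be >= 0).
#' @return Permittivity values, same length as `omega`.
#' @export
eps_parallel <- function(params, omega) {
  stopifnot(inherits(params, "dielectric_params"))
  check_omega(omega)
  params$eps_par_inf +
    (params$eps_par_0 - params$eps_par_inf) / (1 + (omega * params$tau)^2)
}

#' Dielectric anisotropy
#'
#' \eqn{\Delta\varepsilon(\omega) = \varepsilon_\parallel(\omega) -
#' \varepsilon_\perp}.  Positive below the zero-crossing frequency (director
#' aligns with the field), negative above it (perpendicular alignment).
#'
#' @inheritParams eps_parallel
#' @return Anisotropy values, same length as `omega`.
#' @export
delta_eps <- function(params, omega) {
  eps_parallel(params, omega) - params$eps_perp
}

#' Zero-crossing frequency of the dielectric anisotropy
#'
#' Closed form root of \eqn{\Delta\varepsilon(\omega) = 0}:
#' \deqn{\omega_0 = \frac{1}{\tau}\sqrt{
#'   \frac{\varepsilon_{\parallel,0} - \varepsilon_{\parallel,\infty}}
#'        {\varepsilon_\perp - \varepsilon_{\parallel,\infty}} - 1}.}
#' Requires \eqn{\varepsilon_{\parallel,\infty} < \varepsilon_\perp \le
#' \varepsilon_{\parallel,0}}; with the package defaults the value is
#' 2.0944 \eqn{s^{-1}} (2.1 to one decimal).
#'
#' @inheritParams eps_parallel
#' @return The angular frequency \eqn{\omega_0} in \eqn{s^{-1}}.
#' @export
zero_crossing <- function(params) {
  stopifnot(inherits(params, "dielectric_params"))
  lo <- params$eps_par_inf; hi <- params$eps_par_0; ep <- params$eps_perp
  if (!(ep > lo && ep <= hi))
    stop("no zero-crossing: requires eps_par_inf < eps_perp <= eps_par_0")
  sqrt((hi - lo) / (ep - lo) - 1) / params$tau
}

#' Frequency realising a prescribed anisotropy
#'
#' Inverse of [delta_eps()] on its decreasing branch: the \eqn{\omega \ge 0}
#' with \eqn{\Delta\varepsilon(\omega)} equal to `target`.  Useful to drive
#' the simulator at a chosen coupling strength.
#'
#' @inheritParams eps_parallel
#' @param target requested anisotropy; must lie in
#'   `(eps_par_inf - eps_perp, eps_par_0 - eps_perp]`.
#' @return Angular frequency in \eqn{s^{-1}}.
#' @export
omega_for_delta_eps <- function(params, target) {
  stopifnot(inherits(params, "dielectric_params"), length(target) == 1)
  lo <- params$eps_par_inf - params$eps_perp
  hi <- params$eps_par_0 - params$eps_perp
  if (!(target > lo && target <= hi))
    stop(sprintf("'target' must lie in (%g, %g]", lo, hi))
  eps_target <- target + params$eps_perp
  sqrt((params$eps_par_0 - params$eps_par_inf) /
         (eps_target - params$eps_par_inf) - 1) / params$tau
}

#' Debye permittivity with Lorentz local-field factor
#'
#' Evaluates
#' \deqn{\varepsilon(\omega) = \varepsilon_\infty +
#'  \frac{\varepsilon_0 - \varepsilon_\infty}
#'       {1 + \left[\frac{\varepsilon_0 + 2}{\varepsilon_\infty + 2}
#'        \omega\tau\right]^2}.}
#' The local-field factor \eqn{(\varepsilon_0+2)/(\varepsilon_\infty+2)}
#' rescales the effective relaxation time; the simpler single-relaxation
#' form without it ([eps_parallel()]) is the authoritative model everywhere
#' downstream.
#'
#' @param params a [debye_params()] object.
#' @param omega angular frequency in \eqn{s^{-1}}, vectorised, >= 0.
#' @return Permittivity values.
#' @export
debye_eps <- function(params, omega) {
  stopifnot(inherits(params, "debye_params"))
  check_omega(omega)
  f <- (params$eps_0 + 2) / (params$eps_inf + 2)
  params$eps_inf +
    (params$eps_0 - params$eps_inf) / (1 + (f * omega * params$tau)^2)
}

#' Freedericksz transition criterion
#'
#' Tests whether an applied field of magnitude `E` exceeds the Freedericksz
#' threshold of a nematic slab, i.e. whether
#' \deqn{\frac{d^2}{\pi^2}\,\frac{|\Delta\varepsilon|}{R_1} \ge
#'       \frac{1}{E^2}.}
#' The absolute anisotropy is used so the criterion covers both the
#' parallel (\eqn{\Delta\varepsilon > 0}) and perpendicular
#' (\eqn{\Delta\varepsilon < 0}) reorientation branches; equality counts as
#' satisfied.  \eqn{\Delta\varepsilon = 0} never satisfies the criterion.
#'
#' @param delta_eps dielectric anisotropy (may be negative).
#' @param d domain size, model length units; positive.
#' @param R1 elastic constant, model units; positive.
#' @param E field magnitude, model units; positive.
#' @return Logical: is the threshold condition met?
#' @export
freedericksz_satisfied <- function(delta_eps, d, R1, E) {
  stopifnot(is.numeric(delta_eps), is.numeric(d), is.numeric(R1),
            is.numeric(E))
  if (any(d <= 0) || any(R1 <= 0) || any(E <= 0))
    stop("'d', 'R1' and 'E' must be positive")
  ae <- abs(delta_eps)
  ae > 0 & (d^2 / pi^2) * (ae / R1) >= 1 / E^2
}
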