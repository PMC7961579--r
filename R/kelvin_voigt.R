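#' Kelvin-Voigt creep response to a step stress
#'
#' Strain of a Kelvin-Voigt solid (spring of elastic modulus `E` in parallel
#' with a dashpot of viscosity `eta`) under a constant stress `sigma0` applied
#' at `t = 0`:
#' \deqn{\gamma(t) = \frac{\sigma_0}{E}\left(1 - e^{-t/\tau}\right), \qquad
#'   \tau = \eta / E.}
#'
#' @param t Time since stress onset, seconds (vectorised, `t >= 0`).
#' @param E Elastic modulus, Pa (`> 0`).
#' @param eta Viscosity, Pa s (`> 0`).
#' @param sigma0 Step stress, Pa (`>= 0`).
#' @return Dimensionless strain, same length as `t`.
#' @seealso [active_kv_creep()], [kv_relax()]
#' @export
kv_creep <- function(t, E, eta, sigma0) {
  check_kv_params(E, eta)
  if (any(t < 0)) stop("t must be >= 0")
  tau <- eta / E
  (sigma0 / E) * (1 - exp(-t / tau))
}

#' Active Kelvin-Voigt creep with linear contractility
#'
#' Extends the Kelvin-Voigt creep response with an active contraction of the
#' cell opposing the optical stretch: the effective stress decreases linearly
#' at rate `a` (the activity, Pa/s) and is clamped at zero once the
#' contraction has cancelled the applied stress,
#' \deqn{\eta\dot\gamma + E\gamma = \max(\sigma_0 - a t,\, 0), \quad
#'   \gamma(0) = 0.}
#' On the unclamped range the solution is
#' \deqn{\gamma(t) = \frac{\sigma_0}{E}(1 - e^{-t/\tau})
#'   - \frac{a}{E}\left[t - \tau(1 - e^{-t/\tau})\right];}
#' for `t` beyond the clamp time \eqn{t_c = \sigma_0/a} the strain decays
#' exponentially from \eqn{\gamma(t_c)} with time constant \eqn{\tau}.
#'
#' @inheritParams kv_creep
#' @param a Activity (rate of linear stress decrease), Pa/s (`>= 0`).
#' @return Dimensionless strain, same length as `t`.
#' @export
active_kv_creep <- function(t, E, eta, sigma0, a) {
  check_kv_params(E, eta)
  if (length(a) != 1L || is.na(a) || a < 0) stop("activity a must be >= 0")
  if (any(t < 0)) stop("t must be >= 0")
  if (a == 0) {
    return(kv_creep(t, E, eta, sigma0))
  }
  tau <- eta / E
  tc <- sigma0 / a
  g_unclamped <- function(tt) {
    em <- 1 - exp(-tt / tau)
    (sigma0 / E) * em - (a / E) * (tt - tau * em)
  }
  out <- numeric(length(t))
  pre <- t <= tc
  out[pre] <- g_unclamped(t[pre])
  if (any(!pre)) {
    gc_ <- g_unclamped(tc)
    out[!pre] <- gc_ * exp(-(t[!pre] - tc) / tau)
  }
  out
}

#' Exponential strain relaxation after the step stress
#'
#' After the laser is set back to trapping power (approximated as zero
#' stress), a Kelvin-Voigt solid recovers exponentially:
#' \eqn{\gamma(T + \Delta t) = \gamma(T)\, e^{-\Delta t/\tau}}.
#'
#' @param dt_after_stretch Time since the end of the step stress, seconds
#'   (vectorised, `>= 0`).
#' @param strain_at_end Strain at the end of the step stress.
#' @param tau Relaxation time \eqn{\tau = \eta/E}, seconds (`> 0`).
#' @return Dimensionless strain.
#' @export
kv_relax <- function(dt_after_stretch, strain_at_end, tau) {
  if (tau <= 0) stop("tau must be > 0")
  if (any(dt_after_stretch < 0)) stop("dt must be >= 0")
  strain_at_end * exp(-dt_after_stretch / tau)
}

#' Strain over a full protocol (baseline, stretch, relaxation)
#'
#' Piecewise forward model used by the synthetic-trace generator: zero strain
#' during the pre-stretch baseline, active Kelvin-Voigt creep during the
#' stretch phase, exponential recovery during relaxation.
#'
#' @param t_abs Absolute frame times in seconds (from the start of recording).
#' @inheritParams active_kv_creep
#' @param protocol A [stretch_protocol()].
#' @return Dimensionless strain at each `t_abs`.
#' @export
kv_strain_profile <- function(t_abs, E, eta, sigma0, a, protocol) {
  t0 <- protocol$pre_stretch_duration
  t1 <- t0 + protocol$stretch_duration
  tau <- eta / E
  out <- numeric(length(t_abs))
  stretch <- t_abs >= t0 & t_abs <= t1
  relax <- t_abs > t1
  out[stretch] <- active_kv_creep(t_abs[stretch] - t0, E, eta, sigma0, a)
  if (any(relax)) {
    g_end <- active_kv_creep(protocol$stretch_duration, E, eta, sigma0, a)
    out[relax] <- kv_relax(t_abs[relax] - t1, g_end, tau)
  }
  out
}

check_kv_params <- function(E, eta) {
  if (length(E) != 1L || is.na(E) || E <= 0) stop("E must be > 0")
  if (length(eta) != 1L || is.na(eta) || eta <= 0) stop("eta must be > 0")
  invisible(TRUE)
}
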