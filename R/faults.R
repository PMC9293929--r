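#' Actuator fault profile
#'
#' Degradation of the delivered insulin infusion, modeled as a
#' time-dependent multiplicative gain loss `rho(t)` plus an additive bias
#' `phi(t)`:
#' `rho(t) = rho_floor + rho_span * exp(-rho_rate * t)` (decays from 1 to
#' `rho_floor`), `phi(t) = phi_amp * (1 - exp(-phi_rate * t))` (grows from
#' 0 to `phi_amp`).  Defaults give a deliberately severe fault: within
#' about an hour of simulation start the pump delivers only 1% of the
#' commanded dose plus a constant 0.1 uU/ml/min bias.
#'
#' @param rho_floor Asymptotic multiplicative gain (0 < rho <= 1).
#' @param rho_span Initial excess gain above the floor.
#' @param rho_rate Decay rate of the gain loss, 1/min.
#' @param phi_amp Asymptotic additive bias, uU/ml/min.
#' @param phi_rate Growth rate of the bias, 1/min.
#' @param enabled If `FALSE` the profile is the identity.
#' @return Object of class `actuator_fault_profile`.
#' @export
actuator_fault_profile <- function(rho_floor = 0.01, rho_span = 0.99,
                                   rho_rate = 0.1, phi_amp = 0.1,
                                   phi_rate = 0.1, enabled = TRUE) {
  if (rho_floor <= 0) stop("rho_floor must be > 0")
  if (rho_floor + rho_span > 1 + 1e-12) stop("rho(0) must be <= 1")
  if (rho_span < 0 || rho_rate < 0 || phi_amp < 0 || phi_rate < 0) {
    stop("fault profile rates and spans must be >= 0")
  }
  structure(list(rho_floor = rho_floor, rho_span = rho_span,
                 rho_rate = rho_rate, phi_amp = phi_amp,
                 phi_rate = phi_rate, enabled = isTRUE(enabled)),
            class = "actuator_fault_profile")
}

#' Multiplicative actuator fault gain rho(t)
#'
#' @param t Time(s) from simulation start, minutes; vectorized.
#' @param profile An [actuator_fault_profile()].
#' @return rho(t) in (0, 1].
#' @export
multiplicative_fault <- function(t, profile) {
  stopifnot(all(t >= 0))
  profile$rho_floor + profile$rho_span * exp(-profile$rho_rate * t)
}

#' Additive actuator fault bias phi(t)
#'
#' @inheritParams multiplicative_fault
#' @return phi(t) >= 0, uU/ml/min.
#' @export
additive_fault <- function(t, profile) {
  stopifnot(all(t >= 0))
  profile$phi_amp * (1 - exp(-profile$phi_rate * t))
}

#' Apply the actuator fault to a commanded infusion
#'
#' `u_faulty = rho(t) * u + phi(t)`; identity when the profile is disabled
#' or `NULL`.  The controller never sees the faulted value: the fault acts
#' between controller output and plant input.
#'
#' @param u Commanded infusion rate, uU/ml/min.
#' @inheritParams multiplicative_fault
#' @return Delivered infusion rate.
#' @export
apply_actuator_fault <- function(u, t, profile) {
  if (is.null(profile) || !profile$enabled) return(u)
  multiplicative_fault(t, profile) * u + additive_fault(t, profile)
}

#' Controller dropout window
#'
#' During `(t_start, t_end)` (strict inequalities) the delivered infusion
#' is attenuated to `attenuation * u`, emulating a near-total loss of the
#' control channel for a while.  Defaults: 10 A.M. to noon (t = 240 to 360
#' with t = 0 at 6 A.M.) at gain 0.002.
#'
#' @param t_start,t_end Window boundaries, minutes; `t_start < t_end`.
#' @param attenuation Multiplier inside the window (0 < attenuation <= 1).
#' @return Object of class `dropout_window`.
#' @export
dropout_window <- function(t_start = 240, t_end = 360, attenuation = 0.002) {
  if (t_start >= t_end) stop("t_start must be < t_end")
  if (attenuation <= 0 || attenuation > 1) {
    stop("attenuation must be in (0, 1]")
  }
  structure(list(t_start = t_start, t_end = t_end, attenuation = attenuation),
            class = "dropout_window")
}

#' Apply the dropout window to a commanded infusion
#'
#' @param u Commanded (or already fault-degraded) infusion rate.
#' @param t Time, minutes.
#' @param window A [dropout_window()] or `NULL`.
#' @return Delivered infusion rate.
#' @export
apply_dropout <- function(u, t, window) {
  if (is.null(window)) return(u)
  if (t > window$t_start && t < window$t_end) window$attenuation * u else u
}
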