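#' Controller gains for the backstepping cascade
#'
#' Three positive gains, one per backstepping step; the same triple serves
#' the plain and the adaptive controller.
#'
#' @param k1,k2,k3 Positive gains (1/min).  Defaults are the nominal tuning.
#' @return Object of class `controller_gains`.
#' @export
controller_gains <- function(k1 = 0.43, k2 = 0.46, k3 = 0.62) {
  stopifnot(is.numeric(k1), is.numeric(k2), is.numeric(k3))
  if (k1 <= 0 || k2 <= 0 || k3 <= 0) {
    stop("backstepping gains must be positive constants")
  }
  structure(list(k1 = k1, k2 = k2, k3 = k3), class = "controller_gains")
}

#' Desired remote insulin action (first backstepping step)
#'
#' Solves the glucose error dynamics `e1_dot = -k1 e1` for the remote
#' insulin action that would realize it:
#' `x2d = (1/x1) * [-p1 (x1 - Gb) - x1d_dot + k1 (x1 - x1d) + d_hat]`.
#' The plain backstepping law passes `d_hat = 0` (the meal disturbance is
#' unknown and cannot enter the controller); the adaptive law passes its
#' running disturbance estimate.
#'
#' @param x1 Measured glucose, mg/dl.
#' @param x1d Reference glucose, mg/dl.
#' @param x1d_dot Reference derivative, mg/dl/min.
#' @param gains A [controller_gains()] object.
#' @param params A [patient_params()] object.
#' @param d_hat Disturbance estimate, mg/dl/min (0 for plain backstepping).
#' @param guard Minimum admissible glucose (mg/dl) before the division by
#'   `x1` is declared degenerate.
#' @return Desired remote insulin action `x2d`, 1/min.
#' @export
desired_x2 <- function(x1, x1d, x1d_dot, gains, params, d_hat = 0, guard = 1) {
  if (x1 < guard) {
    stop(sprintf("degenerate controller state: G = %.4g mg/dl below guard %g",
                 x1, guard))
  }
  (-params$p1 * (x1 - params$Gb) - x1d_dot + gains$k1 * (x1 - x1d) + d_hat) / x1
}

#' Desired plasma insulin (second backstepping step)
#'
#' `x3d = Ib + (1/p3) * [p2 x2 + x2d_dot - k2 (x2 - x2d)]`.
#'
#' @param x2 Remote insulin action, 1/min.
#' @param x2d Desired remote insulin action, 1/min.
#' @param x2d_dot Its time derivative, 1/min^2.
#' @inheritParams desired_x2
#' @return Desired plasma insulin `x3d`, uU/ml.
#' @export
desired_x3 <- function(x2, x2d, x2d_dot, gains, params) {
  params$Ib +
    (params$p2 * x2 + x2d_dot - gains$k2 * (x2 - x2d)) / params$p3
}

#' Insulin infusion control law (third backstepping step)
#'
#' `u = n (x3 - Ib) + x3d_dot - k3 (x3 - x3d)`.  Optionally clamped at zero
#' (an insulin pump cannot extract insulin); the default leaves `u`
#' unclamped.
#'
#' @param x3 Plasma insulin, uU/ml.
#' @param x3d Desired plasma insulin, uU/ml.
#' @param x3d_dot Its time derivative, uU/ml/min.
#' @param nonnegative Clamp the infusion rate at zero.
#' @inheritParams desired_x2
#' @return Commanded infusion rate `u`, uU/ml/min.
#' @export
control_law <- function(x3, x3d, x3d_dot, gains, params, nonnegative = FALSE) {
  u <- params$n * (x3 - params$Ib) + x3d_dot - gains$k3 * (x3 - x3d)
  if (nonnegative) u <- max(u, 0)
  u
}

#' Backward-difference derivative of a sampled signal
#'
#' The desired-state derivatives `x2d_dot`, `x3d_dot` needed by the cascade
#' are obtained by differencing consecutive controller samples
#' (sample-and-hold digital control).  At the first controller step no
#' previous sample exists and the derivative is zero.
#'
#' @param current Current sample.
#' @param previous Previous sample, or `NULL` at start-up.
#' @param dt Controller step, minutes (> 0).
#' @return The backward-difference derivative, or 0 at start-up.
#' @export
hold_derivative <- function(current, previous, dt) {
  if (dt <= 0) stop("controller step dt must be > 0")
  if (is.null(previous)) return(0)
  (current - previous) / dt
}
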