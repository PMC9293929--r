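#' One step of the adaptive disturbance-estimation rule
#'
#' The Lyapunov-derived update `d(D_hat)/dt = delta * e1` is discretized by
#' forward Euler on the controller grid: the estimate moves in the
#' direction of the glucose tracking error, with no projection or leakage.
#' A persistent positive error (glucose above its reference, as after a
#' meal) therefore inflates the estimate until the extra insulin action it
#' commands pulls the error back.
#'
#' @param d_hat Current disturbance estimate, mg/dl/min.
#' @param e1 Glucose tracking error `G - G_d`, mg/dl.
#' @param delta Adaptation gain (> 0).
#' @param dt Controller step, minutes (> 0).
#' @return Updated estimate.
#' @export
adaptive_update <- function(d_hat, e1, delta, dt) {
  if (dt <= 0) stop("controller step dt must be > 0")
  d_hat + delta * e1 * dt
}

#' Composite Lyapunov function of the adaptive closed loop
#'
#' `V3 = e1^2/2 + e2^2/2 + e3^2/2 + d_tilde^2 / (2 delta)` where `d_tilde`
#' is the disturbance estimation error `D - D_hat`.  Along closed-loop
#' trajectories its derivative is `-k1 e1^2 - k2 e2^2 - k3 e3^2 <= 0`, so
#' between meal onsets (where the true disturbance jumps and re-inflates
#' the estimation term) the series is non-increasing.
#'
#' @param e1,e2,e3 Tracking errors of the three backstepping steps.
#' @param d_tilde Disturbance estimation error, mg/dl/min.
#' @param delta Adaptation gain (> 0).
#' @return Non-negative scalar (vectorized over equal-length inputs).
#' @export
lyapunov_v3 <- function(e1, e2, e3, d_tilde, delta) {
  if (any(delta <= 0)) stop("delta must be > 0")
  0.5 * e1^2 + 0.5 * e2^2 + 0.5 * e3^2 + d_tilde^2 / (2 * delta)
}
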