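#' Patient parameters of the Bergman minimal model
#'
#' Constructs the parameter set of the three-state glucose--insulin minimal
#' model: plasma glucose `G` (mg/dl), remote (interstitial) insulin action
#' `X` (1/min) and plasma insulin `I` (uU/ml).  Defaults are the nominal
#' type-1 diabetic patient used throughout the package.
#'
#' @param p1 Insulin-independent glucose uptake rate (1/min).  Zero for the
#'   nominal type-1 patient: without insulin action glucose does not clear.
#' @param p2 Decay rate of remote insulin action (1/min).
#' @param p3 Gain from plasma insulin excess to remote insulin action
#'   (ml/uU/min).
#' @param n Plasma insulin disappearance rate (1/min).
#' @param Gb Basal glucose level (mg/dl).
#' @param Ib Basal insulin level (uU/ml).
#' @return An object of class `patient_params` (named list).
#' @examples
#' patient_params()
#' @export
patient_params <- function(p1 = 0, p2 = 0.0142, p3 = 1.5e-5, n = 0.2814,
                           Gb = 90, Ib = 7) {
  stopifnot(is.numeric(p1), is.numeric(p2), is.numeric(p3),
            is.numeric(n), is.numeric(Gb), is.numeric(Ib))
  if (p1 < 0) stop("p1 must be >= 0")
  if (p2 <= 0) stop("p2 must be > 0")
  if (p3 <= 0) stop("p3 must be > 0")
  if (n <= 0) stop("n must be > 0")
  if (Gb <= 0) stop("Gb must be > 0")
  if (Ib < 0) stop("Ib must be >= 0")
  structure(list(p1 = p1, p2 = p2, p3 = p3, n = n, Gb = Gb, Ib = Ib),
            class = "patient_params")
}

#' @export
print.patient_params <- function(x, ...) {
  cat("Bergman minimal model parameters:\n")
  cat(sprintf("  p1 = %g 1/min, p2 = %g 1/min, p3 = %g ml/uU/min\n",
              x$p1, x$p2, x$p3))
  cat(sprintf("  n = %g 1/min, Gb = %g mg/dl, Ib = %g uU/ml\n",
              x$n, x$Gb, x$Ib))
  invisible(x)
}

#' Plant state of the minimal model
#'
#' @param G Plasma glucose, mg/dl (must be positive).
#' @param X Remote insulin action, 1/min.
#' @param I Plasma insulin, uU/ml.
#' @return Named numeric vector of class `plant_state`.
#' @export
plant_state <- function(G, X, I) {
  stopifnot(is.numeric(G), is.numeric(X), is.numeric(I))
  if (G <= 0) stop("G must be > 0 for a physically meaningful state")
  structure(c(G = G, X = X, I = I), class = "plant_state")
}

#' Right-hand side of the minimal-model ODE
#'
#' dG/dt = -p1 (G - Gb) - G X + D;
#' dX/dt = -p2 X + p3 (I - Ib);
#' dI/dt = -n (I - Ib) + u.
#'
#' `u` is the insulin infusion rate (uU/ml/min) and `D` the rate of glucose
#' appearance from meals (mg/dl/min).
#'
#' @param state Named numeric vector with components `G`, `X`, `I` (a
#'   [plant_state()] or plain vector).
#' @param u Insulin infusion rate, uU/ml/min.
#' @param D Meal glucose appearance rate, mg/dl/min.
#' @param params A [patient_params()] object.
#' @param guard Minimum admissible glucose (mg/dl); below it the trajectory
#'   is degenerate (the control law divides by G) and an error is raised.
#' @return Named numeric vector `c(G, X, I)` of time derivatives.
#' @export
plant_rhs <- function(state, u, D, params, guard = 1) {
  G <- unname(state[["G"]]); X <- unname(state[["X"]]); I <- unname(state[["I"]])
  if (G < guard) {
    stop(sprintf("degenerate trajectory: G = %.4g mg/dl below guard %g", G, guard))
  }
  c(G = -params$p1 * (G - params$Gb) - G * X + D,
    X = -params$p2 * X + params$p3 * (I - params$Ib),
    I = -params$n * (I - params$Ib) + u)
}

#' Basal equilibrium of the plant
#'
#' The fixed point of the minimal model with no infusion and no meal:
#' `(Gb, 0, Ib)`.  [plant_rhs()] evaluates to exactly zero there.
#'
#' @param params A [patient_params()] object.
#' @return A [plant_state()].
#' @export
basal_equilibrium <- function(params) {
  plant_state(G = params$Gb, X = 0, I = params$Ib)
}

#' A single meal event
#'
#' Each meal contributes a decaying exponential to the glucose appearance
#' rate: `A * exp(-B * (t - t_onset))` for `t >= t_onset`.
#'
#' @param t_onset Onset time, minutes from simulation start.
#' @param A Amplitude, mg/dl/min.
#' @param B Decay rate, 1/min.
#' @return Object of class `meal_event`.
#' @export
meal_event <- function(t_onset, A, B = 0.01) {
  stopifnot(is.numeric(t_onset), is.numeric(A), is.numeric(B))
  if (t_onset < 0) stop("t_onset must be >= 0")
  if (A <= 0) stop("meal amplitude A must be > 0")
  if (B < 0) stop("meal decay rate B must be >= 0")
  structure(list(t_onset = t_onset, A = A, B = B), class = "meal_event")
}

#' An ordered schedule of meals
#'
#' @param ... [meal_event()] objects, or a single list of them.  Onsets must
#'   be strictly increasing.
#' @return Object of class `meal_schedule`.
#' @seealso [default_meals()] for the nominal three-meal day.
#' @export
meal_schedule <- function(...) {
  events <- list(...)
  if (length(events) == 1L && !inherits(events[[1L]], "meal_event")) {
    events <- events[[1L]]
  }
  if (!all(vapply(events, inherits, logical(1), "meal_event"))) {
    stop("all schedule entries must be meal_event objects")
  }
  onsets <- vapply(events, function(e) e$t_onset, numeric(1))
  if (length(onsets) > 1L && any(diff(onsets) <= 0)) {
    stop("meal onsets must be strictly increasing")
  }
  structure(events, class = "meal_schedule")
}

#' The nominal three-meal day
#'
#' Simulation time starts at 6 A.M.  Breakfast at 8 A.M. (t = 120 min,
#' A = 0.4), lunch at 2 P.M. (t = 480, A = 0.6), dinner at 8 P.M.
#' (t = 840, A = 0.5); all decay at B = 0.01/min.  Lunch is the largest
#' meal, dinner second, breakfast smallest.
#'
#' @return A [meal_schedule()].
#' @export
default_meals <- function() {
  meal_schedule(meal_event(120, 0.4, 0.01),
                meal_event(480, 0.6, 0.01),
                meal_event(840, 0.5, 0.01))
}

#' Meal disturbance signal D(t)
#'
#' Glucose appearance rate from the meal schedule.  By default overlapping
#' meal tails are summed (physical additivity of glucose appearance); with
#' `superpose = FALSE` only the most recent meal contributes (each meal
#' resets the signal).
#'
#' @param t Time(s), minutes from simulation start; vectorized.
#' @param schedule A [meal_schedule()].
#' @param superpose Sum overlapping meal tails (default) or keep only the
#'   most recent meal.
#' @return Numeric vector of D(t), mg/dl/min (non-negative).
#' @export
meal_disturbance <- function(t, schedule, superpose = TRUE) {
  stopifnot(all(t >= 0))
  if (length(schedule) == 0L) return(numeric(length(t)))
  onsets <- vapply(schedule, function(e) e$t_onset, numeric(1))
  A <- vapply(schedule, function(e) e$A, numeric(1))
  B <- vapply(schedule, function(e) e$B, numeric(1))
  vapply(t, function(ti) {
    active <- which(ti >= onsets)
    if (length(active) == 0L) return(0)
    if (!superpose) active <- max(active)
    sum(A[active] * exp(-B[active] * (ti - onsets[active])))
  }, numeric(1))
}

#' Exponential reference trajectory for blood glucose
#'
#' The target signal `G_d(t) = Ginf + (G0 - Ginf) * exp(-t / tau)` decays
#' from the patient's initial glucose to the normoglycemic set point.
#'
#' @param G0 Initial reference value, mg/dl (matched to the patient's
#'   starting glucose).
#' @param Ginf Asymptotic target, mg/dl.
#' @param tau Time constant, minutes.
#' @return Object of class `reference_trajectory`.
#' @export
reference_trajectory <- function(G0 = 150, Ginf = 100, tau = 100) {
  stopifnot(is.numeric(G0), is.numeric(Ginf), is.numeric(tau))
  if (tau <= 0) stop("tau must be > 0")
  if (G0 <= 0 || Ginf <= 0) stop("reference glucose levels must be > 0")
  structure(list(G0 = G0, Ginf = Ginf, tau = tau),
            class = "reference_trajectory")
}

#' Evaluate the reference trajectory
#'
#' @param t Time(s), minutes; vectorized.
#' @param traj A [reference_trajectory()].
#' @return G_d(t) in mg/dl.
#' @export
reference_value <- function(t, traj) {
  stopifnot(all(t >= 0))
  traj$Ginf + (traj$G0 - traj$Ginf) * exp(-t / traj$tau)
}

#' Analytic derivatives of the reference trajectory
#'
#' @inheritParams reference_value
#' @return List with components `first` (mg/dl/min) and `second`
#'   (mg/dl/min^2), each the same length as `t`.
#' @export
reference_derivatives <- function(t, traj) {
  stopifnot(all(t >= 0))
  amp <- traj$G0 - traj$Ginf
  e <- exp(-t / traj$tau)
  list(first = -amp / traj$tau * e,
       second = amp / traj$tau^2 * e)
}
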