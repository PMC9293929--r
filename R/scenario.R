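#' Build a closed-loop simulation scenario
#'
#' Bundles the patient, meals, reference trajectory, controller
#' configuration, optional stress profiles and numerical settings into a
#' validated scenario object, the single input of
#' [simulate_closed_loop()].  All defaults reproduce the nominal
#' adaptive-backstepping day: fasting start at 6 A.M. with G = 150 mg/dl,
#' X = 0, I = 100 uU/ml, three unannounced meals, gains 0.43/0.46/0.62 and
#' adaptation gain 0.001.
#'
#' @param params A [patient_params()] object.
#' @param meals A [meal_schedule()]; `default_meals()` gives the nominal
#'   breakfast/lunch/dinner day.
#' @param reference A [reference_trajectory()]; its initial value should
#'   match the patient's starting glucose.
#' @param gains A [controller_gains()] object.
#' @param delta Adaptation gain of the disturbance estimator; `delta = 0`
#'   freezes the estimator at its initial value (useful to demonstrate that
#'   the adaptive law with a frozen zero estimate reduces exactly to plain
#'   backstepping).
#' @param mode `"adaptive"`, `"backstepping"`, or `"none"` (untreated
#'   patient, u = 0 throughout).
#' @param fault Optional [actuator_fault_profile()].
#' @param dropout Optional [dropout_window()].
#' @param init Named numeric vector `c(G, X, I)` of initial conditions.
#' @param horizon Simulation length, minutes (default one day).
#' @param control_step Controller sampling interval, minutes.  The
#'   commanded infusion is held constant (zero-order hold) between samples
#'   while the plant evolves continuously.
#' @param report_step Output grid spacing, minutes; must be a multiple of
#'   `control_step`.
#' @param superpose_meals Sum overlapping meal tails (default) or let each
#'   meal reset the disturbance; see [meal_disturbance()].
#' @param derivatives `"analytic"` (default: chain-rule derivative for the
#'   desired remote insulin action, with the disturbance estimate standing
#'   in for the unknown meal signal) or `"sampled"` (backward differences
#'   of the desired states on the controller grid).  The desired
#'   plasma-insulin derivative is backward-differenced in both schemes.
#'   Backward-differencing the desired remote insulin action feeds the
#'   1/p3 amplification of the cascade and injects discretization spikes
#'   into the infusion command; the analytic scheme reproduces the smooth
#'   input of the continuous-time design.
#' @param nonnegative_insulin Clamp the commanded infusion at zero.
#' @param d_hat0 Initial disturbance estimate, mg/dl/min.
#' @param guard Abort threshold on glucose, mg/dl.
#' @param substeps Runge--Kutta substeps of the plant integrator per
#'   controller interval.
#' @return Object of class `glucose_scenario`.
#' @examples
#' sc <- glucose_scenario()            # nominal adaptive day
#' sc$mode
#' @export
glucose_scenario <- function(params = patient_params(),
                             meals = default_meals(),
                             reference = reference_trajectory(),
                             gains = controller_gains(),
                             delta = 0.001,
                             mode = c("adaptive", "backstepping", "none"),
                             fault = NULL,
                             dropout = NULL,
                             init = c(G = 150, X = 0, I = 100),
                             horizon = 1440,
                             control_step = 0.1,
                             report_step = 1,
                             superpose_meals = TRUE,
                             derivatives = c("analytic", "sampled"),
                             nonnegative_insulin = FALSE,
                             d_hat0 = 0,
                             guard = 1,
                             substeps = 2) {
  mode <- match.arg(mode)
  derivatives <- match.arg(derivatives)
  stopifnot(inherits(params, "patient_params"),
            inherits(meals, "meal_schedule"),
            inherits(reference, "reference_trajectory"),
            inherits(gains, "controller_gains"))
  if (!is.null(fault) && !inherits(fault, "actuator_fault_profile")) {
    stop("fault must be NULL or an actuator_fault_profile")
  }
  if (!is.null(dropout) && !inherits(dropout, "dropout_window")) {
    stop("dropout must be NULL or a dropout_window")
  }
  if (!all(c("G", "X", "I") %in% names(init))) {
    stop("init must be a named vector with components G, X, I")
  }
  if (init[["G"]] <= 0) stop("initial glucose must be > 0")
  if (delta < 0) stop("delta must be >= 0 (0 freezes the estimator)")
  if (horizon <= 0) stop("horizon must be > 0")
  if (control_step <= 0) stop("control_step must be > 0")
  if (report_step <= 0 ||
      abs(report_step / control_step - round(report_step / control_step)) > 1e-9) {
    stop("report_step must be a positive multiple of control_step")
  }
  if (guard <= 0) stop("guard must be > 0")
  if (substeps < 1) stop("substeps must be >= 1")
  structure(list(params = params, meals = meals, reference = reference,
                 gains = gains, delta = delta, mode = mode,
                 fault = fault, dropout = dropout,
                 init = init[c("G", "X", "I")],
                 horizon = horizon, control_step = control_step,
                 report_step = report_step,
                 superpose_meals = isTRUE(superpose_meals),
                 derivatives = derivatives,
                 nonnegative_insulin = isTRUE(nonnegative_insulin),
                 d_hat0 = d_hat0, guard = guard,
                 substeps = as.integer(substeps)),
            class = "glucose_scenario")
}

#' @export
print.glucose_scenario <- function(x, ...) {
  cat("Closed-loop glucose scenario\n")
  cat(sprintf("  mode: %s | horizon: %g min | controller step: %g min\n",
              x$mode, x$horizon, x$control_step))
  cat(sprintf("  gains: k1=%g k2=%g k3=%g | delta: %g\n",
              x$gains$k1, x$gains$k2, x$gains$k3, x$delta))
  cat(sprintf("  initial state: G=%g mg/dl, X=%g 1/min, I=%g uU/ml\n",
              x$init[["G"]], x$init[["X"]], x$init[["I"]]))
  cat(sprintf("  reference: %g -> %g mg/dl (tau = %g min)\n",
              x$reference$G0, x$reference$Ginf, x$reference$tau))
  cat(sprintf("  meals at: %s min\n",
              paste(vapply(x$meals, function(e) e$t_onset, numeric(1)),
                    collapse = ", ")))
  if (!is.null(x$fault)) cat("  actuator fault: enabled\n")
  if (!is.null(x$dropout)) {
    cat(sprintf("  dropout: (%g, %g) min at gain %g\n",
                x$dropout$t_start, x$dropout$t_end, x$dropout$attenuation))
  }
  invisible(x)
}

#' Preset scenarios for the standard experiments
#'
#' Named scenarios for each experiment of the study design:
#' \describe{
#'   \item{`nominal-adaptive`, `nominal-backstepping`}{the nominal day under
#'     each controller.}
#'   \item{`untreated`}{the same day with no insulin infusion.}
#'   \item{`faults-adaptive`, `faults-backstepping`}{nominal day with the
#'     severe actuator-fault profile.}
#'   \item{`dropout-adaptive`, `dropout-backstepping`}{retuned gains
#'     (0.45/0.45/1.5, delta 0.007) with the controller effectively absent
#'     from 10 A.M. to noon.}
#'   \item{`multi-ic`}{a list of adaptive scenarios sweeping the initial
#'     glucose over 150, 200, 250 and 320 mg/dl (reference matched).}
#' }
#'
#' @param name Preset name (see above).
#' @return A `glucose_scenario`, or a named list of them for `multi-ic`.
#' @export
preset_scenario <- function(name) {
  dropout_gains <- controller_gains(k1 = 0.45, k2 = 0.45, k3 = 1.5)
  switch(name,
    "nominal-adaptive" = glucose_scenario(mode = "adaptive"),
    "nominal-backstepping" = glucose_scenario(mode = "backstepping"),
    "untreated" = glucose_scenario(mode = "none"),
    "faults-adaptive" = glucose_scenario(mode = "adaptive",
                                         fault = actuator_fault_profile()),
    "faults-backstepping" = glucose_scenario(mode = "backstepping",
                                             fault = actuator_fault_profile()),
    "dropout-adaptive" = glucose_scenario(mode = "adaptive",
                                          gains = dropout_gains,
                                          delta = 0.007,
                                          dropout = dropout_window()),
    "dropout-backstepping" = glucose_scenario(mode = "backstepping",
                                              gains = dropout_gains,
                                              delta = 0.007,
                                              dropout = dropout_window()),
    "multi-ic" = {
      g0s <- c(150, 200, 250, 320)
      scs <- lapply(g0s, function(g0) {
        glucose_scenario(mode = "adaptive",
                         reference = reference_trajectory(G0 = g0),
                         init = c(G = g0, X = 0, I = 100))
      })
      names(scs) <- paste0("G0_", g0s)
      scs
    },
    stop(sprintf("unknown preset '%s'", name))
  )
}

#' Names of the available presets
#' @return Character vector.
#' @export
preset_names <- function() {
  c("nominal-adaptive", "nominal-backstepping", "untreated",
    "faults-adaptive", "faults-backstepping",
    "dropout-adaptive", "dropout-backstepping", "multi-ic")
}
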