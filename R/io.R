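#' Load a scenario from a YAML configuration file
#'
#' The document may contain the sections `patient`, `meals`, `reference`,
#' `controller`, `faults`, `dropout` and `simulation`, plus an optional
#' top-level `preset` naming the base scenario whose defaults the sections
#' override.  Omitted sections take the nominal values; an empty document
#' yields the nominal adaptive scenario.  Unknown keys anywhere are
#' rejected, and every value passes the same validation as the
#' [glucose_scenario()] constructor.
#'
#' @param path Path to a YAML file.
#' @return A `glucose_scenario`.
#' @export
load_scenario <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  scenario_from_list(doc)
}

check_keys <- function(x, allowed, section) {
  bad <- setdiff(names(x), allowed)
  if (length(bad) > 0L) {
    stop(sprintf("unknown key(s) in %s: %s", section,
                 paste(bad, collapse = ", ")))
  }
}

#' Build a scenario from a plain list
#'
#' Backend of [load_scenario()]; also accepts the scenario echo written by
#' [write_result()], so a result directory can be re-simulated exactly.
#'
#' @param doc Named list with the sections documented in
#'   [load_scenario()].
#' @return A `glucose_scenario`.
#' @export
scenario_from_list <- function(doc) {
  check_keys(doc, c("preset", "patient", "meals", "reference", "controller",
                    "faults", "dropout", "simulation"), "scenario document")
  base_name <- doc$preset %||% "nominal-adaptive"
  if (identical(base_name, "multi-ic")) {
    stop("preset 'multi-ic' is a scenario family; use preset_scenario() or the CLI")
  }
  base <- preset_scenario(base_name)

  pat <- doc$patient %||% list()
  check_keys(pat, c("p1", "p2", "p3", "n", "Gb", "Ib"), "patient")
  params <- do.call(patient_params, utils::modifyList(unclass(base$params), pat))

  ml <- doc$meals %||% list()
  check_keys(ml, c("superpose", "events"), "meals")
  superpose <- ml$superpose %||% base$superpose_meals
  meals <- if (is.null(ml$events)) base$meals else {
    meal_schedule(lapply(ml$events, function(e) {
      check_keys(e, c("t_onset", "A", "B"), "meal event")
      meal_event(e$t_onset, e$A, e$B %||% 0.01)
    }))
  }

  rf <- doc$reference %||% list()
  check_keys(rf, c("G0", "Ginf", "tau"), "reference")
  reference <- do.call(reference_trajectory,
                       utils::modifyList(unclass(base$reference), rf))

  ct <- doc$controller %||% list()
  check_keys(ct, c("mode", "k1", "k2", "k3", "delta", "step",
                   "nonnegative_insulin", "derivatives", "d_hat0"),
             "controller")
  gains <- do.call(controller_gains,
                   utils::modifyList(unclass(base$gains),
                                     ct[intersect(names(ct), c("k1", "k2", "k3"))]))

  ft <- doc$faults
  fault <- if (is.null(ft)) base$fault else {
    check_keys(ft, c("enabled", "rho_floor", "rho_span", "rho_rate",
                     "phi_amp", "phi_rate"), "faults")
    do.call(actuator_fault_profile,
            utils::modifyList(unclass(base$fault %||% actuator_fault_profile()), ft))
  }

  dp <- doc$dropout
  dropout <- if (is.null(dp)) base$dropout else {
    check_keys(dp, c("t_start", "t_end", "attenuation"), "dropout")
    do.call(dropout_window,
            utils::modifyList(unclass(base$dropout %||% dropout_window()), dp))
  }

  sm <- doc$simulation %||% list()
  check_keys(sm, c("horizon", "report_step", "substeps", "guard",
                   "initial"), "simulation")
  init <- base$init
  if (!is.null(sm$initial)) {
    check_keys(sm$initial, c("G", "X", "I"), "simulation$initial")
    for (nm in names(sm$initial)) init[[nm]] <- sm$initial[[nm]]
  }

  glucose_scenario(
    params = params, meals = meals, reference = reference, gains = gains,
    delta = ct$delta %||% base$delta,
    mode = ct$mode %||% base$mode,
    fault = fault, dropout = dropout, init = init,
    horizon = sm$horizon %||% base$horizon,
    control_step = ct$step %||% base$control_step,
    report_step = sm$report_step %||% base$report_step,
    superpose_meals = superpose,
    derivatives = ct$derivatives %||% base$derivatives,
    nonnegative_insulin = ct$nonnegative_insulin %||% base$nonnegative_insulin,
    d_hat0 = ct$d_hat0 %||% base$d_hat0,
    guard = sm$guard %||% base$guard,
    substeps = sm$substeps %||% base$substeps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scenario_to_list <- function(sc) {
  list(
    patient = unclass(sc$params),
    meals = list(superpose = sc$superpose_meals,
                 events = lapply(sc$meals, unclass)),
    reference = unclass(sc$reference),
    controller = list(mode = sc$mode, k1 = sc$gains$k1, k2 = sc$gains$k2,
                      k3 = sc$gains$k3, delta = sc$delta,
                      step = sc$control_step,
                      nonnegative_insulin = sc$nonnegative_insulin,
                      derivatives = sc$derivatives, d_hat0 = sc$d_hat0),
    faults = if (is.null(sc$fault)) NULL else unclass(sc$fault),
    dropout = if (is.null(sc$dropout)) NULL else unclass(sc$dropout),
    simulation = list(horizon = sc$horizon, report_step = sc$report_step,
                      substeps = sc$substeps, guard = sc$guard,
                      initial = as.list(sc$init)))
}

#' Write simulation results to a directory
#'
#' Emits `series.csv` (the time series on the report grid, one row per
#' grid time, columns `time_min,G,X,I,u_commanded,u_applied,D_true,D_hat,
#' G_d`), `scenario.json` (a machine-readable echo of the scenario,
#' re-loadable with [scenario_from_list()]) and `metrics.json` (the
#' [metrics_summary()] block).  Byte content is deterministic for a fixed
#' scenario.
#'
#' @param sim A `glucose_sim`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths of the written files.
#' @export
write_result <- function(sim, out_dir) {
  stopifnot(inherits(sim, "glucose_sim"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  df <- as.data.frame(sim)
  cols <- c("time_min", "G", "X", "I", "u_commanded", "u_applied",
            "D_true", "D_hat", "G_d")
  csv <- file.path(out_dir, "series.csv")
  utils::write.csv(df[cols], csv, row.names = FALSE)
  scn <- file.path(out_dir, "scenario.json")
  jsonlite::write_json(scenario_to_list(sim$scenario), scn,
                       auto_unbox = TRUE, digits = NA, null = "null")
  met <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(metrics_summary(sim), met,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(series = csv, scenario = scn, metrics = met))
}
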