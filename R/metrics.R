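#' Glycemic zone thresholds
#'
#' Clinical zones for blood glucose: below 70 mg/dl (hypoglycemia) and
#' above 180 mg/dl (hyperglycemia) are dangerous; 70--130 mg/dl is the
#' safe zone; 130--180 mg/dl the warning zone.
#'
#' @param hypo,safe_upper,hyper The three thresholds, mg/dl (increasing).
#' @return Object of class `zone_thresholds`.
#' @export
zone_thresholds <- function(hypo = 70, safe_upper = 130, hyper = 180) {
  if (!(hypo < safe_upper && safe_upper < hyper)) {
    stop("thresholds must satisfy hypo < safe_upper < hyper")
  }
  structure(list(hypo = hypo, safe_upper = safe_upper, hyper = hyper),
            class = "zone_thresholds")
}

#' Classify glucose values into clinical zones
#'
#' Boundary convention: the thresholds 70 and 130 belong to the safe zone
#' and 180 to the warning zone, so every positive glucose value receives
#' exactly one label.
#'
#' @param G Glucose value(s), mg/dl (> 0); vectorized.
#' @param thresholds A [zone_thresholds()].
#' @return Factor with levels `dangerous_low`, `safe`, `warning`,
#'   `dangerous_high`.
#' @export
classify_zone <- function(G, thresholds = zone_thresholds()) {
  stopifnot(all(G > 0))
  lv <- c("dangerous_low", "safe", "warning", "dangerous_high")
  idx <- ifelse(G < thresholds$hypo, 1L,
         ifelse(G <= thresholds$safe_upper, 2L,
         ifelse(G <= thresholds$hyper, 3L, 4L)))
  factor(lv[idx], levels = lv)
}

#' Peak glucose in a time window
#'
#' @param sim A `glucose_sim`.
#' @param t_from,t_to Window boundaries, minutes (inclusive, on the report
#'   grid); default the whole run.
#' @return List with components `G` (the maximum, mg/dl) and `time` (the
#'   first grid time attaining it).
#' @export
peak_in_window <- function(sim, t_from = min(sim$time), t_to = max(sim$time)) {
  stopifnot(inherits(sim, "glucose_sim"), t_from <= t_to)
  sel <- sim$time >= t_from & sim$time <= t_to
  if (!any(sel)) stop("window contains no report-grid points")
  i <- which(sel)[which.max(sim$G[sel])]
  list(G = sim$G[i], time = sim$time[i])
}

#' Time until the glucose series first enters a zone
#'
#' @param sim A `glucose_sim`.
#' @param zone Target zone label (see [classify_zone()]).
#' @param t_from Start of the search, minutes.
#' @param thresholds A [zone_thresholds()].
#' @return Duration in minutes from `t_from` to the first report-grid time
#'   at which the glucose is classified in `zone`; error if never reached.
#' @export
time_to_zone <- function(sim, zone = "safe", t_from = 0,
                         thresholds = zone_thresholds()) {
  stopifnot(inherits(sim, "glucose_sim"))
  sel <- sim$time >= t_from
  if (!any(sel)) stop("t_from beyond the simulation horizon")
  z <- classify_zone(sim$G[sel], thresholds)
  hit <- which(z == zone)
  if (length(hit) == 0L) {
    stop(sprintf("zone '%s' never reached after t = %g min", zone, t_from))
  }
  sim$time[sel][hit[1L]] - t_from
}

#' Recovery time after a disturbance event
#'
#' Time from `t_event` until the glucose, after its post-event excursion
#' peak, re-enters a band around the reference trajectory and stays there.
#' Recovery is declared at the first report-grid time (at or after the
#' peak of `|G - G_d|`) from which the deviation remains below `band` for
#' at least `persist` consecutive minutes.  If the deviation never exceeds
#' the band after `t_event` the recovery time is 0.
#'
#' @param sim A `glucose_sim`.
#' @param t_event Event onset, minutes.
#' @param band Tracking band half-width, mg/dl.
#' @param persist Required persistence inside the band, minutes.
#' @return Duration in minutes (0 when there is no excursion); error if
#'   the trajectory never settles back into the band.
#' @export
recovery_time <- function(sim, t_event, band = 5, persist = 10) {
  stopifnot(inherits(sim, "glucose_sim"))
  sel <- which(sim$time >= t_event)
  if (length(sel) == 0L) stop("t_event beyond the simulation horizon")
  dev <- abs(sim$G[sel] - sim$G_d[sel])
  tt <- sim$time[sel]
  if (max(dev) < band) return(0)
  ipk <- which.max(dev)
  for (i in ipk:length(dev)) {
    inwin <- tt >= tt[i] & tt <= tt[i] + persist
    if (all(dev[inwin] < band) && tt[length(tt)] >= tt[i] + persist) {
      return(tt[i] - t_event)
    }
  }
  stop("glucose never settles back into the tracking band")
}

#' Scalar metrics summary of a simulation
#'
#' Flat key-value summary used by [write_result()] and
#' `summary.glucose_sim`: extreme glucose values, peak commanded insulin,
#' fraction of report-grid time per glycemic zone, and the final tracking
#' error.
#'
#' @param sim A `glucose_sim`.
#' @param thresholds A [zone_thresholds()].
#' @return Named list of scalars.
#' @export
metrics_summary <- function(sim, thresholds = zone_thresholds()) {
  stopifnot(inherits(sim, "glucose_sim"))
  z <- classify_zone(sim$G, thresholds)
  frac <- as.list(table(z) / length(z))
  names(frac) <- paste0("frac_", names(frac))
  c(list(G_min = min(sim$G), G_max = max(sim$G),
         G_final = sim$G[length(sim$G)],
         u_peak = max(sim$u_commanded),
         abs_e1_final = abs(sim$e1[length(sim$e1)]),
         max_zone = as.character(z[which.max(as.integer(z))])),
    frac)
}
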