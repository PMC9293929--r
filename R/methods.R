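#' @export
as.data.frame.glucose_sim <- function(x, ...) {
  data.frame(time_min = x$time, G = x$G, X = x$X, I = x$I,
             u_commanded = x$u_commanded, u_applied = x$u_applied,
             D_true = x$D_true, D_hat = x$D_hat, G_d = x$G_d,
             e1 = x$e1, e2 = x$e2, e3 = x$e3)
}

#' @export
print.glucose_sim <- function(x, ...) {
  cat(sprintf("Closed-loop glucose simulation (%s mode, %g min horizon)\n",
              x$scenario$mode, x$scenario$horizon))
  cat(sprintf("  %d report-grid samples every %g min\n",
              length(x$time), x$scenario$report_step))
  cat(sprintf("  glucose range: %.1f to %.1f mg/dl (final %.1f)\n",
              min(x$G), max(x$G), x$G[length(x$G)]))
  invisible(x)
}

#' Summarize a closed-loop simulation
#'
#' @param object A `glucose_sim`.
#' @param thresholds A [zone_thresholds()].
#' @param ... Unused.
#' @return A `summary.glucose_sim` object (the [metrics_summary()] list).
#' @export
summary.glucose_sim <- function(object, thresholds = zone_thresholds(), ...) {
  m <- metrics_summary(object, thresholds)
  structure(m, class = "summary.glucose_sim", mode = object$scenario$mode)
}

#' @export
print.summary.glucose_sim <- function(x, ...) {
  cat(sprintf("Simulation summary (%s mode)\n", attr(x, "mode")))
  cat(sprintf("  glucose: min %.1f, max %.1f, final %.1f mg/dl\n",
              x$G_min, x$G_max, x$G_final))
  cat(sprintf("  peak commanded insulin: %.2f uU/ml/min\n", x$u_peak))
  cat(sprintf("  final |tracking error|: %.3f mg/dl\n", x$abs_e1_final))
  cat(sprintf("  most severe zone reached: %s\n", x$max_zone))
  fr <- x[grep("^frac_", names(x))]
  for (nm in names(fr)) {
    cat(sprintf("  time in %-14s: %5.1f%%\n",
                sub("^frac_", "", nm), 100 * fr[[nm]]))
  }
  invisible(x)
}

#' Plot a closed-loop simulation
#'
#' Base-graphics panels: blood glucose over the clinical zone bands with
#' the reference trajectory, the commanded and delivered insulin infusion,
#' and the true meal disturbance against its on-line estimate.
#'
#' @param x A `glucose_sim`.
#' @param which Subset of `"glucose"`, `"insulin"`, `"disturbance"`.
#' @param thresholds A [zone_thresholds()].
#' @param ... Passed to the underlying `plot` calls.
#' @return Invisibly, `x`.
#' @export
plot.glucose_sim <- function(x, which = c("glucose", "insulin", "disturbance"),
                             thresholds = zone_thresholds(), ...) {
  which <- match.arg(which, several.ok = TRUE)
  op <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  hrs <- x$time / 60
  if ("glucose" %in% which) {
    ylim <- range(x$G, x$G_d, 60, 200)
    plot(hrs, x$G, type = "n", xlab = "time (h from 6 A.M.)",
         ylab = "glucose (mg/dl)", ylim = ylim, main = "Blood glucose", ...)
    usr <- graphics::par("usr")
    bands <- rbind(c(usr[3], thresholds$hypo, "#f4cccc"),
                   c(thresholds$hypo, thresholds$safe_upper, "#d9ead3"),
                   c(thresholds$safe_upper, thresholds$hyper, "#fff2cc"),
                   c(thresholds$hyper, usr[4], "#f4cccc"))
    for (i in seq_len(nrow(bands))) {
      graphics::rect(usr[1], as.numeric(bands[i, 1]), usr[2],
                     as.numeric(bands[i, 2]), col = bands[i, 3], border = NA)
    }
    graphics::lines(hrs, x$G_d, lty = 2, col = "grey30")
    graphics::lines(hrs, x$G, lwd = 1.5, col = "navy")
    graphics::legend("topright", c("G", "reference"), lty = c(1, 2),
                     col = c("navy", "grey30"), bty = "n")
  }
  if ("insulin" %in% which) {
    plot(hrs, x$u_commanded, type = "l", col = "navy", lwd = 1.5,
         xlab = "time (h from 6 A.M.)", ylab = "u (uU/ml/min)",
         main = "Insulin infusion", ...)
    graphics::lines(hrs, x$u_applied, col = "firebrick", lty = 3)
    graphics::legend("topright", c("commanded", "delivered"),
                     col = c("navy", "firebrick"), lty = c(1, 3), bty = "n")
  }
  if ("disturbance" %in% which) {
    plot(hrs, x$D_true, type = "l", col = "navy", lwd = 1.5,
         xlab = "time (h from 6 A.M.)", ylab = "D (mg/dl/min)",
         main = "Meal disturbance and estimate",
         ylim = range(x$D_true, x$D_hat), ...)
    graphics::lines(hrs, x$D_hat, col = "firebrick", lty = 2)
    graphics::legend("topright", c("true D", "estimate"),
                     col = c("navy", "firebrick"), lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
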