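#' Diagnostic plots for a run
#'
#' Base-graphics panels of the quantities usually inspected after a tilt
#' experiment: the pressure history at a monitored site (with per-beat
#' means), the ventricular pressure-volume loop of selected beats, and the
#' normalized controlled-variable trajectories.
#'
#' @param run a `tilt_run`
#' @param site node name for the pressure history (default the right
#'   external carotid outlet)
#' @param beats beat indices for the PV loops (default first and last)
#' @param ... passed to the underlying plot call
#' @return invisibly, the data plotted
#' @export
plot_pressure_history <- function(run, site = "ecar_r", ...) {
  ts <- run$timeseries
  if (!site %in% names(ts)) stop("unknown site column: ", site)
  plot(ts$time, ts[[site]] / MMHG, type = "l", xlab = "time [s]",
       ylab = paste0(site, " pressure [mmHg]"), ...)
  if (!is.null(run$beats)) {
    graphics::points(run$beats$t_end, run$beats[[.site_mean_col(run, site)]] / MMHG,
                     pch = 16, col = 2)
  }
  invisible(ts[, c("time", site)])
}

.site_mean_col <- function(run, site) {
  map <- c(ecar_r = "external_carotid_r", ecar_l = "external_carotid_l",
           icar_r = "internal_carotid_r", icar_l = "internal_carotid_l",
           sub_r = "subclavian_r", sub_l = "subclavian_l", root = "root")
  if (site %in% names(map) && map[[site]] %in% names(run$beats)) map[[site]]
  else if (site %in% names(run$beats)) site
  else stop("no per-beat mean recorded for site ", site)
}

#' @rdname plot_pressure_history
#' @export
plot_pv_loop <- function(run, beats = NULL, ...) {
  if (is.null(run$beats)) stop("run has no completed beats")
  if (is.null(beats)) beats <- unique(c(1L, nrow(run$beats)))
  xs <- lapply(beats, function(i) beat_trace(run, i))
  xr <- range(unlist(lapply(xs, `[[`, "v_lv")))
  yr <- range(unlist(lapply(xs, `[[`, "p_lv"))) / MMHG
  plot(NA, xlim = xr, ylim = yr, xlab = expression(V[LV] ~ "[cm"^3 * "]"),
       ylab = expression(P[LV] ~ "[mmHg]"), ...)
  for (j in seq_along(xs)) {
    graphics::lines(xs[[j]]$v_lv, xs[[j]]$p_lv / MMHG, col = j)
  }
  graphics::legend("topleft", legend = paste("beat", beats),
                   col = seq_along(beats), lty = 1, bty = "n")
  invisible(xs)
}

#' @rdname plot_pressure_history
#' @export
plot_controls <- function(run, ...) {
  b <- run$beats
  if (is.null(b)) stop("run has no completed beats")
  cols <- paste0("x_", c("h", "emax", "r", "cv", "vu"))
  yr <- range(unlist(b[cols]))
  plot(NA, xlim = range(b$t_end), ylim = yr, xlab = "time [s]",
       ylab = "normalized controlled variables", ...)
  for (j in seq_along(cols)) graphics::lines(b$t_end, b[[cols[j]]], col = j)
  graphics::abline(h = 1, lty = 3)
  graphics::legend("topleft", legend = c("heart rate", "max elastance",
                                         "arterial resistance",
                                         "venous compliance",
                                         "venous unstressed volume"),
                   col = seq_along(cols), lty = 1, bty = "n", cex = 0.8)
  invisible(b[, c("t_end", cols)])
}
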