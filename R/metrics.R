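#' Per-beat hemodynamic metrics from a beat trace
#'
#' Computes the classic beat metrics from a trace covering exactly one beat:
#' stroke volume `SV = max(V_LV) - min(V_LV)`, stroke work `SW` as the
#' (loop-closed, trapezoidal) area of the ventricular pressure-volume loop,
#' cardiac output `CO = SV / T`, maximum aortic flow rate `QM = max(Q_AV)`
#' and ejection time `TE` as the aortic-valve open duration taken from the
#' valve-event annotation (not from a flow threshold).
#'
#' @param trace data.frame with columns `time` (s), `p_lv` (dyn cm^-2),
#'   `v_lv` (cm^3), `q_av` (cm^3 s^-1) and `ao_open` (logical or 0/1 valve
#'   annotation); optional extra pressure columns are summarized per site
#' @param sites optional character vector of pressure column names to
#'   summarize (systolic, diastolic, mean, pulse; reported in mmHg)
#' @return list of class `beat_metrics`: `sv` (cm^3), `sw` (erg), `sw_joule`,
#'   `co` (cm^3 s^-1), `qm` (cm^3 s^-1), `te` (s), `period` (s), and `sites`
#'   (data.frame) when requested
#' @export
beat_metrics <- function(trace, sites = NULL) {
  need <- c("time", "p_lv", "v_lv", "q_av", "ao_open")
  miss <- setdiff(need, names(trace))
  if (length(miss)) stop("beat trace lacks column(s): ",
                         paste(miss, collapse = ", "))
  n <- nrow(trace)
  if (n < 3L) stop("beat trace too short")
  period <- diff(range(trace$time)) + stats::median(diff(trace$time))
  sv <- max(trace$v_lv) - min(trace$v_lv)
  p <- trace$p_lv; v <- trace$v_lv
  area <- sum(0.5 * (p[-1] + p[-n]) * diff(v)) +
    0.5 * (p[1] + p[n]) * (v[1] - v[n])   # closing segment
  sw <- abs(area)
  dt <- diff(trace$time)
  te <- sum(dt[as.logical(trace$ao_open[-1])])
  out <- list(sv = sv, sw = sw, sw_joule = erg_to_joule(sw),
              co = sv / period, qm = max(trace$q_av), te = te,
              period = period)
  if (!is.null(sites)) {
    miss <- setdiff(sites, names(trace))
    if (length(miss)) stop("unknown site column(s): ",
                           paste(miss, collapse = ", "))
    out$sites <- do.call(rbind, lapply(sites, function(s) {
      ps <- trace[[s]] / MMHG
      data.frame(site = s, systolic = max(ps), diastolic = min(ps),
                 mean = mean(ps), pulse = max(ps) - min(ps))
    }))
  }
  class(out) <- "beat_metrics"
  out
}

#' @export
print.beat_metrics <- function(x, ...) {
  cat(sprintf("beat metrics: SV %.2f cm^3 | SW %.3f J | CO %.1f cm^3/s | QM %.1f cm^3/s | TE %.3f s\n",
              x$sv, x$sw_joule, x$co, x$qm, x$te))
  if (!is.null(x$sites)) print(x$sites, row.names = FALSE)
  invisible(x)
}

#' Baroreflex sensitivity from per-beat series
#'
#' The clinical index: the change in peak systolic pressure over successive
#' beats. Returns the first-difference series of peak systolic pressure and
#' of the heart period, with a summary regression slope of the period
#' change (in ms) against the systolic change (ms/mmHg) when enough
#' variation is present.
#'
#' @param systolic per-beat peak systolic pressures, mmHg (length >= 2)
#' @param period per-beat heart periods, s (same length)
#' @return list with `d_systolic` (mmHg), `d_period_ms` (ms) and `slope`
#'   (ms/mmHg, `NA` when the systolic series is constant)
#' @export
baroreflex_sensitivity <- function(systolic, period) {
  if (length(systolic) < 2L) stop("need at least two beats")
  if (length(period) != length(systolic))
    stop("systolic and period series must have equal length")
  ds <- diff(systolic)
  dp <- diff(period) * 1000
  slope <- if (length(ds) >= 2L && stats::sd(ds) > 0) {
    unname(stats::coef(stats::lm(dp ~ ds))[2])
  } else NA_real_
  list(d_systolic = ds, d_period_ms = dp, slope = slope)
}

#' Extract one beat's trace from a run
#'
#' Convenience selector: the recorded samples of the `i`-th completed beat
#' of a [simulate_run()] result, with `p_lv`, `v_lv`, `q_av` and a
#' reconstructed `ao_open` annotation (`q_av > 0`).
#'
#' @param run a `tilt_run`
#' @param i beat number (negative counts from the end: `-1` is the last)
#' @return data.frame trace covering the beat
#' @export
beat_trace <- function(run, i = -1L) {
  if (is.null(run$beats)) stop("run has no completed beats")
  nb <- nrow(run$beats)
  if (i < 0) i <- nb + 1L + i
  if (i < 1L || i > nb) stop("beat index out of range")
  t1 <- run$beats$t_end[i]
  t0 <- t1 - run$beats$period[i]
  ts <- run$timeseries
  tr <- ts[ts$time > t0 + 1e-12 & ts$time <= t1 + 1e-12, , drop = FALSE]
  tr$ao_open <- tr$q_av > 0
  tr
}
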