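#' Write and read run time series
#'
#' CSV round trip of the recorded time series. Pressure columns (node
#' pressures and `p_lv`) are written twice: in CGS (`dyn cm^-2`, original
#' column name) and converted (`<name>_mmhg`), so downstream consumers never
#' need to convert. `read_timeseries` restores the data.frame as written.
#'
#' @param run a `tilt_run` from [simulate_run()], or a plain data.frame
#' @param path output file path
#' @return `write_timeseries` the path invisibly; `read_timeseries` a
#'   data.frame
#' @export
write_timeseries <- function(run, path) {
  ts <- if (inherits(run, "tilt_run")) run$timeseries else run
  pcols <- intersect(names(ts),
                     c(if (inherits(run, "tilt_run"))
                         setdiff(names(ts), c("time", "theta", "delta",
                                              grep("^q_|^v_", names(ts),
                                                   value = TRUE)))
                       else character(0), "p_lv"))
  for (cc in pcols) ts[[paste0(cc, "_mmhg")]] <- ts[[cc]] / MMHG
  utils::write.csv(ts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Write per-beat metrics to CSV
#'
#' One row per completed beat (stroke volume, stroke work, cardiac output,
#' peak flow, ejection time, per-site beat means, control variables).
#'
#' @param run a `tilt_run` or a beats data.frame
#' @param path output file path
#' @return the path, invisibly
#' @export
write_metrics <- function(run, path) {
  beats <- if (inherits(run, "tilt_run")) run$beats else run
  if (is.null(beats)) stop("no completed beats to write")
  utils::write.csv(beats, path, row.names = FALSE)
  invisible(path)
}

#' Write run metadata as JSON
#'
#' Records everything needed to identify a run: the configuration hash,
#' control flag, protocol stages, time step, beat count, conservation
#' diagnostics and package/R versions.
#'
#' @param run a `tilt_run`
#' @param path output file path
#' @return the path, invisibly
#' @export
write_run_metadata <- function(run, path) {
  meta <- list(
    config_hash = config_hash(run$config),
    control_on = run$control_on,
    protocol = if (is.null(run$protocol)) NULL else unclass(run$protocol),
    dt = run$dt,
    n_beats = run$diagnostics$n_beats,
    volume_drift = run$diagnostics$volume_drift,
    package_version = as.character(utils::packageVersion("baroloop")),
    r_version = R.version.string
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_metadata
#' @export
read_run_metadata <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
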