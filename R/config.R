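#' Default model configuration
#'
#' Assembles the complete configuration of the closed-loop model: blood
#' properties, heart parameters, surrogate geometry, Windkessel and distal
#' compartment parameters, baroreflex gains, tilt protocol, gravity options,
#' solver settings, initial conditions and tuning targets. Every entry can
#' be overridden by editing the returned list (or a YAML copy written with
#' [write_config()]).
#'
#' @param ... named overrides merged (shallowly, per section) into the
#'   defaults, e.g. `sim = list(dt = 2e-4)`
#' @return nested configuration list of class `tilt_config`
#' @export
default_config <- function(...) {
  cfg <- list(
    blood = list(rho = 1.06, mu = 0.04),
    heart = heart_params(),
    geometry = default_vessel_geometry(),
    surrogate = list(c_scale = 1),
    windkessel = windkessel_defaults(),
    distal = distal_defaults(),
    control = control_params(),
    protocol = tilt_protocol(),
    gravity = list(g = 9.810e2, distal_gravity = FALSE,
                   distal_elevations = list(arterioles = c(0, 0),
                                            venules = c(0, 0),
                                            veins = c(0, 0))),
    sim = list(dt = 1e-4, record_stride = 10L,
               spin_up_max_beats = 30L, spin_up_tol = 1e-3),
    init = list(v_lv = 120, v_la = 60,
                p_arterial = 110 * MMHG, p_arteriole = 90 * MMHG,
                p_venule = 12 * MMHG, p_vein = 6 * MMHG),
    tuning = list(mean_aortic_mmhg = 120, pulse_mmhg = 30,
                  pressure_tol = 0.01, flow_tol = 0.02, max_iter = 20L)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(cfg)) stop("unknown configuration section: ", nm)
    if (is.list(ov[[nm]]) && is.list(cfg[[nm]]) && !is.data.frame(ov[[nm]])) {
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    } else {
      cfg[[nm]] <- ov[[nm]]
    }
  }
  class(cfg) <- "tilt_config"
  validate_config(cfg)
  cfg
}

#' Validate a configuration
#'
#' Checks structural completeness and the physical invariants of a
#' configuration (positive element values, consistent geometry, protocol
#' durations).
#'
#' @param cfg a configuration list
#' @return the configuration, invisibly; errors describe the first problem
#' @export
validate_config <- function(cfg) {
  need <- c("blood", "heart", "geometry", "surrogate", "windkessel", "distal",
            "control", "protocol", "gravity", "sim", "init", "tuning")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("configuration missing section(s): ",
                         paste(miss, collapse = ", "))
  g <- cfg$geometry
  gcols <- c("segment", "from", "to", "radius", "length",
             "x_start", "x_end", "z_start", "z_end", "outlet")
  if (!all(gcols %in% names(g))) stop("geometry table lacks columns: ",
                                      paste(setdiff(gcols, names(g)), collapse = ", "))
  if (any(g$radius <= 0) || any(g$length <= 0))
    stop("geometry radii and lengths must be > 0")
  if (any(!is.finite(c(g$x_start, g$x_end, g$z_start, g$z_end))))
    stop("geometry elevations must be finite")
  if (is.null(cfg$surrogate$c_scale) || cfg$surrogate$c_scale <= 0)
    stop("surrogate$c_scale must be > 0")
  wk <- cfg$windkessel
  if (any(wk$r1 <= 0) || any(wk$r2 <= 0) || any(wk$c <= 0))
    stop("Windkessel parameters must be > 0")
  miss_out <- setdiff(wk$outlet, g$outlet[!is.na(g$outlet)])
  if (length(miss_out)) stop("Windkessel outlets without a feeding segment: ",
                             paste(miss_out, collapse = ", "))
  with(cfg$sim, if (dt <= 0) stop("sim$dt must be > 0"))
  pr <- cfg$protocol
  if (any(c(pr$t_supine, pr$t_rotation, pr$t_upright) < 0))
    stop("protocol durations must be >= 0")
  invisible(cfg)
}

#' Read and write configurations as YAML
#'
#' Round-trippable YAML serialization of a configuration. Tables (geometry,
#' Windkessel outlets, control gains) are stored column-wise and restored as
#' data frames.
#'
#' @param cfg a configuration list
#' @param path file path
#' @return `read_config` returns the configuration; `write_config` its path,
#'   invisibly
#' @export
write_config <- function(cfg, path) {
  ser <- rapply(unclass(cfg), f = function(x) x, how = "replace")
  yaml::write_yaml(ser, path, column.major = TRUE, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$geometry <- as.data.frame(raw$geometry, stringsAsFactors = FALSE)
  raw$geometry$outlet <- as.character(raw$geometry$outlet)
  raw$geometry$outlet[raw$geometry$outlet %in% c("NA", "")] <- NA_character_
  raw$windkessel <- as.data.frame(raw$windkessel, stringsAsFactors = FALSE)
  raw$control$gains <- as.data.frame(raw$control$gains, stringsAsFactors = FALSE)
  class(raw) <- "tilt_config"
  validate_config(raw)
  raw
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical YAML serialization; used in run metadata to identify
#' the exact configuration a result was produced with.
#'
#' @param cfg a configuration list
#' @return character MD5 hash
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_config(cfg, tf)
  unname(tools::md5sum(tf))
}
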