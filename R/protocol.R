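#' Head-up tilt protocol
#'
#' Three-stage protocol: a supine stage, a rotation stage during which the
#' tilt angle ramps monotonically from 0 to `theta_final`, and a fixed
#' upright stage. `head_up = TRUE` orients the rotation so the upright
#' posture raises the carotids above the heart (the literal rotation of
#' [gravity_vector()] has the opposite sense for positive angles; the sign
#' is explicit here rather than guessed inside the physics).
#'
#' @param t_supine,t_rotation,t_upright stage durations, s
#' @param theta_final final tilt angle, radians
#' @param ramp `"linear"` or `"smoothstep"` angle ramp
#' @param head_up logical; see Description
#' @return a `tilt_protocol` list
#' @export
tilt_protocol <- function(t_supine = 10, t_rotation = 5, t_upright = 10,
                          theta_final = pi / 2,
                          ramp = c("linear", "smoothstep"), head_up = TRUE) {
  ramp <- match.arg(ramp)
  stopifnot(t_supine >= 0, t_rotation >= 0, t_upright >= 0)
  structure(list(t_supine = t_supine, t_rotation = t_rotation,
                 t_upright = t_upright, theta_final = theta_final,
                 ramp = ramp, head_up = head_up),
            class = "tilt_protocol")
}

#' Tilt angle schedule
#'
#' Angle as a function of time: 0 during the supine stage, a monotone ramp
#' over the rotation stage, `theta_final` afterwards.
#'
#' @param t time, s (vectorized, >= 0)
#' @param protocol a [tilt_protocol()]
#' @return angle(s), radians
#' @export
theta_schedule <- function(t, protocol) {
  if (any(t < 0)) stop("t must be >= 0")
  s <- (t - protocol$t_supine) / max(protocol$t_rotation, .Machine$double.eps)
  s <- pmin(pmax(s, 0), 1)
  if (protocol$ramp == "smoothstep") s <- s^2 * (3 - 2 * s)
  protocol$theta_final * s
}

#' Relax the model to its periodic supine state
#'
#' Runs supine beats (no gravity trigger, controls at rest) until the
#' beat-to-beat change in stroke volume and in beat-mean aortic root
#' pressure both fall below `tol`, and returns the converged state to be
#' used as the initial condition of an experiment. Any reasonable initial
#' volume distribution converges to the same limit cycle; spin-up removes
#' the sensitivity to the configured initial pressures.
#'
#' @param model a [tilt_model()]
#' @param init optional initial state (default [initial_state()])
#' @param dt time step, s
#' @param max_beats spin-up budget in beats; exceeding it without
#'   convergence is an error reporting the convergence trace
#' @param tol relative beat-to-beat tolerance
#' @return list with `state` (continuation state at a beat boundary),
#'   `beats` (per-beat convergence trace) and `run` (the full `tilt_run`)
#' @export
spin_up <- function(model, init = NULL, dt = model$config$sim$dt,
                    max_beats = model$config$sim$spin_up_max_beats,
                    tol = model$config$sim$spin_up_tol) {
  period0 <- model$config$heart$t_baseline
  run <- simulate_run(model, duration = (max_beats + 1) * period0,
                      init = init, dt = dt, control_on = FALSE,
                      protocol = NULL, record_stride = 0L,
                      stop_when_periodic = list(tol = tol, min_beats = 3L))
  if (!run$diagnostics$periodic) {
    tr <- utils::tail(run$beats[, c("beat", "sv", "root")], 8)
    stop("spin-up failed to reach a periodic supine state within ",
         max_beats, " beats; last beats (sv, mean root pressure):\n",
         paste(utils::capture.output(print(tr)), collapse = "\n"))
  }
  run$state$time <- 0
  list(state = run$state, beats = run$beats, run = run)
}

#' Run the virtual head-up tilt experiment
#'
#' Spins the model up to its periodic supine state, then simulates the full
#' protocol (supine, rotation, upright) with the baroreflex response active
#' (`control_on = TRUE`) or inactive. Deterministic: identical
#' configurations produce identical outputs (there is no randomness
#' anywhere in the model).
#'
#' @param config configuration from [default_config()]
#' @param control_on logical: baroreflex active
#' @param protocol a [tilt_protocol()] (default from the configuration)
#' @param dt time step, s
#' @param record_stride recording stride for the time series
#' @param spin optional pre-computed [spin_up()] result to reuse across the
#'   control and no-control runs
#' @return a `tilt_run` (see [simulate_run()]) with the spin-up attached as
#'   attribute `"spin"`
#' @export
run_experiment <- function(config = default_config(), control_on = TRUE,
                           protocol = config$protocol,
                           dt = config$sim$dt,
                           record_stride = config$sim$record_stride,
                           spin = NULL) {
  model <- tilt_model(config)
  if (is.null(spin)) spin <- spin_up(model, dt = dt)
  duration <- protocol$t_supine + protocol$t_rotation + protocol$t_upright
  run <- simulate_run(model, duration = duration, init = spin$state,
                      dt = dt, control_on = control_on, protocol = protocol,
                      record_stride = record_stride)
  attr(run, "spin") <- spin
  run
}

#' Tune the Windkessel outlets to the pressure and flow-split targets
#'
#' Fixed-point iteration on the distal Windkessel resistances and
#' compliances: per-outlet total resistances are assigned inversely
#' proportional to outlet area (so the flow division is proportional to
#' area), the distal resistances are scaled to bring the beat-mean aortic
#' root pressure to its target, and the Windkessel compliances are scaled to
#' bring the aortic pulse pressure to its target. Characteristic (proximal)
#' resistances are physically determined and never adjusted. Each iteration
#' re-runs the closed loop to its periodic supine beat, warm-starting from
#' the previous state.
#'
#' @param config configuration to tune
#' @param mean_target,pulse_target targets, mmHg
#' @param tol relative pressure tolerance for convergence
#' @param flow_tol relative tolerance on the per-outlet flow fractions
#'   versus area fractions
#' @param max_iter outer-iteration cap; non-convergence is an error
#'   reporting the iteration log
#' @param dt time step, s
#' @return list with `config` (tuned), `log` (per-iteration data.frame),
#'   `mean_mmhg`, `pulse_mmhg`, `flow_fractions`, `area_fractions`, `beats`
#'   of the final converged run and `state` (its periodic supine state)
#' @export
tune_windkessels <- function(config = default_config(),
                             mean_target = config$tuning$mean_aortic_mmhg,
                             pulse_target = config$tuning$pulse_mmhg,
                             tol = config$tuning$pressure_tol,
                             flow_tol = config$tuning$flow_tol,
                             max_iter = config$tuning$max_iter,
                             dt = config$sim$dt) {
  state <- NULL
  log <- list()
  # cumulative log-scaling of the distal resistances, driven by a secant
  # iteration on the log mean-pressure target; compliances follow a damped
  # fixed-point update (pulse pressure scales nearly inversely with C)
  u <- 0; u_prev <- NA; lm_prev <- NA
  for (it in seq_len(max_iter)) {
    model <- tilt_model(config)
    run <- simulate_run(model, duration = 20 * config$heart$t_baseline,
                        init = state, dt = dt, record_stride = 0L,
                        stop_when_periodic = list(tol = 1e-4, min_beats = 5L))
    state <- run$state
    state$time <- 0
    last <- run$beats[nrow(run$beats), ]
    mean_mmhg <- last$root / MMHG
    pulse_mmhg <- last$pulse / MMHG
    wk <- config$windkessel
    qbar <- as.numeric(last[paste0("q_", wk$outlet)])
    frac <- qbar / sum(qbar)
    share <- wk$area / sum(wk$area)
    log[[it]] <- data.frame(iter = it, mean_mmhg = mean_mmhg,
                            pulse_mmhg = pulse_mmhg,
                            flow_err = max(abs(frac - share) / share))
    ok_mean <- abs(mean_mmhg - mean_target) <= tol * mean_target
    ok_pulse <- abs(pulse_mmhg - pulse_target) <= tol * pulse_target
    ok_flow <- all(abs(frac - share) / share <= flow_tol)
    if (ok_mean && ok_pulse && ok_flow) {
      return(list(config = config, log = do.call(rbind, log),
                  mean_mmhg = mean_mmhg, pulse_mmhg = pulse_mmhg,
                  flow_fractions = stats::setNames(frac, wk$outlet),
                  area_fractions = stats::setNames(share, wk$outlet),
                  beats = run$beats, state = state, iterations = it))
    }
    lm_now <- log(mean_mmhg); lp_now <- log(pulse_mmhg)
    du <- if (is.na(u_prev) || abs(lm_now - lm_prev) < 1e-4) {
      0.6 * (log(mean_target) - lm_now)
    } else {
      (log(mean_target) - lm_now) * (u - u_prev) / (lm_now - lm_prev)
    }
    du <- max(min(du, 0.35), -0.35)
    dv <- max(min(0.9 * (lp_now - log(pulse_target)), 0.35), -0.35)
    u_prev <- u; lm_prev <- lm_now; u <- u + du
    # per-outlet totals inversely proportional to area (flow split), with
    # the overall distal level set by the secant scale exp(u)
    path_r <- .arch_path_resistance(model)[wk$outlet]
    rtot <- path_r + wk$r1 + wk$r2
    g_tot <- sum(1 / rtot) / exp(du)
    rtot_new <- sum(wk$area) / (g_tot * wk$area)
    r2_new <- rtot_new - wk$r1 - path_r
    if (any(r2_new <= 0)) {
      stop("flow-split assignment produced a non-positive distal resistance; ",
           "outlet areas are inconsistent with the characteristic resistances")
    }
    config$windkessel$r2 <- r2_new
    # uniform compliance scaling: Windkessel chambers and surrogate
    # segments together (the lumped surrogate concentrates the distributed
    # storage of the large arteries; calibrating the total compliance is
    # the point of the pulse-pressure target)
    config$windkessel$c <- wk$c * exp(dv)
    config$surrogate$c_scale <- config$surrogate$c_scale * exp(dv)
  }
  stop("Windkessel tuning did not converge in ", max_iter,
       " iterations; log:\n",
       paste(utils::capture.output(print(do.call(rbind, log))),
             collapse = "\n"))
}

# Series resistance of the surrogate path from the arch node to each outlet,
# named by outlet.
.arch_path_resistance <- function(model) {
  geo <- model$geometry
  out <- geo[!is.na(geo$outlet), ]
  r <- vapply(seq_len(nrow(out)), function(i) {
    ri <- out$r_seg[i]
    up <- out$from[i]
    while (up != "arch") {
      parent <- geo[geo$to == up, ]
      ri <- ri + parent$r_seg[1]
      up <- parent$from[1]
    }
    ri
  }, numeric(1))
  stats::setNames(r, out$outlet)
}
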