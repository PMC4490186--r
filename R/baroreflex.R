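#' Baroreflex control gains and time constants
#'
#' Published first-order control parameters of the five normalized
#' controlled variables: heart rate `h`, maximum ventricular elastance
#' `emax`, arterial resistance `r`, venous compliance `cv` and venous
#' unstressed volume `vu`. Each variable obeys
#' `tau dx/dt + x = alpha n_s - beta n_p + gamma`; at the baseline afferent
#' index (delta = 1, so `n_s = n_p = 1/2`) every steady state is exactly 1.
#' Only the heart rate carries a parasympathetic gain (`beta != 0`), with
#' the printed negative sign used literally.
#'
#' @param nu sigmoid steepness of the efferent activities
#' @return list with data.frame `gains` (tau, alpha, beta, gamma per
#'   variable) and `nu`
#' @export
control_params <- function(nu = 5) {
  gains <- data.frame(
    variable = c("h", "emax", "r", "cv", "vu"),
    tau   = c(3, 3, 3, 30, 30),
    alpha = c(1.75, 0.40, 0.80, -0.20, -0.42),
    beta  = c(-0.25, 0, 0, 0, 0),
    gamma = c(0.00, 0.80, 0.60, 1.10, 1.21),
    stringsAsFactors = FALSE
  )
  stopifnot(all(gains$tau > 0))
  list(gains = gains, nu = nu)
}

#' Afferent baroreceptor index
#'
#' `delta = p_mean / p_target`: the ratio of the current cardiac-cycle
#' average pressure at a monitored site to its predefined target. With
#' several monitored sites, [select_delta()] picks the index deviating the
#' most from 1, which is assumed to drive the overall response.
#'
#' @param p_mean cycle-average pressure, dyn cm^-2 (or any unit shared with
#'   `p_target`)
#' @param p_target target pressure (> 0), same units
#' @return dimensionless afferent index (vectorized over sites)
#' @export
afferent_index <- function(p_mean, p_target) {
  if (any(p_target <= 0)) stop("p_target must be > 0")
  p_mean / p_target
}

#' @rdname afferent_index
#' @param delta vector of per-site afferent indices
#' @export
select_delta <- function(delta) {
  if (!length(delta)) stop("no afferent indices supplied")
  delta[which.max(abs(delta - 1))]
}

#' Efferent sympathetic and parasympathetic activities
#'
#' Sigmoid pair `n_s = 1 / (1 + delta^nu)`, `n_p = 1 / (1 + delta^-nu)`:
#' sympathetic activity falls and parasympathetic activity rises with the
#' afferent index, both saturating at 0/1, with `n_s + n_p = 1` identically.
#'
#' @param delta afferent index (> 0), vectorized
#' @param nu steepness parameter
#' @return list with `n_s` and `n_p`
#' @export
efferent_activities <- function(delta, nu = 5) {
  if (any(delta <= 0)) stop("delta must be > 0")
  ns <- 1 / (1 + delta^nu)
  list(n_s = ns, n_p = 1 - ns)
}

#' Steady-state value of a controlled variable
#'
#' The fixed point `alpha n_s - beta n_p + gamma` of the control ODE for a
#' held afferent index.
#'
#' @param gains one row of `control_params()$gains` (or a list with
#'   `alpha`, `beta`, `gamma`)
#' @param n_s,n_p efferent activities
#' @return steady-state normalized value
#' @export
control_steady_state <- function(gains, n_s, n_p) {
  gains$alpha * n_s - gains$beta * n_p + gains$gamma
}

#' One backward-Euler step of a control ODE
#'
#' `x+ = (tau x + dt (alpha n_s - beta n_p + gamma)) / (tau + dt)`.
#'
#' @param x current normalized value
#' @param n_s,n_p efferent activities at the new time level
#' @param gains control gains (`tau`, `alpha`, `beta`, `gamma`); vectorized
#'   over variables when given as the full gains data.frame
#' @param dt time step, s (> 0)
#' @return updated normalized value(s)
#' @export
control_step <- function(x, n_s, n_p, gains, dt) {
  if (dt <= 0) stop("dt must be > 0")
  s <- control_steady_state(gains, n_s, n_p)
  (gains$tau * x + dt * s) / (gains$tau + dt)
}

#' Advance a control ODE over many equal backward-Euler steps
#'
#' Closed form of `n` repeated [control_step()] updates with the efferent
#' drive held constant: `x_n = s + (x_0 - s) (tau / (tau + dt))^n`, equal to
#' the value obtained by stepping `dt` at a time (to floating-point
#' rounding). Used by the simulator to advance the controls across a beat
#' (the afferent index is a per-cycle quantity and changes only at beat
#' boundaries).
#'
#' @inheritParams control_step
#' @param n number of steps (>= 0)
#' @return updated normalized value(s)
#' @export
control_advance <- function(x, n_s, n_p, gains, dt, n) {
  if (dt <= 0) stop("dt must be > 0")
  s <- control_steady_state(gains, n_s, n_p)
  s + (x - s) * (gains$tau / (gains$tau + dt))^n
}

#' Apply the normalized controls to baseline model parameters
#'
#' Effective values are `baseline * x` for maximum elastance (`emax`), every
#' distal arterial resistance (`r`: the per-outlet distal Windkessel
#' resistances and the arteriole resistance, never the characteristic
#' proximal resistances), both venous compliances (`cv`) and both venous
#' unstressed volumes (`vu`). The heart-rate variable scales the rate, so
#' the effective heart period is `t_baseline / x_h`. Updates take effect at
#' the next beat boundary.
#'
#' @param x named numeric vector of normalized controls
#'   (`h`, `emax`, `r`, `cv`, `vu`), all > 0
#' @param baselines list with `t_baseline`, `e_max`, `r2` (vector), `r_a`,
#'   `c_v1`, `c_v2`, `v_u_v1`, `v_u_v2`
#' @return list of effective parameters with the same names plus `period`
#' @export
apply_controls <- function(x, baselines) {
  if (any(x <= 0)) stop("all normalized controls must be > 0")
  x <- x[c("h", "emax", "r", "cv", "vu")]
  list(period = baselines$t_baseline / x[["h"]],
       e_max = baselines$e_max * x[["emax"]],
       r2 = baselines$r2 * x[["r"]],
       r_a = baselines$r_a * x[["r"]],
       c_v1 = baselines$c_v1 * x[["cv"]],
       c_v2 = baselines$c_v2 * x[["cv"]],
       v_u_v1 = baselines$v_u_v1 * x[["vu"]],
       v_u_v2 = baselines$v_u_v2 * x[["vu"]])
}

#' Cycle-average pressure at monitored sites
#'
#' Time-average of the pressure trace over the most recently completed beat
#' at each monitored site. The per-site averages update only at beat
#' boundaries; the target pressure of the afferent index is frozen as the
#' pre-tilt value of this average.
#'
#' @param trace data.frame with a `time` column and one column per site
#' @param beat_boundaries increasing vector of beat-boundary times, s
#'   (at least two, bracketing one completed beat)
#' @return named vector of per-site means over the last completed beat
#' @export
update_cycle_mean <- function(trace, beat_boundaries) {
  if (length(beat_boundaries) < 2L) stop("need at least one completed beat")
  b <- sort(beat_boundaries)
  t0 <- b[length(b) - 1L]; t1 <- b[length(b)]
  sel <- trace$time > t0 & trace$time <= t1
  if (!any(sel)) stop("no samples in the last completed beat")
  cols <- setdiff(names(trace), "time")
  vapply(trace[sel, cols, drop = FALSE], mean, numeric(1))
}
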