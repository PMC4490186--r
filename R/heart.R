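#' Left heart parameters
#'
#' Defaults are the published parameter set of the 0D left heart used
#' throughout the package: minimum/maximum ventricular elastance, timing of
#' the normalized elastance curve, nonlinear internal ventricular resistance
#' coefficient, passive atrial elastance and the valve resistances and
#' inertances. Units: elastances dyn cm^-5, times s, `k_lv` s cm^-3,
#' volumes cm^3, resistances dyn s cm^-5, inertances dyn s^2 cm^-5.
#'
#' The baseline heart period `t_baseline` is not part of the published set;
#' the default 0.8 s is consistent with the 0.4 s time-to-peak and 0.2 s
#' relaxation interval occupying 75 % of the beat.
#'
#' @param ... named overrides of any default
#' @return list of heart parameters
#' @export
heart_params <- function(...) {
  p <- list(
    e_min = 4.102e1, e_max = 3.000e3,
    t_max = 4e-1, t_relax = 2e-1,
    k_lv = 5e-4, v_u_lv = 0,
    e_la = 1.333e2, v_u_la = 0,
    r_mv = 1.187e-1, l_mv = 6.667e-1,
    r_av = 1.000e-1, l_av = 1.000e-1,
    t_baseline = 0.8
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown heart parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  with(p, {
    if (!(e_max > e_min && e_min > 0)) stop("need e_max > e_min > 0")
    if (t_max + t_relax > t_baseline + 1e-12)
      stop("t_max + t_relax must not exceed the heart period")
    if (any(c(r_mv, l_mv, r_av, l_av) <= 0))
      stop("valve resistances and inertances must be > 0")
  })
  p
}

#' Normalized ventricular elastance curve
#'
#' Dimensionless activation of the ventricle over one beat, on a normalized
#' beat phase `s` in [0, 1]. The curve rises as a half-cosine from 0 to its
#' peak of exactly 1 at the time-to-maximum, falls back to 0 over the
#' relaxation interval, and stays at 0 for the remainder of the beat:
#' \deqn{e_n(t) = \frac{1}{2}(1 - \cos(\pi t / T_{max})),\quad 0 \le t \le T_{max}}
#' \deqn{e_n(t) = \frac{1}{2}(1 + \cos(\pi (t - T_{max}) / T_{relax})),\quad
#'   T_{max} < t \le T_{max} + T_{relax}}
#' and 0 otherwise, where `t = s * T` and the timing anchors are the fixed
#' beat-phase fractions `f_max = T_max / T` and `f_relax = T_relax / T`
#' evaluated at the baseline period. The curve is universal in normalized
#' time: when the baroreflex shortens the period, systole and relaxation
#' shorten proportionally, preserving the diastolic filling fraction (as the
#' normalized-elastance experiments across heart rates show). This smooth
#' piecewise form stands in for the published analytic curve, is anchored by
#' exactly the published timing constants, and any alternative curve with
#' the same (0, 1, 0) anchors can be substituted.
#'
#' @param s beat phase fraction in [0, 1] (vectorized)
#' @param f_max phase fraction of peak elastance (baseline `t_max /
#'   t_baseline`)
#' @param f_relax phase fraction spanned by relaxation (baseline
#'   `t_relax / t_baseline`)
#' @return normalized elastance in [0, 1]
#' @export
normalized_elastance <- function(s, f_max = 0.5, f_relax = 0.25) {
  if (any(s < 0 | s > 1)) stop("beat phase fraction must lie in [0, 1]")
  if (f_max <= 0 || f_relax <= 0 || f_max + f_relax > 1 + 1e-12)
    stop("need f_max > 0, f_relax > 0, f_max + f_relax <= 1")
  en <- numeric(length(s))
  i1 <- s <= f_max
  en[i1] <- 0.5 * (1 - cos(pi * s[i1] / f_max))
  i2 <- s > f_max & s <= f_max + f_relax
  en[i2] <- 0.5 * (1 + cos(pi * (s[i2] - f_max) / f_relax))
  en
}

#' Ventricular pressure from the time-varying elastance relation
#'
#' `P_LV = [E_min + (E_max_eff - E_min) * e_n] * (V_LV - V_u,LV)`, where
#' `E_max_eff` is the baroreflex-scaled maximum elastance
#' (`e_max * x_emax`).
#'
#' @param v_lv ventricular volume, cm^3 (must exceed the unstressed volume)
#' @param t_in_beat time since beat onset, s
#' @param params heart parameters from [heart_params()]
#' @param period current heart period, s (default baseline)
#' @param x_emax baroreflex scaling of the maximum elastance (default 1)
#' @return ventricular pressure, dyn cm^-2
#' @export
ventricular_pressure <- function(v_lv, t_in_beat, params = heart_params(),
                                 period = params$t_baseline, x_emax = 1) {
  if (any(v_lv <= params$v_u_lv))
    stop("ventricular collapse: V_LV must exceed the unstressed volume")
  en <- normalized_elastance(t_in_beat / period,
                             params$t_max / params$t_baseline,
                             params$t_relax / params$t_baseline)
  e <- params$e_min + (params$e_max * x_emax - params$e_min) * en
  e * (v_lv - params$v_u_lv)
}

#' Nonlinear internal ventricular resistance
#'
#' `R_LV = k_LV * P_LV`: a flow-dependent pressure loss inside the
#' ventricle, linear in the instantaneous ventricular pressure.
#'
#' @param p_lv ventricular pressure, dyn cm^-2 (>= 0)
#' @param k_lv resistance coefficient, s cm^-3
#' @return resistance, dyn s cm^-5
#' @export
ventricular_resistance <- function(p_lv, k_lv = heart_params()$k_lv) {
  if (any(p_lv < 0)) stop("ventricular pressure must be >= 0")
  k_lv * p_lv
}

#' Passive left atrial pressure
#'
#' `P_LA = E_LA * (V_LA - V_u,LA)`. The atrium is passive (no contraction);
#' negative stressed volumes extrapolate to negative pressures.
#'
#' @param v_la atrial volume, cm^3
#' @param params heart parameters
#' @return atrial pressure, dyn cm^-2
#' @export
atrial_pressure <- function(v_la, params = heart_params()) {
  params$e_la * (v_la - params$v_u_la)
}

#' One implicit step of the aortic ejection ODE system
#'
#' Backward-Euler update of the coupled aortic-valve flow / ventricular
#' volume system with the valve open:
#' \deqn{L_{AV} \dot{Q}_{AV} + (R_{AV} + R_{LV}(P_{LV})) Q_{AV} = P_{LV} - P_{AV}}
#' \deqn{\dot{V}_{LV} = -Q_{AV}}
#' with `P_LV` eliminated through the elastance relation, which makes the
#' update a scalar nonlinear equation in `Q_AV` (nonlinear through
#' `R_LV = k_LV P_LV`). Solved by damped Newton–Raphson to a relative
#' residual below `tol`.
#'
#' @param q_av aortic flow at the current step, cm^3 s^-1
#' @param v_lv ventricular volume at the current step, cm^3
#' @param p_av aortic root pressure at the new time level, dyn cm^-2
#' @param t_in_beat time since beat onset at the new time level, s
#' @param dt time step, s
#' @param params heart parameters
#' @param period current heart period, s
#' @param x_emax baroreflex scaling of maximum elastance
#' @param tol relative residual tolerance
#' @param max_iter Newton iteration cap; exceeding it is an error that
#'   reports the residual history
#' @return list with `q_av`, `v_lv`, `p_lv` at the new time level and the
#'   iteration count
#' @export
solve_ejection_step <- function(q_av, v_lv, p_av, t_in_beat, dt,
                                params = heart_params(),
                                period = params$t_baseline, x_emax = 1,
                                tol = 1e-10, max_iter = 50L) {
  en <- normalized_elastance(t_in_beat / period,
                             params$t_max / params$t_baseline,
                             params$t_relax / params$t_baseline)
  e_now <- params$e_min + (params$e_max * x_emax - params$e_min) * en
  res <- .heart_solve(
    q_av0 = q_av, q_mv0 = 0, v_lv = v_lv,
    pf_root = p_av, pf_la = 0,
    g_rr = 0, g_rm = 0, g_lr = 0, g_lm = 0,
    e_now = e_now, dt = dt, hp = params,
    ao_open = TRUE, mv_open = FALSE, tol = tol, max_iter = max_iter)
  list(q_av = res$q_av, v_lv = res$v_lv, p_lv = res$p_lv, iter = res$iter)
}

# Monolithic valve-flow solve. The linear circuit contributes its
# Schur-complement response: P_root = pf_root + g_rr*Q_AV + g_rm*(-Q_MV),
# P_la = pf_la + g_lr*Q_AV + g_lm*(-Q_MV) (the g's already carry the sign
# convention of the boundary-flow vector q = c(Q_AV, -Q_MV)). Unknowns are
# the open-valve flows; with both valves closed the update is trivial.
# Newton with analytic Jacobian; R_LV = k_lv * max(P_LV, 0).
.heart_solve <- function(q_av0, q_mv0, v_lv, pf_root, pf_la,
                         g_rr, g_rm, g_lr, g_lm,
                         e_now, dt, hp, ao_open, mv_open,
                         tol = 1e-10, max_iter = 50L) {
  if (!ao_open && !mv_open) {
    p_lv <- e_now * (v_lv - hp$v_u_lv)
    return(list(q_av = 0, q_mv = 0, v_lv = v_lv, p_lv = p_lv,
                p_root = pf_root, p_la = pf_la, iter = 0L))
  }
  la_dt <- hp$l_av / dt
  lm_dt <- hp$l_mv / dt
  qa <- if (ao_open) q_av0 else 0
  qm <- if (mv_open) q_mv0 else 0
  hist <- numeric(max_iter)
  scale <- max(abs(e_now * (v_lv - hp$v_u_lv)), abs(pf_root), abs(pf_la), 1)
  for (it in seq_len(max_iter)) {
    vl <- v_lv + dt * (qm - qa)
    p_lv <- e_now * (vl - hp$v_u_lv)
    dplv_dqa <- -e_now * dt
    dplv_dqm <- e_now * dt
    r_lv <- hp$k_lv * max(p_lv, 0)
    dr_dp <- if (p_lv > 0) hp$k_lv else 0
    p_root <- pf_root + g_rr * qa - g_rm * qm
    p_la <- pf_la + g_lr * qa - g_lm * qm

    f1 <- if (ao_open)
      la_dt * (qa - q_av0) + (hp$r_av + r_lv) * qa - p_lv + p_root else 0
    f2 <- if (mv_open)
      lm_dt * (qm - q_mv0) + hp$r_mv * qm - p_la + p_lv else 0
    rnorm <- max(abs(f1), abs(f2)) / scale
    hist[it] <- rnorm
    if (rnorm < tol) {
      return(list(q_av = qa, q_mv = qm, v_lv = vl, p_lv = p_lv,
                  p_root = p_root, p_la = p_la, iter = it - 1L))
    }
    j11 <- la_dt + hp$r_av + r_lv + dr_dp * dplv_dqa * qa - dplv_dqa + g_rr
    j12 <- dr_dp * dplv_dqm * qa - dplv_dqm - g_rm
    j21 <- -g_lr + dplv_dqa
    j22 <- lm_dt + hp$r_mv + g_lm + dplv_dqm
    if (ao_open && mv_open) {
      det <- j11 * j22 - j12 * j21
      dqa <- (f1 * j22 - f2 * j12) / det
      dqm <- (j11 * f2 - j21 * f1) / det
      qa <- qa - dqa; qm <- qm - dqm
    } else if (ao_open) {
      qa <- qa - f1 / j11
    } else {
      qm <- qm - f2 / j22
    }
  }
  stop("valve-flow Newton iteration failed to converge in ", max_iter,
       " iterations; relative residual history: ",
       paste(format(hist, digits = 3), collapse = ", "))
}
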