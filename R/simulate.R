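#' Simulate the closed-loop model
#'
#' Advances the full closed loop with the backward-Euler scheme: at every
#' step the linear circuit (surrogate arteries, Windkessels, distal chain,
#' atrium) is solved through its cached LU factors, and the ventricle/valve
#' subsystem is solved monolithically against it via the circuit's
#' boundary-flow response (`x = x_free + G q`, Newton on the open-valve
#' flows), so the whole step is implicit. Valve transitions are detected
#' after a step and applied before the next. Baroreflex bookkeeping is
#' per-beat: cycle-average carotid pressures feed the afferent index, the
#' control ODEs advance with the efferent drive held over the beat, and the
#' controlled parameters (heart period, maximum elastance, distal
#' resistances, venous compliances/unstressed volumes) update at beat
#' boundaries, which is the only time the system matrices are refactorized.
#'
#' @param model a [tilt_model()]
#' @param duration simulated time, s
#' @param init initial state from [initial_state()] or a previous run's
#'   `$state`; `NULL` builds the default
#' @param dt time step, s
#' @param control_on logical: activate the baroreflex response
#' @param protocol a [tilt_protocol()], or `NULL` for a plain supine run
#'   (no gravity trigger, controls at rest)
#' @param record_stride record every `record_stride`-th step
#' @param stop_when_periodic `NULL`, or `list(tol =, min_beats =)`: stop at
#'   the first beat boundary where stroke volume and beat-mean aortic root
#'   pressure both change by less than `tol` (relative) from the previous
#'   beat
#' @return a `tilt_run` list: `timeseries` (data.frame), `beats` (per-beat
#'   metrics data.frame), `state` (continuation state), `diagnostics`
#'   (volume drift, max regurgitant volume per closure, refactorization
#'   count, periodicity flag)
#' @export
simulate_run <- function(model, duration, init = NULL,
                         dt = model$config$sim$dt,
                         control_on = FALSE, protocol = NULL,
                         record_stride = model$config$sim$record_stride,
                         stop_when_periodic = NULL) {
  cfg <- model$config
  hp <- cfg$heart
  f_max <- hp$t_max / hp$t_baseline
  f_relax <- hp$t_relax / hp$t_baseline
  gains <- cfg$control$gains
  nu <- cfg$control$nu
  nvar <- gains$variable
  grav <- cfg$gravity$g

  baselines <- list(
    t_baseline = hp$t_baseline, e_max = hp$e_max,
    r2 = stats::setNames(cfg$windkessel$r2, cfg$windkessel$outlet),
    r_a = cfg$distal$arterioles$r,
    c_v1 = cfg$distal$venules$c, c_v2 = cfg$distal$veins$c,
    v_u_v1 = cfg$distal$venules$v_u, v_u_v2 = cfg$distal$veins$v_u)

  xc <- stats::setNames(rep(1, 5), nvar)       # control ODE state
  delta <- 1
  p_target <- NULL
  if (!is.null(init$control)) {
    xc <- init$control$xc; delta <- init$control$delta
    p_target <- init$control$p_target
  }
  eff <- apply_controls(xc, baselines)
  period <- eff$period
  e_max_eff <- eff$e_max
  cv1_cur <- eff$c_v1; cv2_cur <- eff$c_v2
  vu1_cur <- eff$v_u_v1; vu2_cur <- eff$v_u_v2

  sys <- build_system(model, dt, eff)
  refresh <- function(sys) {
    bd <- diag(sys$B)
    stopifnot(max(abs(sys$B - diag(bd, sys$n))) == 0)
    list(Ainv = sys$Ainv, bd = bd, D0 = sys$D0,
         Es1 = sys$Esrc[, 1], Es2 = sys$Esrc[, 2],
         g1 = sys$G[, 1], g2 = sys$G[, 2],
         cap_idx = vapply(sys$caps, `[[`, integer(1), "ia"),
         cap_c = vapply(sys$caps, `[[`, numeric(1), "c"),
         cap_vu = vapply(sys$caps, `[[`, numeric(1), "vu"))
  }
  fa <- refresh(sys)

  if (is.null(init)) init <- initial_state(model, sys)
  x <- init$x
  hstate <- init$heart
  v_lv <- hstate$v_lv; q_av <- hstate$q_av; q_mv <- hstate$q_mv
  ao_open <- hstate$ao_open; mv_open <- hstate$mv_open
  t0 <- init$time %||% 0
  phase <- init$phase %||% 0

  i_root <- model$i_root; i_la <- model$i_la
  i_pv1 <- model$i_pv1; i_pv2 <- model$i_pv2
  mon_idx <- c(root = i_root, model$upper_sites,
               dao_out = unname(model$outlet_nodes[["desc_aorta"]]),
               pa = model$i_pa, pv1 = i_pv1, pv2 = i_pv2, la = i_la)
  acc_idx <- c(mon_idx, model$outlet_flow_idx)
  acc_names <- c(names(mon_idx), paste0("q_", names(model$outlet_flow_idx)))
  carotid_names <- names(model$carotid_sites)

  n_steps <- round(duration / dt)
  n_rec <- n_steps %/% max(record_stride, 1L)
  flow_names <- paste0("q_", names(sys$qidx))
  ts_cols <- c("time", sys$nodes, flow_names,
               "p_lv", "v_lv", "q_av", "q_mv", "theta", "delta")
  ts <- matrix(NA_real_, n_rec, length(ts_cols),
               dimnames = list(NULL, ts_cols))
  ri <- 0L

  t_sup <- if (is.null(protocol)) Inf else protocol$t_supine
  t_rot_end <- if (is.null(protocol)) Inf else
    protocol$t_supine + protocol$t_rotation
  theta_cur <- 0
  gxz <- c(0, -grav)                     # supine gravity components
  D_cur <- fa$D0 + fa$Es1 * gxz[1] + fa$Es2 * gxz[2]

  p_lv_prev <- e_max_eff * 0 + (hp$e_min) * (v_lv - hp$v_u_lv)
  v_lv_prev <- v_lv
  beat_idx <- 0L
  n_in_beat <- 0L
  acc <- numeric(length(acc_idx))
  vmax <- -Inf; vmin <- Inf; qmax <- 0
  root_max <- -Inf; root_min <- Inf
  sw_acc <- 0; te <- 0
  cand_p_target <- NULL
  beats <- list()
  prev_sv <- NA_real_; prev_mean <- NA_real_
  converged <- is.null(stop_when_periodic)
  regurg_max <- 0
  reassemblies <- 0L
  max_newton <- 0L

  vtot <- function() sum(fa$cap_vu) + sum(fa$cap_c * x[fa$cap_idx]) + v_lv
  v0 <- vtot()
  vdrift <- 0

  tm <- t0
  for (k in seq_len(n_steps)) {
    tm <- t0 + k * dt
    phase <- phase + dt

    if (!is.null(protocol) && tm > t_sup && tm <= t_rot_end + dt) {
      theta_cur <- theta_schedule(tm, protocol)
      th_eff <- if (isTRUE(protocol$head_up)) -theta_cur else theta_cur
      gv <- gravity_vector(th_eff, grav)
      gxz <- c(gv[1], gv[3])
      D_cur <- fa$D0 + fa$Es1 * gxz[1] + fa$Es2 * gxz[2]
    }

    # normalized elastance at the new time level (universal in beat phase:
    # systole/relaxation fractions fixed at their baseline values)
    t_sys <- f_max * period
    t_rel <- f_relax * period
    en <- if (phase <= t_sys) {
      0.5 * (1 - cos(pi * phase / t_sys))
    } else if (phase <= t_sys + t_rel) {
      0.5 * (1 + cos(pi * (phase - t_sys) / t_rel))
    } else 0
    e_now <- hp$e_min + (e_max_eff - hp$e_min) * en

    rhs <- fa$bd * x + D_cur
    xf <- fa$Ainv %*% rhs
    dim(xf) <- NULL

    hs <- .heart_solve(q_av, q_mv, v_lv, xf[i_root], xf[i_la],
                       fa$g1[i_root], fa$g2[i_root],
                       fa$g1[i_la], fa$g2[i_la],
                       e_now, dt, hp, ao_open, mv_open)
    if (hs$iter > max_newton) max_newton <- hs$iter
    x <- xf + fa$g1 * hs$q_av - fa$g2 * hs$q_mv
    if (!all(is.finite(x))) {
      stop("numerical failure: non-finite solution at step ", k,
           " (t = ", format(tm), ")")
    }
    p_root <- x[i_root]; p_la <- x[i_la]
    p_lv <- hs$p_lv
    v_lv <- hs$v_lv
    if (v_lv <= hp$v_u_lv) stop("ventricular collapse at t = ", format(tm))
    q_av <- hs$q_av; q_mv <- hs$q_mv

    sw_acc <- sw_acc + 0.5 * (p_lv + p_lv_prev) * (v_lv - v_lv_prev)
    if (ao_open) {
      te <- te + dt
      if (q_av > qmax) qmax <- q_av
    }
    p_lv_prev <- p_lv; v_lv_prev <- v_lv

    # valve state machine (applied before the next step)
    if (ao_open) {
      if (q_av < 0) {
        ao_open <- FALSE
        regurg_max <- max(regurg_max, -q_av * dt)
        q_av <- 0
      }
    } else if (p_lv > p_root) ao_open <- TRUE
    if (mv_open) {
      if (q_mv < 0) { mv_open <- FALSE; q_mv <- 0 }
    } else if (p_la > p_lv) mv_open <- TRUE

    acc <- acc + x[acc_idx]
    n_in_beat <- n_in_beat + 1L
    if (v_lv > vmax) vmax <- v_lv
    if (v_lv < vmin) vmin <- v_lv
    if (p_root > root_max) root_max <- p_root
    if (p_root < root_min) root_min <- p_root

    if (record_stride > 0L && k %% record_stride == 0L && ri < n_rec) {
      ri <- ri + 1L
      ts[ri, ] <- c(tm, x, p_lv, v_lv, q_av, q_mv, theta_cur, delta)
    }

    if (phase >= period - 1e-12) {
      beat_idx <- beat_idx + 1L
      means <- stats::setNames(acc / n_in_beat, acc_names)
      vnow <- vtot()
      vdrift <- max(vdrift, abs(vnow - v0) / v0)
      sv <- vmax - vmin
      beats[[beat_idx]] <- c(
        beat = beat_idx, t_end = tm, period = period,
        sv = sv, sw = -sw_acc, co = sv / period, qm = qmax, te = te,
        root_sys = root_max, root_dia = root_min,
        pulse = root_max - root_min,
        means, delta = delta, stats::setNames(xc, paste0("x_", nvar)),
        volume = vnow)

      if (!is.null(protocol)) {
        if (tm < t_sup) {
          cand_p_target <- means[carotid_names]
        } else {
          if (is.null(p_target)) {
            p_target <- cand_p_target %||% means[carotid_names]
          }
          if (control_on) {
            ef <- efferent_activities(delta, nu)
            xc <- stats::setNames(
              control_advance(xc, ef$n_s, ef$n_p, gains, dt, n_in_beat),
              nvar)
          }
          delta <- select_delta(means[carotid_names] / p_target)
          if (control_on) {
            eff <- apply_controls(xc, baselines)
            # venous volume repartition at constant compartment volume
            v1 <- vu1_cur + cv1_cur * x[i_pv1]
            v2 <- vu2_cur + cv2_cur * x[i_pv2]
            x[i_pv1] <- (v1 - eff$v_u_v1) / eff$c_v1
            x[i_pv2] <- (v2 - eff$v_u_v2) / eff$c_v2
            cv1_cur <- eff$c_v1; cv2_cur <- eff$c_v2
            vu1_cur <- eff$v_u_v1; vu2_cur <- eff$v_u_v2
            period <- eff$period
            e_max_eff <- eff$e_max
            sys <- build_system(model, dt, eff)
            fa <- refresh(sys)
            D_cur <- fa$D0 + fa$Es1 * gxz[1] + fa$Es2 * gxz[2]
            reassemblies <- reassemblies + 1L
          }
        }
      }

      if (!is.null(stop_when_periodic)) {
        if (beat_idx >= (stop_when_periodic$min_beats %||% 3L) &&
            is.finite(prev_sv) && prev_sv > 0) {
          dsv <- abs(sv - prev_sv) / prev_sv
          dmn <- abs(means[["root"]] - prev_mean) / prev_mean
          if (dsv < stop_when_periodic$tol && dmn < stop_when_periodic$tol) {
            converged <- TRUE
            phase <- phase - period
            break
          }
        }
        prev_sv <- sv; prev_mean <- means[["root"]]
      }

      phase <- phase - period
      n_in_beat <- 0L
      acc[] <- 0
      vmax <- -Inf; vmin <- Inf; qmax <- 0
      root_max <- -Inf; root_min <- Inf
      sw_acc <- 0; te <- 0
    }
  }

  beats_df <- if (length(beats)) as.data.frame(do.call(rbind, beats)) else NULL
  ts_df <- as.data.frame(ts[seq_len(ri), , drop = FALSE])

  structure(list(
    timeseries = ts_df,
    beats = beats_df,
    state = list(x = x, heart = list(v_lv = v_lv, q_av = q_av, q_mv = q_mv,
                                     ao_open = ao_open, mv_open = mv_open),
                 time = tm, phase = phase,
                 control = list(xc = xc, delta = delta, p_target = p_target)),
    diagnostics = list(volume_initial = v0, volume_drift = vdrift,
                       regurgitant_volume_max = regurg_max,
                       reassemblies = reassemblies,
                       max_newton_iterations = max_newton,
                       periodic = converged, n_beats = beat_idx),
    dt = dt, control_on = control_on, protocol = protocol,
    config = model$config),
    class = "tilt_run")
}

#' @export
print.tilt_run <- function(x, ...) {
  nb <- x$diagnostics$n_beats
  cat("<tilt_run> ", if (is.null(x$protocol)) "supine" else "tilt protocol",
      ", control ", if (x$control_on) "on" else "off",
      ", ", nb, " beats, dt = ", format(x$dt), " s\n", sep = "")
  if (!is.null(x$beats) && nb > 0) {
    last <- x$beats[nrow(x$beats), ]
    cat(sprintf("  last beat: SV %.1f cm^3, CO %.1f cm^3/s, mean aortic %.1f mmHg, HR %.1f bpm\n",
                last$sv, last$co, last$root / MMHG, 60 / last$period))
  }
  cat(sprintf("  volume drift %.2e (relative), max regurgitant volume %.2e cm^3\n",
              x$diagnostics$volume_drift, x$diagnostics$regurgitant_volume_max))
  invisible(x)
}
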