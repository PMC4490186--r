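# Integration behavior of the assembled closed loop.

quick_cfg <- function(...) default_config(sim = list(dt = 2e-4,
                                                     record_stride = 1L), ...)

test_that("closed-loop volume is conserved and isovolumic phases are exact", {
  cfg <- quick_cfg()
  model <- tilt_model(cfg)
  run <- simulate_run(model, duration = 2 * 0.8, dt = 2e-4,
                      record_stride = 1L)
  expect_lt(run$diagnostics$volume_drift, 1e-9)
  ts <- run$timeseries
  # both valves closed -> V_LV exactly constant between consecutive steps
  iso <- ts$q_av == 0 & ts$q_mv == 0
  pairs <- which(iso[-1] & iso[-nrow(ts)])
  expect_gt(length(pairs), 100)
  expect_identical(ts$v_lv[pairs + 1L], ts$v_lv[pairs])
  # valve flows are non-negative apart from the single retrograde
  # detection sample that triggers closure
  expect_gt(min(ts$q_av), -5)
  expect_lt(run$diagnostics$regurgitant_volume_max, 0.01)
  expect_true(all(ts$q_mv > -5))
})

test_that("the periodic beat traces a counterclockwise PV loop whose area is the stroke work", {
  cfg <- quick_cfg()
  model <- tilt_model(cfg)
  sp <- spin_up(model, dt = 2e-4)
  run <- simulate_run(model, duration = 0.8, init = sp$state, dt = 2e-4,
                      record_stride = 1L)
  tr <- beat_trace(run, 1)
  # shoelace orientation: integral of V dP positive = counterclockwise in (V, P)
  n <- nrow(tr)
  circ_vdp <- sum(0.5 * (tr$v_lv[-1] + tr$v_lv[-n]) * diff(tr$p_lv)) +
    0.5 * (tr$v_lv[1] + tr$v_lv[n]) * (tr$p_lv[1] - tr$p_lv[n])
  expect_gt(circ_vdp, 0)
  m <- beat_metrics(tr)
  expect_equal(m$sw, run$beats$sw[1], tolerance = 1e-3)
  expect_equal(m$sv, run$beats$sv[1], tolerance = 1e-6)
  expect_equal(m$qm, run$beats$qm[1], tolerance = 1e-6)
  expect_equal(m$te, run$beats$te[1], tolerance = 3e-3)  # one-sample quantization
  # CO equals beat-mean aortic valve flow (independent estimators)
  expect_equal(m$co, mean(tr$q_av), tolerance = 5e-3)
})

test_that("spin-up converges to a limit cycle, deterministically, from distant initial states", {
  cfg <- default_config(sim = list(dt = 2.5e-4, record_stride = 0L))
  model <- tilt_model(cfg)
  sp1 <- spin_up(model, dt = 2.5e-4)
  sp2 <- spin_up(model, dt = 2.5e-4)
  expect_identical(sp1$state$x, sp2$state$x)   # determinism, bit-identical
  nb <- nrow(sp1$beats)
  expect_lt(abs(sp1$beats$sv[nb] / sp1$beats$sv[nb - 1] - 1), 1e-3)
  # absurd initial distribution (all stressed blood pooled in the veins, at
  # the same conserved total volume) reaches the same limit cycle: in a
  # closed conservative loop the total volume selects the cycle, the
  # distribution does not
  sys <- baroloop:::build_system(model, 2.5e-4)
  init <- initial_state(model, sys)
  st0 <- structure(list(x = init$x, time = 0), class = "cc_state")
  v_tot <- total_blood_volume(sys, st0, init$heart$v_lv)
  vu_all <- sum(vapply(sys$caps, `[[`, numeric(1), "vu"))
  cv2 <- sys$caps[["c_ven2"]]$c
  x2 <- init$x * 0
  x2[sys$pidx[["pv2"]]] <- (v_tot - vu_all - 60) / cv2
  init2 <- list(x = x2, heart = list(v_lv = 60, q_av = 0, q_mv = 0,
                                     ao_open = FALSE, mv_open = FALSE),
                time = 0)
  sp3 <- spin_up(model, init = init2, dt = 2.5e-4, max_beats = 40)
  expect_equal(sp3$beats$sv[nrow(sp3$beats)], sp1$beats$sv[nb],
               tolerance = 5e-3)
  expect_equal(sp3$state$heart$v_lv, sp1$state$heart$v_lv, tolerance = 5e-3)
})

test_that("runs are deterministic end to end", {
  cfg <- quick_cfg()
  model <- tilt_model(cfg)
  r1 <- simulate_run(model, duration = 1.6, dt = 2e-4, record_stride = 5L)
  r2 <- simulate_run(model, duration = 1.6, dt = 2e-4, record_stride = 5L)
  expect_identical(r1$timeseries, r2$timeseries)
  expect_identical(r1$beats, r2$beats)
})

test_that("volume stays conserved through active venous compliance and unstressed-volume control", {
  # shortened protocol so the controls engage within a cheap run
  cfg <- default_config(sim = list(dt = 2e-4, record_stride = 0L),
                        protocol = tilt_protocol(t_supine = 1.6,
                                                 t_rotation = 0.8,
                                                 t_upright = 1.6))
  model <- tilt_model(cfg)
  sp <- spin_up(model, dt = 2e-4)
  run <- simulate_run(model, duration = 4, init = sp$state, dt = 2e-4,
                      control_on = TRUE, protocol = cfg$protocol)
  expect_gt(run$diagnostics$reassemblies, 0)       # controls were applied
  expect_false(isTRUE(all.equal(run$beats$x_vu[nrow(run$beats)], 1)))
  expect_lt(run$diagnostics$volume_drift, 1e-9)
})

test_that("theta schedule covers the three stages with a monotone ramp", {
  pr <- tilt_protocol()
  expect_equal(theta_schedule(0, pr), 0)
  expect_equal(theta_schedule(10, pr), 0)
  expect_equal(theta_schedule(12.5, pr), pi / 4)    # linear midpoint
  expect_equal(theta_schedule(15, pr), pi / 2)
  expect_equal(theta_schedule(25, pr), pi / 2)
  t <- seq(10, 15, by = 0.01)
  expect_true(all(diff(theta_schedule(t, pr)) >= 0))
  prs <- tilt_protocol(ramp = "smoothstep")
  expect_true(all(diff(theta_schedule(t, prs)) >= 0))
  expect_equal(theta_schedule(12.5, prs), pi / 4)   # smoothstep midpoint
  expect_equal(theta_schedule(15, prs), pi / 2)
  expect_error(theta_schedule(-1, pr), ">= 0")
})

test_that("a no-trigger protocol run is indistinguishable from a plain supine run", {
  cfg <- default_config(sim = list(dt = 2e-4, record_stride = 5L),
                        protocol = tilt_protocol(t_supine = 3.2,
                                                 t_rotation = 0,
                                                 t_upright = 0,
                                                 theta_final = 0))
  model <- tilt_model(cfg)
  sp <- spin_up(model, dt = 2e-4)
  plain <- simulate_run(model, duration = 3.2, init = sp$state, dt = 2e-4,
                        record_stride = 5L)
  ctl <- simulate_run(model, duration = 3.2, init = sp$state, dt = 2e-4,
                      control_on = TRUE, protocol = cfg$protocol,
                      record_stride = 5L)
  expect_equal(ctl$timeseries$root, plain$timeseries$root, tolerance = 1e-9)
  xs <- unlist(ctl$beats[, paste0("x_", c("h", "emax", "r", "cv", "vu"))])
  expect_equal(unname(xs), rep(1, length(xs)), tolerance = 1e-9)
})

test_that("hydrostatic offsets vanish in the supine posture", {
  cfg <- quick_cfg()
  model <- tilt_model(cfg)
  sys <- build_system(model, 2e-4)
  # supine gravity (0, 0, -g): all segments lie in the z = const plane
  d_sup <- sys$Esrc %*% c(0, -981)
  expect_equal(max(abs(d_sup)), 0)
  # upright gravity along -x: the carotid path carries the full head
  d_up <- sys$Esrc %*% c(-981, 0)
  i_asc <- sys$qidx[["seg_asc_aorta"]]
  i_ccar <- sys$qidx[["seg_common_carotid_r"]]
  i_icar <- sys$qidx[["seg_internal_carotid_r"]]
  head_total <- d_up[i_asc] + d_up[i_ccar] + d_up[i_icar]
  expect_equal(head_total, -1.06 * 981 * 25, tolerance = 1e-9)
})
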