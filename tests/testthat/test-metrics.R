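# Beat metrics, baroreflex sensitivity, unit conversions and file IO.

test_that("stroke work of a rectangular synthetic loop equals its area", {
  # rectangle: fill at P = 10 (V 50 -> 120), pressurize, eject at P = 110
  v <- c(seq(50, 120, length.out = 30), rep(120, 10),
         seq(120, 50, length.out = 30), rep(50, 10))
  p <- c(rep(10, 30), seq(10, 110, length.out = 10),
         rep(110, 30), seq(110, 10, length.out = 10))
  tr <- data.frame(time = seq_along(v) * 1e-2, p_lv = p, v_lv = v,
                   q_av = 0, ao_open = FALSE)
  m <- beat_metrics(tr)
  expect_equal(m$sw, 100 * 70, tolerance = 1e-3)
  expect_equal(m$sv, 70)
})

test_that("a zero-ejection beat has SV = 0, TE = 0, SW ~ 0", {
  t <- seq(0, 0.8, by = 1e-3)
  tr <- data.frame(time = t, p_lv = 5e3 + 1e3 * sin(2 * pi * t / 0.8),
                   v_lv = rep(120, length(t)), q_av = 0, ao_open = FALSE)
  m <- beat_metrics(tr)
  expect_equal(m$sv, 0)
  expect_equal(m$te, 0)
  expect_lt(m$sw, 1e-6)
})

test_that("a triangular flow pulse gives QM from the peak and SV from quadrature", {
  dt <- 1e-4
  t <- seq(0, 0.8, by = dt)
  q <- ifelse(t <= 0.15, t / 0.15 * 400,
              ifelse(t <= 0.3, (0.3 - t) / 0.15 * 400, 0))
  v <- 130 - cumsum(c(0, 0.5 * (q[-1] + q[-length(q)]) * dt))
  tr <- data.frame(time = t, p_lv = 1e5, v_lv = v, q_av = q,
                   ao_open = q > 0)
  m <- beat_metrics(tr)
  expect_equal(m$qm, 400, tolerance = 1e-6)
  expect_equal(m$sv, 60, tolerance = 1e-3)      # triangle area 0.5*400*0.3
  expect_equal(m$te, 0.3, tolerance = 1e-3)     # valve-open duration
  expect_equal(m$co, m$sv / m$period, tolerance = 1e-12)
  # CO equals the beat-mean aortic flow (two independent estimators)
  expect_equal(m$co, mean(q), tolerance = 5e-3)
})

test_that("site summaries report systolic/diastolic/mean/pulse in mmHg", {
  t <- seq(0, 0.8, by = 1e-3)
  tr <- data.frame(time = t, p_lv = 1e5, v_lv = 100, q_av = 0,
                   ao_open = FALSE,
                   root = (100 + 15 * sin(2 * pi * t / 0.8)) * MMHG)
  m <- beat_metrics(tr, sites = "root")
  expect_equal(m$sites$systolic, 115, tolerance = 1e-3)
  expect_equal(m$sites$diastolic, 85, tolerance = 1e-3)
  expect_equal(m$sites$pulse, 30, tolerance = 1e-3)
  expect_error(beat_metrics(tr, sites = "nope"), "unknown site")
})

test_that("baroreflex sensitivity is the per-beat systolic increment series", {
  b <- baroreflex_sensitivity(c(100, 104, 106), c(0.8, 0.78, 0.77))
  expect_equal(b$d_systolic, c(4, 2))
  expect_equal(b$d_period_ms, c(-20, -10))
  expect_equal(baroreflex_sensitivity(rep(110, 5), rep(0.8, 5))$d_systolic,
               rep(0, 4))
  expect_true(is.na(baroreflex_sensitivity(rep(110, 5), rep(0.8, 5))$slope))
  # proportional series: slope recovers the ratio
  sys <- c(100, 102, 105, 103, 108)
  per <- 0.8 - 0.002 * (sys - 100)
  expect_equal(baroreflex_sensitivity(sys, per)$slope, -2, tolerance = 1e-9)
  expect_error(baroreflex_sensitivity(100, 0.8), "two beats")
})

test_that("unit conversions are exact round trips", {
  x <- c(0.1, 1, 97.3, 1e5)
  expect_equal(from_mmhg(to_mmhg(x)), x, tolerance = 1e-15)
  expect_identical(joule_to_erg(erg_to_joule(x)), x)  # power-of-ten factor
  expect_equal(to_mmhg(1333.22), 1)
  expect_equal(erg_to_joule(1e7), 1)
})

test_that("time series, metrics and metadata round-trip through files", {
  cfg <- default_config(sim = list(dt = 2e-4, record_stride = 4L))
  model <- tilt_model(cfg)
  run <- simulate_run(model, duration = 2 * 0.8, record_stride = 4L,
                      dt = 2e-4)
  td <- withr::local_tempdir()
  f1 <- file.path(td, "ts.csv")
  write_timeseries(run, f1)
  ts2 <- read_timeseries(f1)
  expect_equal(nrow(ts2), nrow(run$timeseries))
  expect_equal(ts2$root, run$timeseries$root, tolerance = 1e-12)
  expect_equal(ts2$root_mmhg, run$timeseries$root / MMHG, tolerance = 1e-12)
  expect_equal(ts2$p_lv_mmhg * MMHG, ts2$p_lv, tolerance = 1e-12)

  f2 <- file.path(td, "beats.csv")
  write_metrics(run, f2)
  b2 <- utils::read.csv(f2)
  expect_equal(nrow(b2), run$diagnostics$n_beats)
  expect_equal(b2$sv, run$beats$sv, tolerance = 1e-12)

  f3 <- file.path(td, "meta.json")
  write_run_metadata(run, f3)
  meta <- read_run_metadata(f3)
  expect_false(meta$control_on)
  expect_identical(meta$config_hash, config_hash(cfg))
  expect_equal(meta$n_beats, run$diagnostics$n_beats)

  # protocol and control flag are recorded for an experiment run
  run2 <- simulate_run(model, duration = 0.8, dt = 2e-4,
                       control_on = TRUE, protocol = tilt_protocol())
  write_run_metadata(run2, f3)
  meta2 <- read_run_metadata(f3)
  expect_true(meta2$control_on)
  expect_equal(meta2$protocol$t_rotation, 5)
})

test_that("configurations round-trip through YAML", {
  cfg <- default_config()
  td <- withr::local_tempdir()
  f <- file.path(td, "cfg.yaml")
  write_config(cfg, f)
  cfg2 <- read_config(f)
  expect_equal(cfg2$windkessel, cfg$windkessel, tolerance = 1e-12)
  expect_equal(cfg2$geometry$radius, cfg$geometry$radius, tolerance = 1e-12)
  expect_equal(cfg2$heart, cfg$heart)
  expect_equal(cfg2$control$gains, cfg$control$gains)
  expect_identical(config_hash(cfg2), config_hash(cfg))
})
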