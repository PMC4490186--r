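# Backward-Euler circuit stepper against closed-form fixtures.

rc_error_at <- function(dt, t_end = 1) {
  fx <- make_fixture("rc_decay")
  sys <- assemble_system(fx$circuit, dt)
  st <- fx$state0(sys)
  for (k in seq_len(round(t_end / dt))) st <- circuit_step(sys, st)
  abs(node_pressures(sys, st)[["n"]] - fx$reference(t_end)) /
    fx$reference(t_end)
}

test_that("RC discharge matches exp(-t) and converges at first order", {
  expect_lt(rc_error_at(1e-4), 1e-3)
  e <- vapply(c(4e-3, 2e-3, 1e-3), rc_error_at, numeric(1))
  order <- log2(e[-3] / e[-1])
  expect_true(all(order > 0.8 & order < 1.2))
})

test_that("series RLC step response matches the damped-oscillator solution", {
  fx <- make_fixture("rlc_step")
  dt <- 1e-4
  sys <- assemble_system(fx$circuit, dt)
  st <- fx$state0(sys)
  err <- 0
  for (k in seq_len(round(5 / dt))) {
    st <- circuit_step(sys, st)
    err <- max(err, abs(node_pressures(sys, st)[["n"]] - fx$reference(st$time)))
  }
  expect_lt(err, 1e-3)
})

test_that("assembly rejects invalid inputs", {
  fx <- make_fixture("rc_decay")
  expect_error(assemble_system(fx$circuit, 0), "dt")
  expect_error(assemble_system(fx$circuit, -1e-3), "dt")
  expect_error(el_resistor("r", "a", "b", 0), "> 0")
  expect_error(el_capacitor("c", "a", 1, v_unstressed = -1), ">= 0")
  # floating node pair: no pressure reference anywhere
  floating <- circuit(list(el_resistor("r", "a", "b", 1)))
  expect_error(assemble_system(floating, 1e-3), "singular")
})

test_that("a resistive ladder under constant inflow reaches the hand-computed series solution", {
  # inflow q at node a; a -R1- b -R2- c -R3- ground; caps give dynamics only
  r <- c(8.893e2, 2.973e1, 3.560e1)    # arteriole/venule/venous chain values
  circ <- circuit(list(
    el_capacitor("ca", "a", 1e-3), el_resistor("r1", "a", "b", r[1]),
    el_capacitor("cb", "b", 1e-2), el_resistor("r2", "b", "c", r[2]),
    el_capacitor("cc", "c", 5e-2), el_resistor("r3", "c", "0", r[3])
  ), boundary = "a")
  sys <- assemble_system(circ, 1e-3)
  st <- circuit_state(sys)
  q <- 60
  for (k in seq_len(40000)) st <- circuit_step(sys, st, q = q)
  p <- node_pressures(sys, st)
  # hand-computed cumulative series resistances from ground up
  expect_equal(p[["c"]], q * r[3], tolerance = 1e-6)
  expect_equal(p[["b"]], q * (r[3] + r[2]), tolerance = 1e-6)
  expect_equal(p[["a"]], q * sum(r), tolerance = 1e-6)
})

test_that("a state at rest with zero sources is a fixed point", {
  fx <- make_fixture("rlc_step")
  circ0 <- circuit(list(
    el_pressure_source("src", "s", 0),
    el_inductor("l", "s", "n", l = 1, r_series = 0.5),
    el_capacitor("c", "n", 1)
  ))
  sys <- assemble_system(circ0, 1e-3)
  st <- circuit_state(sys)
  st2 <- circuit_step(sys, st)
  expect_equal(st2$x, st$x, tolerance = 1e-14)
})

test_that("constant inflow into a pure capacitor integrates exactly", {
  circ <- circuit(list(el_capacitor("c", "n", 2, v_unstressed = 5)),
                  boundary = "n")
  dt <- 1e-3
  sys <- assemble_system(circ, dt)
  st <- circuit_state(sys)
  v0 <- total_blood_volume(sys, st)
  expect_equal(v0, 5)
  q <- 3.7
  for (k in 1:100) st <- circuit_step(sys, st, q = q)
  # volume drifts by exactly the net boundary flux integral
  expect_equal(total_blood_volume(sys, st) - v0, q * 100 * dt,
               tolerance = 1e-12)
})

test_that("total volume in a closed loop is conserved, including unstressed volumes", {
  fx <- make_fixture("toy_loop")
  sys <- assemble_system(fx$circuit, 1e-3)
  st <- fx$state0(sys)
  v0 <- total_blood_volume(sys, st)
  for (k in seq_len(2000)) {
    st <- circuit_step(sys, st, g = c(fx$source_fun(st$time + 1e-3), 0))
  }
  expect_equal(total_blood_volume(sys, st), v0, tolerance = 1e-12)
  expect_equal(sum(vapply(sys$caps, `[[`, numeric(1), "vu")), 6)
})

test_that("toy closed loop follows a high-accuracy adaptive reference", {
  skip_if_not_installed("deSolve")
  fx <- make_fixture("toy_loop")
  dt <- 2e-4
  sys <- assemble_system(fx$circuit, dt)
  st <- fx$state0(sys)
  times <- seq(0.1, 2, by = 0.1)
  ref <- fx$reference(times)
  got <- matrix(NA_real_, length(times), 3)
  i <- 0L
  for (k in seq_len(round(2 / dt))) {
    st <- circuit_step(sys, st, g = c(fx$source_fun(st$time + dt), 0))
    if (k %% round(0.1 / dt) == 0L) {
      i <- i + 1L
      got[i, ] <- node_pressures(sys, st)[c("n1", "n2", "n3")]
    }
  }
  expect_lt(max(abs(got - ref[, 1:3])), 2e-3)
})

test_that("diode state machine: pressure opens, retrograde flow closes", {
  circ <- circuit(list(
    el_capacitor("cu", "up", 1), el_capacitor("cd", "dn", 1),
    el_diode("valve", "up", "dn", r = 0.1, open = FALSE)
  ))
  sys <- assemble_system(circ, 1e-3)
  # closed, downstream pressure below upstream -> opens
  st <- circuit_state(sys, p = c(up = 2, dn = 1))
  open <- update_valve_states(circ, sys, st)
  expect_true(open[["valve"]])
  expect_true(attr(open, "changed"))
  # open, forward flow, adverse gradient impossible for a resistive diode,
  # but flow >= 0 keeps it open
  open2 <- update_valve_states(circ, sys, st, open = c(valve = TRUE))
  expect_true(open2[["valve"]])
  # open with retrograde flow (downstream above upstream) -> closes
  st2 <- circuit_state(sys, p = c(up = 1, dn = 2))
  open3 <- update_valve_states(circ, sys, st2, open = c(valve = TRUE))
  expect_false(open3[["valve"]])
  # closed with adverse gradient stays closed
  open4 <- update_valve_states(circ, sys, st2, open = c(valve = FALSE))
  expect_false(open4[["valve"]])
  expect_false(attr(open4, "changed"))
})

test_that("matrix reassembly happens iff a valve changes state", {
  # half-wave rectifier: sinusoidal source, diode, capacitor with bleed
  circ <- circuit(list(
    el_pressure_source("src", "s", 0, dsrc = c(1, 0)),
    el_diode("d", "s", "n", r = 0.05, open = FALSE),
    el_capacitor("c", "n", 1),
    el_resistor("bleed", "n", "0", 5)
  ))
  out <- simulate_circuit(circ, dt = 1e-3, t_end = 3,
                          g_fun = function(t) c(sin(2 * pi * t), 0),
                          record = 5L)
  expect_gt(out$valve_events, 3)
  expect_identical(out$reassemblies, out$valve_events)
  # diode branch never carries retrograde flow for more than the detection step
  expect_true(all(diff(out$trace$n) > -0.06))
  # no diodes -> no reassemblies
  out2 <- simulate_circuit(make_fixture("rc_decay")$circuit, 1e-3, 0.5,
                           state0 = NULL, record = 0L)
  expect_identical(out2$reassemblies, 0L)
})
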