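#' Analytic test fixtures
#'
#' Miniature circuits paired with exact (or high-accuracy) reference
#' solutions, used to verify the circuit stepper against closed forms:
#'
#' * `rc_decay` — unit RC loop discharging from 1; reference `exp(-t)`.
#' * `rlc_step` — series R-L-C (R = 0.5, L = 1, C = 1) charged by a unit
#'   pressure step from rest; reference is the underdamped second-order
#'   step response at the capacitor node.
#' * `static_column` — a 20 cm vertical fluid column (rho = 1.06) between a
#'   fixed-pressure node and a capacitor node; reference is the hydrostatic
#'   head `rho g h` for the supplied gravity vector.
#' * `toy_loop` — three-compartment closed loop driven by a sinusoidal
#'   series source; the reference is a high-accuracy adaptive integration
#'   of the same ODEs (requires the `deSolve` package).
#'
#' @param kind fixture name
#' @return list with `circuit`, `state0` (initial `cc_state` builder taking
#'   an assembled system), `reference` (function of time returning the exact
#'   solution of the probed quantity), `probe` (name of the probed state
#'   column) and `info`
#' @export
make_fixture <- function(kind = c("rc_decay", "rlc_step", "static_column",
                                  "toy_loop")) {
  kind <- match.arg(kind)
  switch(kind,
    rc_decay = {
      circ <- circuit(list(
        el_capacitor("c", "n", 1),
        el_resistor("r", "n", "0", 1)
      ))
      list(circuit = circ,
           state0 = function(sys) circuit_state(sys, p = c(n = 1)),
           reference = function(t) exp(-t),
           probe = "n",
           info = "unit RC discharge from P(0) = 1")
    },
    rlc_step = {
      circ <- circuit(list(
        el_pressure_source("src", "s", 1),
        el_inductor("l", "s", "n", l = 1, r_series = 0.5),
        el_capacitor("c", "n", 1)
      ))
      zeta <- 0.25; wd <- sqrt(1 - zeta^2)
      list(circuit = circ,
           state0 = function(sys) circuit_state(sys),
           reference = function(t)
             1 - exp(-zeta * t) * (cos(wd * t) + zeta / wd * sin(wd * t)),
           probe = "n",
           info = "underdamped series RLC unit step response")
    },
    static_column = {
      rho <- 1.06; h <- 20
      circ <- circuit(list(
        el_pressure_source("top", "a", 0),
        el_resistor("col", "a", "b", 10, dsrc = rho * c(-h, 0)),
        el_capacitor("c", "b", 1e-3)
      ))
      list(circuit = circ,
           state0 = function(sys) circuit_state(sys),
           reference = function(t, g = c(-981, 0))
             rho * (-h) * g[1],   # steady P_b - P_a for gravity along -x
           probe = "b",
           info = "20 cm static column, bottom node b below fixed node a")
    },
    toy_loop = {
      r1 <- 1; r2 <- 2; l3 <- 0.5; rs <- 0.5
      c1 <- 0.8; c2 <- 1.2; c3 <- 0.6
      amp <- 1; om <- 2 * pi
      circ <- circuit(list(
        el_capacitor("c1", "n1", c1, v_unstressed = 1),
        el_capacitor("c2", "n2", c2, v_unstressed = 2),
        el_capacitor("c3", "n3", c3, v_unstressed = 3),
        el_resistor("r12", "n1", "n2", r1),
        el_resistor("r23", "n2", "n3", r2),
        el_inductor("l31", "n3", "n1", l = l3, r_series = rs,
                    dsrc = c(1, 0))   # unit coefficient: drive via g_fun
      ))
      deriv <- function(t, y, parms) {
        p1 <- y[1]; p2 <- y[2]; p3 <- y[3]; q <- y[4]
        src <- amp * sin(om * t)
        q12 <- (p1 - p2) / r1
        q23 <- (p2 - p3) / r2
        list(c((q - q12) / c1, (q12 - q23) / c2, (q23 - q) / c3,
               (p3 - p1 - rs * q + src) / l3))
      }
      list(circuit = circ,
           state0 = function(sys)
             circuit_state(sys, p = c(n1 = 1, n2 = 0.5, n3 = 0)),
           reference = function(times, y0 = c(1, 0.5, 0, 0)) {
             if (!requireNamespace("deSolve", quietly = TRUE))
               stop("the toy_loop reference requires the deSolve package")
             out <- deSolve::lsoda(y0, c(0, times), deriv, NULL,
                                   rtol = 1e-10, atol = 1e-12)
             out[-1, -1, drop = FALSE]
           },
           probe = c("n1", "n2", "n3"),
           source_fun = function(t) amp * sin(om * t),
           info = "3-compartment closed loop with sinusoidal drive on the inductive branch")
    }
  )
}
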