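# Wall properties, characteristic impedance, gravity and hydrostatics.

test_that("pulse wave velocity follows the printed empirical relation", {
  expect_equal(pulse_wave_velocity(0.5), 13.3)
  expect_equal(pulse_wave_velocity(1.0), 13.3 / 2^0.3, tolerance = 1e-12)
  expect_equal(pulse_wave_velocity(1.0), 10.803, tolerance = 1e-4)
  r <- seq(0.1, 3, by = 0.05)
  expect_true(all(diff(pulse_wave_velocity(r)) < 0))   # strictly decreasing
  expect_equal(pulse_wave_velocity(0.5, "cgs"), 1330)
  expect_error(pulse_wave_velocity(0), "> 0")
})

test_that("wall modulus reduces to 30 rho c^2 and is radius-independent at 10% thickness", {
  expect_equal(wall_modulus(1, 1, rho = 1), 30)
  radii <- c(0.05, 0.3, 1.7, 4)
  e <- wall_modulus(radii, c = 700, rho = 1.06)
  expect_true(all(abs(e - e[1]) < 1e-9 * e[1]))
  expect_equal(wall_modulus(1, 1, rho = 1, e_star = 1), 15)  # linear in E*
  # explicit thickness overrides the 10% rule
  expect_equal(wall_modulus(2, 1, rho = 1, zeta = 0.1), 2 * 3 * 2 / (2 * 0.1))
})

test_that("characteristic resistance is rho c / A", {
  expect_equal(characteristic_resistance(1, 100, rho = 1), 100)
  expect_equal(characteristic_resistance(0.5, 100, rho = 1),
               2 * characteristic_resistance(1, 100, rho = 1))
  # independently coded formula evaluation for a configured outlet
  a <- 2.31; cc <- 912.4; rho <- 1.06
  expect_equal(characteristic_resistance(a, cc, rho), rho * cc / a)
})

test_that("outlet radii invert the characteristic-impedance rule", {
  wk <- windkessel_defaults()
  for (i in seq_len(nrow(wk))) {
    r <- outlet_radius_from_r1(wk$r1[i])
    r1_back <- characteristic_resistance(pi * r^2,
                                         pulse_wave_velocity(r, "cgs"))
    expect_equal(r1_back, wk$r1[i], tolerance = 1e-6)
  }
  # descending aorta is the widest outlet, external carotids the narrowest
  expect_identical(which.max(wk$area), 1L)
})

test_that("gravity vector is the literal y-axis rotation of [0, 0, -g]", {
  expect_equal(gravity_vector(0), c(0, 0, -981))
  expect_equal(gravity_vector(pi / 2), c(981, 0, 0))
  for (th in seq(-pi, pi, by = 0.37)) {
    expect_equal(sqrt(sum(gravity_vector(th)^2)), 981)
  }
})

test_that("hydrostatic source is rho (g . delta_r)", {
  # aligned 20 cm column
  expect_equal(hydrostatic_source(c(20, 0), c(981, 0), rho = 1.06), 2.0797e4,
               tolerance = 1e-4)
  expect_equal(2.0797e4 / MMHG, 15.60, tolerance = 1e-3)
  # perpendicular
  expect_equal(hydrostatic_source(c(0, 20), c(981, 0), rho = 1.06), 0)
  # full 3-vector form
  expect_equal(hydrostatic_source(c(1, 2, 3), c(10, 20, 30), rho = 1),
               10 + 40 + 90)
})

test_that("a static no-flow column develops exactly the hydrostatic head", {
  fx <- make_fixture("static_column")
  sys <- assemble_system(fx$circuit, 1e-3)
  st <- fx$state0(sys)
  g_up <- c(-981, 0)    # upright: gravity along -x, node b 20 cm below a
  for (k in seq_len(5000)) st <- circuit_step(sys, st, g = g_up)
  p <- node_pressures(sys, st)
  expect_equal(p[["b"]] - p[["a"]], fx$reference(0, g_up), tolerance = 1e-9)
  expect_equal((p[["b"]] - p[["a"]]) / MMHG, 15.5995, tolerance = 1e-4)
  # supine: column lies in the plane perpendicular to gravity
  st2 <- fx$state0(sys)
  for (k in seq_len(5000)) st2 <- circuit_step(sys, st2, g = c(0, -981))
  p2 <- node_pressures(sys, st2)
  expect_equal(p2[["b"]] - p2[["a"]], 0, tolerance = 1e-9)
})

test_that("surrogate plus Windkessels reproduce an independent nodal-analysis steady state", {
  cfg <- default_config()
  model <- tilt_model(cfg)
  sys <- build_system(model, 1e-3)
  st <- structure(list(x = numeric(sys$n), time = 0), class = "cc_state")
  q <- 80
  for (k in seq_len(60000)) st <- circuit_step(sys, st, q = c(q, -q))
  p <- node_pressures(sys, st)

  # independent oracle: resistive network solved by plain nodal analysis
  geo <- model$geometry
  wk <- cfg$windkessel
  edges <- data.frame(from = geo$from, to = geo$to, r = geo$r_seg)
  out_node <- setNames(geo$to[!is.na(geo$outlet)], geo$outlet[!is.na(geo$outlet)])
  for (i in seq_len(nrow(wk))) {
    o <- wk$outlet[i]
    edges <- rbind(edges,
                   data.frame(from = out_node[[o]], to = paste0("wk_", o),
                              r = wk$r1[i]),
                   data.frame(from = paste0("wk_", o), to = "pa", r = wk$r2[i]))
  }
  edges <- rbind(edges,
                 data.frame(from = "pa", to = "pv1", r = cfg$distal$arterioles$r),
                 data.frame(from = "pv1", to = "pv2", r = cfg$distal$venules$r),
                 data.frame(from = "pv2", to = "la", r = cfg$distal$veins$r))
  nodes <- setdiff(unique(c(edges$from, edges$to)), "la")
  L <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  b <- setNames(numeric(length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    f <- edges$from[i]; t <- edges$to[i]; g <- 1 / edges$r[i]
    if (f %in% nodes) L[f, f] <- L[f, f] + g
    if (t %in% nodes) L[t, t] <- L[t, t] + g
    if (f %in% nodes && t %in% nodes) {
      L[f, t] <- L[f, t] - g; L[t, f] <- L[t, f] - g
    }
  }
  b["root"] <- q
  p_ref <- solve(L, b)    # pressures relative to the atrium
  got <- p[nodes] - p[["la"]]
  expect_equal(unname(got), unname(p_ref), tolerance = 1e-6)

  # mean drop across the surrogate is small compared to the Windkessel drops
  drop_surrogate <- p[["root"]] - p[["icar_r"]]
  drop_wk <- p[["icar_r"]] - p[["pa"]]
  expect_lt(drop_surrogate / drop_wk, 0.1)
})
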