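#' Build the closed-loop tilt model
#'
#' Assembles the full 0D closed loop from a configuration: the R-L-C
#' arterial surrogate (with hydrostatic sources on every segment), the
#' per-outlet three-element Windkessels, the arteriole/venule/vein chain and
#' the passive left atrium, all inside one linear circuit with two boundary
#' flow ports (aortic root inflow, mitral outflow from the atrium). The left
#' ventricle and both valves are solved monolithically against this circuit
#' through its boundary-flow response (see [simulate_run()]).
#'
#' @param config configuration from [default_config()]
#' @return a `tilt_model` list with the configuration, derived segment
#'   parameters, element templates and state-index maps
#' @export
tilt_model <- function(config = default_config()) {
  validate_config(config)
  geo <- segment_parameters(config$geometry, config$blood$rho, config$blood$mu)
  model <- structure(list(config = config, geometry = geo), class = "tilt_model")
  sys <- build_system(model, config$sim$dt)
  model$nodes <- sys$nodes
  model$pidx <- sys$pidx
  model$qidx <- sys$qidx
  model$i_root <- sys$pidx[["root"]]
  model$i_la <- sys$pidx[["la"]]
  model$i_pa <- sys$pidx[["pa"]]
  model$i_pv1 <- sys$pidx[["pv1"]]
  model$i_pv2 <- sys$pidx[["pv2"]]
  out_nodes <- geo$to[!is.na(geo$outlet)]
  names(out_nodes) <- geo$outlet[!is.na(geo$outlet)]
  model$outlet_nodes <- sys$pidx[out_nodes]
  names(model$outlet_nodes) <- names(out_nodes)
  carotid <- c("internal_carotid_r", "internal_carotid_l",
               "external_carotid_r", "external_carotid_l")
  model$carotid_sites <- model$outlet_nodes[carotid]
  model$upper_sites <- model$outlet_nodes[c(carotid, "subclavian_r",
                                            "subclavian_l")]
  term_seg <- paste0("seg_", geo$segment[!is.na(geo$outlet)])
  model$outlet_flow_idx <- sys$qidx[term_seg]
  names(model$outlet_flow_idx) <- geo$outlet[!is.na(geo$outlet)]
  model
}

#' @export
print.tilt_model <- function(x, ...) {
  cat("<tilt_model> closed-loop 0D circulation\n")
  cat("  ", nrow(x$geometry), " surrogate segments, ",
      nrow(x$config$windkessel), " Windkessel outlets\n", sep = "")
  cat("  nodes: ", length(x$nodes), ", state size: ",
      length(x$nodes) + length(x$qidx), "\n", sep = "")
  invisible(x)
}

# Assemble the cc_system for the current effective parameters.
# eff: list(r2 named by outlet, r_a, c_v1, c_v2, v_u_v1, v_u_v2); NULL -> baseline.
build_system <- function(model, dt, eff = NULL) {
  cfg <- model$config
  geo <- model$geometry
  rho <- cfg$blood$rho
  dd <- cfg$distal
  if (is.null(eff)) {
    eff <- list(r2 = stats::setNames(cfg$windkessel$r2, cfg$windkessel$outlet),
                r_a = dd$arterioles$r,
                c_v1 = dd$venules$c, c_v2 = dd$veins$c,
                v_u_v1 = dd$venules$v_u, v_u_v2 = dd$veins$v_u)
  }
  els <- list()
  add <- function(e) els[[length(els) + 1L]] <<- e
  for (i in seq_len(nrow(geo))) {
    g <- geo[i, ]
    add(el_inductor(paste0("seg_", g$segment), g$from, g$to,
                    l = g$l_seg, r_series = g$r_seg,
                    dsrc = rho * c(g$x_end - g$x_start, g$z_end - g$z_start)))
    add(el_capacitor(paste0("cseg_", g$segment), g$to,
                     g$c_seg * cfg$surrogate$c_scale))
  }
  wk <- cfg$windkessel
  out_node <- stats::setNames(geo$to[!is.na(geo$outlet)],
                              geo$outlet[!is.na(geo$outlet)])
  for (i in seq_len(nrow(wk))) {
    o <- wk$outlet[i]
    wknode <- paste0("wk_", o)
    add(el_resistor(paste0("r1_", o), out_node[[o]], wknode, wk$r1[i]))
    add(el_capacitor(paste0("cwk_", o), wknode, wk$c[i]))
    add(el_resistor(paste0("r2_", o), wknode, "pa", eff$r2[[o]]))
  }
  dg <- cfg$gravity$distal_gravity
  del <- cfg$gravity$distal_elevations
  dsrc_of <- function(which) if (isTRUE(dg)) rho * del[[which]] else NULL
  add(el_capacitor("c_art", "pa", dd$arterioles$c, dd$arterioles$v_u))
  add(el_resistor("r_art", "pa", "pv1", eff$r_a, dsrc = dsrc_of("arterioles")))
  add(el_capacitor("c_ven1", "pv1", eff$c_v1, eff$v_u_v1))
  add(el_resistor("r_ven1", "pv1", "pv2", dd$venules$r,
                  dsrc = dsrc_of("venules")))
  add(el_capacitor("c_ven2", "pv2", eff$c_v2, eff$v_u_v2))
  add(el_inductor("ven", "pv2", "la", l = dd$veins$l,
                  r_series = dd$veins$r, dsrc = dsrc_of("veins")))
  add(el_capacitor("c_la", "la", 1 / cfg$heart$e_la, cfg$heart$v_u_la))
  circ <- circuit(els, boundary = c("root", "la"))
  assemble_system(circ, dt)
}

#' Initial circuit and heart state
#'
#' Builds a plausible (not periodic) starting state from the configured
#' initial pressures and chamber volumes; [spin_up()] relaxes it to the
#' periodic supine limit cycle, removing sensitivity to these choices.
#'
#' @param model a [tilt_model()]
#' @param sys an assembled system for the model (defaults to baseline)
#' @return list with `x` (circuit state vector), `heart` (list `v_lv`,
#'   `q_av`, `q_mv`, `ao_open`, `mv_open`) and `time`
#' @export
initial_state <- function(model, sys = NULL) {
  cfg <- model$config
  if (is.null(sys)) sys <- build_system(model, cfg$sim$dt)
  x <- numeric(sys$n)
  arterial <- setdiff(sys$nodes, c("pa", "pv1", "pv2", "la"))
  x[sys$pidx[arterial]] <- cfg$init$p_arterial
  x[sys$pidx[["pa"]]] <- cfg$init$p_arteriole
  x[sys$pidx[["pv1"]]] <- cfg$init$p_venule
  x[sys$pidx[["pv2"]]] <- cfg$init$p_vein
  x[sys$pidx[["la"]]] <- atrial_pressure(cfg$init$v_la, cfg$heart)
  list(x = x,
       heart = list(v_lv = cfg$init$v_lv, q_av = 0, q_mv = 0,
                    ao_open = FALSE, mv_open = FALSE),
       time = 0)
}
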