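#' Default three-element Windkessel parameters of the arterial outlets
#'
#' Published per-outlet Windkessel triplets for the seven arterial outlets:
#' proximal (characteristic) resistance `r1`, compliance `c` and distal
#' resistance `r2`, in CGS units. `area` is the outlet area implied by the
#' characteristic-impedance rule (see [outlet_radius_from_r1()]); the flow
#' split of the tuning loop is proportional to these areas.
#'
#' @return data.frame with columns `outlet`, `r1`, `c`, `r2`, `area`
#' @export
windkessel_defaults <- function() {
  wk <- data.frame(
    outlet = c("desc_aorta", "subclavian_r", "subclavian_l",
               "internal_carotid_r", "internal_carotid_l",
               "external_carotid_r", "external_carotid_l"),
    r1 = c(1.052e2, 4.506e3, 4.922e3, 7.868e3, 8.481e3, 1.898e4, 1.739e4),
    c  = c(9.995e-4, 3.963e-5, 3.673e-5, 2.454e-5, 2.310e-5, 1.161e-5,
           1.251e-5),
    r2 = c(1.650e3, 4.162e4, 4.491e4, 6.722e4, 7.141e4, 1.421e5, 1.318e5),
    stringsAsFactors = FALSE
  )
  wk$area <- pi * vapply(wk$r1, outlet_radius_from_r1, numeric(1))^2
  wk
}

#' Default parameters of the arteriole, venule and venous compartments
#'
#' Published resistances, compliances, unstressed volumes (and the venous
#' inertance) of the shared distal chain that gathers all outlet flows and
#' returns them to the left atrium. CGS units.
#'
#' @return list with members `arterioles` (`r`, `c`, `v_u`), `venules`
#'   (`r`, `c`, `v_u`) and `veins` (`r`, `l`, `c`, `v_u`)
#' @export
distal_defaults <- function() {
  list(
    arterioles = list(r = 8.893e2, c = 1.400e-3, v_u = 4.010e2),
    venules    = list(r = 2.973e1, c = 9.900e-3, v_u = 5.960e2),
    veins      = list(r = 3.560e1, l = 6.670e-2, c = 5.540e-2, v_u = 1.938e3)
  )
}

#' One backward-Euler step of a three-element Windkessel outlet
#'
#' Standalone update of a single outlet: given the inflow `Q` at the new
#' time level and the arteriole pressure `P_a`, advances the
#' compliance-chamber pressure by
#' `C dP_c/dt = Q - (P_c - P_a)/R2` and reports the inlet pressure
#' `P = P_c + R1 Q`. The full model solves the same equations inside the
#' global circuit system; this form is used for unit testing and for
#' working with isolated outlets.
#'
#' @param outlet list with members `r1`, `r2`, `c` and state `p_c`
#'   (dyn cm^-2); e.g. one row of [windkessel_defaults()] plus `p_c`
#' @param q_in inflow at the new time level, cm^3 s^-1
#' @param p_a arteriole pressure at the new time level, dyn cm^-2
#' @param dt time step, s (> 0)
#' @return the outlet with updated `p_c` and the inlet pressure `p` set
#' @export
windkessel_step <- function(outlet, q_in, p_a, dt) {
  if (dt <= 0) stop("dt must be > 0")
  stopifnot(outlet$r1 > 0, outlet$r2 > 0, outlet$c > 0)
  pc0 <- outlet$p_c %||% 0
  pc <- (outlet$c / dt * pc0 + q_in + p_a / outlet$r2) /
        (outlet$c / dt + 1 / outlet$r2)
  outlet$p_c <- pc
  outlet$p <- pc + outlet$r1 * q_in
  outlet$q <- q_in
  outlet
}

#' Gather the outlet flows feeding the arterioles
#'
#' Arithmetic sum of the branch outflows, enforcing explicit continuity of
#' flow between the arterial outlets and the distal chain.
#'
#' @param flows numeric vector of outlet flows at a common time level,
#'   cm^3 s^-1 (must be non-empty)
#' @return total flow into the arterioles, cm^3 s^-1
#' @export
gather_outlet_flows <- function(flows) {
  if (length(flows) == 0L) stop("no outlet flows to gather")
  if (!is.numeric(flows)) stop("flows must be numeric")
  sum(flows)
}

#' One backward-Euler step of the arteriole-venule-vein chain
#'
#' Standalone update of the shared distal compartments: arterioles (series
#' resistance feeding a compliance with unstressed volume), venules
#' (likewise) and veins (compliance plus a resistive-inertial branch
#' returning flow to the left atrium at pressure `p_la`). Baseline venous
#' compliances and unstressed volumes are multiplied by the current
#' baroreflex scalings; arterial resistance control scales `R_a` only
#' (characteristic resistances are never scaled).
#'
#' @param comp list with members `p_a`, `p_v1`, `p_v2` (pressures,
#'   dyn cm^-2) and `q_ven` (venous flow, cm^3 s^-1)
#' @param q_in gathered arteriole inflow at the new time level, cm^3 s^-1
#' @param p_la left atrial pressure at the new time level, dyn cm^-2
#' @param dt time step, s
#' @param params distal parameters, default [distal_defaults()]
#' @param x_r,x_cv scalings of `R_a` and of both venous compliances (> 0)
#' @return updated compartment list
#' @export
distal_chain_step <- function(comp, q_in, p_la, dt,
                              params = distal_defaults(),
                              x_r = 1, x_cv = 1) {
  if (dt <= 0) stop("dt must be > 0")
  if (x_r <= 0 || x_cv <= 0) stop("control scalings must be > 0")
  ra <- params$arterioles$r * x_r
  ca <- params$arterioles$c
  rv1 <- params$venules$r
  cv1 <- params$venules$c * x_cv
  rv2 <- params$veins$r
  lv <- params$veins$l
  cv2 <- params$veins$c * x_cv
  # states: p_a, p_v1, p_v2, q_ven; implicit 4x4 solve
  A <- matrix(0, 4, 4)
  b <- numeric(4)
  A[1, ] <- c(ca / dt + 1 / ra, -1 / ra, 0, 0)
  b[1] <- ca / dt * comp$p_a + q_in
  A[2, ] <- c(-1 / ra, cv1 / dt + 1 / ra + 1 / rv1, -1 / rv1, 0)
  b[2] <- cv1 / dt * comp$p_v1
  A[3, ] <- c(0, -1 / rv1, cv2 / dt + 1 / rv1, 1)
  b[3] <- cv2 / dt * comp$p_v2
  A[4, ] <- c(0, 0, -1, lv / dt + rv2)
  b[4] <- lv / dt * comp$q_ven - p_la
  x <- solve(A, b)
  list(p_a = x[1], p_v1 = x[2], p_v2 = x[3], q_ven = x[4])
}
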