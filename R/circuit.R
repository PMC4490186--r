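#' Lumped-parameter circuit elements
#'
#' Constructors for the hydraulic circuit elements of the 0D model. All
#' values are CGS: resistances in dyn s cm^-5, compliances in cm^5 dyn^-1,
#' inertances in dyn s^2 cm^-5, pressures in dyn cm^-2. Node identifiers are
#' strings; `"0"` (or `"gnd"`) is ground (zero pressure reference).
#'
#' Resistive and inertial branches may carry a series pressure source made of
#' a constant part `src` and a gravity-dependent part `dsrc`, a length-2
#' coefficient vector such that the instantaneous source is
#' `src + dsrc[1]*g_x + dsrc[2]*g_z`. The model builder sets
#' `dsrc = rho * (delta_x, delta_z)` for a vessel segment so the source equals
#' the hydrostatic head `rho * (g . delta_r)` for any gravity vector.
#'
#' @param name unique element name
#' @param from,to node identifiers (flow is positive from `from` to `to`)
#' @param node node identifier for one-port elements
#' @param r resistance (> 0)
#' @param c compliance (> 0)
#' @param l inertance (> 0)
#' @param p fixed pressure value for a source node
#' @param v_unstressed unstressed volume of a capacitor (>= 0), cm^3
#' @param r_series series resistance of an inductive branch (>= 0)
#' @param src constant series pressure source, dyn cm^-2
#' @param dsrc length-2 gravity coefficients (see Details), or `NULL`
#' @param open initial state of a diode branch
#' @return an element object (list with class `cc_element`)
#' @seealso [circuit()], [assemble_system()]
#' @export
el_resistor <- function(name, from, to, r, src = 0, dsrc = NULL) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r))
  if (r <= 0) stop("resistor '", name, "': value must be > 0")
  .element(name, "resistor", from = from, to = to, value = r,
           src = src, dsrc = dsrc)
}

#' @rdname el_resistor
#' @export
el_capacitor <- function(name, node, c, v_unstressed = 0, to = "0") {
  stopifnot(is.numeric(c), length(c) == 1L, is.finite(c))
  if (c <= 0) stop("capacitor '", name, "': value must be > 0")
  if (v_unstressed < 0) stop("capacitor '", name, "': unstressed volume must be >= 0")
  .element(name, "capacitor", from = node, to = to, value = c,
           v_unstressed = v_unstressed)
}

#' @rdname el_resistor
#' @export
el_inductor <- function(name, from, to, l, r_series = 0, src = 0, dsrc = NULL) {
  stopifnot(is.numeric(l), length(l) == 1L, is.finite(l))
  if (l <= 0) stop("inductor '", name, "': value must be > 0")
  if (r_series < 0) stop("inductor '", name, "': series resistance must be >= 0")
  .element(name, "inductor", from = from, to = to, value = l,
           r_series = r_series, src = src, dsrc = dsrc)
}

#' @rdname el_resistor
#' @export
el_pressure_source <- function(name, node, p, dsrc = NULL) {
  .element(name, "pressure_source", from = node, to = "0", value = p,
           src = p, dsrc = dsrc)
}

#' @rdname el_resistor
#' @export
el_diode <- function(name, from, to, r, open = TRUE) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r))
  if (r <= 0) stop("diode '", name, "': series resistance must be > 0")
  .element(name, "diode", from = from, to = to, value = r, open = isTRUE(open))
}

.element <- function(name, kind, from, to, value, ...) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  el <- c(list(name = name, kind = kind,
               from = as.character(from), to = as.character(to),
               value = value), list(...))
  if (!is.null(el$dsrc)) stopifnot(is.numeric(el$dsrc), length(el$dsrc) == 2L)
  class(el) <- "cc_element"
  el
}

.is_ground <- function(node) node %in% c("0", "gnd", "ground")

#' Define a circuit topology
#'
#' Collects elements into a circuit, derives the node set and checks basic
#' consistency (unique element names, declared boundary nodes exist).
#'
#' @param elements list of elements built with [el_resistor()] and friends
#' @param boundary character vector of node names that receive external
#'   boundary flows (the `q` of [circuit_step()]), in order
#' @return a `cc_circuit` object
#' @export
circuit <- function(elements, boundary = character()) {
  stopifnot(is.list(elements), length(elements) > 0L)
  ok <- vapply(elements, inherits, logical(1), "cc_element")
  if (!all(ok)) stop("all elements must be built with the el_* constructors")
  nm <- vapply(elements, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate element names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  nodes <- unique(unlist(lapply(elements, function(e) c(e$from, e$to))))
  nodes <- nodes[!.is_ground(nodes)]
  if (!all(boundary %in% nodes)) {
    stop("boundary nodes not in topology: ",
         paste(setdiff(boundary, nodes), collapse = ", "))
  }
  names(elements) <- nm
  structure(list(elements = elements, nodes = nodes, boundary = boundary),
            class = "cc_circuit")
}

#' @export
print.cc_circuit <- function(x, ...) {
  kinds <- vapply(x$elements, `[[`, character(1), "kind")
  cat("<cc_circuit> ", length(x$nodes), " nodes, ",
      length(x$elements), " elements (",
      paste(sprintf("%s: %d", names(table(kinds)), table(kinds)), collapse = ", "),
      ")\n", sep = "")
  if (length(x$boundary)) cat("  boundary flow nodes:",
                              paste(x$boundary, collapse = ", "), "\n")
  invisible(x)
}

#' Assemble the backward-Euler system matrices of a circuit
#'
#' Discretizes every first-order element ODE with the backward Euler scheme
#' and collects the result into the algebraic system
#' `A x^{n+1} = B x^n + Cq q^{n+1} + D`, where the state `x` stacks node
#' pressures followed by inductor flows, `q` holds the external boundary
#' flows (positive into the node), and `D = D0 + Esrc %*% c(g_x, g_z)`
#' carries the constant and gravity-dependent pressure sources. `A` is
#' LU-factorized once per assembly (its inverse and the boundary-coupling
#' matrix `G = A^-1 Cq` are cached); closed diode branches are removed from
#' the topology so they carry exactly zero flow.
#'
#' @param circ a [circuit()]
#' @param dt time step in seconds (> 0)
#' @param diode_states named logical vector overriding the diode `open`
#'   states, or `NULL` to use the states stored in the elements
#' @return a `cc_system` list with members `A`, `Ainv`, `B`, `Cq`, `G`,
#'   `D0`, `Esrc`, index maps and the capacitor table
#' @export
assemble_system <- function(circ, dt, diode_states = NULL) {
  stopifnot(inherits(circ, "cc_circuit"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("dt must be a single positive number")
  }
  nodes <- circ$nodes
  np <- length(nodes)
  pidx <- stats::setNames(seq_len(np), nodes)
  ind <- Filter(function(e) e$kind == "inductor", circ$elements)
  nq <- length(ind)
  qidx <- if (nq) stats::setNames(np + seq_len(nq),
                                  vapply(ind, `[[`, character(1), "name"))
          else integer(0)
  n <- np + nq

  A <- matrix(0, n, n)
  B <- matrix(0, n, n)
  D0 <- numeric(n)
  Esrc <- matrix(0, n, 2L)
  fixed <- logical(n)           # rows replaced by pressure-source equations

  caps <- list()
  open_state <- logical(0)

  p_of <- function(node) if (.is_ground(node)) 0L else pidx[[node]]

  stamp_res <- function(a, b, r, src, dsrc) {
    ia <- p_of(a); ib <- p_of(b); gcond <- 1 / r
    if (ia) { A[ia, ia] <<- A[ia, ia] + gcond
              if (ib) A[ia, ib] <<- A[ia, ib] - gcond
              D0[ia] <<- D0[ia] - src * gcond
              if (!is.null(dsrc)) Esrc[ia, ] <<- Esrc[ia, ] - dsrc * gcond }
    if (ib) { A[ib, ib] <<- A[ib, ib] + gcond
              if (ia) A[ib, ia] <<- A[ib, ia] - gcond
              D0[ib] <<- D0[ib] + src * gcond
              if (!is.null(dsrc)) Esrc[ib, ] <<- Esrc[ib, ] + dsrc * gcond }
  }

  for (e in circ$elements) {
    switch(e$kind,
      resistor = stamp_res(e$from, e$to, e$value, e$src %||% 0, e$dsrc),
      diode = {
        open <- if (!is.null(diode_states) && e$name %in% names(diode_states))
          isTRUE(diode_states[[e$name]]) else isTRUE(e$open)
        open_state[e$name] <- open
        if (open) stamp_res(e$from, e$to, e$value, 0, NULL)
      },
      capacitor = {
        ia <- p_of(e$from); ib <- p_of(e$to)
        cd <- e$value / dt
        if (ia) { A[ia, ia] <- A[ia, ia] + cd; B[ia, ia] <- B[ia, ia] + cd
                  if (ib) { A[ia, ib] <- A[ia, ib] - cd; B[ia, ib] <- B[ia, ib] - cd } }
        if (ib) { A[ib, ib] <- A[ib, ib] + cd; B[ib, ib] <- B[ib, ib] + cd
                  if (ia) { A[ib, ia] <- A[ib, ia] - cd; B[ib, ia] <- B[ib, ia] - cd } }
        caps[[e$name]] <- list(name = e$name, ia = ia, ib = ib,
                               c = e$value, vu = e$v_unstressed)
      },
      inductor = {
        iq <- qidx[[e$name]]; ia <- p_of(e$from); ib <- p_of(e$to)
        A[iq, iq] <- e$value / dt + e$r_series
        B[iq, iq] <- e$value / dt
        if (ia) { A[iq, ia] <- -1; A[ia, iq] <- A[ia, iq] + 1 }
        if (ib) { A[iq, ib] <- 1;  A[ib, iq] <- A[ib, iq] - 1 }
        D0[iq] <- e$src %||% 0
        if (!is.null(e$dsrc)) Esrc[iq, ] <- e$dsrc
      },
      pressure_source = {
        ia <- p_of(e$from)
        if (!ia) stop("pressure source '", e$name, "' attached to ground")
        fixed[ia] <- TRUE
      },
      stop("unknown element kind: ", e$kind)
    )
  }

  # pressure-source rows replace the nodal balance
  for (e in circ$elements) {
    if (e$kind != "pressure_source") next
    ia <- pidx[[e$from]]
    A[ia, ] <- 0; B[ia, ] <- 0; Esrc[ia, ] <- 0
    A[ia, ia] <- 1
    D0[ia] <- e$src
    if (!is.null(e$dsrc)) Esrc[ia, ] <- e$dsrc
  }

  Cq <- matrix(0, n, length(circ$boundary))
  if (length(circ$boundary)) {
    for (j in seq_along(circ$boundary)) Cq[pidx[[circ$boundary[j]]], j] <- 1
  }

  Ainv <- tryCatch(solve(A), error = function(err) {
    bad <- nodes[rowSums(abs(A[seq_len(np), , drop = FALSE])) == 0]
    stop("singular system matrix",
         if (length(bad)) paste0(": node(s) with no path to ground: ",
                                 paste(bad, collapse = ", "))
         else paste0(" (", conditionMessage(err), ")"),
         call. = FALSE)
  })

  structure(list(A = A, Ainv = Ainv, B = B, Cq = Cq,
                 G = if (ncol(Cq)) Ainv %*% Cq else Cq,
                 D0 = D0, Esrc = Esrc,
                 n = n, np = np, nq = nq,
                 pidx = pidx, qidx = qidx, nodes = nodes,
                 caps = caps, diode_states = open_state,
                 boundary = circ$boundary, dt = dt),
            class = "cc_system")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Create a circuit state vector
#'
#' @param sys a `cc_system` from [assemble_system()]
#' @param p node pressures: a single number or a named vector (dyn cm^-2);
#'   unnamed nodes default to 0
#' @param q inductor flows, same conventions (cm^3 s^-1)
#' @param time simulation time, s
#' @return a `cc_state` list with the stacked state vector `x` and `time`
#' @export
circuit_state <- function(sys, p = 0, q = 0, time = 0) {
  stopifnot(inherits(sys, "cc_system"))
  x <- numeric(sys$n)
  if (length(p) == 1L && is.null(names(p))) {
    x[seq_len(sys$np)] <- p
  } else {
    stopifnot(all(names(p) %in% sys$nodes))
    x[sys$pidx[names(p)]] <- p
  }
  if (sys$nq) {
    if (length(q) == 1L && is.null(names(q))) {
      x[sys$np + seq_len(sys$nq)] <- q
    } else {
      stopifnot(all(names(q) %in% names(sys$qidx)))
      x[sys$qidx[names(q)]] <- q
    }
  }
  structure(list(x = x, time = time), class = "cc_state")
}

#' Advance a circuit state by one backward-Euler step
#'
#' Solves `A x^{n+1} = B x^n + Cq q^{n+1} + D(g)` using the cached
#' factorization of `A`. The factors are reused for every step taken with the
#' same `cc_system`; reassembly is only needed when a diode changes state or
#' an element value changes.
#'
#' @param sys a `cc_system`
#' @param state a `cc_state`
#' @param q external boundary flows at the new time level, one per declared
#'   boundary node (positive into the node)
#' @param g gravity vector components `c(g_x, g_z)` in cm s^-2 multiplying
#'   the elements' `dsrc` coefficients
#' @return the state at `time + dt`
#' @export
circuit_step <- function(sys, state, q = NULL, g = c(0, 0)) {
  stopifnot(inherits(sys, "cc_system"), inherits(state, "cc_state"))
  D <- sys$D0
  if (g[1] != 0 || g[2] != 0) D <- D + sys$Esrc %*% g
  rhs <- sys$B %*% state$x + D
  if (length(sys$boundary)) {
    if (is.null(q)) q <- numeric(length(sys$boundary))
    stopifnot(length(q) == length(sys$boundary))
    rhs <- rhs + sys$Cq %*% q
  }
  xn <- drop(sys$Ainv %*% rhs)
  if (!all(is.finite(xn))) {
    stop("numerical failure: non-finite circuit solution at t = ",
         format(state$time + sys$dt))
  }
  structure(list(x = xn, time = state$time + sys$dt), class = "cc_state")
}

#' Extract node pressures / inductor flows from a state
#'
#' @param sys a `cc_system`
#' @param state a `cc_state`
#' @return named numeric vector
#' @export
node_pressures <- function(sys, state) {
  stats::setNames(state$x[seq_len(sys$np)], sys$nodes)
}

#' @rdname node_pressures
#' @export
inductor_flows <- function(sys, state) {
  if (!sys$nq) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(state$x[sys$np + seq_len(sys$nq)], names(sys$qidx))
}

#' Capacitor volumes and total blood volume
#'
#' Every capacitor obeys `V = V_u + C * (transmural pressure)` at each
#' accepted step; `total_blood_volume` sums all capacitor volumes (stressed
#' plus unstressed) and any extra chamber volumes passed in (ventricle,
#' atrium when it is modelled outside the circuit). This is the conservation
#' audit of the closed loop: with no boundary flux the total is constant.
#'
#' @param sys a `cc_system`
#' @param state a `cc_state`
#' @param extra_volumes numeric vector of chamber volumes (cm^3) to add
#' @return named vector (`capacitor_volumes`) or single total (cm^3)
#' @export
capacitor_volumes <- function(sys, state) {
  vapply(sys$caps, function(cp) {
    pt <- (if (cp$ia) state$x[cp$ia] else 0) - (if (cp$ib) state$x[cp$ib] else 0)
    cp$vu + cp$c * pt
  }, numeric(1))
}

#' @rdname capacitor_volumes
#' @export
total_blood_volume <- function(sys, state, extra_volumes = 0) {
  sum(capacitor_volumes(sys, state)) + sum(extra_volumes)
}

#' Diode (valve) state machine
#'
#' A closed diode opens when the pressure upstream exceeds the pressure
#' downstream (negative gradient in the flow direction); an open diode closes
#' as soon as retrograde flow is detected, regardless of the pressure
#' gradient. Pure state machine: no errors are raised.
#'
#' @param circ a [circuit()] containing diode elements
#' @param sys the `cc_system` the last step was taken with
#' @param state the last accepted `cc_state`
#' @param open named logical vector of current diode states (defaults to the
#'   states stored in `sys`)
#' @return named logical vector of updated diode states, with attribute
#'   `"changed"` (logical scalar)
#' @export
update_valve_states <- function(circ, sys, state, open = NULL) {
  diodes <- Filter(function(e) e$kind == "diode", circ$elements)
  if (is.null(open)) open <- sys$diode_states
  changed <- FALSE
  for (e in diodes) {
    pu <- if (.is_ground(e$from)) 0 else state$x[sys$pidx[[e$from]]]
    pd <- if (.is_ground(e$to)) 0 else state$x[sys$pidx[[e$to]]]
    cur <- isTRUE(open[[e$name]])
    if (!cur) {
      if (pu > pd) { open[e$name] <- TRUE; changed <- TRUE }
    } else {
      flow <- (pu - pd) / e$value
      if (flow < 0) { open[e$name] <- FALSE; changed <- TRUE }
    }
  }
  attr(open, "changed") <- changed
  open
}

#' Run a generic circuit for a fixed duration
#'
#' Small reference driver used for fixtures and the generic-circuit tests:
#' steps the circuit with [circuit_step()], applies the diode state machine
#' after every accepted step, and reassembles the system matrices if and only
#' if a diode changed state (the reassembly count is reported).
#'
#' @param circ a [circuit()]
#' @param dt time step, s
#' @param t_end end time, s
#' @param state0 initial `cc_state` (default: all zeros)
#' @param q_fun `function(t)` returning boundary flows at time `t`, or `NULL`
#' @param g_fun `function(t)` returning `c(g_x, g_z)`, or `NULL`
#' @param record record every `record`-th step (0 = only final state)
#' @return list with `state` (final), `trace` (data.frame of recorded states),
#'   `reassemblies` and `valve_events` counts
#' @export
simulate_circuit <- function(circ, dt, t_end, state0 = NULL, q_fun = NULL,
                             g_fun = NULL, record = 1L) {
  sys <- assemble_system(circ, dt)
  state <- state0 %||% circuit_state(sys)
  n_steps <- round(t_end / dt)
  open <- sys$diode_states
  reassemblies <- 0L
  valve_events <- 0L
  rows <- if (record > 0) vector("list", ceiling(n_steps / record)) else NULL
  ri <- 0L
  for (k in seq_len(n_steps)) {
    tk <- state$time + dt
    q <- if (is.null(q_fun)) NULL else q_fun(tk)
    g <- if (is.null(g_fun)) c(0, 0) else g_fun(tk)
    state <- circuit_step(sys, state, q = q, g = g)
    if (length(open)) {
      newopen <- update_valve_states(circ, sys, state, open)
      if (attr(newopen, "changed")) {
        valve_events <- valve_events + 1L
        open <- newopen
        sys <- assemble_system(circ, dt, diode_states = open)
        reassemblies <- reassemblies + 1L
      }
    }
    if (record > 0 && k %% record == 0L) {
      ri <- ri + 1L
      rows[[ri]] <- c(time = state$time,
                      node_pressures(sys, state), inductor_flows(sys, state))
    }
  }
  trace <- if (!is.null(rows) && ri > 0L)
    as.data.frame(do.call(rbind, rows[seq_len(ri)])) else NULL
  list(state = state, sys = sys, trace = trace,
       reassemblies = reassemblies, valve_events = valve_events)
}
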