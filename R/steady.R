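# Nonlinear steady 0D forward model: Kirchhoff nodal analysis of the vascular
# graph with a Poiseuille + quadratic-stenosis constitutive law per segment,
# solved by damped Newton iteration on nodal pressures.

#' Blood properties
#'
#' @param density kg/m^3 (default 1060).
#' @param viscosity dynamic viscosity, Pa.s (default 0.0035).
#' @return object of class `blood_properties`.
#' @export
blood_properties <- function(density = 1060, viscosity = 0.0035) {
  if (density <= 0 || viscosity <= 0)
    fd_validation_error("blood density and viscosity must be > 0")
  structure(list(density = density, viscosity = viscosity),
            class = "blood_properties")
}

#' Steady-solver controls
#'
#' @param tol relative residual tolerance (max nodal mass imbalance over
#'   inlet flow).
#' @param max_iter Newton iteration cap.
#' @param damping Newton damping factor applied on the first `n_damped`
#'   iterations (stabilizes the quadratic stenosis term).
#' @param n_damped number of damped iterations.
#' @export
solver_control <- function(tol = 1e-10, max_iter = 100L, damping = 0.7,
                           n_damped = 5L) {
  if (tol <= 0 || max_iter < 1) fd_validation_error("invalid solver control")
  list(tol = tol, max_iter = max_iter, damping = damping, n_damped = n_damped)
}

#' Outlet boundary condition
#'
#' @param mode one of `"PRESCRIBED_FRACTION"` (value = fraction of inlet
#'   flow), `"RESISTANCE"` (value = resistance, mmHg.s/mL, pressure varies
#'   with flow against a venous reference), `"ZERO_PRESSURE"` (outlet held at
#'   the venous reference), `"WK3"` (value = [windkessel3()]; transient use).
#' @param value see `mode`.
#' @return object of class `outlet_bc`.
#' @export
outlet_bc <- function(mode, value = NULL) {
  mode <- match.arg(mode, c("PRESCRIBED_FRACTION", "RESISTANCE",
                            "ZERO_PRESSURE", "WK3"))
  if (mode == "PRESCRIBED_FRACTION" &&
      (!is.numeric(value) || value < 0 || value > 1))
    fd_validation_error("fraction must be in [0, 1]")
  if (mode == "RESISTANCE" && (!is.numeric(value) || value < 0))
    fd_validation_error("resistance must be >= 0")
  if (mode == "WK3" && !inherits(value, "windkessel3"))
    fd_validation_error("WK3 mode requires a windkessel3 value")
  structure(list(mode = mode, value = value), class = "outlet_bc")
}

#' Build per-outlet boundary-condition lists
#'
#' `fraction_bcs` turns named fractions (summing to 1) into
#' `PRESCRIBED_FRACTION` conditions; `resistance_bcs` turns named
#' resistances (mmHg.s/mL) into `RESISTANCE` conditions.
#'
#' @param fractions,resistances named numeric vectors keyed by branch.
#' @return named list of [outlet_bc()] objects.
#' @export
fraction_bcs <- function(fractions) {
  s <- sum(fractions)
  if (abs(s - 1) > 1e-9)
    fd_validation_error(sprintf("prescribed fractions sum to %.12f, not 1", s))
  lapply(fractions, function(f) outlet_bc("PRESCRIBED_FRACTION", f))
}
#' @rdname fraction_bcs
#' @export
resistance_bcs <- function(resistances) {
  lapply(resistances, function(r) outlet_bc("RESISTANCE", r))
}

# SI hydraulic coefficients per segment: dP = R*Q + K*Q|Q|  (Pa, m^3/s)
segment_coeffs <- function(seg, blood) {
  r_m <- seg$radius_cm * CM_M
  L_m <- seg$length_cm * CM_M
  R <- 8 * blood$viscosity * L_m / (pi * r_m^4)
  K <- numeric(nrow(seg))
  has <- !is.na(seg$sten_area_ratio)
  if (any(has)) {
    A0 <- pi * r_m[has]^2
    As <- seg$sten_area_ratio[has] * A0
    K[has] <- seg$sten_kt[has] * blood$density / (2 * As^2) *
      (A0 / As - 1)^2
  }
  list(R = R, K = K)
}

#' Pressure drop across a single segment
#'
#' Constitutive law of the 0D model: Poiseuille resistance plus, for
#' stenosed segments, a quadratic expansion-loss term
#' `Kt * rho/(2 As^2) * (A0/As - 1)^2 * Q|Q|` with `As = area_ratio * A0`.
#'
#' @param segment one-row segment data frame (or a list with the same
#'   fields).
#' @param Q flow, mL/s (signed).
#' @param blood a [blood_properties()].
#' @return pressure drop in mmHg, with `sign(dP) == sign(Q)`.
#' @export
segment_dP <- function(segment, Q, blood = blood_properties()) {
  seg <- as.data.frame(segment, stringsAsFactors = FALSE)
  co <- segment_coeffs(seg, blood)
  q <- mls_to_m3s(Q)
  Pa_to_mmHg(co$R * q + co$K * q * abs(q))
}

# flow through a segment given its SI pressure drop (inverts the law above)
flow_from_dP <- function(dP, R, K) {
  lin <- K == 0
  q <- numeric(length(dP))
  q[lin] <- dP[lin] / R[lin]
  if (any(!lin)) {
    a <- abs(dP[!lin])
    q[!lin] <- sign(dP[!lin]) *
      (-R[!lin] + sqrt(R[!lin]^2 + 4 * K[!lin] * a)) / (2 * K[!lin])
  }
  q
}

# internal: index bookkeeping shared by steady and transient solvers
network_matrices <- function(net, blood) {
  seg <- net$segments
  nodes <- sort(unique(c(seg$from, seg$to)))
  co <- segment_coeffs(seg, blood)
  list(nodes = nodes, n = length(nodes),
       ifrom = match(seg$from, nodes), ito = match(seg$to, nodes),
       R = co$R, K = co$K, seg_id = seg$id,
       i_inlet = match(net$inlet, nodes),
       i_outlet = match(net$outlets[names(net$outlets)], nodes),
       outlet_names = names(net$outlets))
}

# segment flows (SI) from nodal pressures (SI)
segment_flows_SI <- function(p, nm) {
  flow_from_dP(p[nm$ifrom] - p[nm$ito], nm$R, nm$K)
}

# nodal net inflow (SI) from segment flows: inflow at `to`, outflow at `from`
nodal_imbalance <- function(q, nm) {
  acc <- numeric(nm$n)
  rs <- rowsum(c(q, -q), c(nm$ito, nm$ifrom))
  acc[as.integer(rownames(rs))] <- rs[, 1L]
  acc
}

# dense Jacobian contribution of segment conductances g = dQ/d(dP)
assemble_jacobian <- function(g, nm) {
  J <- matrix(0, nm$n, nm$n)
  for (s in seq_along(g)) {
    a <- nm$ifrom[s]; b <- nm$ito[s]
    # net inflow at node a loses g*dp_a, gains g*dp_b
    J[a, a] <- J[a, a] - g[s]; J[a, b] <- J[a, b] + g[s]
    J[b, b] <- J[b, b] - g[s]; J[b, a] <- J[b, a] + g[s]
  }
  J
}

#' Steady solve of an aortic network
#'
#' Solves the nonlinear nodal system (mass conservation at every node with
#' the segment law of [segment_dP()]) by damped Newton iteration.
#'
#' Boundary handling: with `PRESCRIBED_FRACTION` outlet conditions the outlet
#' flows are fixed at `fraction * inlet_flow` and pressures are reported
#' relative to a datum chosen so the reported inlet pressure equals
#' `reference_pressure`; pressure differences are datum-independent. With
#' `RESISTANCE` conditions each outlet pressure floats as
#' `P_out = venous_pressure + R * Q`; `ZERO_PRESSURE` pins the outlet at the
#' venous reference.
#'
#' @param net an `aortic_network`.
#' @param inlet_flow inlet flow, mL/s (> 0).
#' @param outlet_bcs named list (by branch) of [outlet_bc()] objects, or the
#'   output of `fraction_bcs()` / `resistance_bcs()`.
#' @param blood a [blood_properties()].
#' @param control a [solver_control()].
#' @param reference_pressure inlet datum (mmHg) for prescribed-fraction
#'   solves.
#' @param venous_pressure distal reference pressure (mmHg) for resistance and
#'   zero-pressure outlets; default 0.
#' @return object of class `steady_result`: `node_pressure` (mmHg, named),
#'   `segment_flow` (mL/s, named), `P_in`, and per-branch `P_out`, `Q`, `dP`
#'   (`dP = P_in - P_out`), plus the inlet flow and Newton iteration count.
#' @export
solve_steady <- function(net, inlet_flow, outlet_bcs,
                         blood = blood_properties(),
                         control = solver_control(),
                         reference_pressure = 0, venous_pressure = 0) {
  stopifnot(inherits(net, "aortic_network"))
  if (!is.numeric(inlet_flow) || inlet_flow <= 0)
    fd_validation_error("inlet_flow must be > 0")
  if (!setequal(names(outlet_bcs), names(net$outlets)))
    fd_validation_error("outlet_bcs must name exactly the network's outlets")
  outlet_bcs <- outlet_bcs[names(net$outlets)]
  modes <- vapply(outlet_bcs, `[[`, "", "mode")
  if (any(modes == "WK3"))
    fd_validation_error("WK3 outlets are for solve_transient(); use RESISTANCE here")
  if (any(modes == "PRESCRIBED_FRACTION") && !all(modes == "PRESCRIBED_FRACTION"))
    fd_validation_error("PRESCRIBED_FRACTION cannot be mixed with other modes")

  nm <- network_matrices(net, blood)
  Qin <- mls_to_m3s(inlet_flow)
  p_ven <- mmHg_to_Pa(venous_pressure)

  if (all(modes == "PRESCRIBED_FRACTION")) {
    fr <- vapply(outlet_bcs, `[[`, 0, "value")
    if (abs(sum(fr) - 1) > 1e-9)
      fd_validation_error("prescribed fractions must sum to 1")
    source <- numeric(nm$n)
    source[nm$i_inlet] <- Qin
    source[nm$i_outlet] <- source[nm$i_outlet] - fr * Qin
    fixed <- nm$i_inlet            # datum
    p_fix <- mmHg_to_Pa(reference_pressure)
    res_R <- NULL
  } else {
    source <- numeric(nm$n)
    source[nm$i_inlet] <- Qin
    vals <- rep(NA_real_, length(modes))
    is_res <- modes == "RESISTANCE"
    vals[is_res] <- vapply(outlet_bcs[is_res], `[[`, 0, "value")
    zp <- modes == "ZERO_PRESSURE" | (is_res & !is.na(vals) & vals == 0)
    fixed <- nm$i_outlet[zp]
    p_fix <- p_ven
    res_R <- rep(NA_real_, nm$n)
    ridx <- is_res & !zp
    res_R[nm$i_outlet[ridx]] <- vals[ridx] * RES_SI
  }

  sol <- newton_nodal(nm, source, fixed, p_fix, res_R, p_ven, Qin, control)
  p <- sol$p; q <- segment_flows_SI(p, nm)

  node_pressure <- stats::setNames(Pa_to_mmHg(p), nm$nodes)
  segment_flow <- stats::setNames(m3s_to_mls(q), nm$seg_id)
  P_in <- node_pressure[[nm$i_inlet]]
  P_out <- stats::setNames(Pa_to_mmHg(p[nm$i_outlet]), nm$outlet_names)
  # branch flow = net flow into the outlet node
  imb <- nodal_imbalance(q, nm)
  Q_out <- stats::setNames(m3s_to_mls(imb[nm$i_outlet]), nm$outlet_names)
  if (all(modes == "PRESCRIBED_FRACTION"))
    Q_out <- stats::setNames(fr * inlet_flow, nm$outlet_names)

  structure(list(node_pressure = node_pressure, segment_flow = segment_flow,
                 P_in = P_in, P_out = P_out, Q = Q_out, dP = P_in - P_out,
                 inlet_flow = inlet_flow, n_iter = sol$iter,
                 residual = sol$res),
            class = "steady_result")
}

# damped Newton on nodal pressures (SI). `fixed` nodes are Dirichlet at
# p_fix; nodes with finite res_R leak (p - p_ven)/res_R to the venous bed.
newton_nodal <- function(nm, source, fixed, p_fix, res_R, p_ven, Qin,
                         control) {
  free <- setdiff(seq_len(nm$n), fixed)
  leak <- if (is.null(res_R)) rep(FALSE, nm$n) else is.finite(res_R)

  residual <- function(p) {
    q <- segment_flows_SI(p, nm)
    F <- nodal_imbalance(q, nm) + source
    F[leak] <- F[leak] - (p[leak] - p_ven) / res_R[leak]
    F
  }

  # initial guess: linearized (pure Poiseuille) solve
  p <- rep(p_fix, nm$n)
  glin <- 1 / nm$R
  J <- assemble_jacobian(glin, nm)
  if (any(leak)) J[cbind(which(leak), which(leak))] <-
      J[cbind(which(leak), which(leak))] - 1 / res_R[leak]
  rhs <- -residual(p)
  p[free] <- p[free] + solve(J[free, free, drop = FALSE], rhs[free])

  for (it in seq_len(control$max_iter)) {
    q <- segment_flows_SI(p, nm)
    F <- residual(p)
    res <- max(abs(F[free])) / Qin
    if (res <= control$tol)
      return(list(p = p, iter = it - 1L, res = res))
    g <- 1 / (nm$R + 2 * nm$K * abs(q))
    J <- assemble_jacobian(g, nm)
    if (any(leak)) J[cbind(which(leak), which(leak))] <-
        J[cbind(which(leak), which(leak))] - 1 / res_R[leak]
    step <- tryCatch(solve(J[free, free, drop = FALSE], -F[free]),
                     error = function(e) fd_convergence_error(
                       sprintf("singular nodal system: %s", conditionMessage(e))))
    lam <- if (it <= control$n_damped) control$damping else 1
    p[free] <- p[free] + lam * step
  }
  fd_convergence_error(
    sprintf("steady solver did not converge in %d iterations (residual %.3e)",
            control$max_iter, res),
    residual = res)
}

#' Zero-pressure-outlet solve
#'
#' Steady solve with every outlet pinned at the venous reference pressure,
#' the flow split then being dictated purely by geometric resistance. Used as
#' a comparison mode: such splits are known to grossly favour the low
#' resistance supra-aortic branches.
#'
#' @inheritParams solve_steady
#' @return list with elements `result` (a `steady_result`) and `division`
#'   (named fractions `Q_i / inlet_flow`).
#' @export
solve_zero_pressure <- function(net, inlet_flow, blood = blood_properties(),
                                control = solver_control(),
                                venous_pressure = 0) {
  bcs <- lapply(net$outlets, function(n) outlet_bc("ZERO_PRESSURE"))
  res <- solve_steady(net, inlet_flow, bcs, blood, control,
                      venous_pressure = venous_pressure)
  division <- res$Q / inlet_flow
  list(result = res, division = flow_division(division))
}

#' @export
print.steady_result <- function(x, ...) {
  cat(sprintf("steady_result: P_in = %.3f mmHg, inlet flow = %.3f mL/s (%d Newton iters)\n",
              x$P_in, x$inlet_flow, x$n_iter))
  print(data.frame(branch = names(x$Q), Q_mL_s = unname(x$Q),
                   P_out_mmHg = unname(x$P_out), dP_mmHg = unname(x$dP)))
  invisible(x)
}
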