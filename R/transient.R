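# Time-resolved 0D simulation: inlet waveforms and the backward-Euler
# transient solver with three-element Windkessel outlets coupled
# monolithically to the nodal system.

#' Inlet flow waveform
#'
#' @param time sample times, s; strictly increasing, `time[1] = 0` and
#'   `time[length(time)]` equal to the period.
#' @param flow flow samples, mL/s.
#' @param period cardiac period T, s (default `max(time)`).
#' @return object of class `inlet_waveform`.
#' @export
inlet_waveform <- function(time, flow, period = max(time)) {
  if (length(time) != length(flow) || length(time) < 2L)
    fd_validation_error("waveform needs matching time/flow vectors (>= 2 samples)")
  if (time[1L] != 0 || any(diff(time) <= 0))
    fd_validation_error("waveform time must start at 0 and increase strictly")
  if (!isTRUE(all.equal(time[length(time)], period)))
    fd_validation_error("waveform must span exactly one period")
  if (any(!is.finite(flow)))
    fd_validation_error("waveform flow must be finite")
  structure(list(time = time, flow = flow, period = period),
            class = "inlet_waveform")
}

as_inlet_waveform <- function(x) {
  if (inherits(x, "inlet_waveform")) return(x)
  if (is.data.frame(x) && all(c("time_s", "flow_mL_s") %in% names(x)))
    return(inlet_waveform(x$time_s, x$flow_mL_s))
  if (is.data.frame(x) && ncol(x) >= 2L)
    return(inlet_waveform(x[[1L]], x[[2L]]))
  fd_validation_error("cannot interpret object as an inlet waveform")
}

#' Template aortic inflow waveform
#'
#' A documented piecewise-analytic pulse standing in for literature aortic
#' waveforms: a half-sine systolic ejection over the first third of the
#' cycle, a short reverse-flow notch at valve closure, and zero diastolic
#' flow. Defaults give a cycle-mean flow of about 83 mL/s (~5 L/min).
#'
#' @param period cycle length, s.
#' @param peak_flow systolic peak, mL/s.
#' @param systole_frac fraction of the cycle occupied by forward ejection.
#' @param notch_frac fraction of the cycle occupied by the reverse notch.
#' @param notch_depth reverse peak as a fraction of `peak_flow`.
#' @param n_samples number of samples over the cycle.
#' @return an [inlet_waveform()].
#' @export
template_waveform <- function(period = 1, peak_flow = 400,
                              systole_frac = 1 / 3, notch_frac = 0.05,
                              notch_depth = 0.08, n_samples = 201L) {
  if (period <= 0 || peak_flow <= 0) fd_validation_error("invalid waveform parameters")
  t <- seq(0, period, length.out = n_samples)
  ts <- systole_frac * period
  tn <- notch_frac * period
  q <- ifelse(t <= ts, peak_flow * sin(pi * t / ts),
       ifelse(t <= ts + tn,
              -notch_depth * peak_flow * sin(pi * (t - ts) / tn), 0))
  inlet_waveform(t, q, period)
}

#' Scale a template waveform to a patient
#'
#' Rescales the time axis to the patient's heart rate (`T = 60 / HR`) and,
#' when a target cardiac output is given, rescales the amplitude so the
#' cycle-mean flow matches it.
#'
#' @param template an [inlet_waveform()].
#' @param heart_rate beats per minute (> 0).
#' @param cardiac_output target cycle-mean flow, mL/s, or `NULL` to keep the
#'   template amplitude.
#' @return an [inlet_waveform()].
#' @export
scale_waveform <- function(template, heart_rate, cardiac_output = NULL) {
  wf <- as_inlet_waveform(template)
  if (!is.numeric(heart_rate) || heart_rate <= 0)
    fd_validation_error("heart_rate must be > 0")
  T_new <- 60 / heart_rate
  t <- wf$time * T_new / wf$period
  q <- wf$flow
  if (!is.null(cardiac_output)) {
    m <- trapz_int(t, q) / T_new
    if (m == 0) fd_validation_error("template has zero mean flow; cannot scale")
    q <- q * cardiac_output / m
  }
  inlet_waveform(t, q, T_new)
}

# periodic linear interpolation of the waveform at arbitrary times
waveform_at <- function(wf, times) {
  ph <- times %% wf$period
  stats::approx(wf$time, wf$flow, xout = ph, rule = 2)$y
}

#' Transient solve with Windkessel outlets
#'
#' Backward-Euler time integration of the nonlinear nodal system. At each
#' step the nodal pressures and the Windkessel capacitor pressures are
#' solved simultaneously: outlet flow obeys `Q_i = (P_out,i - P_c,i) / R_c,i`
#' and the capacitor update is
#' `C_i (P_c^{n+1} - P_c^n) / dt = Q_i^{n+1} - P_c^{n+1} / R_p,i`.
#' Capacitor pressures are initialized from a steady solve at the cycle-mean
#' inflow with equivalent resistances `R_c + R_p`, so simulations start near
#' the periodic regime.
#'
#' @param net an `aortic_network`.
#' @param waveform an [inlet_waveform()].
#' @param wk3_map named list (by branch) of [windkessel3()] objects covering
#'   every outlet.
#' @param n_steps_per_cycle time steps per cardiac cycle (default 1000).
#' @param n_cycles number of cycles to run (default 5; analyses conventionally
#'   use the final cycle).
#' @param blood a [blood_properties()].
#' @param control a [solver_control()] for the per-step Newton solve.
#' @return object of class `transient_result`: `times` (s), `inlet_pressure`
#'   (mmHg), `node_pressure` (steps x nodes, mmHg), `segment_flow`
#'   (steps x segments, mL/s), `capacitor_pressure` (steps x outlets, mmHg),
#'   `inlet_flow` (mL/s), plus the waveform and step bookkeeping.
#' @export
solve_transient <- function(net, waveform, wk3_map,
                            n_steps_per_cycle = 1000L, n_cycles = 5L,
                            blood = blood_properties(),
                            control = solver_control()) {
  stopifnot(inherits(net, "aortic_network"))
  wf <- as_inlet_waveform(waveform)
  if (!setequal(names(wk3_map), names(net$outlets)))
    fd_validation_error("wk3_map must cover exactly the network outlets")
  if (!all(vapply(wk3_map, inherits, TRUE, "windkessel3")))
    fd_validation_error("wk3_map entries must be windkessel3 objects")
  if (n_steps_per_cycle < 2L || n_cycles < 1L)
    fd_validation_error("need n_steps_per_cycle >= 2 and n_cycles >= 1")

  nm <- network_matrices(net, blood)
  ob <- names(net$outlets)
  Rc <- vapply(wk3_map[ob], `[[`, 0, "R_c") * RES_SI
  Rp <- vapply(wk3_map[ob], `[[`, 0, "R_p") * RES_SI
  Cc <- vapply(wk3_map[ob], `[[`, 0, "C") * ML_M3 / MMHG_PA   # m^3/Pa
  if (any(Rc <= 0))
    fd_validation_error("transient coupling requires R_c > 0 at every outlet")

  dt <- wf$period / n_steps_per_cycle
  n_steps <- n_steps_per_cycle * n_cycles
  n_out <- length(ob)

  # initial state: steady solve at cycle-mean inflow with R_c + R_p outlets
  Q_mean <- trapz_int(wf$time, wf$flow) / wf$period
  if (Q_mean <= 0) Q_mean <- max(wf$flow) / pi  # fallback for odd templates
  st <- solve_steady(net, Q_mean,
                     resistance_bcs(stats::setNames((Rc + Rp) / RES_SI, ob)),
                     blood = blood, control = control)
  p <- mmHg_to_Pa(st$node_pressure[nm$nodes])
  pc <- mls_to_m3s(st$Q[ob]) * Rp   # steady capacitor state: P_c = Q_i * R_p

  io <- nm$i_outlet   # node index of each outlet
  n_tot <- nm$n + n_out
  times <- seq_len(n_steps) * dt
  P_node <- matrix(NA_real_, n_steps, nm$n, dimnames = list(NULL, nm$nodes))
  Q_seg <- matrix(NA_real_, n_steps, length(nm$R), dimnames = list(NULL, nm$seg_id))
  P_cap <- matrix(NA_real_, n_steps, n_out, dimnames = list(NULL, ob))
  Q_in_series <- waveform_at(wf, times)

  x <- c(p, pc)
  for (step in seq_len(n_steps)) {
    Qin <- mls_to_m3s(Q_in_series[step])
    pc_old <- x[nm$n + seq_len(n_out)]
    scale <- max(abs(Qin), mls_to_m3s(Q_mean))

    conv <- FALSE
    for (it in seq_len(control$max_iter)) {
      pn <- x[seq_len(nm$n)]; pcn <- x[nm$n + seq_len(n_out)]
      q <- segment_flows_SI(pn, nm)
      F <- numeric(n_tot)
      F[seq_len(nm$n)] <- nodal_imbalance(q, nm)
      F[nm$i_inlet] <- F[nm$i_inlet] + Qin
      qo <- (pn[io] - pcn) / Rc
      F[io] <- F[io] - qo
      F[nm$n + seq_len(n_out)] <- qo - pcn / Rp - Cc * (pcn - pc_old) / dt

      if (max(abs(F)) / scale <= control$tol) { conv <- TRUE; break }

      g <- 1 / (nm$R + 2 * nm$K * abs(q))
      J <- matrix(0, n_tot, n_tot)
      J[seq_len(nm$n), seq_len(nm$n)] <- assemble_jacobian(g, nm)
      for (k in seq_len(n_out)) {
        i <- io[k]; j <- nm$n + k
        J[i, i] <- J[i, i] - 1 / Rc[k]
        J[i, j] <- J[i, j] + 1 / Rc[k]
        J[j, i] <- J[j, i] + 1 / Rc[k]
        J[j, j] <- J[j, j] - 1 / Rc[k] - 1 / Rp[k] - Cc[k] / dt
      }
      step_x <- tryCatch(solve(J, -F), error = function(e)
        fd_convergence_error(sprintf("singular transient system at step %d", step)))
      x <- x + step_x
    }
    if (!conv)
      fd_convergence_error(sprintf(
        "transient Newton failed to converge at step %d (t = %.4f s)",
        step, times[step]), step = step)

    P_node[step, ] <- Pa_to_mmHg(x[seq_len(nm$n)])
    Q_seg[step, ] <- m3s_to_mls(segment_flows_SI(x[seq_len(nm$n)], nm))
    P_cap[step, ] <- Pa_to_mmHg(x[nm$n + seq_len(n_out)])
  }

  structure(list(times = times, inlet_pressure = P_node[, nm$i_inlet],
                 node_pressure = P_node, segment_flow = Q_seg,
                 capacitor_pressure = P_cap, inlet_flow = Q_in_series,
                 cycles_run = n_cycles, n_steps_per_cycle = n_steps_per_cycle,
                 period = wf$period, waveform = wf,
                 inlet_node = nm$nodes[nm$i_inlet],
                 outlet_names = ob, outlet_nodes = nm$nodes[io]),
            class = "transient_result")
}

#' Cycle-to-cycle periodicity of a transient run
#'
#' Maximum phase-wise change of inlet pressure between the final two cycles,
#' relative to the mean inlet pressure of the final cycle. Small values
#' justify analysing only the last cycle.
#'
#' @param result a `transient_result` with at least 2 cycles.
#' @return non-negative scalar.
#' @export
periodicity <- function(result) {
  stopifnot(inherits(result, "transient_result"))
  if (result$cycles_run < 2L)
    fd_validation_error("periodicity needs at least 2 cycles")
  ns <- result$n_steps_per_cycle
  last <- result$inlet_pressure[(result$cycles_run - 1L) * ns + seq_len(ns)]
  prev <- result$inlet_pressure[(result$cycles_run - 2L) * ns + seq_len(ns)]
  max(abs(last - prev)) / abs(mean(last))
}

# rows of the final cycle in a transient_result
final_cycle_rows <- function(result) {
  ns <- result$n_steps_per_cycle
  (result$cycles_run - 1L) * ns + seq_len(ns)
}

#' @export
print.transient_result <- function(x, ...) {
  cat(sprintf(
    "transient_result: %d cycles x %d steps (T = %.3f s), %d nodes, %d segments\n",
    x$cycles_run, x$n_steps_per_cycle, x$period, ncol(x$node_pressure),
    ncol(x$segment_flow)))
  rows <- final_cycle_rows(x)
  cat(sprintf("  final-cycle inlet pressure: %.2f / %.2f / %.2f mmHg (min/mean/max)\n",
              min(x$inlet_pressure[rows]), mean(x$inlet_pressure[rows]),
              max(x$inlet_pressure[rows])))
  invisible(x)
}
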