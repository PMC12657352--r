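# Flow-division estimation: empirical healthy-subject division rules,
# brachial-to-aortic pressure conversion, outlet-resistance conversion, the
# iterative estimation loop, Windkessel tuning, and method comparison.

#' Flow-division container
#'
#' @param fractions named numeric vector (branch -> fraction of cardiac
#'   output); must be non-negative and sum to 1 within 1e-9.
#' @return object of class `flow_division`.
#' @export
flow_division <- function(fractions) {
  if (is.list(fractions)) fractions <- unlist(fractions)
  if (is.null(names(fractions)) || anyDuplicated(names(fractions)))
    fd_validation_error("fractions must be uniquely named by branch")
  if (any(fractions < 0))
    fd_validation_error("fractions must be >= 0")
  if (abs(sum(fractions) - 1) > 1e-9)
    fd_validation_error(sprintf("fractions sum to %.12f, not 1", sum(fractions)))
  structure(fractions, class = "flow_division")
}

#' @export
print.flow_division <- function(x, ...) {
  cat("flow_division (% of cardiac output):\n")
  print(round_half_up(100 * unclass(x), 1))
  invisible(x)
}

#' Empirical healthy-subject flow division
#'
#' Classical healthy-adult allocation of cardiac output across aortic
#' branches: 30\% to the supra-aortic branches, distributed among
#' brachiocephalic trunk, left common carotid, and left subclavian in
#' proportion to their cross-sectional areas; 15.5\% to the celiac trunk;
#' 10.5\% each to the superior mesenteric and the two renal arteries; 0.5\%
#' to the inferior mesenteric artery when present; the remainder split
#' equally between left and right iliac systems, with 70\% of each side's
#' share to the external and 30\% to the internal iliac artery.
#'
#' @param net an `aortic_network` with the canonical branch names;
#'   `branch_inlet_area` must be available for the supra-aortic branches.
#' @return a [flow_division()].
#' @export
empirical_division <- function(net) {
  stopifnot(inherits(net, "aortic_network"))
  present <- names(net$outlets)
  mandatory <- setdiff(BRANCH_NAMES, "IMA")
  if (!all(mandatory %in% present))
    fd_validation_error(sprintf("missing mandatory branch(es): %s",
      paste(setdiff(mandatory, present), collapse = ", ")))
  areas <- net$branch_inlet_area[SUPRA_AORTIC]
  if (any(is.na(areas)) || any(areas <= 0))
    fd_validation_error("supra-aortic branch inlet areas unavailable")

  f <- stats::setNames(numeric(length(present)), present)
  f[SUPRA_AORTIC] <- 0.30 * areas / sum(areas)
  f["CT"] <- 0.155
  f[c("SMA", "LRA", "RRA")] <- 0.105
  ima <- "IMA" %in% present
  if (ima) f["IMA"] <- 0.005
  rest <- 1 - 0.30 - 0.155 - 3 * 0.105 - if (ima) 0.005 else 0
  per_side <- rest / 2
  f[c("LEIA", "REIA")] <- 0.70 * per_side
  f[c("LIIA", "RIIA")] <- 0.30 * per_side
  flow_division(f)
}

#' Pressure targets from brachial cuff readings
#'
#' Converts brachial systolic/diastolic pressure to aortic values with the
#' empirical transfer formulas
#' `P_sys_ao = 0.83 P_sys_bra + 0.15 P_dia_bra`, `P_dia_ao = P_dia_bra`,
#' and `P_mean_ao = 0.4 P_sys_ao + 0.6 P_dia_ao`.
#'
#' @param P_sys_bra brachial systolic pressure, mmHg.
#' @param P_dia_bra brachial diastolic pressure, mmHg (must be below
#'   systolic and positive).
#' @return object of class `pressure_targets` with fields `P_sys_bra`,
#'   `P_dia_bra`, `P_sys_ao`, `P_dia_ao`, `P_mean_ao` (all mmHg).
#' @export
brachial_to_aortic <- function(P_sys_bra, P_dia_bra) {
  if (!is.numeric(P_sys_bra) || !is.numeric(P_dia_bra) ||
      !(P_sys_bra > P_dia_bra) || !(P_dia_bra > 0))
    fd_validation_error("require P_sys_bra > P_dia_bra > 0")
  P_sys_ao <- 0.83 * P_sys_bra + 0.15 * P_dia_bra
  P_dia_ao <- P_dia_bra
  structure(list(P_sys_bra = P_sys_bra, P_dia_bra = P_dia_bra,
                 P_sys_ao = P_sys_ao, P_dia_ao = P_dia_ao,
                 P_mean_ao = 0.4 * P_sys_ao + 0.6 * P_dia_ao),
            class = "pressure_targets")
}

#' Mean systolic inlet flow of a waveform
#'
#' The systolic interval is `[0, t_end_sys]`, where `t_end_sys` defaults to
#' the first post-peak zero crossing of the flow (linearly interpolated), or
#' the time of the global minimum when the flow never crosses zero. The mean
#' is the trapezoidal integral over that interval divided by its duration.
#'
#' @param waveform an [inlet_waveform()].
#' @param t_end_sys optional explicit end of systole, s.
#' @return mean systolic flow, mL/s.
#' @export
mean_systolic_flow <- function(waveform, t_end_sys = NULL) {
  wf <- as_inlet_waveform(waveform)
  t <- wf$time; q <- wf$flow
  if (all(q == 0)) fd_validation_error("all-zero waveform: no systole detectable")
  if (is.null(t_end_sys)) {
    ipk <- which.max(q)
    post <- seq(ipk, length(q))
    neg <- post[which(q[post] <= 0)[1L]]
    if (!is.na(neg) && neg > ipk) {
      i0 <- neg - 1L
      # linear interpolation of the crossing time
      t_end_sys <- t[i0] + (t[neg] - t[i0]) * q[i0] / (q[i0] - q[neg])
    } else {
      imin <- post[which.min(q[post])]
      # flat or monotone waveforms have no deceleration minimum distinct
      # from the peak: treat the whole cycle as the averaging window
      t_end_sys <- if (imin == ipk) max(t) else t[imin]
    }
  }
  if (t_end_sys <= 0 || t_end_sys > max(t))
    fd_validation_error("t_end_sys outside the waveform period")
  keep <- t < t_end_sys
  tt <- c(t[keep], t_end_sys)
  qq <- c(q[keep], stats::approx(t, q, xout = t_end_sys)$y)
  trapz_int(tt, qq) / t_end_sys
}

#' Convert reference-model pressures into outlet resistances
#'
#' Given a steady solve of the reference model, the resistance of branch i
#' is `R_i = (P_mean - dP_i) / Q_i`, with `dP_i = P_in - P_out,i` the
#' geometric pressure drop from the aortic inlet to that branch outlet. The
#' venous-side reference pressure is taken as 0 mmHg.
#'
#' @param ref_result a `steady_result` for the reference geometry.
#' @param P_mean mean aortic pressure used in the conversion, mmHg.
#' @return named numeric vector of resistances, mmHg.s/mL.
#' @export
outlet_resistances <- function(ref_result, P_mean) {
  stopifnot(inherits(ref_result, "steady_result"))
  if (any(ref_result$Q <= 0))
    fd_validation_error("all reference branch flows must be > 0")
  R <- (P_mean - ref_result$dP) / ref_result$Q
  if (any(R <= 0))
    # an unreachable target pressure: the loop cannot converge from here
    stop(errorCondition(sprintf(
      "negative outlet resistance for %s: P_mean = %.3f mmHg is below the geometric drop",
      paste(names(R)[R <= 0], collapse = ", "), P_mean),
      branches = names(R)[R <= 0],
      class = c("fd_negative_resistance_error", "fd_convergence_error",
                "fd_error")))
  R
}

#' Iteratively estimate flow division in a diseased aorta
#'
#' The central estimation loop. One steady solve of the repaired reference
#' geometry under the empirical healthy division fixes the geometric drops
#' `dP_i` and flows `Q_i`. Starting from the target mean aortic pressure,
#' each iteration converts `(P_mean, dP_i, Q_i)` into outlet resistances,
#' solves the diseased geometry under those resistances at the same inlet
#' flow, and compares the predicted inlet pressure with the target. If the
#' relative discrepancy exceeds the threshold, `P_mean` receives the additive
#' update `P_mean + omega * (target - predicted)` and the diseased solve is
#' repeated. At convergence the diseased branch flows divided by the inlet
#' flow are the estimated division.
#'
#' @param reference repaired (near-healthy) `aortic_network`.
#' @param diseased diseased `aortic_network` sharing the branch names.
#' @param targets a [brachial_to_aortic()] result (or compatible list with
#'   `P_mean_ao`).
#' @param waveform inlet flow waveform; its mean systolic flow is the steady
#'   inflow.
#' @param config a [fd_config()]; uses `omega`, `threshold`, `max_iter`,
#'   `blood`, `venous_pressure`, solver controls.
#' @return list with `division` (a [flow_division()]), `trace` (class
#'   `iteration_trace`: per-iteration `P_mean`, `P_pred`, `discrepancy`,
#'   plus `converged` and `n_iter`), `resistances` (mmHg.s/mL), and the
#'   final diseased `steady_result`.
#' @export
estimate_division <- function(reference, diseased, targets, waveform,
                              config = fd_config()) {
  stopifnot(inherits(reference, "aortic_network"),
            inherits(diseased, "aortic_network"))
  if (!setequal(names(reference$outlets), names(diseased$outlets)))
    fd_validation_error("reference and diseased must share branch names")
  target <- targets$P_mean_ao
  if (!is.numeric(target) || target <= 0)
    fd_validation_error("invalid pressure target")

  Q_in <- mean_systolic_flow(waveform)
  emp <- empirical_division(reference)
  ref_res <- solve_steady(reference, Q_in, fraction_bcs(unclass(emp)),
                          blood = config$blood, control = config$control)

  P_mean <- target
  rec <- vector("list", config$max_iter)
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    R <- outlet_resistances(ref_res, P_mean)
    dis_res <- solve_steady(diseased, Q_in, resistance_bcs(R),
                            blood = config$blood, control = config$control,
                            venous_pressure = config$venous_pressure)
    P_pred <- dis_res$P_in
    disc <- abs(P_pred - target) / target
    rec[[it]] <- data.frame(iter = it, P_mean = P_mean, P_pred = P_pred,
                            discrepancy = disc)
    if (config$log_level == "INFO")
      message(sprintf("iter %2d: P_mean = %8.3f  P_pred = %8.3f  discrepancy = %.4f",
                      it, P_mean, P_pred, disc))
    if (disc < config$threshold) { converged <- TRUE; break }
    P_mean <- P_mean + config$omega * (target - P_pred)
  }
  trace <- structure(list(records = do.call(rbind, rec[!vapply(rec, is.null, TRUE)]),
                          converged = converged, n_iter = it,
                          threshold = config$threshold),
                     class = "iteration_trace")
  if (!converged)
    fd_convergence_error(
      sprintf("flow-division estimation did not converge in %d iterations (discrepancy %.4f)",
              config$max_iter, disc),
      trace = trace)
  list(division = flow_division(dis_res$Q / sum(dis_res$Q)),
       trace = trace, resistances = R, diseased_result = dis_res)
}

#' @export
print.iteration_trace <- function(x, ...) {
  cat(sprintf("iteration_trace: %s in %d iteration(s) (threshold %.3g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$threshold))
  print(x$records, row.names = FALSE)
  invisible(x)
}

#' Three-element Windkessel parameters
#'
#' @param R_c characteristic (proximal) resistance, mmHg.s/mL.
#' @param R_p peripheral (distal) resistance, mmHg.s/mL.
#' @param C compliance, mL/mmHg.
#' @return object of class `windkessel3`.
#' @export
windkessel3 <- function(R_c, R_p, C) {
  if (any(c(R_c, R_p, C) < 0) || R_p == 0 || C == 0)
    fd_validation_error("windkessel3 requires R_c >= 0, R_p > 0, C > 0")
  structure(list(R_c = R_c, R_p = R_p, C = C), class = "windkessel3")
}

#' Tune three-element Windkessel outlets from a flow division
#'
#' Single-steady-solve tuning: the diseased network is solved once at the
#' mean systolic inflow with the given division prescribed, yielding the
#' geometric drops `dP_i`. The total resistance of outlet i is
#' `R_i = (P_mean_ao - dP_i) / Qbar_i`, where `Qbar_i = division_i * Qbar`
#' uses the cycle-mean inlet flow (set `flow_basis = "systolic"` to use the
#' mean systolic flow instead). The total splits as `R_c = f_c R_i`,
#' `R_p = (1 - f_c) R_i`, and the compliance follows from a global decay
#' time constant, `C_i = tau / R_p,i`.
#'
#' @param diseased the diseased `aortic_network`.
#' @param division a [flow_division()].
#' @param targets a [brachial_to_aortic()] result.
#' @param waveform an [inlet_waveform()].
#' @param config a [fd_config()]; uses `f_c`, `tau`, `flow_basis`.
#' @return named list (by branch) of [windkessel3()] objects.
#' @export
tune_windkessel <- function(diseased, division, targets, waveform,
                            config = fd_config()) {
  stopifnot(inherits(diseased, "aortic_network"))
  division <- flow_division(unclass(division))
  wf <- as_inlet_waveform(waveform)
  Q_sys <- mean_systolic_flow(wf)
  Q_cyc <- trapz_int(wf$time, wf$flow) / wf$period
  Qbar <- if (config$flow_basis == "cycle") Q_cyc else Q_sys

  res <- solve_steady(diseased, Q_sys,
                      fraction_bcs(unclass(division)[names(diseased$outlets)]),
                      blood = config$blood, control = config$control)
  dP <- res$dP
  Qi <- unclass(division)[names(dP)] * Qbar
  R_tot <- (targets$P_mean_ao - dP) / Qi
  if (any(R_tot <= 0))
    fd_validation_error(sprintf(
      "negative Windkessel resistance for %s",
      paste(names(R_tot)[R_tot <= 0], collapse = ", ")))
  lapply(stats::setNames(names(R_tot), names(R_tot)), function(b) {
    windkessel3(R_c = config$f_c * R_tot[[b]],
                R_p = (1 - config$f_c) * R_tot[[b]],
                C = config$tau / ((1 - config$f_c) * R_tot[[b]]))
  })
}

#' Compare two flow divisions
#'
#' Pearson correlation of the fraction vectors plus Bland-Altman agreement
#' statistics: the mean difference `b - a` (second method minus first, e.g.
#' proposed minus traditional) and the 95\% limits of agreement,
#' mean +/- 1.96 SD of the differences.
#'
#' @param a,b named fraction vectors over the same branch set (>= 3
#'   branches); inputs need not be normalized.
#' @return list with `pearson_r`, `mean_diff`, `sd_diff`, `loa`
#'   (length-2 lower/upper limits).
#' @export
compare_divisions <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (is.null(names(a)) || is.null(names(b)) || !setequal(names(a), names(b)))
    fd_validation_error("divisions must cover the same branch set")
  if (length(a) < 3L)
    fd_validation_error("need at least 3 branches to compare")
  b <- b[names(a)]
  d <- b - a
  sdd <- stats::sd(d)
  r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
       else stats::cor(a, b)
  list(pearson_r = r, mean_diff = mean(d), sd_diff = sdd,
       loa = c(lower = mean(d) - 1.96 * sdd, upper = mean(d) + 1.96 * sdd))
}
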