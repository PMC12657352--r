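# Run configuration: the protocol constants of the pipeline in one place.

#' Pipeline run configuration
#'
#' @param blood a [blood_properties()].
#' @param control a [solver_control()] for steady/transient Newton solves.
#' @param omega relaxation factor of the additive mean-pressure update in
#'   [estimate_division()] (default 1).
#' @param threshold relative inlet-pressure discrepancy below which the
#'   estimation loop converges; must be in (0, 1). Default 0.01 (1\%).
#' @param max_iter estimation-loop iteration cap (default 50).
#' @param venous_pressure distal reference pressure, mmHg (default 0).
#' @param f_c fraction of total outlet resistance assigned to the
#'   characteristic (proximal) Windkessel resistance (default 0.056).
#' @param tau global pressure-decay time constant `R_p C`, s (default 1.79).
#' @param flow_basis `"cycle"` (default) or `"systolic"`: which mean inlet
#'   flow anchors the branch flows in Windkessel tuning.
#' @param n_steps_per_cycle transient steps per cycle (default 1000).
#' @param n_cycles transient cycles (default 5).
#' @param seed integer seed for generators.
#' @param log_level `"INFO"` prints per-iteration estimation records;
#'   `"WARN"` is quiet.
#' @return list of class `fd_config`.
#' @export
fd_config <- function(blood = blood_properties(), control = solver_control(),
                      omega = 1, threshold = 0.01, max_iter = 50L,
                      venous_pressure = 0, f_c = 0.056, tau = 1.79,
                      flow_basis = c("cycle", "systolic"),
                      n_steps_per_cycle = 1000L, n_cycles = 5L,
                      seed = 1L, log_level = c("WARN", "INFO")) {
  if (threshold <= 0 || threshold >= 1)
    fd_validation_error("threshold must be in (0, 1)")
  if (omega <= 0 || max_iter < 1)
    fd_validation_error("invalid omega or max_iter")
  if (f_c < 0 || f_c >= 1 || tau <= 0)
    fd_validation_error("require 0 <= f_c < 1 and tau > 0")
  structure(list(blood = blood, control = control, omega = omega,
                 threshold = threshold, max_iter = as.integer(max_iter),
                 venous_pressure = venous_pressure, f_c = f_c, tau = tau,
                 flow_basis = match.arg(flow_basis),
                 n_steps_per_cycle = as.integer(n_steps_per_cycle),
                 n_cycles = as.integer(n_cycles), seed = as.integer(seed),
                 log_level = match.arg(log_level)),
            class = "fd_config")
}

#' Read a run configuration from YAML
#'
#' Recognized keys mirror the arguments of [fd_config()]; `blood` may be a
#' mapping with `density`/`viscosity`, `control` a mapping with
#' `tol`/`max_iter`. Unknown keys raise a validation error naming the key.
#'
#' @param path YAML file path.
#' @return an `fd_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) fd_io_error(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  known <- setdiff(names(formals(fd_config)), c("blood", "control"))
  extra <- setdiff(names(y), c(known, "blood", "control"))
  if (length(extra))
    fd_validation_error(sprintf("unknown config key(s): %s",
                                paste(extra, collapse = ", ")))
  args <- y[intersect(names(y), known)]
  if (!is.null(y$blood))
    args$blood <- do.call(blood_properties, y$blood)
  if (!is.null(y$control))
    args$control <- do.call(solver_control, y$control)
  do.call(fd_config, args)
}
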