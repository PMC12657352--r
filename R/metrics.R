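# Hemodynamic metric suite: cycle-integrated wall-shear metrics (TAWSS, OSI,
# RRT, AFI), Poiseuille WSS extraction from transient runs, local normalized
# helicity on gridded velocity fields, and transmural pressure.
#
# All cycle integrals use trapezoidal quadrature on the given samples.
# Points where a metric is undefined (zero shear, zero velocity/vorticity)
# are carried as NA flags rather than errors, so field summaries stay
# computable.

#' Wall-shear-stress time series
#'
#' @param times sample times spanning one cardiac cycle, s.
#' @param tau shear samples, Pa: either a `points x times` matrix of signed
#'   scalars, or a `points x times x 3` array of shear vectors.
#' @return object of class `wss_series`.
#' @export
wss_series <- function(times, tau) {
  if (length(times) < 2L)
    fd_validation_error("wss_series needs at least 2 time samples")
  if (is.matrix(tau)) {
    if (ncol(tau) != length(times))
      fd_validation_error("tau columns must match times")
  } else if (is.array(tau) && length(dim(tau)) == 3L) {
    if (dim(tau)[2L] != length(times) || dim(tau)[3L] != 3L)
      fd_validation_error("vector tau must be points x times x 3")
  } else fd_validation_error("tau must be a matrix or points x times x 3 array")
  if (any(!is.finite(tau))) fd_validation_error("tau must be finite")
  structure(list(times = times, tau = tau,
                 T = times[length(times)] - times[1L]),
            class = "wss_series")
}

# |tau| as points x times, and per-component list for vector series
tau_magnitude <- function(s) {
  if (is.matrix(s$tau)) abs(s$tau)
  else sqrt(s$tau[, , 1L]^2 + s$tau[, , 2L]^2 + s$tau[, , 3L]^2)
}

# trapezoid integral over time for each point (rows)
row_trapz <- function(times, m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  w <- diff(times)
  as.vector((m[, -ncol(m), drop = FALSE] + m[, -1L, drop = FALSE]) %*% w) / 2
}

# time integral of the (possibly vector) shear; returns points x ncomp
tau_time_integral <- function(s) {
  if (is.matrix(s$tau)) {
    cbind(row_trapz(s$times, s$tau))
  } else {
    do.call(cbind, lapply(1:3, function(k) {
      comp <- s$tau[, , k]
      if (is.null(dim(comp))) comp <- matrix(comp, nrow = dim(s$tau)[1L])
      row_trapz(s$times, comp)
    }))
  }
}

#' Time-averaged wall shear stress
#'
#' `TAWSS = (1/T) integral |tau_w| dt` per wall point.
#'
#' @param series a [wss_series()].
#' @return numeric vector, Pa.
#' @export
tawss <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  row_trapz(series$times, tau_magnitude(series)) / series$T
}

#' Oscillatory shear index
#'
#' `OSI = 0.5 (1 - |integral tau_w dt| / integral |tau_w| dt)`, clipped to
#' [0, 0.5] against round-off. Points with identically zero shear are
#' undefined and flagged `NA`.
#'
#' @param series a [wss_series()].
#' @return numeric vector in [0, 0.5] with `NA` flags.
#' @export
osi <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  num <- sqrt(rowSums(tau_time_integral(series)^2))
  den <- row_trapz(series$times, tau_magnitude(series))
  out <- 0.5 * (1 - num / den)
  out[den == 0] <- NA_real_
  pmin(pmax(out, 0), 0.5)
}

#' Relative residence time
#'
#' `RRT = 1 / ((1 - 2 OSI) TAWSS) = 1 / ((1/T) |integral tau_w dt|)`.
#' Fully oscillatory points (OSI = 0.5) return `Inf`; undefined points
#' propagate `NA`.
#'
#' @param series a [wss_series()].
#' @return numeric vector, 1/Pa.
#' @export
rrt <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  o <- osi(series); tw <- tawss(series)
  den <- (1 - 2 * o) * tw
  out <- ifelse(den == 0, Inf, 1 / den)
  out[is.na(o)] <- NA_real_
  out
}

#' Aneurysm formation indicator
#'
#' Cosine of the angle between the instantaneous shear vector at `t_obs`
#' (conventionally the mid-systolic deceleration instant) and the
#' cycle-integrated shear vector. For signed scalar series this is the sign
#' product. Zero vectors at `t_obs` (or zero integral) are flagged `NA`.
#'
#' @param series a [wss_series()].
#' @param t_obs observation time within the cycle, s; see
#'   [mid_systolic_deceleration()] for the default choice from an inlet
#'   waveform.
#' @return numeric vector in [-1, 1] with `NA` flags.
#' @export
afi <- function(series, t_obs) {
  stopifnot(inherits(series, "wss_series"))
  if (t_obs < min(series$times) || t_obs > max(series$times))
    fd_validation_error("t_obs outside the cycle")
  i <- which.min(abs(series$times - t_obs))
  integ <- tau_time_integral(series)
  if (is.matrix(series$tau)) {
    inst <- cbind(series$tau[, i])
  } else {
    inst <- series$tau[, i, , drop = FALSE]
    dim(inst) <- dim(inst)[c(1L, 3L)]
  }
  dot <- rowSums(inst * integ)
  n1 <- sqrt(rowSums(inst^2)); n2 <- sqrt(rowSums(integ^2))
  out <- dot / (n1 * n2)
  out[n1 == 0 | n2 == 0] <- NA_real_
  pmin(pmax(out, -1), 1)
}

#' Mid-systolic deceleration instant of a waveform
#'
#' Operationalized as the time of steepest inlet-flow deceleration (most
#' negative dQ/dt, central differences) within systole, systole ending at
#' the first post-peak zero crossing.
#'
#' @param waveform an [inlet_waveform()].
#' @return time, s.
#' @export
mid_systolic_deceleration <- function(waveform) {
  wf <- as_inlet_waveform(waveform)
  t <- wf$time; q <- wf$flow
  ipk <- which.max(q)
  post <- seq(ipk, length(q))
  neg <- post[which(q[post] <= 0)[1L]]
  iend <- if (is.na(neg)) length(q) else neg
  n <- length(t)
  dq <- numeric(n)
  dq[1L] <- (q[2L] - q[1L]) / (t[2L] - t[1L])
  dq[n] <- (q[n] - q[n - 1L]) / (t[n] - t[n - 1L])
  if (n > 2L)
    dq[2:(n - 1L)] <- (q[3:n] - q[1:(n - 2L)]) / (t[3:n] - t[1:(n - 2L)])
  win <- ipk:iend
  t[win[which.min(dq[win])]]
}

#' Poiseuille wall shear stress from a transient run
#'
#' Maps the 0D segment flows of the final cycle to a signed axial wall shear
#' at each segment midpoint via `tau(t) = 4 mu Q(t) / (pi r^3)`.
#'
#' @param result a `transient_result`.
#' @param net the `aortic_network` that produced it.
#' @param blood a [blood_properties()].
#' @return a [wss_series()] (signed scalar, one row per segment, rows named
#'   by segment id).
#' @export
poiseuille_wss <- function(result, net, blood = blood_properties()) {
  stopifnot(inherits(result, "transient_result"),
            inherits(net, "aortic_network"))
  rows <- final_cycle_rows(result)
  Q <- t(result$segment_flow[rows, , drop = FALSE])        # segments x times
  r_m <- net$segments$radius_cm[match(rownames(Q), net$segments$id)] * CM_M
  tau <- 4 * blood$viscosity * (Q * ML_M3) / (pi * r_m^3)
  times <- result$times[rows] - result$times[rows[1L]]
  wss_series(times, tau)
}

#' Decimate a transient result for temporal statistics
#'
#' Keeps every tenth sample (0-based indices 0, 10, 20, ...) of the final
#' cycle, the conventional thinning for cycle statistics.
#'
#' @param result a `transient_result`.
#' @param every keep every `every`-th step (default 10).
#' @return a `transient_result` restricted to the decimated final cycle
#'   (`cycles_run = 1`).
#' @export
sample_every_tenth <- function(result, every = 10L) {
  stopifnot(inherits(result, "transient_result"))
  rows <- final_cycle_rows(result)
  keep <- rows[seq(1L, length(rows), by = every)]
  out <- result
  out$times <- result$times[keep]
  out$inlet_pressure <- result$inlet_pressure[keep]
  out$node_pressure <- result$node_pressure[keep, , drop = FALSE]
  out$segment_flow <- result$segment_flow[keep, , drop = FALSE]
  out$capacitor_pressure <- result$capacitor_pressure[keep, , drop = FALSE]
  out$inlet_flow <- result$inlet_flow[keep]
  out$cycles_run <- 1L
  out$n_steps_per_cycle <- length(keep)
  out
}

#' Structured-grid velocity field
#'
#' @param v a 4D array `nx x ny x nz x 3` of velocity vectors, m/s.
#' @param spacing grid spacing per axis, m (length 3, all > 0).
#' @return object of class `velocity_field`.
#' @export
velocity_field <- function(v, spacing) {
  if (!is.array(v) || length(dim(v)) != 4L || dim(v)[4L] != 3L)
    fd_validation_error("v must be an nx x ny x nz x 3 array")
  if (any(dim(v)[1:3] < 3L))
    fd_validation_error("need >= 3 points along every differentiated axis")
  if (length(spacing) != 3L || any(spacing <= 0))
    fd_validation_error("spacing must be 3 positive values")
  structure(list(v = v, spacing = spacing), class = "velocity_field")
}

# partial derivative of 3D array a along axis (1..3): central differences,
# one-sided at the boundary slabs
ddx <- function(a, axis, h) {
  d <- dim(a); n <- d[axis]
  sl <- function(i) {
    idx <- rep(list(quote(expr = )), 3L)
    idx[[axis]] <- i
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  out <- (sl(c(2:n, n)) - sl(c(1L, 1:(n - 1)))) / (2 * h)
  # one-sided boundaries (spacing h, not 2h)
  bl <- function(i, j) (sl(i) - sl(j)) / h
  idx <- rep(list(quote(expr = )), 3L)
  idx[[axis]] <- 1L
  out <- do.call(`[<-`, c(list(out), idx, list(value = bl(2L, 1L))))
  idx[[axis]] <- n
  do.call(`[<-`, c(list(out), idx, list(value = bl(n, n - 1L))))
}

#' Local normalized helicity
#'
#' `LNH = v . (curl v) / (|v| |curl v|)`, the cosine of the angle between
#' velocity and vorticity; +-1 marks fully helical (Beltrami-like) flow. The
#' curl uses central differences with one-sided stencils at the grid
#' boundary. Points with `|v|` or `|curl v|` below `tol` are flagged `NA`.
#'
#' @param field a [velocity_field()].
#' @param tol degeneracy tolerance (default 1e-12).
#' @return 3D array `nx x ny x nz` in [-1, 1] with `NA` flags.
#' @export
lnh <- function(field, tol = 1e-12) {
  stopifnot(inherits(field, "velocity_field"))
  v <- field$v; h <- field$spacing
  vx <- v[, , , 1L]; vy <- v[, , , 2L]; vz <- v[, , , 3L]
  wx <- ddx(vz, 2L, h[2L]) - ddx(vy, 3L, h[3L])
  wy <- ddx(vx, 3L, h[3L]) - ddx(vz, 1L, h[1L])
  wz <- ddx(vy, 1L, h[1L]) - ddx(vx, 2L, h[2L])
  nv <- sqrt(vx^2 + vy^2 + vz^2)
  nw <- sqrt(wx^2 + wy^2 + wz^2)
  out <- (vx * wx + vy * wy + vz * wz) / (nv * nw)
  out[nv < tol | nw < tol] <- NA_real_
  pmin(pmax(out, -1), 1)
}

#' Transmural pressure across a dissection flap
#'
#' `TMP = P_TL - P_FL` at matched stations, with the "balance point": the
#' first station interval over which the station-profile (time-mean for
#' matrix input) changes sign.
#'
#' @param p_tl,p_fl matched true-/false-lumen pressures, mmHg: vectors
#'   (stations) or matrices (stations x times) of equal shape.
#' @return list with `tmp` (same shape as input), `profile` (per-station
#'   time-mean), and `balance_station` (index of the last station before the
#'   sign change, `NA` if none).
#' @export
tmp_series <- function(p_tl, p_fl) {
  if (!identical(dim(p_tl), dim(p_fl)) || length(p_tl) != length(p_fl))
    fd_validation_error("TL and FL series must have equal shape")
  d <- p_tl - p_fl
  profile <- if (is.matrix(d)) rowMeans(d) else d
  s <- sign(profile)
  cross <- which(s[-length(s)] * s[-1L] < 0 | (s[-length(s)] != 0 & s[-1L] == 0))
  list(tmp = d, profile = profile,
       balance_station = if (length(cross)) cross[1L] else NA_integer_)
}
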