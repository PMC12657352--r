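# Small fixture networks and an independent nonlinear-solver oracle.

seg_row <- function(id, from, to, length_cm, radius_cm, branch = NA_character_,
                    area_ratio = NA_real_, kt = NA_real_) {
  data.frame(id = id, from = from, to = to, length_cm = length_cm,
             radius_cm = radius_cm, lumen_tag = "NONE", branch = branch,
             station = NA_integer_, sten_area_ratio = area_ratio,
             sten_kt = kt, dilation = 1, stringsAsFactors = FALSE)
}

# single straight vessel ending in one outlet (celiac trunk name reused)
straight_network <- function(length_cm = 10, radius_cm = 0.5) {
  aortic_network(seg_row("CT_1", "n0", "nCT", length_cm, radius_cm, "CT"),
                 inlet = "n0", outlets = c(CT = "nCT"))
}

# symmetric (or not) two-branch Y; outlets reuse the renal branch names
y_network <- function(r_left = 0.5, r_right = 0.5, r_trunk = 1,
                      ar_left = NA_real_, kt = 1.52) {
  segs <- rbind(
    seg_row("AO", "n0", "n1", 5, r_trunk),
    seg_row("LRA_1", "n1", "nLRA", 8, r_left, "LRA",
            area_ratio = ar_left, kt = if (is.na(ar_left)) NA_real_ else kt),
    seg_row("RRA_1", "n1", "nRRA", 8, r_right, "RRA"))
  aortic_network(segs, inlet = "n0", outlets = c(LRA = "nLRA", RRA = "nRRA"))
}

# random tree with n_out outlets and <= 8 segments, radii jittered
random_tree <- function(seed, n_out = 6) {
  branches <- c("CT", "SMA", "LRA", "RRA", "LEIA", "REIA")[seq_len(n_out)]
  r <- withr::with_seed(seed, stats::runif(n_out + 2, 0.25, 0.9))
  segs <- rbind(
    seg_row("AO0", "n0", "n1", 6, r[n_out + 1]),
    seg_row("AO1", "n1", "n2", 6, r[n_out + 2]))
  half <- ceiling(n_out / 2)
  for (i in seq_len(n_out)) {
    at <- if (i <= half) "n1" else "n2"
    ar <- if (i == 1L) 0.5 else NA_real_   # one stenosed branch
    segs <- rbind(segs, seg_row(paste0(branches[i], "_1"), at,
                                paste0("n", branches[i]), 4 + i, r[i],
                                branches[i], area_ratio = ar,
                                kt = if (is.na(ar)) NA_real_ else 1.52))
  }
  aortic_network(segs, inlet = "n0",
                 outlets = stats::setNames(paste0("n", branches), branches))
}

# Independent steady-solver oracle: nodal pressures found by pracma's
# Newton/Broyden root finder on a residual assembled from scratch, with each
# segment flow recovered from its pressure drop by scalar bisection
# (uniroot) on the forward law dP(Q) -- a different route than the package's
# closed-form inversion.
oracle_steady_flows <- function(net, inlet_flow_mls, resistances_mmHg_s_ml,
                                blood = blood_properties()) {
  seg <- net$segments
  mu <- blood$viscosity; rho <- blood$density
  r_m <- seg$radius_cm / 100; L_m <- seg$length_cm / 100
  Rp <- 8 * mu * L_m / (pi * r_m^4)
  Kq <- rep(0, nrow(seg))
  has <- !is.na(seg$sten_area_ratio)
  A0 <- pi * r_m^2
  As <- seg$sten_area_ratio * A0
  Kq[has] <- seg$sten_kt[has] * rho / (2 * As[has]^2) * (A0[has] / As[has] - 1)^2

  q_of_dp <- function(dp, i) {
    if (dp == 0) return(0)
    f <- function(q) Rp[i] * q + Kq[i] * q * abs(q) - dp
    lim <- abs(dp) / Rp[i] + 1
    stats::uniroot(f, c(-lim, lim), tol = 1e-16)$root
  }

  nodes <- sort(unique(c(seg$from, seg$to)))
  Qin <- inlet_flow_mls * 1e-6
  Rout <- resistances_mmHg_s_ml[names(net$outlets)] * 133.322 / 1e-6
  i_out <- match(net$outlets[names(net$outlets)], nodes)

  residual <- function(p) {
    F <- numeric(length(nodes))
    for (i in seq_len(nrow(seg))) {
      a <- match(seg$from[i], nodes); b <- match(seg$to[i], nodes)
      q <- q_of_dp(p[a] - p[b], i)
      F[a] <- F[a] - q; F[b] <- F[b] + q
    }
    F[match(net$inlet, nodes)] <- F[match(net$inlet, nodes)] + Qin
    F[i_out] <- F[i_out] - p[i_out] / Rout
    F * 1e6   # scale to keep fsolve's tolerance meaningful
  }
  p0 <- rep(mean(Rout) * Qin, length(nodes))
  # fsolve may hit its iteration cap chasing an unreachable tolerance; the
  # oracle's quality is enforced by the explicit residual check below
  sol <- suppressWarnings(pracma::fsolve(residual, p0, tol = 1e-13))
  p <- sol$x
  if (max(abs(residual(p))) > 1e-9 * inlet_flow_mls)
    stop("oracle root find failed to reach the required residual")
  qs <- vapply(seq_len(nrow(seg)), function(i)
    q_of_dp(p[match(seg$from[i], nodes)] - p[match(seg$to[i], nodes)], i),
    numeric(1))
  stats::setNames(qs / 1e-6, seg$id)
}

# ABC (Beltrami) velocity field on a periodic [0, 2pi)^3 grid: curl v = v,
# so LNH should be +1 everywhere; the mirror image reverses chirality.
abc_field <- function(n = 64L, mirror = FALSE) {
  h <- 2 * pi / n
  x <- (0:(n - 1)) * h
  X <- array(rep(x, times = n * n), c(n, n, n))
  Y <- array(rep(rep(x, each = n), times = n), c(n, n, n))
  Z <- array(rep(x, each = n * n), c(n, n, n))
  v <- array(0, c(n, n, n, 3))
  v[, , , 1] <- sin(Z) + cos(Y)
  v[, , , 2] <- sin(X) + cos(Z)
  v[, , , 3] <- sin(Y) + cos(X)
  if (mirror) {   # reflect x -> -x: reverse the axis and flip v_x
    v <- v[n:1, , , , drop = FALSE]
    v[, , , 1] <- -v[, , , 1]
  }
  velocity_field(v, rep(h, 3))
}
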