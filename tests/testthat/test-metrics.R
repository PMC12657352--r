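# Square-wave shear fixture: +1 Pa for the first 3T/4, -1 Pa for the rest,
# sampled with duplicated jump times so trapezoidal quadrature integrates the
# ideal square wave exactly.
square_series <- function(T = 1) {
  wss_series(times = c(0, 0.75, 0.75, 1) * T,
             tau = matrix(c(1, 1, -1, -1), nrow = 1))
}

test_that("cycle-averaged shear metrics match hand integrals", {
  const <- wss_series(c(0, 0.5, 1), matrix(2, 1, 3))
  expect_equal(tawss(const), 2)
  expect_equal(osi(const), 0)
  expect_equal(rrt(const), 0.5)

  sq <- square_series()
  expect_equal(tawss(sq), 1)           # (1/T) int |tau| dt
  expect_equal(osi(sq), 0.25)          # 0.5 (1 - |0.5|/1)
  expect_equal(rrt(sq), 2)             # 1/((1 - 0.5) * 1)

  zero <- wss_series(c(0, 0.5, 1), matrix(0, 1, 3))
  expect_equal(tawss(zero), 0)
  expect_true(is.na(osi(zero)))
  expect_true(is.na(rrt(zero)))

  alt <- wss_series(c(0, 0.5, 0.5, 1), matrix(c(1, 1, -1, -1), 1))
  expect_equal(osi(alt), 0.5)
  expect_equal(rrt(alt), Inf)
})

test_that("the RRT identity holds pointwise under shared quadrature", {
  s <- wss_series(seq(0, 1, length.out = 41),
                  withr::with_seed(8, matrix(stats::rnorm(5 * 41), 5, 41)))
  o <- osi(s); tw <- tawss(s); r <- rrt(s)
  expect_equal(r * (1 - 2 * o) * tw, rep(1, 5), tolerance = 1e-12)
  # independent route: RRT = T / |int tau dt|
  direct <- 1 / abs(flowdiv:::row_trapz(s$times, s$tau))
  expect_equal(r, direct, tolerance = 1e-12)
  expect_true(all(o >= 0 & o <= 0.5))
})

test_that("metrics are invariant under cyclic rotation of the samples", {
  n <- 48
  t <- seq(0, 1, length.out = n + 1)
  tau <- matrix(sin(2 * pi * t) + 0.4 * cos(4 * pi * t) + 0.2, nrow = 1)
  s <- wss_series(t, tau)
  for (k in c(7, 19)) {
    idx <- c((k + 1):n, 1:k)              # rotate the n distinct samples
    tau_rot <- matrix(c(tau[1, idx], tau[1, idx[1]]), nrow = 1)
    s_rot <- wss_series(t, tau_rot)
    expect_equal(tawss(s_rot), tawss(s), tolerance = 1e-12)
    expect_equal(osi(s_rot), osi(s), tolerance = 1e-12)
    expect_equal(rrt(s_rot), rrt(s), tolerance = 1e-12)
  }
})

test_that("AFI is the cosine between instantaneous and mean shear", {
  t <- c(0, 0.5, 1)
  # choose endpoint vectors so the trapezoidal cycle integral is always
  # (1, 0, 0) whatever the mid-cycle sample is: weights are 1/4, 1/2, 1/4
  make <- function(v_at_mid) {
    ends <- c(2, 0, 0) - v_at_mid
    tau <- array(0, c(1, 3, 3))
    tau[1, 1, ] <- ends; tau[1, 3, ] <- ends
    tau[1, 2, ] <- v_at_mid
    wss_series(t, tau)
  }
  expect_equal(afi(make(c(2, 0, 0)), 0.5), 1)       # parallel
  expect_equal(afi(make(c(-2, 0, 0)), 0.5), -1)     # antiparallel
  expect_equal(afi(make(c(0, 3, 0)), 0.5), 0)       # orthogonal
  expect_true(is.na(afi(make(c(0, 0, 0)), 0.5)))    # zero vector flagged
  expect_error(afi(make(c(1, 0, 0)), 2), class = "fd_validation_error")
})

test_that("mid-systolic deceleration lies between peak and end systole", {
  wf <- template_waveform()
  t_obs <- mid_systolic_deceleration(wf)
  ts <- 1 / 3
  expect_gt(t_obs, ts / 2)        # after the peak
  expect_lt(t_obs, ts + 0.01)     # before systole ends
})

test_that("Poiseuille WSS extraction converts flow to wall shear", {
  fake <- structure(list(
    times = c(0, 0.5, 1),
    segment_flow = matrix(10, 3, 1, dimnames = list(NULL, "CT_1")),
    cycles_run = 1L, n_steps_per_cycle = 3L), class = "transient_result")
  net <- straight_network(radius_cm = 0.5)
  w <- poiseuille_wss(fake, net)
  expect_equal(unname(w$tau[1, 1]), 4 * 0.0035 * 1e-5 / (pi * 0.005^3),
               tolerance = 1e-12)
  expect_equal(unname(round(w$tau[1, 1], 4)), 0.3565)
  fake$segment_flow <- -fake$segment_flow
  expect_equal(unname(poiseuille_wss(fake, net)$tau[1, 1]), -0.35651,
               tolerance = 1e-4)
  fake$segment_flow[] <- 0
  expect_true(all(poiseuille_wss(fake, net)$tau == 0))
})

test_that("LNH is +1 on a Beltrami field and -1 on its mirror image", {
  f <- abc_field(48L)
  L <- lnh(f)
  interior <- L[2:47, 2:47, 2:47]
  expect_lt(max(abs(interior - 1), na.rm = TRUE), 1e-3)
  expect_lt(mean(abs(L - 1), na.rm = TRUE), 1e-3)
  Lm <- lnh(abc_field(48L, mirror = TRUE))
  expect_lt(max(abs(Lm[2:47, 2:47, 2:47] + 1), na.rm = TRUE), 1e-3)
})

test_that("LNH vanishes for planar shear and is scale invariant", {
  n <- 9
  y <- seq(-1, 1, length.out = n)
  v <- array(0, c(n, n, n, 3))
  for (j in 1:n) v[, j, , 1] <- 1 - y[j]^2   # axial Poiseuille-like profile
  f <- velocity_field(v, rep(0.25, 3))
  L <- lnh(f)
  expect_lt(max(abs(L), na.rm = TRUE), 1e-12)  # vorticity perpendicular to v
  f2 <- velocity_field(5 * v, rep(0.25, 3))
  expect_equal(lnh(f2), L, tolerance = 1e-12)
})

test_that("transmural pressure reports differences and the balance point", {
  p_tl <- c(10, 8, 6, 4, 2)
  same <- tmp_series(p_tl, p_tl)
  expect_true(all(same$tmp == 0))
  expect_true(is.na(same$balance_station))
  off <- tmp_series(p_tl + 5, p_tl)
  expect_true(all(off$tmp == 5))
  crossing <- tmp_series(p_tl, c(7, 7, 7, 7, 7))  # TMP: 3 1 -1 -3 -5
  expect_equal(crossing$balance_station, 2L)
  expect_error(tmp_series(p_tl, p_tl[-1]), class = "fd_validation_error")
})

test_that("decimation keeps every tenth step of the final cycle", {
  net <- y_network()
  wf <- template_waveform(n_samples = 101)
  wk <- list(LRA = windkessel3(0.4, 7, 0.25), RRA = windkessel3(0.3, 9, 0.2))
  res <- solve_transient(net, wf, wk, n_steps_per_cycle = 1000, n_cycles = 2)
  dec <- sample_every_tenth(res)
  expect_equal(nrow(dec$segment_flow), 100)
  expect_equal(dec$times[1], res$times[1001])
  w_full <- poiseuille_wss(res, net)
  w_dec <- poiseuille_wss(dec, net)
  expect_lt(max(abs(tawss(w_dec) - tawss(w_full)) / tawss(w_full)), 0.01)

  small <- res
  small$n_steps_per_cycle <- 5L
  small$cycles_run <- 1L
  small$times <- res$times[1:5]
  small$segment_flow <- res$segment_flow[1:5, , drop = FALSE]
  small$node_pressure <- res$node_pressure[1:5, , drop = FALSE]
  small$capacitor_pressure <- res$capacitor_pressure[1:5, , drop = FALSE]
  small$inlet_pressure <- res$inlet_pressure[1:5]
  small$inlet_flow <- res$inlet_flow[1:5]
  expect_equal(nrow(sample_every_tenth(small)$segment_flow), 1)
})
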