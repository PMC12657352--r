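make_targets <- function(P_mean) list(P_mean_ao = P_mean)

test_that("empirical division reproduces the healthy-adult rule set", {
  net <- build_healthy_template(seed = 1)
  # equalize supra-aortic areas so the 30% splits evenly
  net$branch_inlet_area[c("BT", "LCC", "LSA")] <- pi * 0.5^2
  d <- empirical_division(net)
  expect_equal(sum(d), 1, tolerance = 1e-12)
  expect_equal(unname(d[c("BT", "LCC", "LSA")]), rep(0.1, 3))
  expect_equal(d[["CT"]], 0.155)
  expect_equal(unname(d[c("SMA", "LRA", "RRA")]), rep(0.105, 3))
  expect_equal(d[["IMA"]], 0.005)
  # iliac remainder: (1 - 0.775)/2 per side, 70/30 external/internal
  expect_equal(d[["LEIA"]], 0.07875)
  expect_equal(d[["LIIA"]], 0.03375)
  expect_equal(d[["REIA"]], 0.07875)
  expect_equal(d[["RIIA"]], 0.03375)
  # one-decimal percent printing of the iliac fractions
  expect_equal(round_half_up(100 * d[["LEIA"]], 1), 7.9)
  expect_equal(round_half_up(100 * d[["LIIA"]], 1), 3.4)
})

test_that("supra-aortic split is proportional to inlet areas", {
  net <- build_healthy_template(seed = 1)
  net$branch_inlet_area[c("BT", "LCC", "LSA")] <- c(2, 1, 1)
  d <- empirical_division(net)
  expect_equal(unname(d[c("BT", "LCC", "LSA")]), c(0.15, 0.075, 0.075))
})

test_that("absent inferior mesenteric artery enlarges the iliac share", {
  net <- build_healthy_template(seed = 1)
  keep <- setdiff(BRANCH_NAMES, "IMA")
  net$outlets <- net$outlets[keep]
  net$segments <- net$segments[!(net$segments$branch %in% "IMA"), ]
  net <- aortic_network(net$segments, net$inlet, net$outlets)
  d <- empirical_division(net)
  # hand arithmetic: remainder 1 - 0.30 - 0.155 - 3*0.105 = 0.23,
  # per side 0.115 -> external 0.0805, internal 0.0345
  expect_equal(d[["LEIA"]], 0.0805)
  expect_equal(d[["LIIA"]], 0.0345)
  expect_equal(sum(d), 1, tolerance = 1e-12)

  net$outlets <- net$outlets[setdiff(keep, "CT")]
  expect_error(empirical_division(net), class = "fd_validation_error")
})

test_that("brachial-to-aortic conversion matches hand-evaluated values", {
  t1 <- brachial_to_aortic(146, 87)
  expect_equal(t1$P_sys_ao, 0.83 * 146 + 0.15 * 87, tolerance = 1e-12)
  expect_equal(t1$P_mean_ao, 105.892, tolerance = 1e-9)
  expect_equal(brachial_to_aortic(120, 87)$P_mean_ao, 97.26, tolerance = 1e-9)
  expect_equal(brachial_to_aortic(140, 83)$P_mean_ao, 101.26, tolerance = 1e-9)
  expect_error(brachial_to_aortic(100, 100), class = "fd_validation_error")
  expect_error(brachial_to_aortic(80, -10), class = "fd_validation_error")
})

test_that("mean systolic flow integrates the systolic interval", {
  # half-sine over [0, T/3]: closed-form mean 2/pi * peak
  t <- seq(0, 1, length.out = 4001)
  q <- ifelse(t <= 1 / 3, 350 * sin(3 * pi * t), 0)
  wf <- inlet_waveform(t, q)
  # with the systole end given exactly, only quadrature error remains
  expect_equal(mean_systolic_flow(wf, t_end_sys = 1 / 3), 2 / pi * 350,
               tolerance = 1e-6)
  # automatic end-of-systole detection resolves the crossing to O(dt)
  expect_equal(mean_systolic_flow(wf), 2 / pi * 350, tolerance = 2e-3)
  # constant waveform: the mean is the constant
  expect_equal(mean_systolic_flow(inlet_waveform(c(0, 0.5, 1), rep(70, 3))), 70)
  expect_error(mean_systolic_flow(inlet_waveform(c(0, 0.5, 1), rep(0, 3))),
               class = "fd_validation_error")
  # explicit override restricts the window
  expect_equal(mean_systolic_flow(inlet_waveform(c(0, 0.5, 1), c(100, 100, 100)),
                                  t_end_sys = 0.5), 100)
})

test_that("outlet resistance conversion implements (P_mean - dP)/Q", {
  fake <- structure(list(Q = c(CT = 10, SMA = 20),
                         dP = c(CT = 2, SMA = 0),
                         P_in = 5, P_out = c(CT = 3, SMA = 5)),
                    class = "steady_result")
  R <- outlet_resistances(fake, 100)
  expect_equal(R[["CT"]], 9.8)
  expect_equal(R[["SMA"]], 5.0)
  expect_error(outlet_resistances(fake, 1),
               class = "fd_negative_resistance_error")
})

test_that("lesion-free estimation recovers the empirical division at once", {
  net <- build_healthy_template(seed = 21)
  tg <- brachial_to_aortic(146, 87)
  est <- estimate_division(net, net, tg, template_waveform())
  expect_true(est$trace$converged)
  expect_equal(est$trace$n_iter, 1L)
  emp <- empirical_division(net)
  expect_lt(max(abs(unclass(est$division) - unclass(emp))), 1e-8)
  expect_equal(est$trace$records$P_pred[1], tg$P_mean_ao, tolerance = 1e-8)
})

test_that("stenosis steal: tighter celiac stenosis, smaller celiac fraction", {
  healthy <- build_healthy_template(seed = 23)
  tg <- brachial_to_aortic(146, 87)
  wf <- template_waveform()
  fr <- vapply(c(1, 0.5, 0.25, 0.1), function(ar) {
    dis <- apply_lesion(healthy,
                        lesion_spec("OSTIAL_STENOSIS", "CT", area_ratio = ar))
    est <- estimate_division(repair(dis), dis, tg, wf)
    expect_equal(sum(est$division), 1, tolerance = 1e-9)
    est$division[["CT"]]
  }, numeric(1))
  expect_equal(fr[1], 0.155, tolerance = 1e-8)
  expect_true(all(diff(fr) < 0))
  expect_lt(fr[4], 0.155)
})

test_that("converged resistances are self-consistent with the stopping rule", {
  healthy <- build_healthy_template(seed = 29)
  dis <- apply_lesion(healthy,
                      lesion_spec("OSTIAL_STENOSIS", "CT", area_ratio = 0.25))
  tg <- brachial_to_aortic(120, 87)
  wf <- template_waveform()
  est <- estimate_division(repair(dis), dis, tg, wf)
  Q_in <- mean_systolic_flow(wf)
  re <- solve_steady(dis, Q_in, resistance_bcs(est$resistances))
  expect_lt(abs(re$P_in - tg$P_mean_ao) / tg$P_mean_ao, 0.01)
})

test_that("predicted inlet pressure rises monotonically with P_mean", {
  healthy <- build_healthy_template(seed = 31)
  dis <- apply_lesion(healthy,
                      lesion_spec("OSTIAL_STENOSIS", "SMA", area_ratio = 0.3))
  ref <- repair(dis)
  wf <- template_waveform()
  Q_in <- mean_systolic_flow(wf)
  emp <- empirical_division(ref)
  ref_res <- solve_steady(ref, Q_in, fraction_bcs(unclass(emp)))
  preds <- vapply(seq(60, 140, by = 20), function(pm) {
    R <- outlet_resistances(ref_res, pm)
    solve_steady(dis, Q_in, resistance_bcs(R))$P_in
  }, numeric(1))
  expect_true(all(diff(preds) > 0))
})

test_that("an unreachable target pressure raises the negative-resistance error", {
  net <- build_healthy_template(seed = 33)
  expect_error(estimate_division(net, net, make_targets(0.5), template_waveform()),
               class = "fd_negative_resistance_error")
})

test_that("Windkessel tuning obeys its structural identities", {
  net <- y_network()
  div <- flow_division(c(LRA = 0.5, RRA = 0.5))
  tg <- brachial_to_aortic(120, 80)
  wf <- template_waveform()
  cfg <- fd_config()
  wk <- tune_windkessel(net, div, tg, wf, cfg)
  # symmetric geometry + uniform division -> identical parameters
  expect_equal(wk$LRA, wk$RRA)
  expect_equal(wk$LRA$R_c / (wk$LRA$R_c + wk$LRA$R_p), cfg$f_c,
               tolerance = 1e-12)
  expect_equal(wk$LRA$R_p * wk$LRA$C, cfg$tau, tolerance = 1e-12)
  # doubling tau doubles every compliance
  wk2 <- tune_windkessel(net, div, tg, wf, fd_config(tau = 2 * cfg$tau))
  expect_equal(wk2$LRA$C, 2 * wk$LRA$C, tolerance = 1e-12)
  # f_c = 0 puts all resistance in the peripheral element
  wk0 <- tune_windkessel(net, div, tg, wf, fd_config(f_c = 0))
  expect_equal(wk0$LRA$R_c, 0)
  expect_equal(wk0$LRA$R_p, wk$LRA$R_c + wk$LRA$R_p, tolerance = 1e-12)
})

test_that("division comparison returns correlation and Bland-Altman limits", {
  a <- c(BT = 0.2, LCC = 0.1, LSA = 0.1, CT = 0.15, SMA = 0.15, LEIA = 0.3)
  self <- compare_divisions(a, a)
  expect_equal(self$pearson_r, 1)
  expect_equal(self$mean_diff, 0)
  shift <- compare_divisions(a, a + 0.01)
  expect_equal(shift$pearson_r, 1)
  expect_equal(shift$mean_diff, 0.01)
  expect_equal(shift$sd_diff, 0)
  expect_equal(unname(shift$loa), c(0.01, 0.01))
  # brute-force Pearson formula on two fixed 12-vectors
  b <- withr::with_seed(5, {
    x <- stats::runif(12); stats::setNames(x / sum(x), BRANCH_NAMES)
  })
  c2 <- withr::with_seed(6, {
    x <- stats::runif(12); stats::setNames(x / sum(x), BRANCH_NAMES)
  })
  n <- 12
  r_brute <- (sum(b * c2) - n * mean(b) * mean(c2)) /
    sqrt((sum(b^2) - n * mean(b)^2) * (sum(c2^2) - n * mean(c2)^2))
  expect_equal(compare_divisions(b, c2)$pearson_r, r_brute, tolerance = 1e-12)
  expect_error(compare_divisions(a, a[-1]), class = "fd_validation_error")
})
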