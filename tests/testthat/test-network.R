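test_that("healthy template satisfies its construction contract", {
  net <- build_healthy_template(seed = 1)
  expect_s3_class(net, "aortic_network")
  expect_setequal(names(net$outlets), BRANCH_NAMES)
  expect_true(all(net$segments$radius_cm > 0))
  expect_true(all(net$segments$length_cm > 0))
  expect_silent(validate_network(net))
  # branch inlet areas are pi r^2 of each branch's first segment
  for (b in BRANCH_NAMES) {
    first <- net$segments[which(net$segments$branch %in% b)[1], ]
    expect_equal(net$branch_inlet_area[[b]], pi * first$radius_cm^2)
  }
})

test_that("template generation is deterministic under a seed", {
  expect_identical(build_healthy_template(seed = 42),
                   build_healthy_template(seed = 42))
  n1 <- build_healthy_template(seed = 1)
  n2 <- build_healthy_template(seed = 2)
  expect_false(identical(n1$segments$radius_cm, n2$segments$radius_cm))
})

test_that("invalid morphometry is rejected", {
  mp <- list(branches = within(flowdiv:::default_morphometry()$branches,
                               radius_cm[1] <- -1))
  expect_error(build_healthy_template(mp, seed = 1), class = "fd_validation_error")
  expect_error(build_healthy_template(list(jitter_sd = -0.1), seed = 1),
               class = "fd_validation_error")
})

test_that("ostial stenosis attaches only to the first segment of its branch", {
  net <- build_healthy_template(seed = 3)
  dis <- apply_lesion(net, lesion_spec("OSTIAL_STENOSIS", "CT", area_ratio = 0.25))
  seg <- dis$segments
  i <- which(seg$id == "CT_1")
  expect_equal(seg$sten_area_ratio[i], 0.25)
  expect_true(all(is.na(seg$sten_area_ratio[-i])))
  # geometry untouched otherwise
  expect_equal(seg[c("radius_cm", "length_cm", "from", "to")],
               net$segments[c("radius_cm", "length_cm", "from", "to")])
  expect_error(apply_lesion(net, lesion_spec("OSTIAL_STENOSIS", "XYZ",
                                             area_ratio = 0.5)),
               class = "fd_validation_error")
})

test_that("area_ratio 1 is hemodynamically inert", {
  net <- y_network()
  dis <- apply_lesion(net, lesion_spec("OSTIAL_STENOSIS", "LRA", area_ratio = 1))
  bcs <- resistance_bcs(c(LRA = 5, RRA = 5))
  a <- solve_steady(net, 100, bcs)
  b <- solve_steady(dis, 100, bcs)
  expect_lt(max(abs(a$Q - b$Q)), 1e-12)
  expect_lt(abs(a$P_in - b$P_in), 1e-12)
})

test_that("dissection splits the trunk into TL/FL chains joined by tears", {
  net <- build_healthy_template(seed = 7)
  les <- lesion_spec("DISSECTION", c(4L, 8L), tears = c(4L, 8L),
                     fl_branches = "RRA")
  dis <- apply_lesion(net, les)
  k <- 5L  # stations 4..8
  expect_equal(nrow(dis$segments), nrow(net$segments) + k + 2L)
  expect_equal(sum(dis$segments$lumen_tag == "TL"), k)
  expect_equal(sum(dis$segments$lumen_tag == "FL"), k)
  expect_equal(sum(dis$segments$lumen_tag == "TEAR"), 2L)
  expect_silent(validate_network(dis))        # still connected
  expect_setequal(names(dis$outlets), BRANCH_NAMES)
  # the false-lumen branch hangs off an FL node
  rra <- dis$segments[dis$segments$branch %in% "RRA", ]
  expect_match(rra$from, "_FL$")
  # tear outside the flap extent is rejected
  expect_error(lesion_spec("DISSECTION", c(4L, 8L), tears = 9L),
               class = "fd_validation_error")
})

test_that("repair undoes stenosis and aneurysm to radius tolerance 1e-9", {
  net <- build_healthy_template(seed = 11)
  sten <- apply_lesion(net, lesion_spec("OSTIAL_STENOSIS", "LCC", area_ratio = 0.3))
  fixed <- repair(sten)
  expect_lt(max(abs(fixed$segments$radius_cm - net$segments$radius_cm)), 1e-9)
  expect_true(all(is.na(fixed$segments$sten_area_ratio)))

  an_branch <- apply_lesion(net, lesion_spec("FUSIFORM_ANEURYSM", "BT",
                                             dilation = 2))
  expect_gt(an_branch$segments$radius_cm[an_branch$segments$id == "BT_1"],
            net$segments$radius_cm[net$segments$id == "BT_1"])
  expect_lt(max(abs(repair(an_branch)$segments$radius_cm -
                    net$segments$radius_cm)), 1e-9)

  an_trunk <- apply_lesion(net, lesion_spec("FUSIFORM_ANEURYSM", c(8L, 9L),
                                            dilation = 1.8))
  expect_lt(max(abs(repair(an_trunk)$segments$radius_cm -
                    net$segments$radius_cm)), 1e-9)
})

test_that("repair is idempotent on lesion-free input and clears lumen tags", {
  net <- build_healthy_template(seed = 5)
  expect_equal(repair(net), net)
  dis <- apply_lesion(net, lesion_spec("DISSECTION", c(4L, 8L),
                                       tears = c(5L, 7L), fl_branches = "RRA"))
  ref <- repair(dis)
  expect_true(all(ref$segments$lumen_tag == "NONE"))
  expect_equal(sort(ref$segments$id), sort(net$segments$id))
  expect_setequal(names(ref$outlets), BRANCH_NAMES)
  # merged trunk radii interpolate between the bounding healthy stations
  st <- ref$segments$station
  merged <- ref$segments$radius_cm[!is.na(st) & st >= 4 & st <= 8]
  r_lo <- net$segments$radius_cm[match(3L, net$segments$station)]
  r_hi <- net$segments$radius_cm[match(9L, net$segments$station)]
  expect_true(all(merged <= max(r_lo, r_hi) & merged >= min(r_lo, r_hi)))
})

test_that("generated cohorts are reproducible and pair diseased with repair", {
  c1 <- generate_cohort(3, seed = 7)
  c2 <- generate_cohort(3, seed = 7)
  expect_identical(c1, c2)
  expect_length(c1, 3L)
  for (pair in c1) {
    expect_equal(pair$reference, repair(pair$diseased))
    expect_silent(validate_network(pair$diseased))
    # solvability under a uniform split
    nb <- length(pair$diseased$outlets)
    uni <- fraction_bcs(stats::setNames(
      rep(1 / nb, nb), names(pair$diseased$outlets)))
    expect_s3_class(solve_steady(pair$diseased, 100, uni), "steady_result")
  }
  expect_error(generate_cohort(0, seed = 1), class = "fd_validation_error")

  sten_only <- generate_cohort(4, lesion_menu = list(
    lesion_spec("OSTIAL_STENOSIS", "CT", area_ratio = 0.4)), seed = 2)
  for (pair in sten_only)
    expect_gte(sum(!is.na(pair$diseased$segments$sten_area_ratio)), 1L)
})
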