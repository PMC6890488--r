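test_that("named generators hit their printed anchor points", {
  expect_equal(curve_generator("circle")$fun(0), cbind(1, 0),
               ignore_attr = TRUE)
  expect_equal(curve_generator("ellipse")$fun(0), cbind(3, 0),
               ignore_attr = TRUE)
  expect_equal(curve_generator("nonconvex")$fun(0), cbind(1, sin(1)),
               ignore_attr = TRUE, tolerance = 1e-12)
  p18 <- curve_generator("lpball")$fun(1 / 8)
  expect_equal(sqrt(sum(p18^2)), 2^(2 / 5), tolerance = 1e-12)
  expect_error(curve_generator("banana"), "unknown curve")
})

test_that("uniform-u sampling and equidistributed sampling both close the curve", {
  for (name in c("circle", "ellipse", "nonconvex", "selfintersect", "lpball")) {
    crv <- make_curve(name, 64, mesh = "uniform_u")
    expect_equal(nrow(crv), 64)
    expect_true(all(is.finite(crv$x)))
  }
  eq <- make_curve("circle", 32)
  expect_equal(nrow(eq), 32)
})

test_that("exact circle solutions are correct and guarded", {
  expect_equal(exact_circle_radius(0), 1)
  expect_equal(exact_circle_radius(0.25), sqrt(0.5))
  expect_error(exact_circle_radius(0.6), "t <= 0.5")
  expect_equal(exact_csf_area(pi, 0.25), pi / 2)
  expect_equal(exact_csf_area(5, 0), 5)
})

test_that("L2 area error matches its closed form for a constant offset", {
  # fabricate an evolution whose area is exact + c: the L2 norm is c sqrt(T)
  circ <- make_curve("circle", 64, monitor_spec("uniform"))
  ev <- evolve_curve(circ, 0.1, 25, scheme = "cnbe",
                     monitor = monitor_spec("uniform"), tau = 0.1,
                     p_mode = "identity")
  a0 <- ev$area[1]
  c_off <- 0.37
  rep1 <- area_error_l2(ev, function(t) exact_csf_area(a0, t) - c_off)
  rep0 <- area_error_l2(ev, function(t) exact_csf_area(a0, t))
  # the true error is ~1e-4; the offset dominates
  expect_equal(rep1$l2_norm, c_off * sqrt(0.1), tolerance = 1e-2)
  expect_lt(rep0$l2_norm, 1e-3)
  expect_equal(nrow(rep1$series), 26)
  # identically matching series gives zero
  rep_self <- area_error_l2(ev, function(t) {
    stats::approx(ev$times, ev$area, xout = t)$y
  })
  expect_equal(rep_self$l2_norm, 0)
})

test_that("convergence order recovers exact slopes", {
  expect_equal(convergence_order(c(10, 20), c(0.1, 0.05)), 1.0)
  expect_equal(convergence_order(c(10, 20, 40), c(1e-2, 2.5e-3, 6.25e-4)),
               2.0)
  expect_error(convergence_order(10, 0.1), "two")
  expect_error(convergence_order(c(10, 20), c(0.1, -1)), "positive")
})

test_that("picard_stats reports the per-step extremes", {
  circ <- make_curve("circle", 64, monitor_spec("uniform"))
  ev <- evolve_curve(circ, 0.05, 10, scheme = "be",
                     monitor = monitor_spec("uniform"), tau = 0.1,
                     p_mode = "identity")
  ps <- picard_stats(ev)
  expect_equal(ps[["max"]], max(ev$picard_iters))
  expect_equal(ps[["min"]], min(ev$picard_iters))
  capped <- evolve_curve(circ, 0.05, 10, scheme = "cnbe",
                         monitor = monitor_spec("uniform"), tau = 0.1,
                         p_mode = "identity", picard_cap = 2)
  expect_equal(unname(picard_stats(capped)), c(2, 2))
})

test_that("gold-standard comparison requires nested grids and is zero on itself", {
  circ <- make_curve("circle", 64, monitor_spec("uniform"))
  gold <- evolve_curve(circ, 0.1, 40, scheme = "cnbe",
                       monitor = monitor_spec("uniform"), tau = 0.1,
                       p_mode = "identity")
  coarse <- evolve_curve(circ, 0.1, 10, scheme = "cnbe",
                         monitor = monitor_spec("uniform"), tau = 0.1,
                         p_mode = "identity")
  self_rep <- gold_standard_error(gold, gold)
  expect_equal(self_rep$l2_norm, 0)
  expect_equal(self_rep$abs_final, 0)
  rep <- gold_standard_error(coarse, gold)
  expect_equal(rep$abs_final, abs(coarse$area[11] - gold$area[41]))
  bad <- evolve_curve(circ, 0.1, 7, scheme = "cnbe",
                      monitor = monitor_spec("uniform"), tau = 0.1,
                      p_mode = "identity")
  expect_error(gold_standard_error(gold, bad), "divide")
})

test_that("tidy and glance summarise an evolution", {
  circ <- make_curve("circle", 48, monitor_spec("uniform"))
  ev <- evolve_curve(circ, 0.05, 10, scheme = "cnbe",
                     monitor = monitor_spec("uniform"), tau = 0.1,
                     p_mode = "identity", record_edge_ratio = TRUE)
  td <- tidy(ev)
  expect_equal(nrow(td), 11)
  expect_named(td, c("step", "time", "area", "picard_iters", "edge_ratio"))
  expect_true(is.na(td$picard_iters[1]))
  gl <- glance(ev)
  expect_equal(gl$status, "completed")
  expect_equal(gl$n_nodes, 48L)
  snaps <- curve_snapshots(ev)
  expect_true(all(c(0, 10) %in% snaps$step))
})
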