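# Membrane dynamics and threshold search, driven by an analytic
# point-source extracellular field (independent of the FV solver).

test_that("the resting fiber is stable and silent", {
  ax <- build_axon_geometry(fx_traj(), 10, seed = 1)
  ve <- ve_point_source(ax$compartments$z, 100)
  expect_false(simulate_membrane(ax, ve, 0, window_ms = 10))
})

test_that("thresholds exist, bracket correctly, and scale linearly", {
  ax <- build_axon_geometry(fx_traj(), 10, seed = 1)
  ve <- ve_point_source(ax$compartments$z, 100)
  th <- find_threshold(ax, ve)
  expect_true(th$converged)
  expect_gt(th$threshold_nC, 0)
  expect_true(simulate_membrane(ax, ve, 2 * th$threshold_mA))
  expect_false(simulate_membrane(ax, ve, 0.5 * th$threshold_mA))
  # doubling the lead field halves the threshold
  th2 <- find_threshold(ax, 2 * ve)
  expect_equal(th2$threshold_mA / th$threshold_mA, 0.5, tolerance = 0.02)
  # determinism
  expect_identical(th$threshold_nC, find_threshold(ax, ve)$threshold_nC)
})

test_that("larger fibers are recruited first by a distant source", {
  d_src <- 1000
  th_of <- function(d) {
    ax <- build_axon_geometry(fx_traj(), d, seed = 1)
    find_threshold(ax, ve_point_source(ax$compartments$z, d_src))$threshold_nC
  }
  t57 <- th_of(5.7); t10 <- th_of(10); t14 <- th_of(14)
  expect_lt(t14, t57)
  expect_lt(t14, t10)
  expect_lt(t10, t57)
})

test_that("threshold grows with source distance", {
  ax <- build_axon_geometry(fx_traj(), 10, seed = 1)
  th <- vapply(c(100, 300, 1000), function(d)
    find_threshold(ax, ve_point_source(ax$compartments$z, d))$threshold_nC,
    numeric(1))
  expect_true(all(diff(th) > 0))
})

test_that("a spatially uniform field cannot excite the fiber", {
  ax <- build_axon_geometry(fx_traj(), 10, seed = 1)
  ve <- ve_point_source(ax$compartments$z, 100)
  th <- find_threshold(ax, ve)
  uni <- rep(0.5, nrow(ax$compartments))
  expect_false(simulate_membrane(ax, uni, 100 * th$threshold_mA))
})

test_that("current threshold decreases with pulse width (strength-duration)", {
  ax <- build_axon_geometry(fx_traj(), 10, seed = 1)
  ve <- ve_point_source(ax$compartments$z, 200)
  i50 <- find_threshold(ax, ve, pulse_us = 50)$threshold_mA
  i500 <- find_threshold(ax, ve, pulse_us = 500)$threshold_mA
  expect_lt(i500, i50)
})

test_that("unreachable fibers are flagged rather than fabricated", {
  ax <- build_axon_geometry(fx_traj(), 10, seed = 1)
  ve <- rep(0, nrow(ax$compartments))   # no coupling at all
  th <- find_threshold(ax, ve, max_amp_mA = 10)
  expect_true(th$unreachable)
  expect_identical(th$threshold_nC, Inf)
})

test_that("the activating function is the scaled nodal second difference", {
  ax <- build_axon_geometry(fx_traj(6e3), 10, seed = 2)
  n <- nrow(ax$compartments)
  expect_equal(max(abs(activating_function(rep(1, n), ax)), na.rm = TRUE), 0)
  # linear profile along the chain -> zero everywhere
  lin <- seq(0, 1, length.out = n)
  expect_lt(max(abs(activating_function(lin, ax)), na.rm = TRUE), 1e-9)
  # a single depolarized node: center value negative, sign flips with it
  nodes <- which(ax$compartments$type == "node")
  ve <- rep(0, n); ve[nodes[3]] <- 1e-3
  af <- activating_function(ve, ax)
  expect_lt(af[3], 0)
  expect_gt(af[2], 0)
  af_neg <- activating_function(-ve, ax)
  expect_equal(af_neg[3], -af[3])
  short <- ax; short$compartments <- ax$compartments[1:3, ]
  expect_error(activating_function(rep(0, 3), short), ">= 3 nodes")
})

test_that("the double-cable reference agrees with the reduced model's ordering", {
  ds <- c(5.7, 10, 14)
  d_src <- 300
  th_r <- th_f <- numeric(length(ds))
  for (i in seq_along(ds)) {
    axr <- build_axon_geometry(fx_traj(12e3), ds[i], seed = 1)
    axf <- build_axon_geometry(fx_traj(12e3), ds[i], seed = 1, detail = "full")
    th_r[i] <- find_threshold(axr, ve_point_source(axr$compartments$z, d_src),
                              dt_us = 2)$threshold_nC
    th_f[i] <- find_threshold(axf, ve_point_source(axf$compartments$z, d_src),
                              dt_us = 2)$threshold_nC
  }
  # identical recruitment order and same order of magnitude
  expect_identical(order(th_r), order(th_f))
  expect_true(all(th_f / th_r > 0.3 & th_f / th_r < 3))
})

test_that("rank correlation separates distance- and diameter-dominated recruitment", {
  # intrafascicular source: thresholds track distance more than diameter;
  # extrafascicular (distant) source: diameter dominates
  set.seed(5)
  n <- 24
  dists <- runif(n, 60, 900)
  diams <- sample(seq(3, 14, length.out = n))
  th_near <- th_far <- numeric(n)
  for (i in seq_len(n)) {
    ax <- build_axon_geometry(fx_traj(12e3), diams[i], seed = i)
    z <- ax$compartments$z
    th_near[i] <- find_threshold(ax, ve_point_source(z, dists[i]),
                                 dt_us = 2)$threshold_nC
    th_far[i] <- find_threshold(ax, ve_point_source(z, 2500 + dists[i] / 10),
                                dt_us = 2)$threshold_nC
  }
  rho_near_dist <- abs(cor(th_near, dists, method = "spearman"))
  rho_near_diam <- abs(cor(th_near, diams, method = "spearman"))
  rho_far_diam <- abs(cor(th_far, diams, method = "spearman"))
  rho_far_dist <- abs(cor(th_far, dists, method = "spearman"))
  expect_gt(rho_near_dist, rho_near_diam)
  expect_gt(rho_far_diam, rho_far_dist)
})
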