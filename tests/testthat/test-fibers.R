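# Fiber populations: diameter mixture, endoneurial seeding density, and
# MRG compartment geometry.

test_that("mixture sampling respects truncation and component selection", {
  d <- sample_diameters(5000, seed = 1)
  expect_true(all(d >= 1 & d <= 16))
  one <- sample_diameters(2000, diameter_mixture(weights = c(1, 0)), seed = 2)
  expect_lt(mean(one), 5)   # all draws from the 3.1 um component
  expect_error(diameter_mixture(weights = c(0, 0)), "degenerate")
  expect_identical(sample_diameters(100, seed = 9),
                   sample_diameters(100, seed = 9))
})

test_that("a two-component fit recovers the mixture means", {
  d <- sample_diameters(10000, seed = 4)
  mu <- fit_diameter_mixture(d)$means
  expect_equal(mu[1], 3.1, tolerance = 0.15)
  expect_equal(mu[2], 9.2, tolerance = 0.1)
  # small-fiber fraction consistent with the truncated mixture CDF
  mix <- diameter_mixture()
  p_small_raw <- sum(mix$weights * stats::pnorm(6, mix$means, mix$sds))
  expect_equal(mean(d < 6), p_small_raw, tolerance = 0.05)
})

test_that("axon seeding hits the target density and stays inside", {
  cs <- fx_pudendal_section()
  seeds <- place_axon_seeds(cs, seed = 5)
  per_f <- table(seeds$fascicle)
  areas <- vapply(cs$fascicles, `[[`, numeric(1), "endo_area")
  for (f in cs$fascicles) {
    n_f <- sum(seeds$fascicle == f$id)
    expect_equal(n_f, round(2330 * f$endo_area / 1e6))
    sel <- seeds$fascicle == f$id
    expect_true(all(points_in_polygon(seeds$u[sel], seeds$v[sel], f$endo)))
  }
  # realized density over all fascicles within 1%
  expect_equal(nrow(seeds) / (sum(areas) / 1e6), 2330, tolerance = 0.01)
  # counts scale linearly with endoneurial area
  fit <- stats::lm(as.numeric(per_f[as.character(seq_along(areas))]) ~ areas)
  expect_gt(summary(fit)$r.squared, 0.999)
})

test_that("population subsampling caps axons per fascicle", {
  nerve <- fx_toy_nerve()
  ax <- build_axon_population(nerve, seed = 6, max_per_fascicle = 5)
  expect_true(all(table(ax$fascicle) <= 5))
  expect_true(all(ax$diameter_um > 0))
  full <- build_axon_population(nerve, seed = 6)
  expect_identical(full, build_axon_population(nerve, seed = 6))
})

test_that("MRG geometry interpolates the published table", {
  p <- mrg_parameters(11.5)
  expect_equal(p$internode, 1250)
  expect_equal(p$node_d, 3.9)
  expect_equal(p$axon_d, 8.1)
  expect_equal(p$nl, 130)
  # interpolation between rows
  p2 <- mrg_parameters(7.0)
  expect_gt(p2$internode, 750 - 250)
  expect_lt(p2$internode, 1000)
  expect_error(mrg_parameters(0.5), "range")
  expect_error(mrg_parameters(25), "range")
})

test_that("MRG parameters stay positive and monotone over [1, 20] um", {
  dd <- seq(1, 20, by = 0.5)
  vals <- t(vapply(dd, function(d) {
    p <- mrg_parameters(d)
    c(p$internode, p$node_d, p$axon_d, p$stin_len, p$nl)
  }, numeric(5)))
  expect_true(all(vals > 0))
  for (j in 1:5) expect_true(all(diff(vals[, j]) > -1e-9))
})

test_that("compartment chains tile the trajectory correctly", {
  tr <- fx_traj(10e3)
  ax <- build_axon_geometry(tr, 10, seed = 3)
  nodes <- sum(ax$compartments$type == "node")
  expect_true(abs(nodes - floor(10e3 / ax$params$internode)) <= 1)
  expect_lt(ax$shift, ax$params$internode)
  ax2 <- build_axon_geometry(tr, 10, seed = 4)
  expect_false(identical(ax$shift, ax2$shift))
  # terminal compartments are nodes
  expect_identical(ax$compartments$type[1], "node")
  expect_identical(ax$compartments$type[nrow(ax$compartments)], "node")
  expect_error(build_axon_geometry(fx_traj(400), 10), "shorter")
})

test_that("full-detail chains follow the MRG section pattern", {
  ax <- build_axon_geometry(fx_traj(6e3), 10, seed = 1, detail = "full")
  tt <- ax$compartments$type
  expect_identical(tt[1:11],
                   c("node", "mysa", "flut", rep("stin", 6), "flut", "mysa"))
  expect_identical(tt[12], "node")
})

test_that("axon trajectories stay at their seed cross-section position", {
  nerve <- fx_toy_nerve()
  f <- nerve$section$fascicles[[2]]
  tr <- axon_trajectory(nerve, f$centroid[1], f$centroid[2])
  expect_equal(max(abs(tr$points[, 1] - f$centroid[1])), 0)
  expect_equal(max(tr$arclen), nerve$length)
})
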