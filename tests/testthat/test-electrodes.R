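# Electrode families, placement, and the displaced-volume invasiveness
# measure.

test_that("family geometries match their specifications", {
  is_ <- build_interstim()
  expect_equal(nrow(is_$sites), 4)
  expect_equal(active_site_area(is_$sites[1, ]), pi * 1270 * 3000)
  expect_equal(diff(sort(is_$sites$z_local))[1], 6000)  # 6 mm pitch

  cuff <- build_cuff()
  expect_equal(nrow(cuff$sites), 12)
  expect_equal(diff(cuff$sites$angle_deg)[1], 30)
  expect_equal(active_site_area(cuff$sites[1, ]), pi * 200^2)
  expect_equal(nrow(build_cuff(n_sites = 1)$sites), 1)

  tm <- build_time()
  expect_equal(nrow(tm$sites), 12)
  expect_equal(diff(range(tm$sites$chord_pos_um)), 2475)
  expect_equal(active_site_area(tm$sites[1, ]), pi * 40^2, tolerance = 1e-10)
  expect_setequal(unique(tm$sites$side), c(-1, 1))
  expect_equal(sum(tm$sites$side == 1), 6)

  air <- build_air()
  expect_equal(nrow(air$sites), 12)
  expect_equal(sum(air$sites$kind == "surface_disc"), 4)
  expect_equal(sum(air$sites$kind == "intrafascicular_tip"), 8)
  expect_equal(air$symmetry_angle, 90)
  expect_equal(nrow(build_air(n_heads = 3, spikes_per_head = 3)$sites), 12)
})

test_that("surface disc area is 25x and tip area 2.5x the 80 um disc", {
  a80 <- active_site_area(build_time()$sites[1, ])
  air <- build_air()
  a_surf <- active_site_area(air$sites[air$sites$kind == "surface_disc", ][1, ], air)
  a_tip <- active_site_area(air$sites[air$sites$kind == "intrafascicular_tip", ][1, ], air)
  expect_equal(a_surf / a80, 25)
  expect_equal(a_tip / a80, 2.5)
  zero <- build_cuff(site_diameter = 0)$sites[1, ]
  expect_equal(active_site_area(zero), 0)
})

test_that("cuff placement is invariant under its symmetry angle", {
  nerve <- fx_single_nerve()   # round nerve, centered fascicle
  p0 <- place_electrode(build_cuff(), nerve, list(angle = 0))
  p1 <- place_electrode(build_cuff(), nerve, list(angle = 30))
  # same set of positions up to relabeling
  d0 <- p0$sites[order(p0$sites$u, p0$sites$v), c("u", "v")]
  d1 <- p1$sites[order(p1$sites$u, p1$sites$v), c("u", "v")]
  expect_equal(as.matrix(d0), as.matrix(d1), tolerance = 0.05)
})

test_that("AIR standoffs follow the truncated-normal spacing statistics", {
  so <- nervestim:::standoff_sampler_default()(20000)
  expect_true(all(so >= 0))
  expect_equal(mean(so), 189, tolerance = 0.05)
  expect_equal(sd(so), 87, tolerance = 0.10)
})

test_that("intrafascicular placements stay inside the nerve or error", {
  nerve <- fx_pudendal_nerve()
  p <- place_electrode(build_time(), nerve, list(chord_angle = 0))
  inside <- points_in_polygon(p$sites$u, p$sites$v, nerve$section$epineurium)
  expect_true(all(inside))
  expect_error(place_electrode(build_time(), nerve, list(chord_angle = 90)),
               "exits the nerve")
  expect_error(
    place_electrode(build_air(spike_length = 5000), nerve, list(angle = 0)),
    "spike")
})

test_that("the quadripolar lead cannot be placed through the nerve", {
  nerve <- fx_toy_nerve()
  expect_error(place_electrode(build_interstim(), nerve,
                               list(corner_angle = 45, gap = -1000)),
               "intersects")
  p <- place_electrode(build_interstim(), nerve,
                       list(corner_angle = 45, gap = 500))
  expect_false(any(points_in_polygon(p$sites$u[1], p$sites$v[1],
                                     nerve$section$epineurium)))
})

test_that("displaced volume matches the analytic cylinder oracle", {
  # one spike fully inside a large centered fascicle
  cs <- synthesize_cross_section(2e6, 1, seed = 4, packing_fraction = 0.6)
  nerve <- sweep_nerve(cs, trajectory_straight(12e3))
  p <- place_electrode(build_air(n_heads = 1, spikes_per_head = 1,
                                 spike_length = 500, shank_diameter = 60),
                       nerve, list(angle = 0), seed = 1)
  vol <- displaced_endoneurial_volume(p, step = 5)
  # depth of endoneurium along the spike path
  sol <- p$solids[[2]]
  tt <- seq(2.5, 500, by = 5)
  u <- sol$entry_uv[1] + sol$dir_uv[1] * tt
  v <- sol$entry_uv[2] + sol$dir_uv[2] * tt
  L_in <- sum(points_in_polygon(u, v, cs$fascicles[[1]]$endo)) * 5
  expect_equal(vol, pi * 30^2 * L_in, tolerance = 0.02)
})

test_that("invasiveness is zero for extraneural and ordered for intraneural", {
  nerve <- fx_pudendal_nerve()
  vols <- vapply(c("cuff", "interstim", "air", "time"), function(fam) {
    des <- switch(fam, air = build_air(), cuff = build_cuff(),
                  time = build_time(), interstim = build_interstim())
    plc <- switch(fam, time = list(chord_angle = 0),
                  interstim = list(corner_angle = 45, gap = 500),
                  list(angle = 0))
    displaced_endoneurial_volume(place_electrode(des, nerve, plc, seed = 2))
  }, numeric(1))
  expect_equal(unname(vols["cuff"]), 0)
  expect_equal(unname(vols["interstim"]), 0)
  expect_gt(vols["air"], 0)
  expect_gt(vols["time"], vols["air"])
})

test_that("displaced volume grows with spike length and spikes per head", {
  nerve <- fx_pudendal_nerve()
  vol_of <- function(len, spk) {
    p <- place_electrode(build_air(spike_length = len, spikes_per_head = spk),
                         nerve, list(angle = 0), seed = 3)
    displaced_endoneurial_volume(p)
  }
  expect_lte(vol_of(400, 2), vol_of(600, 2))
  expect_lte(vol_of(600, 1), vol_of(600, 2))
  expect_lte(vol_of(600, 2), vol_of(600, 3))
})
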