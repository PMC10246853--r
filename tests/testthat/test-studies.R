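# Design studies on the cheap geometric objective.

fx_study_nerves <- function(n = 4) {
  cached(paste0("study_nerves", n), {
    lapply(seq_len(n), function(i)
      synthesize_nerve("pudendal", seed = 200 + i))
  })
}

test_that("the optimization grid returns its own argmax", {
  nerves <- fx_study_nerves(2)
  opt <- optimize_air_dimensions(nerves, pitch_grid = c(400, 600, 800),
                                 length_grid = c(300, 600, 900), seed = 1)
  expect_equal(nrow(opt$surface), 9)
  best_row <- opt$surface[which.max(opt$surface$mean_selectivity), ]
  expect_equal(opt$best$mean_selectivity, best_row$mean_selectivity)
  expect_s3_class(ggplot2::autoplot(opt), "ggplot")
})

test_that("a single centered fascicle is best reached at its depth", {
  # fascicle centroid at the nerve center: d_min hits zero once the tip
  # reaches the fascicle, so the optimum length is within one grid step
  # of the centroid depth
  cs <- synthesize_cross_section(1.5e6, 1, seed = 8, packing_fraction = 0.25)
  nerve <- sweep_nerve(cs, trajectory_straight(12e3))
  depth_grid <- seq(100, 650, by = 50)
  surf <- vapply(depth_grid, function(L) {
    pl <- tryCatch(place_electrode(build_air(spike_length = L, n_heads = 2),
                                   nerve, list(angle = 0), seed = 1),
                   error = function(e) NULL)
    if (is.null(pl)) return(NA_real_)
    st <- pl$sites[pl$sites$kind == "intrafascicular_tip", ]
    min(distance_to_contour(st$u, st$v, cs$fascicles[[1]]$outer))
  }, numeric(1))
  sp <- nervestim:::surface_point_at_angle(cs, 0)
  f_depth <- distance_to_contour(sp$point[1], sp$point[2],
                                 cs$fascicles[[1]]$outer)
  best_L <- depth_grid[which.min(surf)]
  expect_lt(abs(best_L - f_depth), 100)
})

test_that("site-count saturation shows shrinking increments", {
  nerves <- fx_study_nerves(4)
  sat_air <- site_count_saturation("air", c(6, 9, 12, 15), nerves, seed = 2)
  expect_true(all(diff(sat_air$mean_selectivity) >= -1e-9))
  sat_cuff <- site_count_saturation("cuff", c(4, 8, 12, 16, 20, 24),
                                    nerves, seed = 2)
  inc <- sat_cuff$increment_per_site[-1]
  # increments shrink toward a plateau
  expect_lt(mean(inc[(length(inc) - 1):length(inc)]), mean(inc[1:2]) + 1e-9)
  expect_error(site_count_saturation("air", c(5, 7), nerves), "multiples of 3")
})

test_that("already-perfect targets gain nothing from extra sites", {
  # one fascicle nerve with an intrafascicular site: geometric
  # selectivity is undefined for m = 1, so use a two-fascicle toy where
  # the target already holds a tip site
  cs <- synthesize_cross_section(1.2e6, 2, seed = 9, packing_fraction = 0.3)
  nerve <- sweep_nerve(cs, trajectory_straight(12e3))
  sp <- cbind(cs$fascicles[[1]]$centroid[1], cs$fascicles[[1]]$centroid[2])
  s1 <- geometric_selectivity(cs, sp, 1)
  expect_equal(s1, 1)
  extra <- rbind(sp, c(0, 0), c(200, 100))
  expect_equal(geometric_selectivity(cs, extra, 1), 1)
})

test_that("spikes-per-head increments are non-negative and saturate", {
  nerves <- fx_study_nerves(4)
  spk <- spikes_per_head_analysis(nerves, spikes = 1:3, seed = 3)
  expect_equal(nrow(spk), 3)
  expect_true(all(spk$increment_per_spike[-1] >= -1e-9))
  # prismatic nerves: the extra spike shares the 2D position, so the
  # third spike adds (essentially) nothing to the 2D surrogate
  expect_lt(spk$increment_per_spike[3], 0.01)
})

test_that("the adaptability scaling keeps AIR selectivity roughly flat", {
  res <- adaptability_study(scales = c(1, 4), n_nerves = 3, seed = 4)
  air <- dplyr::filter(res$results, electrode == "air")
  m <- tapply(air$selectivity, air$scale, mean)
  expect_lt(abs(m["4"] - m["1"]), 0.10)
  # surface sites help, and never hurt, at every scale
  wide <- tidyr::pivot_wider(
    dplyr::filter(res$results, electrode %in% c("air", "air_no_surface")),
    names_from = "electrode", values_from = "selectivity")
  expect_true(all(wide$air - wide$air_no_surface >= -1e-9))
  expect_s3_class(res$results, "tbl_df")
  expect_true(!is.null(res$anova))
})

test_that("diameter-class analysis returns exact zero gains for identical inputs", {
  thr <- tibble::tibble(
    axon = rep(1:10, 4),
    fascicle = rep(rep(1:2, each = 5), 4),
    diameter_um = rep(c(3, 4, 5, 9, 11, 3.5, 4.5, 8, 10, 12), 4),
    site = rep(1:4, each = 10),
    site_kind = rep(c("surface_disc", "surface_disc",
                      "intrafascicular_tip", "intrafascicular_tip"),
                    each = 10),
    threshold_nC = rep(stats::rlnorm(10, 1, 0.5), 4),
    converged = TRUE)
  class(thr) <- c("ns_thresholds", class(thr))
  res <- diameter_class_analysis(thr, tip_sites = c(3, 4))
  expect_equal(unname(res$gains["small"]), 0)
  expect_equal(unname(res$gains["large"]), 0)
  expect_equal(res$interaction_estimate, 0)
})
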