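# Synthetic nerve anatomy: contour generation, packing, scaling laws,
# and the swept 3D model.

test_that("fascicle contours hit the target area and are deterministic", {
  for (area in c(1e4, 2.5e5)) {
    cc <- generate_fascicle_contour(seed = 7, target_area = area)
    expect_equal(polygon_area(cc), area, tolerance = 0.005)
    expect_gte(nrow(cc), 16)
  }
  a <- generate_fascicle_contour(seed = 42, target_area = 1e4)
  b <- generate_fascicle_contour(seed = 42, target_area = 1e4)
  expect_identical(a, b)
  expect_false(identical(a, generate_fascicle_contour(seed = 43,
                                                      target_area = 1e4)))
})

test_that("spline smoothing stays within 2% of the hull area", {
  # oracle: the convex hull area computed directly from the same Gaussian
  # point sample that the generator draws
  for (seed in 1:10) {
    set.seed(seed)
    asp <- runif(1, 1, 2.5)
    th <- runif(1, 0, pi)
    pts <- cbind(rnorm(24, sd = asp), rnorm(24))
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    pts <- pts %*% t(R)
    hull <- pts[grDevices::chull(pts), ]
    hull_area <- polygon_area(hull)
    smooth <- nervestim:::periodic_spline_contour(
      nervestim:::ensure_ccw(hull), 64)
    expect_lte(polygon_area(smooth), hull_area * 1.02)
  }
})

test_that("equivalent diameter and perineurium thickness follow the closed forms", {
  expect_equal(equivalent_diameter(pi / 4 * 1e6), 1000)
  expect_equal(equivalent_diameter(0), 0)
  expect_equal(equivalent_diameter(1e6), 1128.379, tolerance = 1e-6)
  expect_equal(perineurium_thickness(pi / 4 * 1e6), 30)
  expect_equal(perineurium_thickness(0), 0)
  expect_equal(perineurium_thickness(1e6), 33.85138, tolerance = 1e-6)
  expect_error(equivalent_diameter(-1), "non-negative")
})

test_that("the 3% perineurium rule holds for every generated fascicle", {
  cs <- fx_pudendal_section()
  for (f in cs$fascicles) {
    expect_equal(f$peri_thickness / f$d_eq, 0.03, tolerance = 1e-12)
    # endoneurium strictly inside the outer contour
    expect_true(all(points_in_polygon(f$endo[, 1], f$endo[, 2], f$outer)))
  }
})

test_that("packing yields disjoint fascicles inside the epineurium across seeds", {
  n_bad_overlap <- 0L
  n_bad_inside <- 0L
  for (seed in 1:25) {
    cs <- synthesize_cross_section(1.2e6, 6, seed = seed, epi_aspect = 1.5)
    fs <- cs$fascicles
    for (i in seq_along(fs)) {
      if (!all(points_in_polygon(fs[[i]]$outer[, 1], fs[[i]]$outer[, 2],
                                 cs$epineurium)))
        n_bad_inside <- n_bad_inside + 1L
      if (i < length(fs)) for (j in (i + 1):length(fs)) {
        if (nervestim:::polygon_gap(fs[[i]]$outer, fs[[j]]$outer) <
            cs$min_gap * 0.99)
          n_bad_overlap <- n_bad_overlap + 1L
      }
    }
  }
  expect_identical(n_bad_overlap, 0L)
  expect_identical(n_bad_inside, 0L)
})

test_that("a single fascicle is centered when placement bias is disabled", {
  cs <- synthesize_cross_section(0.5e6, 1, seed = 5, packing_fraction = 0.4)
  epi_c <- nervestim:::polygon_centroid(cs$epineurium)
  f_c <- cs$fascicles[[1]]$centroid
  d_eq <- equivalent_diameter(cs$nerve_area)
  expect_lt(sqrt(sum((epi_c - f_c)^2)), 0.01 * d_eq)
})

test_that("infeasible packing fails with a diagnostic", {
  expect_error(
    synthesize_cross_section(2e5, 4, seed = 1, packing_fraction = 0.7,
                             min_gap = 400),
    "packing failed")
})

test_that("identical seeds reproduce bit-identical geometry", {
  a <- synthesize_cross_section(1e6, 5, seed = 99)
  b <- synthesize_cross_section(1e6, 5, seed = 99)
  expect_identical(a$epineurium, b$epineurium)
  for (k in seq_along(a$fascicles))
    expect_identical(a$fascicles[[k]]$outer, b$fascicles[[k]]$outer)
})

test_that("tissue labels are z-invariant for a straight sweep", {
  nerve <- fx_toy_nerve()
  cs <- nerve$section
  probe <- rbind(c(0, 0), cs$fascicles[[1]]$centroid,
                 c(nerve$r_max * 2, 0))
  for (z in c(-4000, 0, 3500)) {
    lab <- tissue_query(nerve, cbind(probe[, 1], probe[, 2], z))
    lab0 <- tissue_query(nerve, cbind(probe[, 1], probe[, 2], 0))
    expect_identical(lab, lab0)
  }
})

test_that("swept volume of an arc matches the Pappus oracle", {
  cs <- synthesize_cross_section(0.4e6, 1, seed = 3, packing_fraction = 0.3)
  radius <- 8e3
  nerve <- sweep_nerve(cs, trajectory_arc(radius, 90))
  # Monte-Carlo volume of the epineurium via the tissue query
  set.seed(1)
  n <- 200000
  half_z <- radius * sin(pi / 4)
  lo <- c(-radius * (1 - cos(pi / 4)) - 1200, -1200, -half_z - 1200)
  hi <- c(1200, 1200, half_z + 1200)
  pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
               runif(n, lo[3], hi[3]))
  lab <- tissue_query(nerve, pts)
  vol_box <- prod(hi - lo)
  vol_mc <- mean(lab != "saline") * vol_box
  vol_pappus <- cs$nerve_area * radius * pi / 2
  expect_equal(vol_mc, vol_pappus, tolerance = 0.02)
})

test_that("a sweep tighter than the nerve radius errors", {
  cs <- synthesize_cross_section(0.4e6, 1, seed = 3, packing_fraction = 0.3)
  expect_error(sweep_nerve(cs, trajectory_arc(100, 90)), "self-intersecting")
})

test_that("fascicle count scales with the nerve equivalent diameter", {
  ref <- synthesize_cross_section(1.2e6, 6, seed = 21, epi_aspect = 1.5)
  scales <- c(1, 2.25, 4, 9)
  n_mean <- numeric(length(scales))
  for (si in seq_along(scales)) {
    counts <- vapply(1:6, function(r) {
      cs <- scale_cross_section(ref, scales[si], seed = 100 * si + r)
      length(cs$fascicles)
    }, numeric(1))
    n_mean[si] <- mean(counts)
  }
  fit <- stats::lm(n_mean ~ sqrt(scales))
  expect_gt(suppressWarnings(summary(fit))$r.squared, 0.99)
  # area-scale 4 doubles the diameter and hence the fascicle count
  expect_equal(n_mean[3] / n_mean[1], 2, tolerance = 0.1)
})

test_that("scaled sections keep the fascicle-area to nerve-diameter ratio", {
  ref <- synthesize_cross_section(1.2e6, 6, seed = 22, epi_aspect = 1.5)
  ratio <- function(cs) {
    mean(vapply(cs$fascicles, `[[`, numeric(1), "area")) /
      equivalent_diameter(cs$nerve_area)
  }
  r1 <- mean(vapply(1:8, function(r)
    ratio(scale_cross_section(ref, 1, seed = r)), numeric(1)))
  r9 <- mean(vapply(1:8, function(r)
    ratio(scale_cross_section(ref, 9, seed = r)), numeric(1)))
  expect_equal(r9 / r1, 1, tolerance = 0.2)
  expect_error(scale_cross_section(list(), 2), "empty")
})

test_that("tidy() summarizes a cross-section", {
  td <- generics::tidy(fx_pudendal_section())
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 11)
  expect_true(all(td$peri_thickness_um / td$d_eq_um - 0.03 < 1e-12))
})
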