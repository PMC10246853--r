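# Finite-volume volume conduction: rasterization, closed-form oracles,
# linearity/superposition, conservation, and the perineurial sheet.

# all-saline raster on a uniform grid with a single synthetic disc site
homog_raster <- function(h = 150, half = 3000, zhalf = half) {
  g <- nervestim:::new_grid(seq(-half, half, by = h),
                            seq(-half, half, by = h),
                            seq(-zhalf, zhalf, by = h))
  stub <- structure(list(
    section = list(epineurium = matrix(c(1e6, 1e6 + 1, 1e6,
                                         1e6, 1e6, 1e6 + 1), 3, 2),
                   fascicles = list(), nerve_area = 1, seed = 1),
    trajectory = trajectory_straight(1), length = 1, r_max = 1,
    bone_block = NULL), class = "ns_nerve")
  r <- rasterize_tissues(stub, NULL, g)
  r$placed <- list(
    sites = tibble::tibble(site = 1, kind = "surface_disc", u = 0, v = 0,
                           du = 1, dv = 0, x = 0, y = 0, z = 0,
                           diameter_um = h),
    design = list(params = list(tip_exposure = 200)))
  r
}

test_that("an empty box rasterizes to isotropic saline", {
  r <- homog_raster(h = 300, half = 1500)
  expect_true(all(r$label == 0L))
  expect_true(all(r$sigma$x == 2) && all(r$sigma$y == 2) && all(r$sigma$z == 2))
})

test_that("endoneurial voxels carry the fiber-aligned tensor", {
  nerve <- fx_toy_nerve()
  placed <- place_electrode(build_cuff(n_sites = 4), nerve, list(angle = 0))
  r <- rasterize_tissues(nerve, placed, build_grid(placed, resolution = 40))
  endo <- r$label >= 10L
  expect_gt(sum(endo), 100)
  expect_true(all(r$sigma$z[endo] == 0.571))
  expect_true(all(r$sigma$x[endo] == 0.0826))
  expect_true(all(r$sigma$y[endo] == 0.0826))
  epi <- r$label == 1L
  expect_true(all(r$sigma$x[epi] == 0.0826))
  # the insulating wrap is present outside the nerve
  expect_gt(sum(r$label == 3L), 0)
  expect_true(all(r$sigma$x[r$label == 3L] == 1e-14))
})

test_that("perineurium sheet resistance follows thickness / sigma", {
  # 1 mm equivalent-diameter fascicle: 30 um / 0.00088 S/m = 0.0341 Ohm m^2
  t_p <- perineurium_thickness(pi / 4 * 1e6) * 1e-6
  expect_equal(t_p / 0.00088, 0.0341, tolerance = 0.001)
})

test_that("a compact source reproduces the Coulomb field", {
  r <- homog_raster()
  lf <- solve_lead_field(r, 1, tol = 1e-8)
  expect_lt(conservation_residual(lf), 1e-6)
  rr <- seq(750, 2250, by = 150)
  v <- sample_potentials(lf, cbind(rr, 0, 0))
  # fit V = a/r + c: the constant offset is the grounded-boundary image
  # term; the 1/r coefficient must match I / (4 pi sigma)
  fit <- stats::lm(v ~ I(1 / rr))
  a_th <- 1e-3 / (4 * pi * 2) * 1e6   # V um
  expect_equal(unname(stats::coef(fit)[2]) / a_th, 1, tolerance = 0.05)
})

test_that("an anisotropic medium reproduces the closed-form kernel", {
  sl <- 0.571; st <- 0.0826
  stretch <- sqrt(sl / st)
  h <- 150
  zh <- round(3000 * stretch / h) * h
  r <- homog_raster(h = h, half = 3000, zhalf = zh)
  hm <- h * 1e-6
  r$gx[] <- hm * st; r$gy[] <- hm * st; r$gz[] <- hm * sl
  r$diag_add[] <- 0
  nx <- dim(r$diag_add)[1]; ny <- dim(r$diag_add)[2]; nz <- dim(r$diag_add)[3]
  r$diag_add[1, , ] <- r$diag_add[1, , ] + 2 * hm * st
  r$diag_add[nx, , ] <- r$diag_add[nx, , ] + 2 * hm * st
  r$diag_add[, 1, ] <- r$diag_add[, 1, ] + 2 * hm * st
  r$diag_add[, ny, ] <- r$diag_add[, ny, ] + 2 * hm * st
  r$diag_add[, , 1] <- r$diag_add[, , 1] + 2 * hm * sl
  r$diag_add[, , nz] <- r$diag_add[, , nz] + 2 * hm * sl
  lf <- solve_lead_field(r, 1, tol = 1e-8)
  pts <- rbind(cbind(seq(750, 2250, 150), 0, 0),
               cbind(0, 0, seq(750, 2250, 150) * stretch),
               cbind(seq(600, 1500, 150), 0, seq(600, 1500, 150) * stretch))
  v <- sample_potentials(lf, pts)
  vth <- 1e-3 / (4 * pi * sqrt(st * (sl * (pts[, 1]^2 + pts[, 2]^2) * 1e-12 +
                                       st * pts[, 3]^2 * 1e-12)))
  fit <- stats::lm(v ~ vth)
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 0.07)
  off <- unname(stats::coef(fit)[1])
  expect_true(all(abs((v - off) / vth - 1) < 0.07))
})

test_that("the lead field is linear in the injected current", {
  r <- homog_raster(h = 300, half = 1500)
  lf1 <- solve_lead_field(r, 1, current_mA = 1, tol = 1e-10)
  lf2 <- solve_lead_field(r, 1, current_mA = 2, tol = 1e-10)
  expect_equal(lf2$v, 2 * lf1$v, tolerance = 1e-6)
})

test_that("fields of two sources superpose", {
  r <- homog_raster(h = 300, half = 1500)
  r$placed$sites <- dplyr::bind_rows(
    r$placed$sites,
    dplyr::mutate(r$placed$sites, site = 2, x = 600, u = 600))
  lf1 <- solve_lead_field(r, 1, tol = 1e-10)
  lf2 <- solve_lead_field(r, 2, tol = 1e-10)
  # drive both together by adding the RHS contributions: solve manually
  g <- r$grid
  b <- numeric(g$nx * g$ny * g$nz)
  b[lf1$source_idx] <- 1e-3 / length(lf1$source_idx)
  b[lf2$source_idx] <- b[lf2$source_idx] - 1e-3 / length(lf2$source_idx)
  sol <- nervestim:::pcg_structured(g$nx, g$ny, g$nz, as.vector(r$gx),
                                    as.vector(r$gy), as.vector(r$gz),
                                    as.vector(r$diag_add), b, tol = 1e-10)
  both <- array(sol$v, dim(lf1$v))
  expect_equal(both, lf1$v - lf2$v, tolerance = 1e-5)
  # net boundary flux of the dipole pair is (nearly) zero
  expect_lt(abs(sum(r$diag_add * both)) / 1e-3, 1e-6)
})

test_that("potential decays monotonically along a ray from the source", {
  r <- homog_raster()
  lf <- solve_lead_field(r, 1, tol = 1e-8)
  rr <- seq(450, 2700, by = 150)
  v <- sample_potentials(lf, cbind(rr / sqrt(2), rr / sqrt(2), 0))
  expect_true(all(diff(v) < 0))
})

test_that("trilinear sampling is exact on affine fields and handles outside points", {
  r <- homog_raster(h = 300, half = 1500)
  g <- r$grid
  aff <- function(x, y, z) 0.3 + 2 * x - 0.5 * y + 0.25 * z
  fld <- array(0, c(g$nx, g$ny, g$nz))
  for (k in seq_len(g$nz)) for (j in seq_len(g$ny))
    fld[, j, k] <- aff(g$xc, g$yc[j], g$zc[k])
  lf <- structure(list(grid = g, v = fld, site = 1, current_mA = 1,
                       raster = r), class = "ns_leadfield")
  set.seed(1)
  pts <- cbind(runif(50, -1300, 1300), runif(50, -1300, 1300),
               runif(50, -1300, 1300))
  expect_equal(sample_potentials(lf, pts),
               aff(pts[, 1], pts[, 2], pts[, 3]), tolerance = 1e-10)
  out_pt <- matrix(c(5000, 0, 0), 1)
  expect_error(sample_potentials(lf, out_pt), "outside")
  expect_equal(sample_potentials(lf, out_pt, outside = "zero"), 0)
  # a grid point returns the stored value
  expect_equal(sample_potentials(lf, matrix(c(g$xc[3], g$yc[4], g$zc[5]), 1)),
               fld[3, 4, 5])
})

test_that("the perineurial sheet flattens within-fascicle potentials", {
  nerve <- fx_toy_nerve()
  placed <- place_electrode(build_cuff(n_sites = 4), nerve, list(angle = 0))
  g <- build_grid(placed, resolution = 40)
  range_for <- function(sheet) {
    # sample a ring well inside the endoneurium so the interpolation
    # stencil does not straddle the sheet discontinuity
    r <- rasterize_tissues(nerve, placed, g, perineurium_sheet = sheet)
    lf <- solve_lead_field(r, 1, tol = 1e-7)
    f <- nerve$section$fascicles[[1]]
    pts <- cbind(f$centroid[1] + 0.7 * (f$endo[, 1] - f$centroid[1]),
                 f$centroid[2] + 0.7 * (f$endo[, 2] - f$centroid[2]), 0)
    v <- sample_potentials(lf, pts)
    diff(range(v))
  }
  expect_lt(range_for(TRUE), range_for(FALSE))
})

test_that("conservation residual is reported and zero current is defined", {
  r <- homog_raster(h = 300, half = 1500)
  lf <- solve_lead_field(r, 1, tol = 1e-8)
  expect_lt(conservation_residual(lf), 10 * 1e-8 + 1e-7)
  lf0 <- lf; lf0$current_mA <- 0; lf0$v[] <- 0
  expect_equal(conservation_residual(lf0), 0)
})

test_that("grids refuse under-resolved nerves", {
  nerve <- fx_toy_nerve()
  placed <- place_electrode(build_cuff(n_sites = 4), nerve, list(angle = 0))
  expect_error(build_grid(placed, resolution = 300), "resolution")
})
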