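# Shared small fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, force(expr), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# Small 3-fascicle straight nerve (fast packing, fast rasters)
fx_toy_nerve <- function() cached("toy_nerve", toy_nerve(seed = 11))

# Round single-fascicle nerve with a centered fascicle, for symmetry and
# streamline tests
fx_single_nerve <- function() cached("single_nerve", {
  cs <- synthesize_cross_section(0.5e6, 1, seed = 2, packing_fraction = 0.4)
  sweep_nerve(cs, trajectory_straight(6e3))
})

# Flattened multi-fascicle preset section (pudendal-like geometry)
fx_pudendal_section <- function() cached("pud_cs",
  synthesize_preset_section("pudendal", seed = 3))

fx_pudendal_nerve <- function() cached("pud_nerve",
  sweep_nerve(fx_pudendal_section(), trajectory_straight(20e3)))

# Analytic extracellular potential (V per mA) of a point source at
# perpendicular distance d_um from a straight fiber along z in anisotropic
# endoneurium; used as an independent field for membrane-level tests.
ve_point_source <- function(z_um, d_um, sl = 0.571, st = 0.0826) {
  1e-3 / (4 * pi * sqrt(st * (sl * d_um^2 * 1e-12 + st * z_um^2 * 1e-12)))
}

# Straight 20 mm trajectory reused by cable tests
fx_traj <- function(len = 20e3, step = 100) {
  z <- seq(-len / 2, len / 2, by = step)
  list(points = cbind(0, 0, z), arclen = z - z[1])
}

# Exactly 4-fold symmetric nerve: circular epineurium with four identical
# circular fascicles at 90 degree spacing, for rotation-invariance tests.
fx_symmetric_nerve <- function() cached("sym_nerve", {
  circle <- function(cx, cy, r, n = 64) {
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    cbind(cx + r * cos(th), cy + r * sin(th))
  }
  r_f <- 130
  fas <- lapply(0:3, function(k) {
    a <- k * pi / 2
    nervestim:::new_fascicle_section(circle(320 * cos(a), 320 * sin(a), r_f),
                                     pi * r_f^2, k + 1)
  })
  cs <- structure(list(epineurium = circle(0, 0, 620), fascicles = fas,
                       nerve_area = pi * 620^2, min_gap = 20, seed = 0),
                  class = "ns_cross_section")
  sweep_nerve(cs, trajectory_straight(12e3))
})
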