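# Anisotropic volume conduction on rectilinear finite-volume grids:
# current conservation div(sigma grad V) = 0 with a unit current source on
# the active site, fiber-aligned endoneurial conductivity, a thin-sheet
# perineurium on fascicle-boundary faces, and Dirichlet V = 0 on the outer
# box boundary. Face conductances use harmonic averaging; the SPD system
# is solved by Jacobi-preconditioned conjugate gradients.

#' Tissue conductivities
#'
#' Default conductivities (S/m): endoneurium 0.571 longitudinal / 0.0826
#' transverse, epineurium 0.0826, perineurium 0.00088, saline 2, electrode
#' substrate 1e-14, bone 0.02.
#'
#' @param endoneurium_l,endoneurium_t,epineurium,perineurium,saline,substrate,bone
#'   Conductivities in S/m.
#' @return Named list.
#' @export
ns_conductivities <- function(endoneurium_l = 0.571, endoneurium_t = 0.0826,
                              epineurium = 0.0826, perineurium = 0.00088,
                              saline = 2, substrate = 1e-14, bone = 0.02) {
  as.list(environment())
}

# Cell-edge axis with a uniform fine core and geometrically stretched
# cells out to the box limits.
stretched_axis <- function(fine_lo, fine_hi, h, lo, hi, ratio = 1.3) {
  stopifnot(fine_lo < fine_hi, lo <= fine_lo, hi >= fine_hi)
  n_f <- max(2L, ceiling((fine_hi - fine_lo) / h))
  core <- seq(fine_lo, fine_hi, length.out = n_f + 1)
  h0 <- core[2] - core[1]
  down <- numeric(0); e <- fine_lo; w <- h0
  while (e > lo + 1e-9) {
    w <- w * ratio
    e <- max(e - w, lo)
    if (lo - (e - w) > 0 || e - lo < w * 0.4) e <- lo   # absorb tiny last cell
    down <- c(e, down)
  }
  up <- numeric(0); e <- fine_hi; w <- h0
  while (e < hi - 1e-9) {
    w <- w * ratio
    e <- min(e + w, hi)
    if (hi - e < w * 0.4) e <- hi
    up <- c(up, e)
  }
  unique(c(down, core, up))
}

# Bounding box of the swept nerve in world coordinates.
nerve_world_bbox <- function(nerve, n_stations = 15) {
  s <- seq(0, nerve$length, length.out = n_stations)
  epi <- nerve$section$epineurium
  lo <- c(Inf, Inf, Inf); hi <- -lo
  for (si in s) {
    w <- section_to_world(nerve, epi[, 1], epi[, 2], rep(si, nrow(epi)))
    lo <- pmin(lo, apply(w, 2, min)); hi <- pmax(hi, apply(w, 2, max))
  }
  list(lo = lo, hi = hi)
}

#' Build a simulation grid around a placed electrode
#'
#' Rectilinear grid: uniform `resolution` over the nerve cross-section
#' (plus `fine_margin`), geometrically stretched cells through the saline
#' padding (at least `padding` nerve equivalent diameters on each
#' transverse side), and an axial spacing refined over the electrode span.
#'
#' @param placed An `ns_placed`.
#' @param resolution Transverse voxel size in the fine region, um.
#' @param padding Saline padding in nerve equivalent diameters.
#' @param z_resolution Axial voxel size over the electrode span, um
#'   (default scales with the span).
#' @param fine_margin Transverse fine-region margin beyond the nerve, um.
#' @return An `ns_grid` (cell edges and centers per axis).
#' @export
build_grid <- function(placed, resolution = 60, padding = 2,
                       z_resolution = NULL, fine_margin = 300) {
  nerve <- placed$nerve
  bb <- nerve_world_bbox(nerve)
  D <- equivalent_diameter(nerve$section$nerve_area)
  if (resolution > D / 20)
    stop("resolution too coarse: nerve diameter must span >= 20 voxels")
  # electrode extents that must live inside the box
  ex_lo <- c(Inf, Inf); ex_hi <- -ex_lo
  for (sol in placed$solids) {
    if (sol$type == "lead") {
      ex_lo <- pmin(ex_lo, sol$axis_uv - sol$radius - 300)
      ex_hi <- pmax(ex_hi, sol$axis_uv + sol$radius + 300)
    }
  }
  sxy <- cbind(placed$sites$x, placed$sites$y)
  ex_lo <- pmin(ex_lo, apply(sxy, 2, min) - 300)
  ex_hi <- pmax(ex_hi, apply(sxy, 2, max) + 300)
  xlo <- min(bb$lo[1] - padding * D, ex_lo[1])
  xhi <- max(bb$hi[1] + padding * D, ex_hi[1])
  ylo <- min(bb$lo[2] - padding * D, ex_lo[2])
  yhi <- max(bb$hi[2] + padding * D, ex_hi[2])
  xe <- stretched_axis(bb$lo[1] - fine_margin, bb$hi[1] + fine_margin,
                       resolution, xlo, xhi)
  ye <- stretched_axis(bb$lo[2] - fine_margin, bb$hi[2] + fine_margin,
                       resolution, ylo, yhi)
  z_span <- range(placed$sites$z)
  fine_z <- c(z_span[1] - 1000, z_span[2] + 1000)
  fine_z[1] <- max(fine_z[1], bb$lo[3]); fine_z[2] <- min(fine_z[2], bb$hi[3])
  if (is.null(z_resolution))
    z_resolution <- max(2 * resolution, (fine_z[2] - fine_z[1]) / 100)
  ze <- stretched_axis(fine_z[1], fine_z[2], z_resolution, bb$lo[3], bb$hi[3])
  new_grid(xe, ye, ze)
}

new_grid <- function(xe, ye, ze) {
  structure(list(
    xe = xe, ye = ye, ze = ze,
    xc = (xe[-1] + xe[-length(xe)]) / 2,
    yc = (ye[-1] + ye[-length(ye)]) / 2,
    zc = (ze[-1] + ze[-length(ze)]) / 2,
    dx = diff(xe), dy = diff(ye), dz = diff(ze),
    nx = length(xe) - 1L, ny = length(ye) - 1L, nz = length(ze) - 1L
  ), class = "ns_grid")
}

#' Uniform grid over an explicit box (testing and small analytic problems)
#' @param lo,hi Length-3 box corners (um).
#' @param h Voxel size (um).
#' @return An `ns_grid`.
#' @export
uniform_grid <- function(lo, hi, h) {
  new_grid(seq(lo[1], hi[1], by = h), seq(lo[2], hi[2], by = h),
           seq(lo[3], hi[3], by = h))
}

#' @export
print.ns_grid <- function(x, ...) {
  cat("<ns_grid>", x$nx, "x", x$ny, "x", x$nz, "voxels (",
      x$nx * x$ny * x$nz, "total )\n")
  invisible(x)
}

# label codes
LBL_SALINE <- 0L; LBL_EPI <- 1L; LBL_BONE <- 2L; LBL_SUBSTRATE <- 3L
LBL_ENDO0 <- 10L   # endoneurium of fascicle f -> 10 + f

#' Rasterize tissues and electrode solids onto a grid
#'
#' Assigns a tissue label and a diagonal conductivity tensor to every
#' voxel (endoneurial tensors aligned with the local fiber direction) and
#' precomputes finite-volume face conductances with harmonic averaging.
#' The perineurium enters as a thin resistive sheet (thickness / sigma_p)
#' in series on every face crossing a fascicle boundary, so it never needs
#' to be resolved by the voxel size. Electrode substrates are insulating.
#'
#' @param nerve An `ns_nerve`.
#' @param placed Optional `ns_placed` whose solids are rasterized.
#' @param grid An `ns_grid`.
#' @param conductivities See [ns_conductivities()].
#' @param perineurium_sheet Include the perineurial sheet (default TRUE;
#'   disabling it is only meant for sensitivity analyses).
#' @return An `ns_raster` with label array, sigma arrays and face
#'   conductances (SI units).
#' @export
rasterize_tissues <- function(nerve, placed = NULL, grid,
                              conductivities = ns_conductivities(),
                              perineurium_sheet = TRUE) {
  cn <- conductivities
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  straight <- nerve$trajectory$kind == "straight"
  cs <- nerve$section

  if (straight) {
    xy <- cbind(rep(grid$xc, ny), rep(grid$yc, each = nx))
    lab2 <- integer(nx * ny)            # 0 saline, 1 epi, 10+f endo-of-outer
    in_epi <- points_in_polygon(xy[, 1], xy[, 2], cs$epineurium)
    lab2[in_epi] <- LBL_EPI
    fid2 <- integer(nx * ny)
    for (f in cs$fascicles) {
      idx <- which(in_epi & fid2 == 0L)
      if (length(idx) == 0) break
      hit <- points_in_polygon(xy[idx, 1], xy[idx, 2], f$outer)
      fid2[idx[hit]] <- f$id
    }
    lab2[fid2 > 0L] <- LBL_ENDO0 + fid2[fid2 > 0L]
    dist_epi2 <- points_to_polygon_boundary(xy[, 1], xy[, 2], cs$epineurium)
    dist_epi2[in_epi] <- 0
    lab <- array(rep(lab2, nz), c(nx, ny, nz))
    fid <- array(rep(fid2, nz), c(nx, ny, nz))
  } else {
    pts <- cbind(rep(grid$xc, times = ny * nz),
                 rep(rep(grid$yc, each = nx), times = nz),
                 rep(grid$zc, each = nx * ny))
    tl <- tissue_query(nerve, pts)
    lab <- array(LBL_SALINE, c(nx, ny, nz))
    lab[tl == "epineurium"] <- LBL_EPI
    fid <- array(0L, c(nx, ny, nz))
    endo <- startsWith(tl, "endoneurium:") | startsWith(tl, "perineurium:")
    fid[endo] <- as.integer(sub(".*:", "", tl[endo]))
    lab[endo] <- LBL_ENDO0 + fid[endo]
  }

  # bone block
  if (!is.null(nerve$bone_block)) {
    bbk <- nerve$bone_block
    inx <- grid$xc >= bbk$min[1] & grid$xc <= bbk$max[1]
    iny <- grid$yc >= bbk$min[2] & grid$yc <= bbk$max[2]
    inz <- grid$zc >= bbk$min[3] & grid$zc <= bbk$max[3]
    sel <- outer(outer(inx, iny, "&"), inz, "&") & lab == LBL_SALINE
    lab[sel] <- LBL_BONE
  }

  # electrode solids
  if (!is.null(placed)) {
    s_mid <- nerve$length / 2
    for (sol in placed$solids) {
      if (sol$type == "wrap" && straight) {
        ring2 <- dist_epi2 > 1e-9 & dist_epi2 <= sol$thickness + sol$standoff
        zin <- abs(grid$zc - sol$s_center) <= sol$length / 2
        sel <- array(outer(ring2, zin, "&"), c(nx, ny, nz)) & lab == LBL_SALINE
        lab[sel] <- LBL_SUBSTRATE
      } else if (sol$type == "lead") {
        r2 <- outer((grid$xc - sol$axis_uv[1])^2, (grid$yc - sol$axis_uv[2])^2, "+")
        incyl2 <- r2 <= sol$radius^2
        zsub <- rep(TRUE, nz)
        for (bcz in sol$band_centers)
          zsub <- zsub & !(abs(grid$zc - bcz) <= sol$band_length / 2)
        sel <- array(outer(incyl2, zsub, "&"), c(nx, ny, nz)) & lab == LBL_SALINE
        lab[sel] <- LBL_SUBSTRATE
      }
      # needle shanks / ribbons are thinner than a voxel: omitted from the
      # raster (their exposed contacts still act as sources)
    }
  }

  # diagonal conductivity tensors (S/m)
  sx <- array(cn$saline, c(nx, ny, nz)); sy <- sx; sz <- sx
  sx[lab == LBL_EPI] <- cn$epineurium; sy[lab == LBL_EPI] <- cn$epineurium
  sz[lab == LBL_EPI] <- cn$epineurium
  sx[lab == LBL_BONE] <- cn$bone; sy[lab == LBL_BONE] <- cn$bone
  sz[lab == LBL_BONE] <- cn$bone
  sx[lab == LBL_SUBSTRATE] <- cn$substrate; sy[lab == LBL_SUBSTRATE] <- cn$substrate
  sz[lab == LBL_SUBSTRATE] <- cn$substrate
  endo_sel <- lab >= LBL_ENDO0
  if (any(endo_sel)) {
    if (straight) {
      sx[endo_sel] <- cn$endoneurium_t
      sy[endo_sel] <- cn$endoneurium_t
      sz[endo_sel] <- cn$endoneurium_l
    } else {
      idx <- which(endo_sel)
      pts <- cbind(rep(grid$xc, times = ny * nz)[idx],
                   rep(rep(grid$yc, each = nx), times = nz)[idx],
                   rep(grid$zc, each = nx * ny)[idx])
      tg <- trajectory_tangent_at(nerve, local_coordinates(nerve, pts)$s)
      sl <- cn$endoneurium_l; st <- cn$endoneurium_t
      sx[idx] <- tg[, 1]^2 * sl + (1 - tg[, 1]^2) * st
      sy[idx] <- tg[, 2]^2 * sl + (1 - tg[, 2]^2) * st
      sz[idx] <- tg[, 3]^2 * sl + (1 - tg[, 3]^2) * st
    }
  }

  # perineurial sheet resistivity per fascicle (Ohm m^2)
  tp <- vapply(cs$fascicles, `[[`, numeric(1), "peri_thickness") * 1e-6
  rs_f <- tp / cn$perineurium
  sheet_res <- function(fa, fb) {
    r <- numeric(length(fa))
    diffm <- fa != fb
    r[diffm & fa > 0L] <- r[diffm & fa > 0L] + rs_f[fa[diffm & fa > 0L]]
    r[diffm & fb > 0L] <- r[diffm & fb > 0L] + rs_f[fb[diffm & fb > 0L]]
    r
  }

  um <- 1e-6
  dxm <- grid$dx * um; dym <- grid$dy * um; dzm <- grid$dz * um
  # x faces
  A_x <- outer(dym, dzm)                     # ny x nz
  s1 <- sx[-nx, , , drop = FALSE]; s2 <- sx[-1, , , drop = FALSE]
  d1 <- array(dxm[-nx] / 2, c(nx - 1, ny, nz))
  d2 <- array(dxm[-1] / 2, c(nx - 1, ny, nz))
  Rx <- if (perineurium_sheet)
    array(sheet_res(as.vector(fid[-nx, , ]), as.vector(fid[-1, , ])),
          c(nx - 1, ny, nz)) else array(0, c(nx - 1, ny, nz))
  gx <- array(rep(as.vector(A_x), each = nx - 1), c(nx - 1, ny, nz)) /
    (d1 / s1 + d2 / s2 + Rx)
  # y faces
  A_y <- outer(dxm, dzm)                     # nx x nz
  s1 <- sy[, -ny, , drop = FALSE]; s2 <- sy[, -1, , drop = FALSE]
  d1 <- array(rep(dym[-ny] / 2, each = nx), c(nx, ny - 1, nz))
  d2 <- array(rep(dym[-1] / 2, each = nx), c(nx, ny - 1, nz))
  Ry <- if (perineurium_sheet)
    array(sheet_res(as.vector(fid[, -ny, ]), as.vector(fid[, -1, ])),
          c(nx, ny - 1, nz)) else array(0, c(nx, ny - 1, nz))
  Ay_full <- array(0, c(nx, ny - 1, nz))
  for (k in seq_len(nz)) Ay_full[, , k] <- matrix(dxm * dzm[k], nx, ny - 1)
  gy <- Ay_full / (d1 / s1 + d2 / s2 + Ry)
  # z faces
  s1 <- sz[, , -nz, drop = FALSE]; s2 <- sz[, , -1, drop = FALSE]
  d1 <- array(rep(dzm[-nz] / 2, each = nx * ny), c(nx, ny, nz - 1))
  d2 <- array(rep(dzm[-1] / 2, each = nx * ny), c(nx, ny, nz - 1))
  Rz <- if (perineurium_sheet)
    array(sheet_res(as.vector(fid[, , -nz]), as.vector(fid[, , -1])),
          c(nx, ny, nz - 1)) else array(0, c(nx, ny, nz - 1))
  Az_full <- array(outer(dxm, dym), c(nx, ny, nz - 1))
  gz <- Az_full / (d1 / s1 + d2 / s2 + Rz)

  # Dirichlet V = 0 on the outer boundary: half-cell conductances
  diag_add <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    diag_add[1, , k] <- diag_add[1, , k] + (dym * dzm[k]) / (dxm[1] / 2 / sx[1, , k])
    diag_add[nx, , k] <- diag_add[nx, , k] + (dym * dzm[k]) / (dxm[nx] / 2 / sx[nx, , k])
    diag_add[, 1, k] <- diag_add[, 1, k] + (dxm * dzm[k]) / (dym[1] / 2 / sy[, 1, k])
    diag_add[, ny, k] <- diag_add[, ny, k] + (dxm * dzm[k]) / (dym[ny] / 2 / sy[, ny, k])
  }
  diag_add[, , 1] <- diag_add[, , 1] + outer(dxm, dym) / (dzm[1] / 2 / sz[, , 1])
  diag_add[, , nz] <- diag_add[, , nz] + outer(dxm, dym) / (dzm[nz] / 2 / sz[, , nz])

  structure(list(grid = grid, label = lab, fid = fid,
                 sigma = list(x = sx, y = sy, z = sz),
                 gx = gx, gy = gy, gz = gz, diag_add = diag_add,
                 conductivities = cn,
                 perineurium_sheet = perineurium_sheet,
                 nerve = nerve, placed = placed),
            class = "ns_raster")
}

#' @export
print.ns_raster <- function(x, ...) {
  cat("<ns_raster>", x$grid$nx, "x", x$grid$ny, "x", x$grid$nz, "voxels;",
      sum(x$label >= LBL_ENDO0), "endoneurial voxels\n")
  invisible(x)
}

# local tangent of the nerve trajectory at arc length s (n x 3)
trajectory_tangent_at <- function(nerve, s) {
  tr <- nerve$trajectory
  if (tr$kind == "straight")
    return(matrix(rep(c(0, 0, 1), each = length(s)), length(s)))
  phi <- s / tr$radius - (tr$angle_deg * pi / 180) / 2
  cbind(-sin(phi), 0, cos(phi))
}

# Identify source voxels for an active site. Returns linear voxel indices.
site_source_voxels <- function(raster, placed, site_row) {
  g <- raster$grid
  nx <- g$nx; ny <- g$ny; nz <- g$nz
  h <- min(g$dx)
  st <- site_row
  if (st$kind == "band") {
    r2 <- outer((g$xc - st$u)^2, (g$yc - st$v)^2, "+")
    incyl <- r2 <= (st$diameter_um / 2 + h / 2)^2
    zin <- abs(g$zc - st$z) <= st$band_length_um / 2
    idx <- which(array(outer(incyl, zin, "&"), c(nx, ny, nz)))
  } else if (st$kind == "surface_disc") {
    # voxels within the disc radius of the center, within one cell of the
    # disc plane
    n3 <- c(st$du, st$dv, 0)
    px <- rep(g$xc, times = ny * nz) - st$x
    py <- rep(rep(g$yc, each = nx), times = nz) - st$y
    pz <- rep(g$zc, each = nx * ny) - st$z
    dn <- px * n3[1] + py * n3[2] + pz * n3[3]
    dt2 <- px^2 + py^2 + pz^2 - dn^2
    idx <- which(abs(dn) <= h * 0.75 & dt2 <= (st$diameter_um / 2 + h / 2)^2)
  } else {  # intrafascicular tip: exposed segment ending at the tip
    exposure <- placed$design$params$tip_exposure
    p1 <- c(st$x, st$y, st$z)
    dir3 <- c(st$du, st$dv, 0)
    p0 <- p1 - dir3 * exposure
    px <- rep(g$xc, times = ny * nz)
    py <- rep(rep(g$yc, each = nx), times = nz)
    pz <- rep(g$zc, each = nx * ny)
    vx <- p1 - p0; L2 <- sum(vx^2)
    tpar <- ((px - p0[1]) * vx[1] + (py - p0[2]) * vx[2] + (pz - p0[3]) * vx[3]) / L2
    tpar <- pmin(1, pmax(0, tpar))
    qx <- p0[1] + tpar * vx[1]; qy <- p0[2] + tpar * vx[2]; qz <- p0[3] + tpar * vx[3]
    d2 <- (px - qx)^2 + (py - qy)^2 + (pz - qz)^2
    rad <- max(st$diameter_um / 2, h * 0.51)
    idx <- which(d2 <= rad^2)
  }
  if (length(idx) == 0) {
    # fallback: nearest voxel to the site center
    ix <- which.min(abs(g$xc - st$x))
    iy <- which.min(abs(g$yc - st$y))
    iz <- which.min(abs(g$zc - st$z))
    idx <- ix + nx * ((iy - 1) + ny * (iz - 1))
  }
  # never inject inside the insulating substrate
  ok <- raster$label[idx] != LBL_SUBSTRATE
  if (any(ok)) idx <- idx[ok]
  idx
}

#' Solve the lead field of one active site
#'
#' Unit (or `current_mA`) current injection distributed uniformly over the
#' source voxels of the active site, grounded (V = 0) outer boundary.
#'
#' @param raster An `ns_raster` (with the electrode rasterized).
#' @param site Site id (row of `placed$sites`).
#' @param current_mA Injected current (default 1 mA).
#' @param tol PCG relative tolerance.
#' @return An `ns_leadfield`: potential array (V), solver diagnostics,
#'   source voxel indices.
#' @export
solve_lead_field <- function(raster, site, current_mA = 1, tol = 1e-8) {
  placed <- raster$placed
  if (is.null(placed)) stop("raster was built without a placed electrode")
  st <- placed$sites[placed$sites$site == site, ]
  if (nrow(st) != 1) stop("unknown site id: ", site)
  g <- raster$grid
  idx <- site_source_voxels(raster, placed, st)
  b <- numeric(g$nx * g$ny * g$nz)
  I_A <- current_mA * 1e-3
  b[idx] <- I_A / length(idx)
  sol <- pcg_structured(g$nx, g$ny, g$nz,
                        as.vector(raster$gx), as.vector(raster$gy),
                        as.vector(raster$gz), as.vector(raster$diag_add),
                        b, tol = tol)
  if (sol$relres > tol * 10)
    stop("lead-field solver did not converge: relative residual ",
         signif(sol$relres, 3))
  structure(list(grid = g, v = array(sol$v, c(g$nx, g$ny, g$nz)),
                 site = site, current_mA = current_mA,
                 iterations = sol$iter, relres = sol$relres,
                 source_idx = idx, raster = raster),
            class = "ns_leadfield")
}

#' @export
print.ns_leadfield <- function(x, ...) {
  cat("<ns_leadfield> site", x$site, "-", x$current_mA, "mA;",
      x$iterations, "PCG iterations, relres", signif(x$relres, 2), "\n")
  invisible(x)
}

#' Sample extracellular potentials at points
#'
#' Trilinear interpolation of the lead-field potential at arbitrary
#' points (e.g. axon compartment centers).
#'
#' @param lead_field An `ns_leadfield`.
#' @param pts n x 3 matrix (um).
#' @param outside `"error"` (default) or `"zero"`: potentials for points
#'   outside the solved box (the outer boundary is grounded, so zero is
#'   the consistent far-field continuation).
#' @return Potentials in volts at the solved current.
#' @export
sample_potentials <- function(lead_field, pts, outside = c("error", "zero")) {
  outside <- match.arg(outside)
  g <- lead_field$grid
  out <- trilinear_interp(g$xc, g$yc, g$zc, as.vector(lead_field$v), pts,
                          g$xe[1], g$xe[length(g$xe)],
                          g$ye[1], g$ye[length(g$ye)],
                          g$ze[1], g$ze[length(g$ze)],
                          outside = if (outside == "zero") 1L else 0L)
  if (outside == "error" && anyNA(out))
    stop("point(s) outside the solved grid")
  out
}

#' Discrete conservation audit
#'
#' Net current leaving through the grounded outer boundary compared with
#' the injected current.
#'
#' @param lead_field An `ns_leadfield`.
#' @return |boundary flux - injected| / injected (0 for zero injection).
#' @export
conservation_residual <- function(lead_field) {
  raster <- lead_field$raster
  I_A <- lead_field$current_mA * 1e-3
  flux <- sum(raster$diag_add * lead_field$v)
  if (I_A == 0) return(if (flux == 0) 0 else Inf)
  abs(flux - I_A) / abs(I_A)
}
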