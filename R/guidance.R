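# Fiber-direction guidance field: a Laplace (steady diffusion) problem on
# the endoneurial interior of one fascicle, with inlet/outlet Dirichlet
# values on the fascicle end faces and zero-flux lateral walls. The
# normalized gradient gives the local fiber tangent; its streamlines are
# axon trajectories intrinsically aligned with the conductivity
# anisotropy.

#' Solve the guidance field of one fascicle
#'
#' @param nerve An `ns_nerve`.
#' @param fascicle Fascicle id.
#' @param resolution Voxel size, um.
#' @return An `ns_guidance`: grid, scalar solution, interior mask, and
#'   unit tangent arrays.
#' @export
solve_guidance_field <- function(nerve, fascicle = 1, resolution = 25) {
  f <- NULL
  for (ff in nerve$section$fascicles) if (ff$id == fascicle) f <- ff
  if (is.null(f)) stop("no fascicle with id ", fascicle)
  # bounding box of the swept endoneurium
  s_st <- seq(0, nerve$length, length.out = 31)
  lo <- c(Inf, Inf, Inf); hi <- -lo
  for (si in s_st) {
    w <- section_to_world(nerve, f$endo[, 1], f$endo[, 2],
                          rep(si, nrow(f$endo)))
    lo <- pmin(lo, apply(w, 2, min)); hi <- pmax(hi, apply(w, 2, max))
  }
  lo <- lo - resolution; hi <- hi + resolution
  g <- uniform_grid(lo, hi, resolution)
  nx <- g$nx; ny <- g$ny; nz <- g$nz
  pts <- cbind(rep(g$xc, times = ny * nz),
               rep(rep(g$yc, each = nx), times = nz),
               rep(g$zc, each = nx * ny))
  lc <- local_coordinates(nerve, pts)
  inside <- rep(FALSE, nrow(pts))
  sel <- lc$s >= 0 & lc$s <= nerve$length
  inside[sel] <- points_in_polygon(lc$u[sel], lc$v[sel], f$endo)
  mask <- array(inside, c(nx, ny, nz))
  if (sum(mask) < 8) stop("fascicle interior not resolved at this resolution")

  # unit face conductances between interior voxels, zero at walls
  mk <- function(a, b) as.numeric(a & b)
  gx <- array(mk(mask[-nx, , ], mask[-1, , ]), c(nx - 1, ny, nz))
  gy <- array(mk(mask[, -ny, ], mask[, -1, ]), c(nx, ny - 1, nz))
  gz <- array(mk(mask[, , -nz], mask[, , -1]), c(nx, ny, nz - 1))
  # Dirichlet 1/0 at the inlet/outlet end faces, applied by penalty on the
  # voxels of the first and last axial slabs of the fascicle
  s_arr <- array(lc$s, c(nx, ny, nz))
  slab <- 1.5 * resolution
  inlet <- mask & s_arr <= slab
  outlet <- mask & s_arr >= nerve$length - slab
  if (!any(inlet) || !any(outlet)) stop("fascicle end faces not found")
  G_big <- 100
  diag_add <- array(0, c(nx, ny, nz))
  diag_add[inlet] <- G_big
  diag_add[outlet] <- G_big
  b <- numeric(nx * ny * nz)
  b[which(inlet)] <- G_big * 1
  sol <- pcg_structured(nx, ny, nz, as.vector(gx), as.vector(gy),
                        as.vector(gz), as.vector(diag_add), b, tol = 1e-8)
  if (sol$relres > 1e-6)
    stop("guidance-field solver did not converge: relres ",
         signif(sol$relres, 3))
  v <- array(sol$v, c(nx, ny, nz))

  # tangent = normalized negative gradient (flow from inlet to outlet),
  # one-sided differences at walls
  tx <- ty <- tz <- array(0, c(nx, ny, nz))
  grad_axis <- function(v, mask, axis, h) {
    n <- dim(v)
    gshift <- function(arr, k) {
      # shift along `axis` by k with edge replication
      idx <- lapply(n, seq_len)
      idx[[axis]] <- pmin(pmax(idx[[axis]] + k, 1), n[axis])
      do.call(`[`, c(list(arr), idx))
    }
    vp <- gshift(v, 1); vm <- gshift(v, -1)
    mp <- gshift(mask, 1); mm <- gshift(mask, -1)
    num <- (vp - vm); den <- array(2 * h, n)
    one_p <- mask & mp & !mm
    one_m <- mask & !mp & mm
    num[one_p] <- (vp - v)[one_p]; den[one_p] <- h
    num[one_m] <- (v - vm)[one_m]; den[one_m] <- h
    flat <- mask & !mp & !mm
    num[flat] <- 0
    num / den
  }
  h <- resolution
  gxv <- grad_axis(v, mask, 1, h)
  gyv <- grad_axis(v, mask, 2, h)
  gzv <- grad_axis(v, mask, 3, h)
  mag <- sqrt(gxv^2 + gyv^2 + gzv^2)
  ok <- mask & mag > 1e-12
  tx[ok] <- -gxv[ok] / mag[ok]
  ty[ok] <- -gyv[ok] / mag[ok]
  tz[ok] <- -gzv[ok] / mag[ok]
  structure(list(grid = g, v = v, mask = mask,
                 tangent = list(x = tx, y = ty, z = tz),
                 fascicle = fascicle, nerve = nerve,
                 resolution = resolution, relres = sol$relres),
            class = "ns_guidance")
}

#' @export
print.ns_guidance <- function(x, ...) {
  cat("<ns_guidance> fascicle", x$fascicle, "-", sum(x$mask),
      "interior voxels at", x$resolution, "um\n")
  invisible(x)
}

guidance_dir_at <- function(gf, pts) {
  g <- gf$grid
  bb <- c(g$xe[1], g$xe[length(g$xe)], g$ye[1], g$ye[length(g$ye)],
          g$ze[1], g$ze[length(g$ze)])
  d <- cbind(
    trilinear_interp(g$xc, g$yc, g$zc, as.vector(gf$tangent$x), pts,
                     bb[1], bb[2], bb[3], bb[4], bb[5], bb[6], outside = 2L),
    trilinear_interp(g$xc, g$yc, g$zc, as.vector(gf$tangent$y), pts,
                     bb[1], bb[2], bb[3], bb[4], bb[5], bb[6], outside = 2L),
    trilinear_interp(g$xc, g$yc, g$zc, as.vector(gf$tangent$z), pts,
                     bb[1], bb[2], bb[3], bb[4], bb[5], bb[6], outside = 2L))
  d
}

#' Trace a fiber streamline through the guidance field
#'
#' Fixed-step 4th-order Runge-Kutta integration of the tangent field in
#' both directions from the seed until the first and last cross-sections
#' are reached; vertices are projected back into the fascicle endoneurium
#' on wall contact.
#'
#' @param guidance An `ns_guidance`.
#' @param seed_point Length-3 world point (um) inside the fascicle.
#' @param step Integration step, um.
#' @return List: `points` (n x 3), `arclen`.
#' @export
trace_streamline <- function(guidance, seed_point, step = 50) {
  nerve <- guidance$nerve
  f <- NULL
  for (ff in nerve$section$fascicles) if (ff$id == guidance$fascicle) f <- ff
  lc0 <- local_coordinates(nerve, matrix(seed_point, 1))
  if (!points_in_polygon(lc0$u, lc0$v, f$endo))
    stop("seed point outside the fascicle endoneurium")
  d0 <- guidance_dir_at(guidance, matrix(seed_point, 1))
  if (sqrt(sum(d0^2)) < 1e-3) stop("stagnation: guidance gradient vanishes at the seed")

  project_in <- function(p) {
    lc <- local_coordinates(nerve, matrix(p, 1))
    if (points_in_polygon(lc$u, lc$v, f$endo)) return(p)
    # pull the cross-section position to the nearest endoneurium vertex
    dd <- sqrt((f$endo[, 1] - lc$u)^2 + (f$endo[, 2] - lc$v)^2)
    j <- which.min(dd)
    c0 <- polygon_centroid(f$endo)
    tgt <- f$endo[j, ] + 0.02 * (c0 - f$endo[j, ])
    as.vector(section_to_world(nerve, tgt[1], tgt[2], min(max(lc$s, 0), nerve$length)))
  }
  march <- function(p0, sgn) {
    pts <- list()
    p <- p0
    for (i in seq_len(ceiling(2 * nerve$length / step) + 10)) {
      dirf <- function(q) {
        d <- guidance_dir_at(guidance, matrix(q, 1))
        nrm <- sqrt(sum(d^2))
        if (nrm < 1e-6) return(NULL)
        sgn * d / nrm
      }
      k1 <- dirf(p); if (is.null(k1)) break
      k2 <- dirf(p + step / 2 * k1); if (is.null(k2)) k2 <- k1
      k3 <- dirf(p + step / 2 * k2); if (is.null(k3)) k3 <- k2
      k4 <- dirf(p + step * k3); if (is.null(k4)) k4 <- k3
      p <- p + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      p <- project_in(p)
      s_here <- local_coordinates(nerve, matrix(p, 1))$s
      pts[[length(pts) + 1]] <- p
      if (s_here <= 0 || s_here >= nerve$length) break
    }
    pts
  }
  fwd <- march(seed_point, +1)
  bwd <- march(seed_point, -1)
  allp <- c(rev(bwd), list(seed_point), fwd)
  pts <- do.call(rbind, allp)
  seg <- sqrt(rowSums(diff(pts)^2))
  list(points = pts, arclen = c(0, cumsum(seg)))
}
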