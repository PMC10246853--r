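# Posing electrode designs on a nerve: world coordinates for every active
# site, substrate/needle solids for the rasterizer, and the displaced
# endoneurial volume (invasiveness) measure.

# Intersection of the ray from the epineurium centroid at `angle_deg`
# with the epineurium contour. Returns the surface point and the unit
# outward radial direction in cross-section (u, v) coordinates.
surface_point_at_angle <- function(cs, angle_deg) {
  c0 <- polygon_centroid(cs$epineurium)
  th <- angle_deg * pi / 180
  dir <- c(cos(th), sin(th))
  p <- cs$epineurium
  a <- sweep(p, 2, c0)
  b <- sweep(rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE]), 2, c0)
  t_best <- Inf
  for (j in seq_len(nrow(p))) {
    e <- b[j, ] - a[j, ]
    den <- dir[1] * (-e[2]) - dir[2] * (-e[1])
    if (abs(den) < 1e-12) next
    t <- (a[j, 1] * (-e[2]) - a[j, 2] * (-e[1])) / den
    u <- (dir[1] * a[j, 2] - dir[2] * a[j, 1]) / den
    if (t > 0 && u >= 0 && u <= 1 && t < t_best) t_best <- t
  }
  if (!is.finite(t_best)) stop("ray does not intersect epineurium")
  list(point = c0 + t_best * dir, dir = dir, radius = t_best)
}

# Truncated-normal standoff sampler (>= 0) matching the assumed
# surface-site-to-nerve spacing statistics.
standoff_sampler_default <- function(mean = 189, sd = 87) {
  function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      repeat { x <- stats::rnorm(1, mean, sd); if (x >= 0) break }
      out[i] <- x
    }
    out
  }
}

#' Place an electrode design on a nerve
#'
#' Computes world coordinates of every active site and the solid geometry
#' (insulating substrate, needle shanks) used by the volume-conduction
#' rasterizer and the invasiveness measure.
#'
#' Placement parameters by family:
#' \describe{
#'   \item{cuff/air}{`angle`: rotation about the nerve axis (deg);
#'     `axial_offset`: shift of the device center along the nerve (um);
#'     `standoff`: number or sampler function for the surface-site gap
#'     (um; AIR defaults to a truncated normal with mean 189, sd 87).}
#'   \item{time}{`chord_angle`: direction of the insertion chord (deg);
#'     `chord_offset`: perpendicular offset of the chord from the
#'     epineurium centroid (um).}
#'   \item{interstim}{`corner_angle`: direction from the nerve center to
#'     the lead axis (deg); `gap`: surface-to-surface clearance (um).}
#' }
#'
#' @param design An `ns_electrode`.
#' @param nerve An `ns_nerve`.
#' @param placement Named list of placement parameters (see Details).
#' @param seed Integer seed for the standoff draws.
#' @return An object of class `ns_placed` with a `sites` tibble
#'   (site, kind, world x/y/z, cross-section u/v, standoff).
#' @export
place_electrode <- function(design, nerve, placement = list(), seed = NULL) {
  cs <- nerve$section
  s_mid <- nerve$length / 2
  angle <- placement$angle %||% 0
  ax_off <- placement$axial_offset %||% 0
  with_seed(seed, {
    placed <- switch(design$family,
      cuff = place_cuff(design, nerve, angle, ax_off, placement$standoff %||% 0),
      air = place_air(design, nerve, angle, ax_off,
                      placement$standoff %||% standoff_sampler_default()),
      time = place_time(design, nerve, placement$chord_angle %||% 0,
                        placement$chord_offset %||% 0, ax_off),
      interstim = place_interstim(design, nerve,
                                  placement$corner_angle %||% 45,
                                  placement$gap %||% 500),
      stop("unknown electrode family: ", design$family))
  })
  sites <- placed$sites
  w <- section_to_world(nerve, sites$u, sites$v, s_mid + ax_off + sites$z_local)
  sites$x <- w[, 1]; sites$y <- w[, 2]; sites$z <- w[, 3]
  structure(list(design = design, nerve = nerve, sites = sites,
                 solids = placed$solids, placement = placement,
                 axial_offset = ax_off),
            class = "ns_placed")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

place_cuff <- function(design, nerve, angle, ax_off, standoff) {
  cs <- nerve$section
  st <- design$sites
  n <- nrow(st)
  so <- if (is.function(standoff)) standoff(n) else rep(standoff, n)
  u <- v <- du <- dv <- numeric(n)
  for (i in seq_len(n)) {
    sp <- surface_point_at_angle(cs, st$angle_deg[i] + angle)
    u[i] <- sp$point[1] + sp$dir[1] * so[i]
    v[i] <- sp$point[2] + sp$dir[2] * so[i]
    du[i] <- sp$dir[1]; dv[i] <- sp$dir[2]
  }
  sites <- tibble::tibble(site = st$site, kind = st$kind, head = NA_integer_,
                          u = u, v = v, z_local = st$z_local,
                          du = du, dv = dv, standoff = so,
                          diameter_um = st$diameter_um)
  solids <- list(list(type = "wrap", s_center = ax_off,
                      length = design$params$substrate_length,
                      thickness = design$params$substrate_thickness,
                      standoff = 0))
  list(sites = sites, solids = solids)
}

place_air <- function(design, nerve, angle, ax_off, standoff) {
  cs <- nerve$section
  st <- design$sites
  p <- design$params
  n <- nrow(st)
  is_surf <- st$kind == "surface_disc"
  so <- rep(0, n)
  so[is_surf] <- if (is.function(standoff)) standoff(sum(is_surf)) else
    rep(standoff, sum(is_surf))
  u <- v <- du <- dv <- numeric(n)
  solids <- list(list(type = "wrap", s_center = ax_off,
                      length = p$spike_pitch * (p$spikes_per_head - 1) + 600,
                      thickness = p$substrate_thickness,
                      standoff = 0))
  for (i in seq_len(n)) {
    sp <- surface_point_at_angle(cs, st$angle_deg[i] + angle)
    if (is_surf[i]) {
      u[i] <- sp$point[1] + sp$dir[1] * so[i]
      v[i] <- sp$point[2] + sp$dir[2] * so[i]
      du[i] <- sp$dir[1]; dv[i] <- sp$dir[2]
    } else {
      # needle from the surface toward the centroid, tip at spike_length
      tip <- sp$point - sp$dir * p$spike_length
      if (!points_in_polygon(tip[1], tip[2], cs$epineurium))
        stop("AIR spike tip exits the nerve (spike_length too large for ",
             "this placement)")
      u[i] <- tip[1]; v[i] <- tip[2]
      du[i] <- -sp$dir[1]; dv[i] <- -sp$dir[2]
      solids[[length(solids) + 1]] <- list(
        type = "needle", entry_uv = sp$point, dir_uv = -sp$dir,
        length = p$spike_length, radius = p$shank_diameter / 2,
        z_local = st$z_local[i] + ax_off)
    }
  }
  sites <- tibble::tibble(site = st$site, kind = st$kind, head = st$head,
                          u = u, v = v, z_local = st$z_local,
                          du = du, dv = dv, standoff = so,
                          diameter_um = st$diameter_um)
  list(sites = sites, solids = solids)
}

place_time <- function(design, nerve, chord_angle, chord_offset, ax_off) {
  cs <- nerve$section
  p <- design$params
  c0 <- polygon_centroid(cs$epineurium)
  th <- chord_angle * pi / 180
  dir <- c(cos(th), sin(th))         # along the chord
  nrm <- c(-sin(th), cos(th))        # shaft normal (side direction)
  base <- c0 + nrm * chord_offset
  st <- design$sites
  u <- base[1] + dir[1] * st$chord_pos_um
  v <- base[2] + dir[2] * st$chord_pos_um
  if (!all(points_in_polygon(u, v, cs$epineurium)))
    stop("TIME insertion chord exits the nerve: site(s) outside the ",
         "epineurium for this chord angle/offset")
  sites <- tibble::tibble(site = st$site, kind = st$kind, head = NA_integer_,
                          u = u, v = v, z_local = st$z_local,
                          du = nrm[1] * st$side, dv = nrm[2] * st$side,
                          standoff = 0, diameter_um = st$diameter_um)
  solids <- list(list(type = "ribbon", base_uv = base, dir_uv = dir,
                      half_span = p$span / 2 + 150,
                      width = p$ribbon_width, thickness = p$ribbon_thickness,
                      z_local = ax_off))
  if (isTRUE(p$conservative_track))
    solids[[2]] <- list(type = "track", base_uv = base, dir_uv = dir,
                        half_span = p$span / 2 + 150,
                        radius = p$needle_track / 2, z_local = ax_off)
  list(sites = sites, solids = solids)
}

place_interstim <- function(design, nerve, corner_angle, gap) {
  cs <- nerve$section
  p <- design$params
  sp <- surface_point_at_angle(cs, corner_angle)
  axis_uv <- sp$point + sp$dir * (gap + p$lead_diameter / 2)
  if (any(points_in_polygon(axis_uv[1], axis_uv[2], cs$epineurium)))
    stop("InterStim lead axis intersects the nerve")
  st <- design$sites
  sites <- tibble::tibble(site = st$site, kind = st$kind, head = NA_integer_,
                          u = axis_uv[1], v = axis_uv[2], z_local = st$z_local,
                          du = -sp$dir[1], dv = -sp$dir[2],
                          standoff = gap,
                          diameter_um = st$diameter_um,
                          band_length_um = st$band_length_um)
  solids <- list(list(type = "lead", axis_uv = axis_uv,
                      radius = p$lead_diameter / 2,
                      band_centers = st$z_local, band_length = p$band_length))
  list(sites = sites, solids = solids)
}

#' @export
print.ns_placed <- function(x, ...) {
  cat("<ns_placed>", x$design$family, "on",
      length(x$nerve$section$fascicles), "fascicle nerve;",
      nrow(x$sites), "sites\n")
  invisible(x)
}

#' Endoneurial volume displaced by intraneural electrode parts
#'
#' Numerically integrates the intersection of the electrode's intraneural
#' solids (needle shanks, intrafascicular shafts, optional needle track)
#' with the endoneurial tissue regions. Fully extraneural electrodes
#' (cuff, quadripolar lead) displace no endoneurium.
#'
#' @param placed An `ns_placed`.
#' @param step Integration grid step, um (error below ~2% at the default).
#' @return Displaced volume, um^3.
#' @export
displaced_endoneurial_volume <- function(placed, step = 10) {
  nerve <- placed$nerve
  cs <- nerve$section
  total <- 0
  in_endo <- function(u, v) {
    inside <- rep(FALSE, length(u))
    for (f in cs$fascicles) {
      idx <- !inside
      if (!any(idx)) break
      inside[idx] <- points_in_polygon(u[idx], v[idx], f$endo)
    }
    inside
  }
  for (sol in placed$solids) {
    if (sol$type == "needle") {
      # sample along the axis; cross-section area constant (cylinder)
      tt <- seq(step / 2, sol$length - step / 2, by = step)
      u <- sol$entry_uv[1] + sol$dir_uv[1] * tt
      v <- sol$entry_uv[2] + sol$dir_uv[2] * tt
      frac <- in_endo(u, v)
      total <- total + sum(frac) * step * pi * sol$radius^2
    } else if (sol$type == "ribbon") {
      tt <- seq(-sol$half_span + step / 2, sol$half_span - step / 2, by = step)
      u <- sol$base_uv[1] + sol$dir_uv[1] * tt
      v <- sol$base_uv[2] + sol$dir_uv[2] * tt
      frac <- in_endo(u, v)
      total <- total + sum(frac) * step * sol$width * sol$thickness
    } else if (sol$type == "track") {
      tt <- seq(-sol$half_span + step / 2, sol$half_span - step / 2, by = step)
      u <- sol$base_uv[1] + sol$dir_uv[1] * tt
      v <- sol$base_uv[2] + sol$dir_uv[2] * tt
      frac <- in_endo(u, v)
      total <- total + sum(frac) * step * pi * sol$radius^2
    }
    # "wrap" and "lead" solids are extraneural: no displaced endoneurium
  }
  total
}
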