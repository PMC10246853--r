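# 3D nerve models: a cross-section swept along a trajectory, with a
# tissue-label query used by the volume-conduction rasterizer.

#' Straight trajectory along the z axis
#'
#' @param length Trajectory length (um).
#' @param n Number of stations.
#' @return An `ns_trajectory`: centerline points with
#'   tangent/normal/binormal frames, arc-length parameterized, centered on
#'   z = 0 (the central cross-section).
#' @export
trajectory_straight <- function(length, n = 41) {
  z <- seq(-length / 2, length / 2, length.out = n)
  structure(list(
    points = cbind(0, 0, z),
    tangent = matrix(rep(c(0, 0, 1), each = n), n),
    normal = matrix(rep(c(1, 0, 0), each = n), n),
    binormal = matrix(rep(c(0, 1, 0), each = n), n),
    arclen = z - z[1], length = length, kind = "straight"
  ), class = "ns_trajectory")
}

#' Circular-arc trajectory
#'
#' An arc of given radius in the x-z plane, arc-length parameterized and
#' centered so that the central cross-section (s = L/2) sits at the origin
#' with tangent +z. The cross-section normal axis (local x) points away
#' from the arc center.
#'
#' @param radius Arc radius (um).
#' @param angle_deg Swept angle in degrees.
#' @param n Number of stations.
#' @return An `ns_trajectory`.
#' @export
trajectory_arc <- function(radius, angle_deg, n = 81) {
  phi <- seq(-1, 1, length.out = n) * (angle_deg * pi / 180) / 2
  # arc center at (-radius, 0, 0); s = 0 mid-arc at origin
  pts <- cbind(radius * (cos(phi) - 1), 0, radius * sin(phi))
  tang <- cbind(-sin(phi), 0, cos(phi))
  norm <- cbind(cos(phi), 0, sin(phi))   # radially outward
  bin <- matrix(rep(c(0, 1, 0), each = n), n)
  L <- radius * (angle_deg * pi / 180)
  structure(list(points = pts, tangent = tang, normal = norm, binormal = bin,
                 arclen = (phi - phi[1]) * radius, length = L,
                 kind = "arc", radius = radius, angle_deg = angle_deg),
            class = "ns_trajectory")
}

nerve_max_radius <- function(cs) {
  max(sqrt(rowSums(cs$epineurium^2)))
}

#' Sweep a cross-section along a trajectory
#'
#' Produces a 3D nerve model whose tissue query labels any point in space
#' as endoneurium (with fascicle id), perineurium (with fascicle id),
#' epineurium, bone (optional axis-aligned block) or saline. Cross-sections
#' are orthogonal to the local tangent; the fascicle topology is constant
#' along the sweep.
#'
#' @param cross_section An `ns_cross_section`.
#' @param trajectory An `ns_trajectory` (its length defines the nerve
#'   length).
#' @param bone_block Optional list with `min` and `max` length-3 vectors
#'   (um) defining an axis-aligned bone block.
#' @return An object of class `ns_nerve`.
#' @export
sweep_nerve <- function(cross_section, trajectory, bone_block = NULL) {
  r_max <- nerve_max_radius(cross_section)
  if (identical(trajectory$kind, "arc") && trajectory$radius <= r_max)
    stop("self-intersecting sweep: arc radius (", trajectory$radius,
         " um) must exceed the maximal nerve radius (", round(r_max), " um)")
  structure(list(section = cross_section, trajectory = trajectory,
                 length = trajectory$length, r_max = r_max,
                 bone_block = bone_block),
            class = "ns_nerve")
}

#' Straight preset nerve helper
#'
#' Convenience constructor: preset cross-section swept along its preset
#' trajectory (straight for pudendal-like, curved for sacral-like).
#'
#' @inheritParams synthesize_preset_section
#' @return An `ns_nerve`.
#' @export
synthesize_nerve <- function(preset = c("pudendal", "sacral"), seed = NULL,
                             area_scale = 1) {
  p <- nerve_preset(preset)
  cs <- synthesize_preset_section(preset, seed = seed, area_scale = area_scale)
  traj <- if (p$curved) {
    trajectory_arc(p$arc_radius, p$length / p$arc_radius * 180 / pi)
  } else trajectory_straight(p$length)
  sweep_nerve(cs, traj)
}

# Map 3D points to local cross-section coordinates (u = along the local
# normal, v = along the binormal, s = arc length). Straight and arc
# trajectories use closed-form projection.
local_coordinates <- function(nerve, pts) {
  tr <- nerve$trajectory
  if (tr$kind == "straight") {
    return(list(u = pts[, 1], v = pts[, 2], s = pts[, 3] + tr$length / 2))
  }
  if (tr$kind == "arc") {
    R <- tr$radius
    # arc center at (-R, 0, 0); phi measured from +x direction of center
    dx <- pts[, 1] + R; dz <- pts[, 3]
    phi <- atan2(dz, dx)
    rho <- sqrt(dx^2 + dz^2)
    u <- rho - R
    v <- pts[, 2]
    s <- (phi + (tr$angle_deg * pi / 180) / 2) * R
    return(list(u = u, v = v, s = s))
  }
  stop("unsupported trajectory kind")
}

#' Tissue labels at 3D points
#'
#' @param nerve An `ns_nerve`.
#' @param pts n x 3 matrix of points (um).
#' @return Character vector of labels: `"endoneurium:<id>"`,
#'   `"perineurium:<id>"`, `"epineurium"`, `"bone"` or `"saline"`.
#' @export
tissue_query <- function(nerve, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  lab <- rep("saline", nrow(pts))
  if (!is.null(nerve$bone_block)) {
    bb <- nerve$bone_block
    inb <- pts[, 1] >= bb$min[1] & pts[, 1] <= bb$max[1] &
      pts[, 2] >= bb$min[2] & pts[, 2] <= bb$max[2] &
      pts[, 3] >= bb$min[3] & pts[, 3] <= bb$max[3]
    lab[inb] <- "bone"
  }
  lc <- local_coordinates(nerve, pts)
  in_len <- lc$s >= 0 & lc$s <= nerve$length
  cs <- nerve$section
  cand <- which(in_len & (lc$u^2 + lc$v^2) <= (nerve$r_max * 1.05)^2)
  if (length(cand) == 0) return(lab)
  u <- lc$u[cand]; v <- lc$v[cand]
  in_epi <- points_in_polygon(u, v, cs$epineurium)
  lab[cand[in_epi]] <- "epineurium"
  idx_epi <- cand[in_epi]
  uu <- u[in_epi]; vv <- v[in_epi]
  for (f in cs$fascicles) {
    in_outer <- points_in_polygon(uu, vv, f$outer)
    if (!any(in_outer)) next
    in_endo <- logical(length(uu))
    in_endo[in_outer] <- points_in_polygon(uu[in_outer], vv[in_outer], f$endo)
    lab[idx_epi[in_outer & !in_endo]] <- paste0("perineurium:", f$id)
    lab[idx_epi[in_endo]] <- paste0("endoneurium:", f$id)
  }
  lab
}

#' World coordinates of a point given in cross-section coordinates
#'
#' Maps (u, v) in the cross-section plane at arc length s to 3D world
#' coordinates.
#'
#' @param nerve An `ns_nerve`.
#' @param u,v Cross-section coordinates (um).
#' @param s Arc length along the nerve (um), 0 at the first station.
#' @return n x 3 matrix.
#' @export
section_to_world <- function(nerve, u, v, s) {
  tr <- nerve$trajectory
  if (tr$kind == "straight") {
    return(cbind(u, v, s - tr$length / 2))
  }
  R <- tr$radius
  phi <- s / R - (tr$angle_deg * pi / 180) / 2
  rho <- R + u
  cbind(rho * cos(phi) - R, v, rho * sin(phi))
}

#' @export
print.ns_nerve <- function(x, ...) {
  cat("<ns_nerve>", length(x$section$fascicles), "fascicles,",
      x$trajectory$kind, "course, length", signif(x$length / 1e3, 4), "mm\n")
  invisible(x)
}
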