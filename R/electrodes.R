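# Parametric electrode families: clinical quadripolar lead ("interstim"),
# multipolar cuff, transversal intrafascicular array ("time"), and the
# adaptable intrafascicular radial design ("air") combining surface discs
# with paired radially inserted needle tips.

new_electrode_design <- function(family, sites, params, symmetry_angle) {
  k <- 360 / symmetry_angle
  stopifnot(abs(k - round(k)) < 1e-9)
  structure(list(family = family, sites = sites, params = params,
                 symmetry_angle = symmetry_angle),
            class = "ns_electrode")
}

#' @export
print.ns_electrode <- function(x, ...) {
  cat("<ns_electrode>", x$family, "-", nrow(x$sites), "active sites,",
      "symmetry", x$symmetry_angle, "deg\n")
  invisible(x)
}

#' Quadripolar cylindrical lead
#'
#' Clinical-style quadripolar lead: 1.27 mm diameter, four 3 mm long
#' cylindrical band contacts separated by 3 mm gaps (6 mm center-to-center
#' pitch).
#'
#' @return An `ns_electrode`.
#' @export
build_interstim <- function() {
  lead_d <- 1270; band_len <- 3000; gap <- 3000
  pitch <- band_len + gap
  zc <- (seq_len(4) - 2.5) * pitch
  sites <- tibble::tibble(
    site = seq_len(4), kind = "band", z_local = zc,
    diameter_um = lead_d, band_length_um = band_len)
  new_electrode_design("interstim", sites,
                       list(lead_diameter = lead_d, band_length = band_len,
                            band_gap = gap, pitch = pitch),
                       symmetry_angle = 360)
}

#' Multipolar cuff electrode
#'
#' Thin insulating film conformal to the nerve surface carrying
#' `n_sites` equally spaced radial disc contacts in one ring.
#'
#' @param n_sites Number of contacts (default 12).
#' @param site_diameter Contact diameter, um (default 400).
#' @param substrate_length Length of the insulating wrap along the nerve, um.
#' @param substrate_thickness Effective radial thickness of the wrap used
#'   by the rasterizer, um.
#' @return An `ns_electrode`.
#' @export
build_cuff <- function(n_sites = 12, site_diameter = 400,
                       substrate_length = 1200, substrate_thickness = 60) {
  stopifnot(n_sites >= 1)
  ang <- (seq_len(n_sites) - 1) * 360 / n_sites
  sites <- tibble::tibble(
    site = seq_len(n_sites), kind = "surface_disc", angle_deg = ang,
    z_local = 0, diameter_um = site_diameter)
  new_electrode_design("cuff", sites,
                       list(site_diameter = site_diameter,
                            substrate_length = substrate_length,
                            substrate_thickness = substrate_thickness),
                       symmetry_angle = 360 / n_sites)
}

#' Transversal intrafascicular multichannel electrode
#'
#' Thin straight shaft inserted through a chord of the nerve
#' cross-section: 12 disc contacts of 80 um diameter, 6 per side, 450 um
#' pitch, the two sides shifted by half a pitch (total span 2475 um).
#'
#' @return An `ns_electrode`.
#' @export
build_time <- function() {
  pitch <- 450; site_d <- 80; n_side <- 6
  # positions along the shaft; sides alternate and are offset by pitch/2
  pos_a <- (seq_len(n_side) - 1) * pitch
  pos_b <- pos_a + pitch / 2
  pos <- c(rbind(pos_a, pos_b))
  span <- max(pos) - min(pos)
  pos <- pos - mean(range(pos))   # centered on the chord midpoint
  side <- rep(c(1, -1), n_side)
  sites <- tibble::tibble(
    site = seq_len(2 * n_side), kind = "surface_disc",
    chord_pos_um = pos, side = side, z_local = 0, diameter_um = site_d)
  new_electrode_design("time", sites,
                       list(site_diameter = site_d, pitch = pitch,
                            span = span, ribbon_width = 300,
                            ribbon_thickness = 10, needle_track = 150,
                            conservative_track = FALSE),
                       symmetry_angle = 180)
}

#' Adaptable intrafascicular radial electrode
#'
#' Cuff-like flexible substrate with `n_heads` equally spaced heads; each
#' head carries one surface disc contact and `spikes_per_head` rigid
#' parallel needles pointing radially into the nerve, separated by
#' `spike_pitch` along the nerve axis and deinsulated over `tip_exposure`
#' at depth `spike_length`.
#'
#' The needle shank diameter defaults to 20 um so that the exposed
#' cylindrical tip area equals `pi * shank_diameter * tip_exposure` =
#' 2.5 times the area of an 80 um disc contact, matching the intended
#' surface-to-needle charge-capacity ratio (the 400 um surface discs are
#' 25 times an 80 um disc).
#'
#' @param n_heads Number of electrode heads (>= 1).
#' @param spike_pitch Axial separation of the paired spikes, um.
#' @param spike_length Insertion depth of the spike tips below the local
#'   nerve surface, um.
#' @param tip_exposure Deinsulated length at the tip, um.
#' @param surface_site_diameter Surface disc diameter, um.
#' @param spikes_per_head 1, 2 or 3 needles per head.
#' @param shank_diameter Needle shank diameter, um.
#' @param substrate_thickness Effective wrap thickness for rasterization, um.
#' @return An `ns_electrode`.
#' @export
build_air <- function(n_heads = 4, spike_pitch = 600, spike_length = 600,
                      tip_exposure = 200, surface_site_diameter = 400,
                      spikes_per_head = 2, shank_diameter = 20,
                      substrate_thickness = 60) {
  stopifnot(n_heads >= 1, spikes_per_head %in% 1:3)
  ang <- (seq_len(n_heads) - 1) * 360 / n_heads
  spike_z <- switch(spikes_per_head,
                    `1` = 0,
                    `2` = c(-0.5, 0.5) * spike_pitch,
                    `3` = c(-1, 0, 1) * spike_pitch)
  rows <- list()
  sid <- 0
  for (h in seq_len(n_heads)) {
    sid <- sid + 1
    rows[[length(rows) + 1]] <- tibble::tibble(
      site = sid, kind = "surface_disc", head = h, angle_deg = ang[h],
      z_local = 0, diameter_um = surface_site_diameter)
  }
  for (h in seq_len(n_heads)) for (k in seq_len(spikes_per_head)) {
    sid <- sid + 1
    rows[[length(rows) + 1]] <- tibble::tibble(
      site = sid, kind = "intrafascicular_tip", head = h, angle_deg = ang[h],
      z_local = spike_z[k], diameter_um = shank_diameter)
  }
  sites <- dplyr::bind_rows(rows)
  new_electrode_design("air", sites,
                       list(n_heads = n_heads, spike_pitch = spike_pitch,
                            spike_length = spike_length,
                            tip_exposure = tip_exposure,
                            surface_site_diameter = surface_site_diameter,
                            spikes_per_head = spikes_per_head,
                            shank_diameter = shank_diameter,
                            substrate_thickness = substrate_thickness),
                       symmetry_angle = 360 / n_heads)
}

#' Active site surface area
#'
#' Disc contacts: `pi (d/2)^2`. Band contacts: lateral cylinder area
#' `pi * lead_diameter * band_length`. Needle tips: lateral area of the
#' deinsulated cylindrical segment `pi * shank_diameter * tip_exposure`.
#'
#' @param site One row of an electrode's site table (list or one-row
#'   data frame), or an `ns_electrode` whose sites are all measured.
#' @param design The owning design (needed for tip exposure), optional for
#'   disc sites.
#' @return Area(s) in um^2.
#' @export
active_site_area <- function(site, design = NULL) {
  if (inherits(site, "ns_electrode")) {
    return(vapply(seq_len(nrow(site$sites)),
                  function(i) active_site_area(site$sites[i, ], site),
                  numeric(1)))
  }
  kind <- site$kind
  if (kind == "surface_disc") return(pi * (site$diameter_um / 2)^2)
  if (kind == "band") return(pi * site$diameter_um * site$band_length_um)
  if (kind == "intrafascicular_tip") {
    exposure <- if (!is.null(design)) design$params$tip_exposure else 200
    return(pi * site$diameter_um * exposure)
  }
  stop("unknown site kind: ", kind)
}
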