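# Synthesis of multi-fascicle nerve cross-sections: random fascicle shapes
# packed inside an epineurium contour with a minimum clearance, plus the
# scaling laws used by the adaptability analysis.

new_fascicle_section <- function(outer, area, id) {
  d_eq <- equivalent_diameter(area)
  t_p <- perineurium_thickness(area)
  # Endoneurium = outer contour offset inward by the perineurium thickness,
  # approximated by uniform scaling about the centroid (offset is exact for
  # circles; within a few percent for the mildly eccentric generated shapes).
  shrink <- max(1 - t_p / (d_eq / 2), 0.05)
  c0 <- polygon_centroid(outer)
  endo <- sweep(sweep(outer, 2, c0) * shrink, 2, c0, FUN = "+")
  list(id = id, outer = outer, endo = endo, area = area,
       endo_area = polygon_area(endo),
       d_eq = d_eq, peri_thickness = t_p, centroid = c0)
}

fascicle_centroids <- function(cs) {
  do.call(rbind, lapply(cs$fascicles, `[[`, "centroid"))
}

#' Synthesize a multi-fascicle nerve cross-section
#'
#' Generates an epineurium contour and `n_fascicles` fascicle contours
#' (each with a perineurial sheath of thickness 3% of its equivalent
#' diameter) and packs the fascicles inside the epineurium with pairwise
#' clearance of at least `min_gap`. Placement is by seeded rejection
#' sampling of candidate centers; if the requested density is too high for
#' pure rejection, a deterministic pairwise push-apart relaxation resolves
#' residual clearance violations, and packing fails with a diagnostic if
#' relaxation cannot.
#'
#' @param nerve_area Epineurium cross-section area, um^2.
#' @param n_fascicles Number of fascicles (>= 1).
#' @param fascicle_area_sampler Function `n -> areas (um^2)`; defaults to
#'   gamma-distributed relative areas normalized so total fascicular area
#'   equals `packing_fraction * nerve_area`.
#' @param min_gap Minimum clearance between fascicle outer contours (um).
#'   Default: twice the maximum perineurium thickness among the fascicles.
#' @param seed Integer seed.
#' @param epi_aspect Aspect ratio of the epineurium shape (2 for a
#'   flattened pudendal-like nerve, 1 for a round sacral-like nerve).
#' @param packing_fraction Total fascicular (outer contour) area as a
#'   fraction of the nerve area, used by the default area sampler.
#' @param centered Place a single fascicle exactly at the epineurium
#'   centroid (default when `n_fascicles == 1`).
#' @param contour_points Vertices per contour.
#' @return An object of class `ns_cross_section`.
#' @export
synthesize_cross_section <- function(nerve_area, n_fascicles,
                                     fascicle_area_sampler = NULL,
                                     min_gap = NULL, seed = NULL,
                                     epi_aspect = 1, packing_fraction = 0.55,
                                     centered = n_fascicles == 1,
                                     contour_points = 64) {
  stopifnot(n_fascicles >= 1, nerve_area > 0)
  with_seed(seed, {
    if (is.null(fascicle_area_sampler)) {
      fascicle_area_sampler <- function(n) {
        w <- stats::rgamma(n, shape = 3)
        w / sum(w) * packing_fraction * nerve_area
      }
    }
    areas <- fascicle_area_sampler(n_fascicles)
    if (sum(areas) >= 0.8 * nerve_area)
      stop("requested total fascicular area must stay below 0.8 x nerve area")
    min_gap_user <- min_gap
    # epineurium major axis fixed along x so that flattened presets are
    # axis-aligned (transversal insertions run along the wide direction)
    epi <- generate_fascicle_contour(NULL, nerve_area,
                                     n_gauss_points = 48,
                                     smoothness = max(contour_points, 96),
                                     aspect = epi_aspect, rotation = 0)
    placed <- NULL
    for (redraw in 1:8) {   # resample areas and shapes if a draw cannot
                            # be packed, drawing progressively rounder
                            # fascicles
      if (redraw > 1) {
        cand <- fascicle_area_sampler(n_fascicles)
        if (sum(cand) < 0.8 * nerve_area) areas <- cand
      }
      ord <- order(areas, decreasing = TRUE)
      if (is.null(min_gap_user))
        min_gap <- 2 * max(perineurium_thickness(areas))
      amax <- max(1.4, 2.5 - 0.25 * (redraw - 1))
      shapes <- lapply(areas[ord], function(a)
        generate_fascicle_contour(NULL, a, smoothness = contour_points,
                                  aspect_range = c(1, amax)))
      placed <- pack_fascicles(epi, shapes, min_gap, centered)
      if (!is.null(placed)) break
    }
    if (is.null(placed))
      stop("fascicle packing failed: density too high for the requested ",
           "min_gap (total fascicular fraction ",
           signif(sum(areas) / nerve_area, 3), ")")
    fascicles <- vector("list", n_fascicles)
    for (k in seq_along(placed)) {
      fascicles[[ord[k]]] <- new_fascicle_section(placed[[k]], areas[ord[k]], ord[k])
    }
    for (k in seq_len(n_fascicles)) fascicles[[k]]$id <- k
    structure(list(epineurium = epi, fascicles = fascicles,
                   nerve_area = nerve_area, min_gap = min_gap,
                   seed = seed),
              class = "ns_cross_section")
  })
}

# Seeded rejection placement of shrunken fascicle shapes followed by a
# grow-and-relax pass (C++): shapes are inflated to full size while
# violating pairs are pushed apart, strays are pulled back inside the
# epineurium, and jammed shapes may rotate. Returns the placed outer
# contours (same order as `shapes`) or NULL.
pack_fascicles <- function(epi, shapes, min_gap, centered,
                           tries_per_fascicle = 200, n_restarts = 4,
                           start_scale = 0.65) {
  epi_c <- polygon_centroid(epi)
  bb <- apply(epi, 2, range)
  n <- length(shapes)
  shapes0 <- lapply(shapes, function(sh) {
    sh <- translate_polygon(sh, -polygon_centroid(sh))
    # align the shape's principal axis with x (the epineurium major axis);
    # the relaxation may rotate it later
    ev <- eigen(stats::cov(sh))$vectors[, 1]
    rotate_polygon(sh, -atan2(ev[2], ev[1]) * 180 / pi)
  })
  rad <- vapply(shapes0, function(sh) max(sqrt(rowSums(sh^2))), numeric(1))
  poly_at <- function(k, ctr, scale) translate_polygon(shapes0[[k]] * scale, ctr)
  inside_ok <- function(poly, clearance) {
    all(points_in_polygon(poly[, 1], poly[, 2], epi)) &&
      min(points_to_polygon_boundary(poly[, 1], poly[, 2], epi)) >= clearance
  }
  if (centered && n == 1) {
    cand <- poly_at(1, epi_c, 1)
    if (!inside_ok(cand, min_gap / 2)) return(NULL)
    return(list(cand))
  }
  for (restart in seq_len(n_restarts)) {
    ctrs <- matrix(NA_real_, n, 2)
    failed <- FALSE
    for (k in seq_len(n)) {
      found <- FALSE
      for (t in seq_len(tries_per_fascicle)) {
        ctr <- c(stats::runif(1, bb[1, 1], bb[2, 1]),
                 stats::runif(1, bb[1, 2], bb[2, 2]))
        cand <- poly_at(k, ctr, start_scale)
        if (!inside_ok(cand, min_gap / 2)) next
        ok <- TRUE
        for (q in seq_len(k - 1)) {
          lb <- sqrt(sum((ctr - ctrs[q, ])^2)) - (rad[k] + rad[q]) * start_scale
          if (lb < min_gap &&
              polygon_gap(cand, poly_at(q, ctrs[q, ], start_scale)) < min_gap) {
            ok <- FALSE; break
          }
        }
        if (ok) { ctrs[k, ] <- ctr; found <- TRUE; break }
      }
      if (!found) { failed <- TRUE; break }
    }
    if (failed) next
    res <- cpp_pack_relax(shapes0, rad, as.matrix(epi), ctrs, min_gap,
                          start_scale = start_scale)
    if (isTRUE(res$ok)) {
      return(lapply(seq_len(n), function(k)
        translate_polygon(rotate_polygon(shapes0[[k]], res$rot[k]),
                          res$ctrs[k, ])))
    }
  }
  NULL
}

#' Total endoneurial area of a cross-section
#' @param cs An `ns_cross_section`.
#' @return Area in um^2.
#' @export
endoneurial_area <- function(cs) sum(vapply(cs$fascicles, `[[`, numeric(1), "endo_area"))

#' @export
print.ns_cross_section <- function(x, ...) {
  cat("<ns_cross_section>", length(x$fascicles), "fascicles,",
      "nerve area", signif(x$nerve_area / 1e6, 4), "mm^2,",
      "endoneurium", signif(endoneurial_area(x) / 1e6, 4), "mm^2\n")
  invisible(x)
}

#' Nerve presets
#'
#' Parameter sets for the two synthetic nerves used throughout:
#' a flattened pudendal-like nerve (2:1 elliptical epineurium, 11
#' fascicles, straight course) and a rounder sacral-like nerve (10
#' fascicles, curved course). Cross-section areas are chosen so that the
#' 2.475 mm span of a transversally inserted shaft electrode covers a
#' whole nerve diameter and a 0.6 mm needle insertion stays interior.
#'
#' @param preset `"pudendal"` or `"sacral"`.
#' @return Named list of generator parameters.
#' @export
nerve_preset <- function(preset = c("pudendal", "sacral")) {
  preset <- match.arg(preset)
  switch(preset,
    pudendal = list(nerve_area = 3.6e6, n_fascicles = 11, epi_aspect = 2,
                    packing_fraction = 0.55, length = 20e3, curved = FALSE),
    sacral = list(nerve_area = 5.0e6, n_fascicles = 10, epi_aspect = 1,
                  packing_fraction = 0.55, length = 20e3, curved = TRUE,
                  arc_radius = 15e3))
}

#' Generate a preset cross-section
#'
#' @inheritParams nerve_preset
#' @param seed Integer seed.
#' @param area_scale Multiplier on the preset cross-section area; fascicle
#'   count and areas follow the diameter scaling law (see
#'   [scale_cross_section()]).
#' @return An `ns_cross_section`.
#' @export
synthesize_preset_section <- function(preset = c("pudendal", "sacral"),
                                      seed = NULL, area_scale = 1) {
  p <- nerve_preset(preset)
  cs <- NULL
  # rare unpackable fascicle-area draws are retried under salted sub-seeds
  for (salt in 0:4) {
    sd <- if (salt == 0) seed else derive_seed(seed, paste0("salt", salt))
    cs <- tryCatch(
      synthesize_cross_section(p$nerve_area, p$n_fascicles, seed = sd,
                               epi_aspect = p$epi_aspect,
                               packing_fraction = p$packing_fraction),
      error = function(e) NULL)
    if (!is.null(cs)) break
  }
  if (is.null(cs))
    stop("preset cross-section could not be packed for this seed")
  if (area_scale != 1) cs <- scale_cross_section(cs, area_scale,
                                                 seed = derive_seed(seed, "scale"))
  cs
}

#' Scale a cross-section following the diameter scaling law
#'
#' Builds a new synthetic cross-section whose area is `scale_factor` times
#' the reference area. Fascicle count and mean fascicle area both scale
#' with the nerve equivalent diameter (the square root of the area scale):
#' fascicle areas are drawn from a Gaussian kernel-density fit to the
#' reference fascicle areas and multiplied by the diameter scale.
#'
#' @param reference One `ns_cross_section` or a list of them pooled as
#'   reference.
#' @param scale_factor Area scale factor in `[1, 9]`.
#' @param seed Integer seed.
#' @return An `ns_cross_section`.
#' @export
scale_cross_section <- function(reference, scale_factor, seed = NULL) {
  if (inherits(reference, "ns_cross_section")) reference <- list(reference)
  if (length(reference) == 0) stop("empty reference set")
  stopifnot(scale_factor >= 1, scale_factor <= 9)
  ref_areas <- unlist(lapply(reference, function(cs)
    vapply(cs$fascicles, `[[`, numeric(1), "area")))
  n_ref <- mean(vapply(reference, function(cs) length(cs$fascicles), numeric(1)))
  area_ref <- mean(vapply(reference, `[[`, numeric(1), "nerve_area"))
  epi_aspect <- {
    e <- reference[[1]]$epineurium
    r <- apply(e, 2, function(v) diff(range(v)))
    max(r) / min(r)
  }
  d_scale <- sqrt(scale_factor)
  n_new <- max(1L, as.integer(round(n_ref * d_scale)))
  bw <- stats::bw.nrd0(ref_areas)
  sampler <- function(n) {
    a <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        cand <- sample(ref_areas, 1) + stats::rnorm(1, sd = bw)
        if (cand > 0) break
      }
      a[i] <- cand * d_scale
    }
    a
  }
  synthesize_cross_section(area_ref * scale_factor, n_new,
                           fascicle_area_sampler = sampler,
                           seed = seed, epi_aspect = epi_aspect)
}

#' Tidy summary of a cross-section
#'
#' @param x An `ns_cross_section`.
#' @param ... Unused.
#' @return A tibble with one row per fascicle: id, area, endoneurial area,
#'   equivalent diameter, perineurium thickness and centroid coordinates.
#' @exportS3Method generics::tidy
tidy.ns_cross_section <- function(x, ...) {
  tibble::tibble(
    fascicle = vapply(x$fascicles, `[[`, numeric(1), "id"),
    area_um2 = vapply(x$fascicles, `[[`, numeric(1), "area"),
    endo_area_um2 = vapply(x$fascicles, `[[`, numeric(1), "endo_area"),
    d_eq_um = vapply(x$fascicles, `[[`, numeric(1), "d_eq"),
    peri_thickness_um = vapply(x$fascicles, `[[`, numeric(1), "peri_thickness"),
    cx_um = vapply(x$fascicles, function(f) f$centroid[1], numeric(1)),
    cy_um = vapply(x$fascicles, function(f) f$centroid[2], numeric(1))
  )
}
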