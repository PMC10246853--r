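# Random closed contours for fascicle and epineurium outlines: convex hull
# of a 2D Gaussian point cloud, smoothed by periodic cubic spline
# interpolation and rescaled to a target area.

#' Equivalent circular diameter of an area
#'
#' Diameter of the circle whose area equals `area`.
#'
#' @param area Area in um^2 (non-negative).
#' @return Diameter in um.
#' @export
#' @examples
#' equivalent_diameter(pi / 4 * 1e6) # 1000 um
equivalent_diameter <- function(area) {
  if (any(area < 0)) stop("`area` must be non-negative")
  2 * sqrt(area / pi)
}

#' Perineurium thickness for a fascicle of given area
#'
#' The perineurial sheath is modeled with thickness equal to 3% of the
#' fascicle's equivalent diameter.
#'
#' @param fascicle_area Fascicle area in um^2.
#' @return Thickness in um.
#' @export
#' @examples
#' perineurium_thickness(pi / 4 * 1e6) # 30 um for a 1 mm fascicle
perineurium_thickness <- function(fascicle_area) {
  0.03 * equivalent_diameter(fascicle_area)
}

# Two rounds of Chaikin corner cutting: the refined polygon is convex,
# lies inside the hull, and is dense enough that the interpolating
# spline cannot overshoot the hull appreciably.
chaikin_refine <- function(poly, iterations = 2) {
  for (it in seq_len(iterations)) {
    nxt <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
    a <- 0.75 * poly + 0.25 * nxt
    b <- 0.25 * poly + 0.75 * nxt
    poly <- matrix(rbind(t(a), t(b)), ncol = 2, byrow = TRUE)
  }
  poly
}

# Evaluate a periodic cubic spline through the Chaikin-refined hull and
# resample it at n_out uniformly spaced parameter values.
periodic_spline_contour <- function(hull, n_out) {
  hull <- chaikin_refine(hull)
  closed <- rbind(hull, hull[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  t_in <- c(0, cumsum(seg))
  t_in <- t_in / t_in[length(t_in)]
  t_out <- seq(0, 1, length.out = n_out + 1)[-(n_out + 1)]
  sx <- stats::spline(t_in, closed[, 1], method = "periodic", xout = t_out)$y
  sy <- stats::spline(t_in, closed[, 2], method = "periodic", xout = t_out)$y
  cbind(sx, sy)
}

#' Generate a random fascicle-like closed contour
#'
#' Draws `n_gauss_points` from an anisotropic 2D normal distribution
#' (random orientation; aspect ratio drawn uniformly from
#' `aspect_range` unless `aspect` is fixed), takes the convex hull, smooths
#' it with a periodic cubic spline, and uniformly rescales the result so
#' its enclosed area equals `target_area`.
#'
#' @param seed Integer seed; the same seed reproduces the same contour.
#' @param target_area Target enclosed area, um^2 (> 0).
#' @param n_gauss_points Number of Gaussian samples (>= 8).
#' @param smoothness Number of vertices of the returned contour (>= 16).
#' @param aspect Optional fixed aspect ratio of the Gaussian covariance;
#'   overrides `aspect_range`.
#' @param aspect_range Range the aspect ratio is drawn from.
#' @param rotation Orientation of the covariance major axis in radians
#'   (default: drawn uniformly).
#' @return A `smoothness` x 2 matrix of CCW vertices (um), centered so the
#'   contour centroid is at the origin.
#' @export
generate_fascicle_contour <- function(seed = NULL, target_area,
                                      n_gauss_points = 24, smoothness = 64,
                                      aspect = NULL, aspect_range = c(1, 2.5),
                                      rotation = NULL) {
  stopifnot(target_area > 0, n_gauss_points >= 8, smoothness >= 16)
  with_seed(seed, {
    for (try in 1:25) {
      asp <- if (is.null(aspect)) stats::runif(1, aspect_range[1], aspect_range[2]) else aspect
      th <- if (is.null(rotation)) stats::runif(1, 0, pi) else rotation
      pts <- cbind(stats::rnorm(n_gauss_points, sd = asp), stats::rnorm(n_gauss_points))
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      pts <- pts %*% t(R)
      hull_idx <- grDevices::chull(pts)
      if (length(hull_idx) < 4) next  # degenerate hull: resample
      hull <- ensure_ccw(pts[hull_idx, , drop = FALSE])
      contour <- periodic_spline_contour(hull, smoothness)
      if (polygon_area(contour) <= 0) next
      contour <- rescale_polygon_area(ensure_ccw(contour), target_area)
      contour <- translate_polygon(contour, -polygon_centroid(contour))
      return(contour)
    }
    stop("degenerate Gaussian hull after 25 resampling attempts")
  })
}
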