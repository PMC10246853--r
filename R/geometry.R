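# Low-level 2D polygon helpers shared by the anatomy, electrode and metric
# layers. Contours are n x 2 matrices in micrometres, implicitly closed
# (last vertex connects back to the first), positively oriented (CCW).

#' Signed area of a closed polygon
#'
#' Shoelace formula; positive for counter-clockwise orientation.
#'
#' @param xy n x 2 matrix of vertices (um), implicitly closed.
#' @return Signed area in um^2.
#' @keywords internal
polygon_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Absolute polygon area
#' @inheritParams polygon_signed_area
#' @return Area in um^2.
#' @export
polygon_area <- function(xy) abs(polygon_signed_area(xy))

#' Polygon centroid
#' @inheritParams polygon_signed_area
#' @return Length-2 numeric (um).
#' @keywords internal
polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(xy))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

ensure_ccw <- function(xy) {
  if (polygon_signed_area(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

#' Test points against a closed polygon
#'
#' Vectorized even-odd (ray casting) test. Points exactly on the boundary
#' may fall on either side; callers that care use a clearance margin.
#'
#' @param px,py numeric vectors of point coordinates (um).
#' @param poly n x 2 polygon matrix.
#' @return Logical vector, TRUE for points inside.
#' @export
points_in_polygon <- function(px, py, poly) {
  cpp_points_in_polygon(as.numeric(px), as.numeric(py),
                        as.matrix(poly))
}

# Minimum distance from points to a polyline segment set (closed polygon
# boundary). Returns one distance per point.
points_to_polygon_boundary <- function(px, py, poly) {
  cpp_dist_to_polygon(as.numeric(px), as.numeric(py), as.matrix(poly))
}

#' Distance from a point to a fascicle/epineurium contour
#'
#' Zero for points inside the contour (the convention used by the
#' geometric selectivity index), otherwise Euclidean distance to the
#' boundary in the cross-section plane.
#'
#' @param px,py point coordinates (um).
#' @param poly contour matrix.
#' @return Non-negative distances (um).
#' @export
distance_to_contour <- function(px, py, poly) {
  d <- points_to_polygon_boundary(px, py, poly)
  d[points_in_polygon(px, py, poly)] <- 0
  d
}

# Minimum gap between two polygon boundaries; 0 if they overlap
# (vertex containment test). Contours are densely sampled so the
# vertex-to-edge approximation is accurate to the vertex spacing.
polygon_gap <- function(a, b) {
  cpp_polygon_gap(as.matrix(a), as.matrix(b))
}

# Uniform scaling of a polygon about its centroid so that its area
# becomes `target_area`.
rescale_polygon_area <- function(xy, target_area) {
  a <- polygon_area(xy)
  stopifnot(a > 0)
  c0 <- polygon_centroid(xy)
  s <- sqrt(target_area / a)
  sweep(sweep(xy, 2, c0) * s, 2, c0, FUN = "+")
}

translate_polygon <- function(xy, dxy) sweep(xy, 2, dxy, FUN = "+")

rotate_polygon <- function(xy, angle_deg, center = c(0, 0)) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sweep(xy, 2, center) %*% t(R), 2, center, FUN = "+")
}

# Run code with a temporary RNG state seeded by `seed`; the caller's
# global stream is untouched. With seed = NULL the current stream is used.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Deterministic sub-seed for an operation tag
#'
#' Derives a stable integer seed (< 2^31) from a global seed and a
#' character tag, so every stochastic stage of a pipeline draws from its
#' own reproducible stream.
#'
#' @param seed Integer global seed (NULL passes through).
#' @param tag Character operation tag.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 2654435761) %% 1000000007
  as.integer((as.numeric(seed) * 31 + h) %% 2147483647L)
}
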