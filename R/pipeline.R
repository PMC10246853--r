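# End-to-end hybrid pipeline: placed electrode -> conductivity raster ->
# per-site lead fields -> per-axon compartment potentials -> recruitment
# threshold matrix -> selectivity metrics.

#' Solve lead fields for all (or selected) active sites
#'
#' @param raster An `ns_raster` built with the placed electrode.
#' @param sites Site ids (default: all).
#' @param tol PCG relative tolerance.
#' @return Named list of `ns_leadfield` objects (names = site ids).
#' @export
solve_lead_fields <- function(raster, sites = NULL, tol = 1e-6) {
  placed <- raster$placed
  if (is.null(sites)) sites <- placed$sites$site
  out <- list()
  for (s in sites) out[[as.character(s)]] <- solve_lead_field(raster, s, tol = tol)
  out
}

#' Compute the axon x site recruitment threshold matrix
#'
#' The substrate of all selectivity metrics: for every axon in the
#' population and every active site, the cathodic charge threshold from
#' the membrane model driven by the site's lead field.
#'
#' @param placed An `ns_placed`.
#' @param axons Tibble from [build_axon_population()] (columns axon,
#'   fascicle, u, v, diameter_um).
#' @param resolution Grid resolution, um (see [build_grid()]).
#' @param solver_tol Lead-field PCG tolerance.
#' @param pulse_us Pulse width (50 us cathodic square pulse).
#' @param dt_us Membrane integration step, us.
#' @param window_ms Simulation window, ms.
#' @param tol Threshold bisection relative tolerance.
#' @param detail `"reduced"` (fast screen) or `"full"` (double cable).
#' @param seed Seed for the per-axon longitudinal node shifts.
#' @param sites Site ids to include (default: all).
#' @param raster Optional prebuilt `ns_raster` (reused across calls).
#' @return Tidy tibble: axon, fascicle, diameter_um, site, site_kind,
#'   threshold_nC, converged; one row per axon x site.
#' @export
threshold_matrix <- function(placed, axons, resolution = 60,
                             solver_tol = 1e-6, pulse_us = 50, dt_us = 1,
                             window_ms = 2, tol = 0.01,
                             detail = c("reduced", "full"), seed = NULL,
                             sites = NULL, raster = NULL) {
  detail <- match.arg(detail)
  nerve <- placed$nerve
  if (is.null(raster))
    raster <- rasterize_tissues(nerve, placed, build_grid(placed, resolution))
  if (is.null(sites)) sites <- placed$sites$site
  # build axon geometries once
  geoms <- vector("list", nrow(axons))
  for (i in seq_len(nrow(axons))) {
    tr <- axon_trajectory(nerve, axons$u[i], axons$v[i])
    geoms[[i]] <- build_axon_geometry(tr, axons$diameter_um[i],
                                      seed = derive_seed(seed, paste0("ax", axons$axon[i])),
                                      detail = detail)
  }
  kind_of <- stats::setNames(placed$sites$kind, placed$sites$site)
  rows <- list()
  for (s in sites) {
    lf <- solve_lead_field(raster, s, tol = solver_tol)
    ve_list <- lapply(geoms, function(gm)
      sample_potentials(lf, as.matrix(gm$compartments[, c("x", "y", "z")]),
                        outside = "zero"))
    peak <- vapply(ve_list, function(v) max(abs(v)), numeric(1))
    ord <- order(peak, decreasing = TRUE)
    thr <- rep(NA_real_, length(geoms))
    conv <- rep(FALSE, length(geoms))
    guess <- NULL
    for (i in ord) {
      res <- find_threshold(geoms[[i]], ve_list[[i]], pulse_us = pulse_us,
                            tol = tol, dt_us = dt_us, window_ms = window_ms,
                            init_guess = guess)
      thr[i] <- res$threshold_nC
      conv[i] <- res$converged
      if (is.finite(res$threshold_mA)) guess <- res$threshold_mA
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      axon = axons$axon, fascicle = axons$fascicle,
      diameter_um = axons$diameter_um, site = s,
      site_kind = unname(kind_of[as.character(s)]),
      threshold_nC = thr, converged = conv)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "placed") <- placed
  attr(out, "detail") <- detail
  class(out) <- c("ns_thresholds", class(out))
  out
}

#' Per-configuration selectivity summary
#'
#' Joins the hybrid fascicular selectivity (from the threshold matrix)
#' with the geometric selectivity surrogate (from distances only), per
#' target fascicle.
#'
#' @param placed An `ns_placed`.
#' @param thresholds Output of [threshold_matrix()].
#' @param level Recruitment level for fascicular thresholds.
#' @return Tibble: fascicle, threshold_nC, fascicular_selectivity,
#'   geometric_selectivity.
#' @export
config_selectivities <- function(placed, thresholds, level = 0.10) {
  fm <- fascicle_metrics(thresholds, level = level)
  sp <- cbind(placed$sites$u, placed$sites$v)
  fm$geometric_selectivity <- vapply(fm$fascicle, function(fi)
    geometric_selectivity(placed$nerve$section, sp, fi), numeric(1))
  fm
}

#' Best-site geometric selectivity averaged over targets
#'
#' The cheap screening objective used for electrode design optimization:
#' mean over target fascicles of the best-site geometric selectivity.
#'
#' @param placed An `ns_placed`.
#' @return Mean best-site geometric selectivity.
#' @export
mean_geometric_selectivity <- function(placed) {
  cs <- placed$nerve$section
  sp <- cbind(placed$sites$u, placed$sites$v)
  mean(vapply(vapply(cs$fascicles, `[[`, numeric(1), "id"),
              function(fi) geometric_selectivity(cs, sp, fi), numeric(1)))
}

#' @exportS3Method generics::tidy
tidy.ns_thresholds <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method generics::glance
glance.ns_thresholds <- function(x, ...) {
  tibble::tibble(
    n_axons = length(unique(x$axon)),
    n_sites = length(unique(x$site)),
    n_unreachable = sum(!is.finite(x$threshold_nC)),
    median_threshold_nC = stats::median(x$threshold_nC[is.finite(x$threshold_nC)]),
    detail = attr(x, "detail") %||% NA_character_)
}
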