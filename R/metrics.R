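# Benchmark metrics computed from the axon x site threshold matrix:
# recruitment curves, the 10% fascicular recruitment threshold,
# fascicular selectivity, axonal selectivity (via minimal collateral
# recruitment over sites), and the distance-only geometric selectivity
# surrogate.

#' Recruitment curve of a fascicle
#'
#' Fraction of axons with threshold at or below each charge.
#'
#' @param thresholds Threshold charges (nC) of the axons in one fascicle
#'   for one active site (`Inf` = unreachable).
#' @param charge_grid Charges (nC) at which to evaluate.
#' @return Tibble: charge_nC, fraction (non-decreasing in charge).
#' @export
recruitment_curve <- function(thresholds, charge_grid) {
  if (length(thresholds) == 0) stop("empty axon set")
  tibble::tibble(
    charge_nC = charge_grid,
    fraction = vapply(charge_grid, function(q) mean(thresholds <= q),
                      numeric(1)))
}

#' Fascicular recruitment threshold
#'
#' The charge needed to recruit a fraction `level` of the fascicle's
#' axons: the `ceiling(level * n)`-th order statistic of the thresholds.
#'
#' @param thresholds Thresholds (nC) for one fascicle and one site.
#' @param level Target recruitment level in (0, 1], default 10%.
#' @return Charge in nC (`Inf` if not reachable).
#' @export
fascicular_threshold <- function(thresholds, level = 0.10) {
  stopifnot(level > 0, level <= 1, length(thresholds) >= 1)
  sort(thresholds)[ceiling(level * length(thresholds))]
}

#' Fascicular selectivity
#'
#' Target relative recruitment minus the mean relative recruitment of the
#' other fascicles: `mu_i - mean_{j != i}(mu_j)`; in `[-1, 1]`.
#'
#' @param mu Relative recruitment per fascicle (values in `[0, 1]`).
#' @param target Index of the target fascicle.
#' @return Selectivity score.
#' @export
fascicular_selectivity <- function(mu, target) {
  m <- length(mu)
  if (m < 2) stop("fascicular selectivity needs >= 2 fascicles")
  stopifnot(target >= 1, target <= m)
  mu[target] - mean(mu[-target])
}

#' Minimal collateral recruitment of a target axon
#'
#' Over all sites, the smallest number of other axons whose threshold is
#' at or below the target's threshold at that site (ties recruit
#' together).
#'
#' @param tmat N x S matrix of threshold charges (nC; `Inf` allowed).
#' @param target Target axon (row index).
#' @return Integer collateral count.
#' @export
collateral_count <- function(tmat, target) {
  tt <- tmat[target, ]
  if (all(!is.finite(tt)))
    stop("target axon unreachable at every site: no stimulation policy")
  counts <- vapply(which(is.finite(tt)), function(s)
    sum(tmat[-target, s] <= tt[s]), numeric(1))
  as.integer(min(counts))
}

#' Axonal selectivity
#'
#' `1 - n_coll / N`: one minus the minimal fraction of the nerve
#' co-recruited with the target axon using the best available site.
#'
#' @inheritParams collateral_count
#' @return Score in `[1/N, 1]`.
#' @export
axonal_selectivity <- function(tmat, target) {
  1 - collateral_count(tmat, target) / nrow(tmat)
}

#' Geometric selectivity
#'
#' Distance-only surrogate of fascicular selectivity:
#' `1 - d_min_i / mean_{j != i}(d_min_j)`, where `d_min` is the minimum
#' distance from the active site to each fascicle in the cross-section
#' plane (0 if the site is inside the fascicle). Reported per target for
#' the best available site (maximum over sites).
#'
#' @param cross_section An `ns_cross_section`.
#' @param site_positions S x 2 matrix of site positions (um) in the
#'   cross-section plane.
#' @param target Target fascicle id.
#' @param per_site Return the per-site scores instead of the best-site
#'   maximum.
#' @return Best-site score (or vector of per-site scores).
#' @export
geometric_selectivity <- function(cross_section, site_positions, target,
                                  per_site = FALSE) {
  fs <- cross_section$fascicles
  m <- length(fs)
  if (m < 2) stop("geometric selectivity needs >= 2 fascicles")
  ids <- vapply(fs, `[[`, numeric(1), "id")
  ti <- which(ids == target)
  if (length(ti) != 1) stop("no fascicle with id ", target)
  if (is.null(dim(site_positions))) site_positions <- matrix(site_positions, ncol = 2)
  d <- matrix(0, nrow(site_positions), m)
  for (j in seq_len(m))
    d[, j] <- distance_to_contour(site_positions[, 1], site_positions[, 2],
                                  fs[[j]]$outer)
  scores <- 1 - d[, ti] / rowMeans(d[, -ti, drop = FALSE])
  if (per_site) scores else max(scores)
}

#' Threshold-matrix metrics per target fascicle
#'
#' For each target fascicle and site, finds the charge at which the
#' target reaches the `level` recruitment, evaluates every fascicle's
#' relative recruitment at that charge, and reports the best-site
#' fascicular threshold and selectivity.
#'
#' @param thresholds Tidy tibble with columns `axon`, `fascicle`, `site`,
#'   `threshold_nC` (as returned by [threshold_matrix()]).
#' @param level Recruitment level for the fascicular threshold.
#' @return Tibble: fascicle, threshold_nC (best site), best_site,
#'   fascicular_selectivity (best site).
#' @export
fascicle_metrics <- function(thresholds, level = 0.10) {
  fasc <- sort(unique(thresholds$fascicle))
  sites <- sort(unique(thresholds$site))
  tl <- split(thresholds, thresholds$site)
  out <- list()
  for (fi in fasc) {
    best_thr <- Inf; best_site <- NA_integer_; best_sel <- -Inf
    for (s in sites) {
      d <- tl[[as.character(s)]]
      t_f <- d$threshold_nC[d$fascicle == fi]
      if (length(t_f) == 0) next
      q10 <- fascicular_threshold(t_f, level)
      if (is.finite(q10) && q10 < best_thr) { best_thr <- q10; best_site <- s }
      if (is.finite(q10)) {
        mu <- vapply(fasc, function(fj)
          mean(d$threshold_nC[d$fascicle == fj] <= q10), numeric(1))
        sel <- fascicular_selectivity(mu, which(fasc == fi))
        if (sel > best_sel) best_sel <- sel
      }
    }
    out[[length(out) + 1]] <- tibble::tibble(
      fascicle = fi, threshold_nC = best_thr, best_site = best_site,
      fascicular_selectivity = if (is.finite(best_sel)) best_sel else NA_real_)
  }
  dplyr::bind_rows(out)
}

#' Axonal selectivity for every axon of a threshold table
#'
#' @inheritParams fascicle_metrics
#' @return Tibble: axon, fascicle, diameter_um (if present), axonal
#'   selectivity.
#' @export
axon_metrics <- function(thresholds) {
  wide <- tidyr::pivot_wider(
    thresholds[c("axon", "site", "threshold_nC")],
    names_from = "site", values_from = "threshold_nC")
  axons <- wide$axon
  tmat <- as.matrix(wide[, -1, drop = FALSE])
  meta <- dplyr::distinct(thresholds[intersect(
    c("axon", "fascicle", "diameter_um"), names(thresholds))])
  sel <- vapply(seq_along(axons), function(i) {
    if (all(!is.finite(tmat[i, ]))) return(NA_real_)
    axonal_selectivity(tmat, i)
  }, numeric(1))
  dplyr::left_join(tibble::tibble(axon = axons, axonal_selectivity = sel),
                   meta, by = "axon")
}
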