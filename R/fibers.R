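# Myelinated fiber populations: bimodal diameter mixture, uniform seeding
# of fascicle endoneurium at a fixed areal density, and trajectories
# following the nerve sweep.

#' Two-component fiber diameter mixture
#'
#' Human peripheral myelinated fiber calibers are bimodal; the default
#' mixture has component means 3.1 and 9.2 um. Standard deviations,
#' weights and the truncation interval are configurable (the literature
#' reports only the means).
#'
#' @param means,sds,weights Component parameters (um; weights sum to 1).
#' @param truncation Length-2 interval (um); draws outside are rejected.
#' @return A `ns_mixture` list.
#' @export
diameter_mixture <- function(means = c(3.1, 9.2), sds = c(1.0, 2.0),
                             weights = c(0.55, 0.45),
                             truncation = c(1, 16)) {
  stopifnot(length(means) == 2, all(sds > 0), truncation[1] > 0,
            truncation[2] > truncation[1])
  if (sum(weights) <= 0) stop("degenerate mixture: weights must sum > 0")
  weights <- weights / sum(weights)
  structure(list(means = means, sds = sds, weights = weights,
                 truncation = truncation), class = "ns_mixture")
}

#' Sample fiber diameters
#'
#' @param n Number of draws (>= 1).
#' @param mixture A [diameter_mixture()].
#' @param seed Integer seed.
#' @return Numeric vector of n diameters (um), all inside the truncation
#'   interval.
#' @export
sample_diameters <- function(n, mixture = diameter_mixture(), seed = NULL) {
  stopifnot(n >= 1)
  with_seed(seed, {
    out <- numeric(n)
    done <- 0
    while (done < n) {
      k <- n - done
      comp <- sample.int(2, k, replace = TRUE, prob = mixture$weights)
      d <- stats::rnorm(k, mixture$means[comp], mixture$sds[comp])
      ok <- d >= mixture$truncation[1] & d <= mixture$truncation[2]
      if (any(ok)) {
        out[(done + 1):(done + sum(ok))] <- d[ok]
        done <- done + sum(ok)
      }
    }
    out
  })
}

#' Seed axon positions in the endoneurium
#'
#' Per fascicle, `round(density * endoneurial_area)` axons are placed
#' uniformly at random strictly inside the endoneurium contour of the
#' central cross-section.
#'
#' @param cross_section An `ns_cross_section`.
#' @param density Areal density in axons per mm^2 (default 2.33e3).
#' @param seed Integer seed.
#' @return Tibble: axon, fascicle, u, v (um).
#' @export
place_axon_seeds <- function(cross_section, density = 2.33e3, seed = NULL) {
  stopifnot(density > 0)
  with_seed(seed, {
    rows <- list()
    aid <- 0
    for (f in cross_section$fascicles) {
      n_f <- round(density * f$endo_area / 1e6)
      if (n_f < 1) next
      bb <- apply(f$endo, 2, range)
      u <- v <- numeric(n_f)
      got <- 0
      while (got < n_f) {
        k <- max(2 * (n_f - got), 16)
        cu <- stats::runif(k, bb[1, 1], bb[2, 1])
        cv <- stats::runif(k, bb[1, 2], bb[2, 2])
        ok <- points_in_polygon(cu, cv, f$endo)
        take <- min(sum(ok), n_f - got)
        if (take > 0) {
          u[(got + 1):(got + take)] <- cu[ok][seq_len(take)]
          v[(got + 1):(got + take)] <- cv[ok][seq_len(take)]
          got <- got + take
        }
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        axon = aid + seq_len(n_f), fascicle = f$id, u = u, v = v)
      aid <- aid + n_f
    }
    if (length(rows) == 0) return(tibble::tibble(axon = integer(),
                                                 fascicle = integer(),
                                                 u = numeric(), v = numeric()))
    dplyr::bind_rows(rows)
  })
}

#' Build a fiber population on a nerve
#'
#' Seeds axons in the central cross-section, assigns diameters from the
#' mixture, and (optionally) subsamples to at most `max_per_fascicle`
#' axons per fascicle for downstream membrane simulations.
#'
#' @param nerve An `ns_nerve`.
#' @param density Axons per mm^2.
#' @param mixture A [diameter_mixture()].
#' @param seed Integer seed.
#' @param max_per_fascicle Optional cap per fascicle (uniform subsample).
#' @return Tibble: axon, fascicle, u, v, diameter_um.
#' @export
build_axon_population <- function(nerve, density = 2.33e3,
                                  mixture = diameter_mixture(), seed = NULL,
                                  max_per_fascicle = NULL) {
  seeds <- place_axon_seeds(nerve$section, density,
                            seed = derive_seed(seed, "seeds") %||% NULL)
  if (nrow(seeds) == 0) return(dplyr::mutate(seeds, diameter_um = numeric(0)))
  seeds$diameter_um <- sample_diameters(nrow(seeds), mixture,
                                        seed = derive_seed(seed, "diam"))
  if (!is.null(max_per_fascicle)) {
    seeds <- with_seed(derive_seed(seed, "sub"), {
      dplyr::slice_sample(dplyr::group_by(seeds, .data$fascicle),
                          n = max_per_fascicle) |> dplyr::ungroup()
    })
    seeds <- dplyr::arrange(seeds, .data$axon)
  }
  seeds
}

#' Axon trajectory through the swept nerve
#'
#' The trajectory of the axon seeded at (u0, v0) in the central
#' cross-section is the sweep of that point along the nerve course (for
#' the non-branching swept nerves generated here this coincides with the
#' streamlines of the guidance field; see [trace_streamline()] for the
#' general machinery).
#'
#' @param nerve An `ns_nerve`.
#' @param u0,v0 Seed position (um) in cross-section coordinates.
#' @param step Arc-length sampling step (um).
#' @return List: `points` (n x 3 world um), `arclen` (per-vertex axon arc
#'   length, um).
#' @export
axon_trajectory <- function(nerve, u0, v0, step = 100) {
  s <- seq(0, nerve$length, by = step)
  if (s[length(s)] < nerve$length) s <- c(s, nerve$length)
  pts <- section_to_world(nerve, rep(u0, length(s)), rep(v0, length(s)), s)
  seg <- sqrt(rowSums(diff(pts)^2))
  list(points = pts, arclen = c(0, cumsum(seg)))
}

#' Fit a two-component normal mixture to fiber diameters
#'
#' Model-based clustering fit (unequal variances) used to check that the
#' generator's component means are recoverable from samples.
#'
#' @param diameters Numeric vector of fiber diameters (um).
#' @return List: `means` (sorted ascending), `sds`, `weights`.
#' @export
fit_diameter_mixture <- function(diameters) {
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller
  fit <- mclust::Mclust(diameters, G = 2, modelNames = "V", verbose = FALSE)
  ord <- order(fit$parameters$mean)
  list(means = unname(fit$parameters$mean[ord]),
       sds = unname(sqrt(fit$parameters$variance$sigmasq[ord])),
       weights = unname(fit$parameters$pro[ord]))
}
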