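# Reusable experiment pipelines: AIR dimension optimization by grid
# search on geometric selectivity, site-count saturation, spikes-per-head
# analysis, geometric-vs-fascicular validation, adaptability to nerve
# size, repeatability across placements, diameter-class selectivity, and
# comparison against experimental thresholds.

air_placed_or_null <- function(nerve, seed, ...) {
  tryCatch(place_electrode(build_air(...), nerve,
                           placement = list(angle = 0), seed = seed),
           error = function(e) NULL)
}

#' Grid-search optimization of the AIR spike dimensions
#'
#' Evaluates the mean best-site geometric selectivity over a set of
#' nerves for every (spike pitch, spike length) grid cell and returns the
#' argmax with the full score surface. Placement failures (spikes leaving
#' the nerve) are recorded and excluded.
#'
#' @param nerve_set List of `ns_nerve` objects.
#' @param pitch_grid,length_grid Grids in um (>= 3 values each
#'   recommended).
#' @param n_heads,spikes_per_head AIR configuration under optimization.
#' @param seed Integer seed (standoff draws).
#' @return List: `surface` (tibble pitch, length, mean selectivity,
#'   n_failed), `best` (row of the surface), class `ns_air_optimum`.
#' @export
optimize_air_dimensions <- function(nerve_set, pitch_grid, length_grid,
                                    n_heads = 4, spikes_per_head = 2,
                                    seed = NULL) {
  rows <- list()
  for (p in pitch_grid) for (L in length_grid) {
    vals <- numeric(0); failed <- 0
    for (i in seq_along(nerve_set)) {
      pl <- air_placed_or_null(nerve_set[[i]], derive_seed(seed, paste0("o", i)),
                               n_heads = n_heads, spike_pitch = p,
                               spike_length = L,
                               spikes_per_head = spikes_per_head)
      if (is.null(pl)) { failed <- failed + 1; next }
      vals <- c(vals, mean_geometric_selectivity(pl))
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      spike_pitch_um = p, spike_length_um = L,
      mean_selectivity = if (length(vals)) mean(vals) else NA_real_,
      n_failed = failed)
  }
  surface <- dplyr::bind_rows(rows)
  ok <- which(!is.na(surface$mean_selectivity))
  # tie-break toward the least invasive (shortest, then narrowest) design
  ord <- ok[order(-surface$mean_selectivity[ok], surface$spike_length_um[ok],
                  surface$spike_pitch_um[ok])]
  structure(list(surface = surface, best = surface[ord[1], ]),
            class = "ns_air_optimum")
}

#' @export
print.ns_air_optimum <- function(x, ...) {
  cat("<ns_air_optimum> best pitch", x$best$spike_pitch_um, "um, length",
      x$best$spike_length_um, "um, mean geometric selectivity",
      signif(x$best$mean_selectivity, 4), "\n")
  invisible(x)
}

#' Selectivity saturation with the number of active sites
#'
#' Mean best-site geometric selectivity as a function of the total number
#' of active sites, with the marginal increment per added site between
#' consecutive counts. The AIR keeps its 2-spikes-per-surface-site ratio
#' (counts are multiples of 3: one head = 3 sites); the cuff adds ring
#' contacts.
#'
#' @param family `"air"` or `"cuff"`.
#' @param site_counts Increasing site counts.
#' @param nerve_set List of `ns_nerve` objects.
#' @param seed Integer seed.
#' @param ... Extra arguments to the electrode builder.
#' @return Tibble: n_sites, mean_selectivity, increment_per_site
#'   (x100 = percent selectivity per added site vs the previous count).
#' @export
site_count_saturation <- function(family = c("air", "cuff"), site_counts,
                                  nerve_set, seed = NULL, ...) {
  family <- match.arg(family)
  stopifnot(!is.unsorted(site_counts))
  rows <- list()
  for (n_sites in site_counts) {
    vals <- numeric(0)
    for (i in seq_along(nerve_set)) {
      sd_i <- derive_seed(seed, paste0("sat", i))
      pl <- if (family == "air") {
        if (n_sites %% 3 != 0)
          stop("AIR site counts must be multiples of 3 (1 surface + 2 spikes per head)")
        air_placed_or_null(nerve_set[[i]], sd_i, n_heads = n_sites / 3, ...)
      } else {
        tryCatch(place_electrode(build_cuff(n_sites = n_sites, ...),
                                 nerve_set[[i]], placement = list(angle = 0),
                                 seed = sd_i),
                 error = function(e) NULL)
      }
      if (!is.null(pl)) vals <- c(vals, mean_geometric_selectivity(pl))
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      n_sites = n_sites,
      mean_selectivity = if (length(vals)) mean(vals) else NA_real_,
      n_nerves = length(vals))
  }
  out <- dplyr::bind_rows(rows)
  out$increment_per_site <- c(NA, diff(out$mean_selectivity) / diff(out$n_sites))
  out
}

#' Marginal selectivity of additional spikes per head
#'
#' @param nerve_set List of `ns_nerve` objects.
#' @param spikes Spikes-per-head values (subset of 1:3).
#' @param n_heads Number of heads.
#' @param seed Integer seed.
#' @return Tibble: spikes_per_head, mean_selectivity,
#'   increment_per_spike (difference vs previous row divided by the
#'   number of added spikes).
#' @export
spikes_per_head_analysis <- function(nerve_set, spikes = 1:3, n_heads = 4,
                                     seed = NULL) {
  rows <- list()
  for (spk in spikes) {
    vals <- numeric(0)
    for (i in seq_along(nerve_set)) {
      pl <- air_placed_or_null(nerve_set[[i]], derive_seed(seed, paste0("sp", i)),
                               n_heads = n_heads, spikes_per_head = spk)
      if (!is.null(pl)) vals <- c(vals, mean_geometric_selectivity(pl))
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      spikes_per_head = spk,
      mean_selectivity = if (length(vals)) mean(vals) else NA_real_)
  }
  out <- dplyr::bind_rows(rows)
  added <- diff(out$spikes_per_head) * n_heads
  out$increment_per_spike <- c(NA, diff(out$mean_selectivity) / added)
  out
}

#' Default configuration plan for the geometric-vs-fascicular validation
#'
#' Twelve configurations over four synthetic flattened (pudendal-like)
#' nerves: each nerve carries three of the four electrode families, so
#' every family appears in three distinct placements.
#'
#' @param n_nerves Number of synthetic nerves (>= 4).
#' @param seed Integer seed.
#' @return Tibble of configuration descriptors.
#' @export
default_correlation_configs <- function(n_nerves = 4, seed = 1) {
  fams <- c("air", "cuff", "time", "interstim")
  rows <- list()
  cfg <- 0
  for (i in seq_len(n_nerves)) {
    use <- fams[-(1 + (i - 1) %% 4)]
    for (fam in use) {
      cfg <- cfg + 1
      rows[[cfg]] <- tibble::tibble(
        config = cfg, nerve_seed = derive_seed(seed, paste0("nerve", i)),
        nerve_index = i, family = fam,
        angle = switch(fam, air = (cfg * 37) %% 90,
                       cuff = (cfg * 13) %% 30, 0),
        chord_angle = if (fam == "time") ((cfg %% 3) - 1) * 12 else 0,
        corner_angle = if (fam == "interstim") 45 + 90 * (cfg %% 4) else 0)
    }
  }
  dplyr::bind_rows(rows)
}

build_config_placed <- function(cfg_row, nerve, seed) {
  fam <- cfg_row$family
  design <- switch(fam, air = build_air(), cuff = build_cuff(),
                   time = build_time(), interstim = build_interstim())
  sd <- derive_seed(seed, paste0("pl", cfg_row$config))
  if (fam == "time") {
    # narrow nerves may not admit the requested chord; search nearby
    # angles until the shaft fits
    for (ang in cfg_row$chord_angle + c(0, -4, 4, -8, 8, -12, 12, -16, 16)) {
      p <- tryCatch(place_electrode(design, nerve,
                                    list(chord_angle = ang), seed = sd),
                    error = function(e) NULL)
      if (!is.null(p)) return(p)
    }
    stop("transversal shaft does not fit this nerve at any candidate angle")
  }
  placement <- switch(fam,
    air = list(angle = cfg_row$angle),
    cuff = list(angle = cfg_row$angle),
    interstim = list(corner_angle = cfg_row$corner_angle, gap = 500))
  place_electrode(design, nerve, placement, seed = sd)
}

#' Geometric vs fascicular selectivity correlation
#'
#' Runs the full hybrid pipeline (threshold matrix with the reduced cable
#' model) for a sample of electrode configurations, computes per-target
#' fascicular selectivity and the geometric surrogate, and regresses one
#' on the other at two aggregation levels: per-configuration means and
#' per-fascicle points.
#'
#' @param configs Configuration tibble (see
#'   [default_correlation_configs()]).
#' @param seed Integer seed.
#' @param axons_per_fascicle Subsample cap for the membrane simulations.
#' @param resolution Grid resolution, um.
#' @param solver_tol Lead-field tolerance.
#' @param dt_us Membrane time step, us.
#' @param progress Print per-configuration progress.
#' @return An `ns_correlation`: per-fascicle points, per-configuration
#'   means, and the two least-squares fits.
#' @export
correlate_geometric_vs_fascicular <- function(configs = default_correlation_configs(),
                                              seed = 1,
                                              axons_per_fascicle = 8,
                                              resolution = 60,
                                              solver_tol = 1e-6,
                                              dt_us = 2,
                                              progress = FALSE) {
  if (nrow(configs) < 3) stop("need >= 3 configurations")
  nerves <- list()
  pts <- list()
  for (ci in seq_len(nrow(configs))) {
    cfg <- configs[ci, ]
    key <- as.character(cfg$nerve_index)
    if (is.null(nerves[[key]]))
      nerves[[key]] <- synthesize_nerve("pudendal", seed = cfg$nerve_seed)
    nerve <- nerves[[key]]
    placed <- build_config_placed(cfg, nerve, seed)
    axons <- build_axon_population(nerve, seed = derive_seed(seed, paste0("ax", ci)),
                                   max_per_fascicle = axons_per_fascicle)
    thr <- threshold_matrix(placed, axons, resolution = resolution,
                            solver_tol = solver_tol, dt_us = dt_us,
                            seed = derive_seed(seed, paste0("th", ci)))
    cs <- config_selectivities(placed, thr)
    cs$config <- cfg$config; cs$family <- cfg$family
    pts[[length(pts) + 1]] <- cs
    if (progress)
      message("config ", cfg$config, " (", cfg$family, "): done")
  }
  points <- dplyr::bind_rows(pts)
  points <- points[is.finite(points$fascicular_selectivity) &
                     is.finite(points$geometric_selectivity), ]
  means <- dplyr::summarise(
    dplyr::group_by(points, .data$config, .data$family),
    fascicular = mean(.data$fascicular_selectivity),
    geometric = mean(.data$geometric_selectivity), .groups = "drop")
  fit_mean <- stats::lm(fascicular ~ geometric, data = means)
  fit_fasc <- stats::lm(fascicular_selectivity ~ geometric_selectivity,
                        data = points)
  structure(list(points = points, config_means = means,
                 fit_mean = fit_mean, fit_fascicle = fit_fasc,
                 r2_mean = summary(fit_mean)$r.squared,
                 r2_fascicle = summary(fit_fasc)$r.squared),
            class = "ns_correlation")
}

#' @export
print.ns_correlation <- function(x, ...) {
  cat("<ns_correlation>", nrow(x$config_means), "configurations,",
      nrow(x$points), "fascicle points\n",
      " R^2 (configuration means):", signif(x$r2_mean, 3), "\n",
      " R^2 (per fascicle):      ", signif(x$r2_fascicle, 3), "\n")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.ns_correlation <- function(x, ...) {
  tibble::tibble(r2_mean = x$r2_mean, r2_fascicle = x$r2_fascicle,
                 n_configs = nrow(x$config_means), n_points = nrow(x$points),
                 p_mean = stats::anova(x$fit_mean)$`Pr(>F)`[1],
                 p_fascicle = stats::anova(x$fit_fascicle)$`Pr(>F)`[1])
}

#' Adaptability of selectivity to nerve size
#'
#' Geometric selectivity of AIR (with and without surface sites), cuff,
#' and 1-3 transversal shaft implants on synthetic cross-sections scaled
#' up to 9x the reference area, with fascicle count, fascicle areas, and
#' active-site counts scaled proportionally to the nerve equivalent
#' diameter. Mean over `n_nerves` random cross-sections per scale; a
#' three-factor analysis of variance (scale, electrode, nerve) with
#' Tukey correction summarizes the effects.
#'
#' @param scales Area scale factors (default `c(1, 2.25, 4, 9)`).
#' @param n_nerves Random synthetic cross-sections per scale.
#' @param seed Integer seed.
#' @param reference Optional reference `ns_cross_section` (default: the
#'   flattened pudendal-like preset).
#' @return List: `results` tibble, `anova` fit, `tukey` comparisons.
#' @export
adaptability_study <- function(scales = c(1, 2.25, 4, 9), n_nerves = 20,
                               seed = 1, reference = NULL) {
  stopifnot(n_nerves >= 2)
  if (is.null(reference))
    reference <- synthesize_preset_section("pudendal",
                                           seed = derive_seed(seed, "ref"))
  rows <- list()
  for (sc in scales) {
    d_scale <- sqrt(sc)
    for (i in seq_len(n_nerves)) {
      cs <- scale_cross_section(reference, sc,
                                seed = derive_seed(seed, paste0("a", sc, "_", i)))
      nerve <- sweep_nerve(cs, trajectory_straight(20e3))
      n_heads <- max(1L, round(4 * d_scale))
      n_cuff <- max(4L, round(12 * d_scale))
      sd_i <- derive_seed(seed, paste0("ad", sc, "_", i))
      entries <- list()
      pl_air <- air_placed_or_null(nerve, sd_i, n_heads = n_heads)
      if (!is.null(pl_air)) {
        entries$air <- mean_geometric_selectivity(pl_air)
        # drop surface sites: intrafascicular contacts only
        pl2 <- pl_air
        pl2$sites <- pl2$sites[pl2$sites$kind == "intrafascicular_tip", ]
        entries$air_no_surface <- mean_geometric_selectivity(pl2)
      }
      pl_cuff <- tryCatch(place_electrode(build_cuff(n_sites = n_cuff), nerve,
                                          list(angle = 0), seed = sd_i),
                          error = function(e) NULL)
      if (!is.null(pl_cuff)) entries$cuff <- mean_geometric_selectivity(pl_cuff)
      for (k in 1:3) {
        pls <- list()
        angs <- c(0, 12, -12)[seq_len(k)]
        ok <- TRUE
        for (a in angs) {
          p <- tryCatch(place_electrode(build_time(), nerve,
                                        list(chord_angle = a,
                                             chord_offset = (a != 0) * 0),
                                        seed = sd_i),
                        error = function(e) NULL)
          if (is.null(p)) { ok <- FALSE; break }
          pls[[length(pls) + 1]] <- p
        }
        if (ok) {
          sp <- do.call(rbind, lapply(pls, function(p) cbind(p$sites$u, p$sites$v)))
          cs_ids <- vapply(cs$fascicles, `[[`, numeric(1), "id")
          entries[[paste0("time", k)]] <-
            mean(vapply(cs_ids, function(fi)
              geometric_selectivity(cs, sp, fi), numeric(1)))
        }
      }
      for (nm in names(entries))
        rows[[length(rows) + 1]] <- tibble::tibble(
          scale = sc, nerve = i, electrode = nm, selectivity = entries[[nm]])
    }
  }
  results <- dplyr::bind_rows(rows)
  fit <- stats::aov(selectivity ~ factor(scale) + electrode + factor(nerve),
                    data = results)
  structure(list(results = results, anova = fit,
                 tukey = stats::TukeyHSD(fit, which = "electrode")),
            class = "ns_adaptability")
}

#' @export
print.ns_adaptability <- function(x, ...) {
  agg <- dplyr::summarise(dplyr::group_by(x$results, .data$scale, .data$electrode),
                          mean = mean(.data$selectivity),
                          sd = stats::sd(.data$selectivity), .groups = "drop")
  cat("<ns_adaptability>\n")
  print(as.data.frame(agg), digits = 3)
  invisible(x)
}

#' Repeatability of metrics across surgical placements
#'
#' Evaluates the per-target metrics for each placement of the same
#' design on the same nerve and tests the placement effect with a one-way
#' analysis of variance per metric (Bonferroni-corrected pairwise
#' comparisons).
#'
#' @param nerve An `ns_nerve`.
#' @param design An `ns_electrode`.
#' @param placements List of placement parameter lists.
#' @param metric `"geometric"` (distance-based, fast) or `"full"`
#'   (threshold matrix; needs `axons`).
#' @param axons Axon population for `metric = "full"`.
#' @param seed Integer seed.
#' @param ... Passed to [threshold_matrix()].
#' @return List: `results` tibble (placement, target, metric values),
#'   `anova` per metric (NULL with a warning for a single placement).
#' @export
repeatability_study <- function(nerve, design, placements,
                                metric = c("geometric", "full"),
                                axons = NULL, seed = NULL, ...) {
  metric <- match.arg(metric)
  rows <- list()
  for (pi in seq_along(placements)) {
    pl <- place_electrode(design, nerve, placements[[pi]],
                          seed = derive_seed(seed, paste0("rep", pi)))
    if (metric == "geometric") {
      cs <- nerve$section
      ids <- vapply(cs$fascicles, `[[`, numeric(1), "id")
      sp <- cbind(pl$sites$u, pl$sites$v)
      rows[[length(rows) + 1]] <- tibble::tibble(
        placement = pi, target = ids,
        metric = "geometric_selectivity",
        value = vapply(ids, function(fi) geometric_selectivity(cs, sp, fi),
                       numeric(1)))
    } else {
      if (is.null(axons)) stop("metric = 'full' needs an axon population")
      thr <- threshold_matrix(pl, axons, seed = derive_seed(seed, paste0("t", pi)),
                              ...)
      fm <- fascicle_metrics(thr)
      am <- axon_metrics(thr)
      rows[[length(rows) + 1]] <- dplyr::bind_rows(
        tibble::tibble(placement = pi, target = fm$fascicle,
                       metric = "threshold_nC", value = fm$threshold_nC),
        tibble::tibble(placement = pi, target = fm$fascicle,
                       metric = "fascicular_selectivity",
                       value = fm$fascicular_selectivity),
        tibble::tibble(placement = pi, target = am$axon,
                       metric = "axonal_selectivity",
                       value = am$axonal_selectivity))
    }
  }
  results <- dplyr::bind_rows(rows)
  tests <- NULL
  if (length(placements) < 2) {
    warning("single placement: placement-effect test skipped")
  } else {
    tests <- lapply(split(results, results$metric), function(d) {
      d <- d[is.finite(d$value), ]
      if (stats::var(d$value) == 0)
        return(list(p_value = 1, note = "identical metrics across placements"))
      fit <- stats::aov(value ~ factor(placement), data = d)
      list(p_value = summary(fit)[[1]][["Pr(>F)"]][1], fit = fit,
           pairwise = stats::pairwise.t.test(d$value, factor(d$placement),
                                             p.adjust.method = "bonferroni"))
    })
  }
  list(results = results, tests = tests)
}

#' Selectivity gain by fiber diameter class
#'
#' Splits fibers into small (< 6 um) and large (>= 6 um) classes and
#' compares the axonal selectivity achievable with the surface contacts
#' against an equal number of intrafascicular contacts (half of the
#' spikes, one per head by default), with a two-factor analysis of
#' variance with interaction.
#'
#' @param thresholds `ns_thresholds` for an AIR configuration (must
#'   contain `site_kind`).
#' @param small_cut Class boundary, um.
#' @param tip_sites Which intrafascicular site ids to keep (default: the
#'   first spike of each head).
#' @return List: `gains` (per fiber class), `cell_means`, `anova`,
#'   `interaction_estimate`, `data`.
#' @export
diameter_class_analysis <- function(thresholds, small_cut = 6,
                                    tip_sites = NULL) {
  placed <- attr(thresholds, "placed")
  surf <- unique(thresholds$site[thresholds$site_kind == "surface_disc"])
  tips <- unique(thresholds$site[thresholds$site_kind == "intrafascicular_tip"])
  if (length(surf) == 0 || length(tips) == 0)
    stop("both surface and intrafascicular sites are required")
  if (is.null(tip_sites)) {
    if (!is.null(placed)) {
      st <- placed$sites[placed$sites$kind == "intrafascicular_tip", ]
      tip_sites <- vapply(split(st$site, st$head), min, numeric(1))
    } else tip_sites <- tips[seq_len(ceiling(length(tips) / 2))]
  }
  sel_for <- function(site_set) {
    sub <- thresholds[thresholds$site %in% site_set, ]
    axon_metrics(sub)
  }
  a_surf <- sel_for(surf); a_surf$site_class <- "extrafascicular"
  a_tip <- sel_for(tip_sites); a_tip$site_class <- "intrafascicular"
  dat <- dplyr::bind_rows(a_surf, a_tip)
  dat$fiber_class <- ifelse(dat$diameter_um < small_cut, "small", "large")
  dat <- dat[is.finite(dat$axonal_selectivity), ]
  if (!all(c("small", "large") %in% dat$fiber_class))
    stop("empty fiber class: need fibers on both sides of ", small_cut, " um")
  cm <- dplyr::summarise(
    dplyr::group_by(dat, .data$site_class, .data$fiber_class),
    mean_sel = mean(.data$axonal_selectivity), n = dplyr::n(),
    .groups = "drop")
  gain <- function(fc) {
    cm$mean_sel[cm$site_class == "intrafascicular" & cm$fiber_class == fc] -
      cm$mean_sel[cm$site_class == "extrafascicular" & cm$fiber_class == fc]
  }
  gains <- c(small = gain("small"), large = gain("large"))
  fit <- stats::aov(axonal_selectivity ~ site_class * fiber_class, data = dat)
  list(gains = gains, cell_means = cm, anova = fit,
       interaction_estimate = unname(gains["small"] - gains["large"]),
       data = dat)
}

#' Lowest deliverable threshold of a placement
#'
#' The minimum finite fascicular recruitment threshold over all sites and
#' fascicles: the model counterpart of the charge a practitioner titrates
#' to when choosing the best contact.
#'
#' @param thresholds `ns_thresholds` of one placement.
#' @param level Recruitment level.
#' @return Charge in nC.
#' @export
placement_best_threshold <- function(thresholds, level = 0.10) {
  best <- Inf
  for (s in unique(thresholds$site)) {
    d <- thresholds[thresholds$site == s, ]
    for (fi in unique(d$fascicle)) {
      q <- fascicular_threshold(d$threshold_nC[d$fascicle == fi], level)
      if (is.finite(q) && q < best) best <- q
    }
  }
  best
}

#' Compare model thresholds with experimental thresholds
#'
#' Two-sample Kolmogorov-Smirnov test between per-placement best-site
#' model thresholds and an experimental sample of charges.
#'
#' @param model_thresholds Numeric vector of per-placement thresholds
#'   (nC), e.g. from [placement_best_threshold()].
#' @param experimental Numeric vector of charges (nC), or path to a CSV
#'   file with a `charge_nC` column.
#' @param alpha Significance level for the decision.
#' @return Tibble: D, p_value, different (logical at `alpha`), n_model,
#'   n_experimental.
#' @export
validate_thresholds <- function(model_thresholds, experimental,
                                alpha = 0.05) {
  if (is.character(experimental)) {
    if (!file.exists(experimental)) stop("file not found: ", experimental)
    df <- utils::read.csv(experimental)
    if (!"charge_nC" %in% names(df))
      stop("experimental CSV must have a charge_nC column")
    experimental <- df$charge_nC
  }
  if (!is.numeric(experimental) || anyNA(experimental))
    stop("invalid experimental thresholds")
  ks <- suppressWarnings(stats::ks.test(model_thresholds, experimental))
  tibble::tibble(D = unname(ks$statistic), p_value = ks$p.value,
                 different = ks$p.value < alpha,
                 n_model = length(model_thresholds),
                 n_experimental = length(experimental))
}
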