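# ggplot2 views of the main result types.

contour_df <- function(xy, id, part) {
  tibble::tibble(x = xy[, 1], y = xy[, 2], id = id, part = part)
}

#' Plot a nerve cross-section
#'
#' Epineurium outline, fascicle outer (perineurium) and endoneurium
#' contours.
#'
#' @param object An `ns_cross_section`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ns_cross_section <- function(object, ...) {
  epi <- contour_df(object$epineurium, 0, "epineurium")
  fo <- dplyr::bind_rows(lapply(object$fascicles, function(f)
    contour_df(f$outer, f$id, "perineurium")))
  fe <- dplyr::bind_rows(lapply(object$fascicles, function(f)
    contour_df(f$endo, f$id, "endoneurium")))
  ggplot2::ggplot(mapping = ggplot2::aes(.data$x, .data$y,
                                         group = interaction(.data$id, .data$part))) +
    ggplot2::geom_polygon(data = epi, fill = "#f2e8d5", color = "grey40") +
    ggplot2::geom_polygon(data = fo, fill = "#d5e2f2", color = "grey30") +
    ggplot2::geom_polygon(data = fe, fill = "#9fc2e8", color = NA) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Plot a placed electrode on its nerve cross-section
#'
#' @param placed An `ns_placed`.
#' @return A ggplot with active sites overlaid on the cross-section.
#' @export
plot_placement <- function(placed) {
  p <- autoplot.ns_cross_section(placed$nerve$section)
  st <- placed$sites
  p + ggplot2::geom_point(
    data = tibble::tibble(x = st$u, y = st$v, kind = st$kind),
    mapping = ggplot2::aes(.data$x, .data$y, shape = .data$kind),
    inherit.aes = FALSE, color = "red3", size = 2) +
    ggplot2::labs(shape = "site kind")
}

#' Plot recruitment curves per fascicle
#'
#' Empirical recruitment (fraction of axons at or below each charge) for
#' the best site of each fascicle.
#'
#' @param object An `ns_thresholds`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ns_thresholds <- function(object, ...) {
  fm <- fascicle_metrics(object)
  dfs <- list()
  for (i in seq_len(nrow(fm))) {
    if (!is.finite(fm$threshold_nC[i]) || is.na(fm$best_site[i])) next
    d <- object[object$site == fm$best_site[i] &
                  object$fascicle == fm$fascicle[i], ]
    tt <- sort(d$threshold_nC[is.finite(d$threshold_nC)])
    if (length(tt) == 0) next
    qq <- exp(seq(log(min(tt) * 0.5), log(max(tt) * 2), length.out = 80))
    rc <- recruitment_curve(d$threshold_nC, qq)
    rc$fascicle <- fm$fascicle[i]
    dfs[[length(dfs) + 1]] <- rc
  }
  dd <- dplyr::bind_rows(dfs)
  ggplot2::ggplot(dd, ggplot2::aes(.data$charge_nC, .data$fraction,
                                   color = factor(.data$fascicle))) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "charge (nC)", y = "fraction recruited",
                  color = "fascicle") +
    ggplot2::theme_minimal()
}

#' Plot the geometric-vs-fascicular correlation
#'
#' @param object An `ns_correlation`.
#' @param ... Unused.
#' @return A ggplot: per-fascicle points (circles), configuration means
#'   (crosses), least-squares lines.
#' @exportS3Method ggplot2::autoplot
autoplot.ns_correlation <- function(object, ...) {
  ggplot2::ggplot() +
    ggplot2::geom_point(data = object$points,
                        ggplot2::aes(.data$geometric_selectivity,
                                     .data$fascicular_selectivity),
                        shape = 1, alpha = 0.5) +
    ggplot2::geom_point(data = object$config_means,
                        ggplot2::aes(.data$geometric, .data$fascicular),
                        shape = 4, size = 3, color = "red3") +
    ggplot2::geom_smooth(data = object$config_means,
                         ggplot2::aes(.data$geometric, .data$fascicular),
                         method = "lm", se = FALSE, formula = y ~ x,
                         linetype = 2, color = "red3") +
    ggplot2::labs(x = "geometric selectivity", y = "fascicular selectivity",
                  subtitle = sprintf("R² means = %.2f, R² fascicles = %.2f",
                                     object$r2_mean, object$r2_fascicle)) +
    ggplot2::theme_minimal()
}

#' Plot the AIR optimization score surface
#'
#' @param object An `ns_air_optimum`.
#' @param ... Unused.
#' @return A ggplot tile map of mean geometric selectivity over the
#'   (pitch, length) grid with the optimum marked.
#' @exportS3Method ggplot2::autoplot
autoplot.ns_air_optimum <- function(object, ...) {
  ggplot2::ggplot(object$surface,
                  ggplot2::aes(.data$spike_pitch_um, .data$spike_length_um,
                               fill = .data$mean_selectivity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = object$best, fill = NA, color = "white",
                        shape = 8, size = 3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "spike pitch (µm)", y = "spike length (µm)",
                  fill = "selectivity") +
    ggplot2::theme_minimal()
}
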