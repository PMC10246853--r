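# Configuration, serialization, fixtures and result export. Unit
# conventions at the boundary: um for geometry, S/m for conductivity,
# mA for current, us for pulse width, nC for charge.

#' Default run configuration
#'
#' @return Nested named list of all tunable parameters with defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    mode = "fast",
    nerve = list(preset = "pudendal", area_scale = 1),
    fibers = list(density_mm2 = 2330, mixture_means = c(3.1, 9.2),
                  mixture_sds = c(1.0, 2.0), mixture_weights = c(0.55, 0.45),
                  truncation = c(1, 16), max_per_fascicle = 8),
    electrode = list(family = "air", n_heads = 4, spike_pitch = 600,
                     spike_length = 600, tip_exposure = 200,
                     spikes_per_head = 2),
    solver = list(resolution = 60, tolerance = 1e-6, padding = 2),
    membrane = list(pulse_us = 50, dt_us = 1, window_ms = 2,
                    bisection_tol = 0.01, detail = "reduced"),
    metrics = list(recruitment_level = 0.10),
    output = list(dir = "results")
  )
}

check_config_keys <- function(user, ref, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(ref))
      stop("unknown configuration key: ", paste0(path, nm))
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) && is.list(user[[nm]]))
      check_config_keys(user[[nm]], ref[[nm]], paste0(path, nm, "."))
  }
  invisible(TRUE)
}

merge_config <- function(user, ref) {
  for (nm in names(user)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) && is.list(user[[nm]]))
      ref[[nm]] <- merge_config(user[[nm]], ref[[nm]])
    else ref[[nm]] <- user[[nm]]
  }
  ref
}

#' Load a run configuration from YAML
#'
#' Missing keys are filled with defaults; unknown keys are rejected.
#'
#' @param path YAML file (an empty file yields the full default
#'   configuration).
#' @return Configuration list with a `hash` attribute.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  ref <- default_config()
  check_config_keys(user, ref)
  cfg <- merge_config(user, ref)
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

#' Save a configuration to YAML
#' @param config Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  attr(config, "hash") <- NULL
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Stable configuration hash
#' @param config Configuration list.
#' @return Character hash.
#' @export
config_hash <- function(config) {
  attr(config, "hash") <- NULL
  rlang::hash(config)
}

#' Serialize a nerve to JSON
#'
#' Contours as vertex lists with metadata (areas, seed, trajectory).
#'
#' @param nerve An `ns_nerve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
nerve_to_json <- function(nerve, path) {
  cs <- nerve$section
  tr <- nerve$trajectory
  obj <- list(
    nerve_area = cs$nerve_area, seed = cs$seed, min_gap = cs$min_gap,
    epineurium = unname(as.matrix(cs$epineurium)),
    fascicles = lapply(cs$fascicles, function(f)
      list(id = f$id, area = f$area, outer = unname(as.matrix(f$outer)))),
    trajectory = list(kind = tr$kind, length = tr$length,
                      radius = tr$radius %||% NA,
                      angle_deg = tr$angle_deg %||% NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a nerve back from JSON
#' @param path JSON path written by [nerve_to_json()].
#' @return An `ns_nerve`.
#' @export
nerve_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fascicles <- lapply(seq_len(length(obj$fascicles$id)), function(i) {
    new_fascicle_section(obj$fascicles$outer[[i]], obj$fascicles$area[i],
                         obj$fascicles$id[i])
  })
  cs <- structure(list(epineurium = obj$epineurium, fascicles = fascicles,
                       nerve_area = obj$nerve_area, min_gap = obj$min_gap,
                       seed = obj$seed),
                  class = "ns_cross_section")
  tr <- if (obj$trajectory$kind == "arc")
    trajectory_arc(obj$trajectory$radius, obj$trajectory$angle_deg)
  else trajectory_straight(obj$trajectory$length)
  sweep_nerve(cs, tr)
}

#' Generate a small test fixture
#'
#' Seconds-scale inputs exercising the downstream modules: a 3-fascicle
#' toy nerve, a 20-axon x 4-site threshold matrix with hand-checkable
#' collateral counts, or a coarse lead field on a toy nerve.
#'
#' @param kind `"toy_nerve"`, `"toy_threshold_matrix"` or
#'   `"toy_leadfield"`.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files.
#' @export
generate_fixture <- function(kind = c("toy_nerve", "toy_threshold_matrix",
                                      "toy_leadfield"),
                             seed = 1, dir = tempdir()) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (kind == "toy_nerve") {
    nerve <- toy_nerve(seed)
    path <- file.path(dir, "toy_nerve.json")
    nerve_to_json(nerve, path)
    return(path)
  }
  if (kind == "toy_threshold_matrix") {
    tm <- with_seed(seed, {
      tibble::tibble(
        axon = rep(1:20, times = 4),
        fascicle = rep(rep(1:4, each = 5), times = 4),
        diameter_um = rep(round(stats::runif(20, 2, 14), 1), times = 4),
        site = rep(1:4, each = 20),
        threshold_nC = round(stats::rlnorm(80, log(5), 0.8), 3))
    })
    path <- file.path(dir, "toy_threshold_matrix.csv")
    utils::write.csv(tm, path, row.names = FALSE)
    return(path)
  }
  nerve <- toy_nerve(seed)
  placed <- place_electrode(build_cuff(n_sites = 4), nerve,
                            list(angle = 0), seed = seed)
  raster <- rasterize_tissues(nerve, placed, build_grid(placed, resolution = 40))
  lf <- solve_lead_field(raster, 1, tol = 1e-6)
  meta_path <- file.path(dir, "toy_leadfield.json")
  v_path <- file.path(dir, "toy_leadfield_v.csv")
  jsonlite::write_json(list(site = lf$site, current_mA = lf$current_mA,
                            relres = lf$relres,
                            xc = lf$grid$xc, yc = lf$grid$yc, zc = lf$grid$zc),
                       meta_path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(v = as.vector(lf$v)), v_path, row.names = FALSE)
  c(meta_path, v_path)
}

#' Small 3-fascicle toy nerve
#'
#' A fast, well-conditioned nerve for tests and examples: round 0.8 mm^2
#' epineurium, three fascicles, straight 12 mm course.
#'
#' @param seed Integer seed.
#' @return An `ns_nerve`.
#' @export
toy_nerve <- function(seed = 1) {
  cs <- synthesize_cross_section(0.8e6, 3, seed = seed, epi_aspect = 1,
                                 packing_fraction = 0.4)
  sweep_nerve(cs, trajectory_straight(12e3))
}

#' Export tidy result tables
#'
#' CSV per table plus a JSON summary and a manifest with configuration
#' hash and package versions; re-export with the same inputs is
#' byte-identical.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory.
#' @param config Optional configuration (hashed into the manifest).
#' @return Paths of the written files.
#' @export
export_results <- function(tables, dir, config = NULL) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    df <- as.data.frame(tables[[nm]])
    if (nrow(df) > 1)
      df <- df[do.call(order, df), , drop = FALSE]   # stable ordering
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  summary <- lapply(tables, function(t)
    list(rows = nrow(t), cols = ncol(t), names = names(t)))
  sp <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "nervestim",
    version = as.character(utils::packageVersion("nervestim")),
    config_hash = if (!is.null(config)) config_hash(config) else NA,
    tables = names(tables))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  c(paths, sp, mp)
}
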