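# End-to-end orchestration: generate a chamber, detect and measure, select,
# expose, encapsulate, sort, verify by spike detection, dispense, and write
# every artefact plus a JSON summary into a run directory. One global seed
# deterministically spawns per-stage sub-seeds, so a rerun with the same
# config reproduces every output bit for bit while individual stages remain
# independently re-runnable.

#' Default pipeline configuration
#'
#' Nested list mirroring the module structure; every field can be overridden
#' through [read_pipeline_config()] or by passing a modified copy to
#' [run_pipeline()]. The demo scale (a 6 x 6 mm chamber window with 80
#' spheroids plus 30% debris at 3 um/px) keeps a full run within seconds
#' while leaving enough objects for every filter to act.
#'
#' @param seed Global seed.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 42L) {
  list(
    seed = as.integer(seed),
    synthgen = list(
      chamber = list(width = 6000, height = 6000, pixel_size = 3,
                     background_level = 500, foreground_level = 30000,
                     fluor_level = 20000, noise_sigma = 0.02 * 65535),
      population = list(n = 80, diameter_range = c(120, 280),
                        circularity_range = c(0.55, 1.0),
                        viable_frac = 0.8, debris_frac = 0.3,
                        debris_diameter_range = c(20, 80))
    ),
    detect = list(threshold_method = "otsu", fixed_threshold = NULL,
                  min_area = 100, fill_holes = TRUE, smoothing_sigma = 0),
    select = list(fluor_threshold = 5000, diameter_min = 200,
                  diameter_max = 215, circularity_min = 0.8,
                  ges_footprint_diameter = 550, min_edge_gap = 50,
                  boundary_margin = 325),
    fabricate = list(spot_diameter = 550, gel_cv = 0.05,
                     power_density = 3, exposure_s = 75,
                     wavelength_nm = 405),
    sortsim = list(d1 = 400, d2 = 700, measurement_sigma = 10,
                   trace = list(sampling_rate = 1000, spacing_s = 2,
                                baseline = 100, baseline_sigma = 2,
                                amplitude_k = 10, spike_width = 0.05,
                                threshold_k = 5, refractory_s = 0.5),
                   per_well = 1)
  )
}

# Recursive key validation: unknown keys anywhere in the tree are rejected
# so typos cannot silently fall back to defaults.
check_config_keys <- function(cfg, template, path = "") {
  extra <- setdiff(names(cfg), names(template))
  if (length(extra)) {
    stopf("unknown configuration key%s: %s",
          if (length(extra) > 1) "s" else "",
          paste0(path, extra, collapse = ", "))
  }
  for (k in names(cfg)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]]))) {
      if (!is.list(cfg[[k]])) stopf("configuration section '%s%s' must be a mapping", path, k)
      check_config_keys(cfg[[k]], template[[k]], paste0(path, k, "."))
    }
  }
  invisible(cfg)
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]) &&
                     !is.null(names(base[[k]]))) {
      merge_config(base[[k]], override[[k]])
    } else override[[k]]
  }
  base
}

#' Read and validate a pipeline configuration file
#'
#' YAML file with (any subset of) the sections of
#' [default_pipeline_config()]; missing fields take the defaults, unknown
#' keys are an error. Numeric invariants are validated when the stage
#' constructors run.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  template <- default_pipeline_config()
  check_config_keys(user, template)
  merge_config(template, user)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full pipeline into a run directory
#'
#' Executes generate -> detect -> select -> photomask -> encapsulate ->
#' sort -> spike-detect -> dispense, writing images (TIFF/PNG), tables
#' (CSV) and a `summary.json` with stage counts, selected-set uniformity
#' statistics and sorting accuracy. Any stage error aborts with the stage
#' name; artefacts written before the failure are retained for post-mortem.
#'
#' @param config Configuration list (see [default_pipeline_config()]).
#' @param out_dir Run directory, created if needed.
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("spheroidfab_run_")) {
  check_config_keys(config, default_pipeline_config())
  config <- merge_config(default_pipeline_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 4L)   # population, noise, gel, sorter

  cg <- config$synthgen$chamber
  pop_cfg <- config$synthgen$population
  spec <- stage("synthgen", chamber_spec(
    width = cg$width, height = cg$height, pixel_size = cg$pixel_size,
    background_level = cg$background_level,
    foreground_level = cg$foreground_level, fluor_level = cg$fluor_level,
    noise_sigma = cg$noise_sigma, seed = seeds[2]))
  truth <- stage("synthgen", sample_population(
    n = pop_cfg$n, diameter_dist = pop_cfg$diameter_range,
    circularity_dist = pop_cfg$circularity_range,
    viable_frac = pop_cfg$viable_frac, chamber = spec, seed = seeds[1],
    debris_frac = pop_cfg$debris_frac,
    debris_diameter = pop_cfg$debris_diameter_range))
  images <- stage("synthgen", generate_chamber(spec, truth))
  stage("synthgen", write_chamber(images, out_dir))

  dcfg <- stage("detect", detect_config(
    threshold_method = config$detect$threshold_method,
    fixed_threshold = config$detect$fixed_threshold,
    min_area = config$detect$min_area,
    fill_holes = config$detect$fill_holes,
    smoothing_sigma = config$detect$smoothing_sigma))
  objects <- stage("detect", detect_objects(images$darkfield,
                                            images$fluorescence, dcfg,
                                            spec$pixel_size))
  stage("detect", write_measurements(objects,
                                     file.path(out_dir, "measurements.csv")))

  s <- config$select
  scfg <- stage("select", selection_config(
    fluor_threshold = s$fluor_threshold, diameter_min = s$diameter_min,
    diameter_max = s$diameter_max, circularity_min = s$circularity_min,
    ges_footprint_diameter = s$ges_footprint_diameter,
    min_edge_gap = s$min_edge_gap, boundary_margin = s$boundary_margin))
  selection <- stage("select", run_selection(objects, spec, scfg))
  stage("select", write_selection(selection,
                                  file.path(out_dir, "selection.csv"),
                                  file.path(out_dir, "selection.json")))

  f <- config$fabricate
  mask <- stage("fabricate", build_photomask(
    selection, spot_diameter = f$spot_diameter, chamber = spec,
    pixel_size = spec$pixel_size, power_density = f$power_density,
    exposure_s = f$exposure_s, wavelength_nm = f$wavelength_nm))
  stage("fabricate", write_photomask(mask,
                                     file.path(out_dir, "photomask.png"),
                                     file.path(out_dir, "photomask.json")))
  ges <- stage("fabricate", simulate_encapsulation(
    selection, spot_diameter = f$spot_diameter, gel_cv = f$gel_cv,
    seed = seeds[3], exposure = mask$exposure))
  ges_tab <- as.data.frame(ges)
  ges_tab$power_density_mw_cm2 <- rep(mask$exposure$power_density_mw_cm2,
                                      nrow(ges_tab))
  ges_tab$exposure_s <- rep(mask$exposure$exposure_s, nrow(ges_tab))
  ges_tab$wavelength_nm <- rep(mask$exposure$wavelength_nm, nrow(ges_tab))
  stage("fabricate", write.csv(ges_tab, file.path(out_dir, "ges.csv"),
                               row.names = FALSE))

  # everything flushed from the chamber reaches the sorter: the GES gel
  # discs plus every detected-but-unselected object at its measured size
  so <- config$sortsim
  gates <- stage("sortsim", sorter_gates(d1 = so$d1, d2 = so$d2,
                                         measurement_sigma = so$measurement_sigma))
  unselected <- objects$diameter_um[!objects$id %in% ges$source_spheroid_id]
  batch_d <- c(ges$gel_diameter_um, unselected)
  outcome <- stage("sortsim", sort_batch(batch_d, gates, seed = seeds[4]))
  stage("sortsim", write.csv(as.data.frame(outcome),
                             file.path(out_dir, "sort_outcome.csv"),
                             row.names = FALSE))
  n_ges <- nrow(ges)
  collected <- sum(outcome$routed[seq_len(n_ges)] == "collect")

  tr <- so$trace
  events <- NULL
  plate <- dispense(0L, per_well = so$per_well)
  if (collected > 0) {
    tspec <- stage("sortsim", trace_spec(
      arrival_times = seq_len(collected) * tr$spacing_s,
      sampling_rate = tr$sampling_rate, baseline = tr$baseline,
      baseline_sigma = tr$baseline_sigma,
      spike_amplitude = tr$amplitude_k * tr$baseline_sigma,
      spike_width = tr$spike_width, seed = seeds[4]))
    trace <- stage("sortsim", generate_trace(tspec))
    write.csv(trace, file.path(out_dir, "trace.csv"), row.names = FALSE)
    events <- stage("sortsim", detect_spikes(trace,
                                             threshold_k = tr$threshold_k,
                                             refractory = tr$refractory_s))
    plate <- stage("sortsim", dispense(events, per_well = so$per_well))
  }
  stage("sortsim", write_plate_map(plate, file.path(out_dir, "plate_map.csv")))

  sel_obj <- selection$objects[selection$objects$status == "SELECTED", ]
  reasons <- table(factor(selection$rejected$reason, levels = REASON_CODES))
  summary <- list(
    seed = config$seed,
    counts = list(
      truth_objects = nrow(truth),
      detected = nrow(objects),
      viable = sum(selection$objects$viable),
      selected = nrow(sel_obj),
      encapsulated = n_ges,
      collected = collected,
      events = if (is.null(events)) 0L else length(events$event_times),
      dispensed = nrow(plate)),
    rejections = as.list(setNames(as.integer(reasons), names(reasons))),
    uniformity = list(
      diameter_min_um = if (nrow(sel_obj)) min(sel_obj$diameter_um) else NA,
      diameter_max_um = if (nrow(sel_obj)) max(sel_obj$diameter_um) else NA,
      circularity_mean = if (nrow(sel_obj)) mean(sel_obj$circularity) else NA,
      circularity_sd = if (nrow(sel_obj) > 1) sd(sel_obj$circularity) else NA),
    sorting_accuracy = attr(outcome, "accuracy"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Human-readable report for a completed run directory
#'
#' Rebuilds the per-filter rejection table (which always totals to the
#' detected count) and the headline statistics from the run artefacts.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return Character vector of markdown lines (also printable via `cat`).
#' @export
pipeline_report <- function(run_dir) {
  need <- file.path(run_dir, c("summary.json", "selection.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stopf("run directory is missing artefact(s): %s",
          paste(basename(missing), collapse = ", "))
  }
  s <- jsonlite::read_json(need[1], simplifyVector = TRUE)
  lines <- c(
    sprintf("# Pipeline run report (seed %s)", s$seed),
    "",
    sprintf("- detected objects: %d", s$counts$detected),
    sprintf("- viable (Calcein-positive): %d", s$counts$viable),
    sprintf("- selected for encapsulation: %d", s$counts$selected),
    sprintf("- encapsulated (GES): %d", s$counts$encapsulated),
    sprintf("- collected by sorter: %d", s$counts$collected),
    sprintf("- dispensed into wells: %d", s$counts$dispensed),
    sprintf("- sorting accuracy: %.3f", s$sorting_accuracy),
    "",
    "| rejection reason | count |",
    "|---|---|")
  for (r in REASON_CODES) {
    lines <- c(lines, sprintf("| %s | %d |", r, s$rejections[[r]] %||% 0L))
  }
  if (s$counts$selected > 0) {
    lines <- c(lines, "",
               sprintf("Selected-set uniformity: diameter %.1f-%.1f um, circularity %.2f +/- %.2f",
                       s$uniformity$diameter_min_um,
                       s$uniformity$diameter_max_um,
                       s$uniformity$circularity_mean,
                       s$uniformity$circularity_sd %||% NA))
  }
  lines
}
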