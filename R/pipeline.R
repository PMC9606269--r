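pb_defaults <- function() {
  list(
    detect = list(n_detect_frames = 3, n_levels = 3, k_sigma = 3,
                  detect_level = 2, min_separation = 2, half_window = 3,
                  min_amplitude = NULL, refine = TRUE, refine_passes = 2,
                  merge_radius = 2, min_track_detections = 2,
                  exclude_overlaps = FALSE),
    link = list(max_displacement = 2, max_gap = 0),
    trace = list(aperture_radius = 3, annulus = c(5, 7)),
    qc = list(end_tol = 0.5, blink_thresh = 0.5, end_window = 20,
              min_duration = 3, neighbor_radius = NULL),
    steps = list(min_step_frac = 0.5, penalty = NULL),
    correct = list(p_f = NULL, n_max = NULL, conditional = TRUE,
                   bootstrap = 0, conf_level = 0.95, cell_area = 1200)
  )
}

merge_section <- function(defaults, user, section) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown key(s) in config section `%s`: %s",
                  section, paste(unknown, collapse = ", ")))
  }
  utils::modifyList(defaults, user)
}

#' Assemble and validate a full pipeline configuration
#'
#' Merges user settings over defaults for every pipeline stage, rejects
#' unknown keys with a named error, and bounds-checks the simulation
#' parameters through [sim_config()]. Stage sections: `sim` (see
#' [sim_config()]), `detect`, `link`, `trace`, `qc`, `steps`, `correct`.
#'
#' @param sim,detect,link,trace,qc,steps,correct Named lists of stage
#'   parameters (defaults used for anything omitted).
#' @param seed Integer seed making the whole run reproducible.
#' @param stages Character vector of stages to run, in order; a prefix of
#'   `c("simulate", "detect", "link", "trace", "steps", "correct")`.
#' @return A validated list of class `pb_config`.
#' @export
pb_config <- function(sim = list(), detect = list(), link = list(),
                      trace = list(), qc = list(), steps = list(),
                      correct = list(), seed = NULL,
                      stages = c("simulate", "detect", "link", "trace",
                                 "steps", "correct")) {
  all_stages <- c("simulate", "detect", "link", "trace", "steps", "correct")
  if (!all(stages %in% all_stages)) {
    abort(sprintf("Unknown stage(s): %s",
                  paste(setdiff(stages, all_stages), collapse = ", ")))
  }
  sim_known <- names(formals(sim_config))
  unknown <- setdiff(names(sim), sim_known)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown key(s) in config section `sim`: %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg_sim <- do.call(sim_config, sim)
  d <- pb_defaults()
  out <- list(
    sim = cfg_sim,
    detect = merge_section(d$detect, detect, "detect"),
    link = merge_section(d$link, link, "link"),
    trace = merge_section(d$trace, trace, "trace"),
    qc = merge_section(d$qc, qc, "qc"),
    steps = merge_section(d$steps, steps, "steps"),
    correct = merge_section(d$correct, correct, "correct"),
    seed = seed,
    stages = stages
  )
  if (is.null(out$correct$p_f)) out$correct$p_f <- cfg_sim$labeling_efficiency
  if (is.null(out$correct$n_max)) out$correct$n_max <- cfg_sim$n_max
  if (is.null(out$qc$neighbor_radius)) {
    out$qc$neighbor_radius <- 3 * cfg_sim$psf_sigma
  }
  assert_probability(out$correct$p_f, "correct$p_f")
  structure(out, class = "pb_config")
}

#' Parse and validate a pipeline configuration from JSON
#'
#' @param raw Path to a JSON config file, a JSON string, or a named list.
#' @return A validated [pb_config()].
#' @export
validate_config <- function(raw) {
  if (inherits(raw, "pb_config")) return(raw)
  if (is.character(raw)) {
    raw <- jsonlite::fromJSON(raw, simplifyVector = TRUE)
  }
  if (!is.list(raw)) abort("Config must be a named list or JSON object.")
  known <- names(formals(pb_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown top-level config key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  do.call(pb_config, raw)
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full photobleaching analysis pipeline
#'
#' Executes simulate, detect, link, trace, step counting, and
#' stoichiometry correction in order (or the prefix selected in the config),
#' returning a consolidated report. Deterministic given `seed`. When
#' `out_dir` is given, intermediate artifacts are written there (movie as
#' 16-bit TIFF, tables as CSV, report as JSON).
#'
#' @param config A [pb_config()] (or anything [validate_config()] accepts).
#' @param seed Integer seed; overrides `config$seed`.
#' @param out_dir Optional output directory for artifacts.
#' @param verbose Log per-stage progress and counts?
#' @return A list of class `pb_report`: stage record counts, observed
#'   histogram, unit-intensity estimate, the `oligomer_correction` object,
#'   entity and grouped fractions, density and receptors-per-cell, and the
#'   seed.
#' @export
run_pipeline <- function(config = pb_config(), seed = NULL, out_dir = NULL,
                         verbose = FALSE) {
  config <- validate_config(config)
  if (is.null(seed)) seed <- config$seed
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  with_seed_if(seed, run_pipeline_impl(config, out_dir, verbose, seed))
}

run_pipeline_impl <- function(config, out_dir, verbose, seed) {
  stages <- config$stages
  cfg <- config$sim
  report <- list(seed = seed, stages = stages)
  save_csv <- function(x, name) {
    if (!is.null(out_dir)) write_pb_csv(x, file.path(out_dir, name))
  }

  # -- simulate ---------------------------------------------------------------
  sim <- simulate_movie(cfg)
  report$n_particles <- nrow(sim$truth)
  report$n_visible <- sum(sim$truth$visible)
  report$realized_density <- sim$realized_density
  pipeline_log(verbose, "simulate: %d particles (%d visible), %.3g /um^2",
               report$n_particles, report$n_visible, sim$realized_density)
  save_csv(sim$truth, "ground_truth.csv")
  if (!is.null(out_dir) && identical(stages, "simulate")) {
    write_movie_tiff(sim$movie, file.path(out_dir, "movie.tif"))
  }
  if (!"detect" %in% stages) {
    return(structure(report, class = "pb_report"))
  }

  # -- detect -----------------------------------------------------------------
  det <- config$detect
  det_frames <- cfg$preacq_frames + seq_len(min(det$n_detect_frames,
                                                cfg$n_frames - cfg$preacq_frames))
  spots <- detect_spots(
    sim$movie, frames = det_frames, n_levels = det$n_levels,
    k_sigma = det$k_sigma, detect_level = det$detect_level,
    min_separation = det$min_separation, half_window = det$half_window,
    sigma_init = cfg$psf_sigma, min_amplitude = det$min_amplitude,
    refine = det$refine, refine_passes = det$refine_passes,
    merge_radius = det$merge_radius,
    exclude_overlaps = det$exclude_overlaps)
  report$n_detections <- nrow(spots)
  first_frame_spots <- spots %>% filter(.data$frame == det_frames[1])
  report$density <- spot_density(first_frame_spots, fov_area(sim$movie))
  pipeline_log(verbose, "detect: %d detections over %d frames, %.3g /um^2",
               nrow(spots), length(det_frames), report$density)
  save_csv(spots, "spots.csv")
  if (!"link" %in% stages) return(structure(report, class = "pb_report"))

  # -- link + trace -----------------------------------------------------------
  tracks <- link_spots(spots, config$link$max_displacement,
                       config$link$max_gap)
  anchors <- track_anchors(tracks) %>%
    filter(.data$n_detections >= min(config$detect$min_track_detections,
                                     length(det_frames)))
  report$n_tracks <- nrow(anchors)
  pipeline_log(verbose, "link: %d tracks", nrow(anchors))
  save_csv(tracks, "tracks.csv")
  if (!"trace" %in% stages) return(structure(report, class = "pb_report"))

  tr <- extract_traces(sim$movie, anchors, config$trace$aperture_radius,
                       config$trace$annulus)
  traces <- tr$traces %>% filter(.data$frame > cfg$preacq_frames)
  report$n_traces <- length(unique(traces$track_id))
  report$n_border_rejected <- nrow(tr$rejected)
  pipeline_log(verbose, "trace: %d traces (%d rejected at border)",
               report$n_traces, nrow(tr$rejected))
  save_csv(traces, "traces.csv")
  if (!"steps" %in% stages) return(structure(report, class = "pb_report"))

  # -- step counting ----------------------------------------------------------
  sa <- analyze_traces(traces, min_step_frac = config$steps$min_step_frac,
                       penalty = config$steps$penalty)
  report$unit_intensity <- sa$unit_intensity
  qc <- qc_filter_traces(
    traces, unit_intensity = sa$unit_intensity, anchors = anchors,
    neighbor_radius = config$qc$neighbor_radius, end_tol = config$qc$end_tol,
    blink_thresh = config$qc$blink_thresh, end_window = config$qc$end_window,
    min_duration = config$qc$min_duration)
  accepted_ids <- unique(qc$accepted$track_id)
  fits <- sa$step_fits %>% filter(.data$track_id %in% accepted_ids)
  report$n_qc_accepted <- length(accepted_ids)
  report$qc_rejections <- qc$rejections %>% count(.data$reason)
  histogram <- aggregate_histogram(fits, n_max = config$correct$n_max)
  report$histogram <- histogram
  report$n_histogram <- attr(histogram, "total")
  report$n_overflow <- attr(histogram, "n_overflow")
  pipeline_log(verbose,
               "steps: unit %.3g counts; %d QC-accepted, histogram n = %d",
               sa$unit_intensity, report$n_qc_accepted, report$n_histogram)
  save_csv(fits, "step_fits.csv")
  save_csv(qc$rejections, "qc_rejections.csv")
  save_csv(histogram, "step_histogram.csv")
  if (!"correct" %in% stages) return(structure(report, class = "pb_report"))

  # -- stoichiometry correction ----------------------------------------------
  cc <- config$correct
  correction <- correct_stoichiometry(
    histogram, p_f = cc$p_f, n_max = cc$n_max, conditional = cc$conditional,
    bootstrap = cc$bootstrap, conf_level = cc$conf_level)
  corrected <- tidy(correction)
  report$correction <- correction
  report$corrected <- corrected
  report$entity <- tibble(order = corrected$order,
                          fraction = particle_to_entity(corrected$fraction))
  report$grouped_particles <- group_fractions(corrected$fraction)
  report$grouped_entities <- group_fractions(report$entity$fraction)
  report$receptors_per_cell <- receptors_per_cell(report$density,
                                                  cc$cell_area)
  pipeline_log(verbose, "correct: fractions (%s), residual %.3g",
               paste(sprintf("%.3f", corrected$fraction), collapse = ", "),
               correction$residual_norm)
  save_csv(corrected, "corrected_fractions.csv")
  if (!is.null(out_dir)) {
    jsonlite::write_json(report_as_list(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  structure(report, class = "pb_report")
}

report_as_list <- function(report) {
  keep <- setdiff(names(report), "correction")
  out <- report[keep]
  out$histogram <- as.list(as.data.frame(report$histogram))
  if (!is.null(report$correction)) {
    out$residual_norm <- report$correction$residual_norm
    out$condition_indicator <- report$correction$condition_indicator
    out$p_f <- report$correction$p_f
  }
  out
}

#' @export
print.pb_report <- function(x, ...) {
  cat("Photobleaching pipeline report\n")
  cat(sprintf("  particles simulated: %d (%d visible)\n",
              x$n_particles, x$n_visible))
  if (!is.null(x$density)) {
    cat(sprintf("  detected density: %.3g /um^2", x$density))
    if (!is.null(x$receptors_per_cell)) {
      cat(sprintf("  (~%d receptors/cell)", x$receptors_per_cell))
    }
    cat("\n")
  }
  if (!is.null(x$n_tracks)) {
    cat(sprintf("  tracks: %d; QC-accepted traces: %s; histogram n = %s\n",
                x$n_tracks,
                x$n_qc_accepted %||% "-", x$n_histogram %||% "-"))
  }
  if (!is.null(x$histogram)) {
    cat("  observed steps:",
        paste(sprintf("%d:%d", x$histogram$m, x$histogram$count),
              collapse = "  "), "\n")
  }
  if (!is.null(x$corrected)) {
    cat("  corrected fractions:",
        paste(sprintf("%.3f", x$corrected$fraction), collapse = ", "), "\n")
  }
  invisible(x)
}
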