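#' Validate a track CSV file
#'
#' Checks the track schema (`track_id, frame, x_um, y_um`), that frames are
#' non-negative integers and strictly increasing within each track, that no
#' (track, frame) pair is duplicated, and that coordinates look like
#' micrometres rather than pixels (warning when values greatly exceed the
#' stated field of view).
#'
#' @param file path to a track CSV.
#' @param fov_um optional field-of-view extent in micrometres used for the
#'   unit sanity check.
#' @return A list of class `track_report` with `ok`, `n_tracks`, `n_points`,
#'   `errors` (character), `warnings` (character).
#' @export
validate_tracks <- function(file, fov_um = NULL) {
  if (!file.exists(file)) stop("unreadable file: ", file)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  errors <- character(0)
  warns <- character(0)
  need <- c("track_id", "frame", "x_um", "y_um")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    errors <- c(errors, paste0("missing column(s): ",
                               paste(missing_cols, collapse = ", ")))
  } else {
    if (any(!is.finite(df$x_um)) || any(!is.finite(df$y_um))) {
      errors <- c(errors, "non-finite coordinates")
    }
    if (any(df$frame < 0 | df$frame != round(df$frame))) {
      errors <- c(errors, "frames must be non-negative integers")
    }
    dup <- duplicated(df[, c("track_id", "frame")])
    if (any(dup)) {
      errors <- c(errors, paste0("duplicated (track_id, frame) at row(s): ",
                                 paste(utils::head(which(dup), 10), collapse = ", ")))
    }
    if (!is.null(fov_um)) {
      mx <- max(abs(c(df$x_um, df$y_um)), na.rm = TRUE)
      if (is.finite(mx) && mx > 10 * max(fov_um)) {
        warns <- c(warns, sprintf(
          "coordinates up to %.3g with a %g um field of view: values look like pixels; convert with pixel_size_um at import",
          mx, max(fov_um)))
      }
    }
  }
  structure(list(ok = length(errors) == 0L,
                 n_tracks = if ("track_id" %in% names(df)) length(unique(df$track_id)) else NA_integer_,
                 n_points = nrow(df), errors = errors, warnings = warns),
            class = "track_report")
}

#' @export
print.track_report <- function(x, ...) {
  cat(sprintf("track_report: %s (%s tracks, %d points)\n",
              if (x$ok) "OK" else "INVALID", x$n_tracks, x$n_points))
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

pipeline_schema <- list(
  seed = "integer", out_dir = "character", frame_interval = "numeric"
)

check_config_fields <- function(config) {
  problems <- character(0)
  for (field in names(pipeline_schema)) {
    if (is.null(config[[field]])) {
      problems <- c(problems, paste0("missing required field: ", field))
    }
  }
  if (!is.null(config$frame_interval) && config$frame_interval <= 0) {
    problems <- c(problems, "frame_interval must be > 0")
  }
  problems
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the stages in dependency order — simulate ground-truth tracks,
#' render detections, re-link them with the LAP tracker, fit the step-size
#' diffusion mixture, fit the dwell-time mixture, and process simulated
#' recruitment traces — writing every artifact plus a machine-readable
#' provenance record (configuration, seed, package version, config hash) to
#' the output directory. Rerunning with the same configuration and seed
#' reproduces the artifacts byte for byte. A failing stage aborts with an
#' error naming the stage.
#'
#' @param config path to a YAML configuration or an equivalent list. Required
#'   fields: `seed`, `out_dir`, `frame_interval`; stage blocks `simulate`
#'   (fields of [sim_config()] minus seed/frame_interval), optional `track`,
#'   `stepsize`, `dwell`, `recruit` parameter blocks.
#' @return Invisibly, a named character vector of artifact paths (the
#'   manifest).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  problems <- check_config_fields(config)
  if (length(problems) > 0L) {
    stop("invalid pipeline config:\n  ", paste(problems, collapse = "\n  "))
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- c()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sim_cfg <- stage("simulate", {
    sc <- config$simulate
    if (is.null(sc)) stop("missing 'simulate' block")
    sim_config(
      n_particles = sc$n_particles, n_frames = sc$n_frames,
      states = unlist(sc$states),
      frame_interval = config$frame_interval,
      fov = if (!is.null(sc$fov)) unlist(sc$fov) else c(25, 25),
      switch_rates = if (!is.null(sc$switch_rates)) do.call(rbind, sc$switch_rates) else NULL,
      desorb_rate = if (!is.null(sc$desorb_rate)) unlist(sc$desorb_rate) else 0,
      adsorb_rate = if (!is.null(sc$adsorb_rate)) sc$adsorb_rate else 0,
      loc_noise_sigma = if (!is.null(sc$loc_noise_sigma)) sc$loc_noise_sigma else 0,
      p_missed_detection = if (!is.null(sc$p_missed_detection)) sc$p_missed_detection else 0,
      seed = config$seed
    )
  })
  sim <- stage("simulate", simulate_trajectories(sim_cfg))
  truth_file <- file.path(out_dir, "truth_tracks.csv")
  write_tracks_csv(sim$tracks, truth_file)
  manifest["truth_tracks"] <- truth_file

  det <- stage("detections", render_detections(
    sim$tracks, loc_noise_sigma = sim_cfg$loc_noise_sigma,
    p_missed_detection = sim_cfg$p_missed_detection,
    seed = config$seed + 1L))
  det_file <- file.path(out_dir, "detections.csv")
  utils::write.csv(as.data.frame(det), det_file, row.names = FALSE, quote = FALSE)
  manifest["detections"] <- det_file

  tc <- config$track
  tracks <- stage("track", link_detections(
    det,
    max_link_dist = if (!is.null(tc$max_link_dist)) tc$max_link_dist else 1.5,
    max_gap = if (!is.null(tc$max_gap)) tc$max_gap else 2,
    max_gap_dist = if (!is.null(tc$max_gap_dist)) tc$max_gap_dist else 1.5,
    frame_interval = config$frame_interval))
  tracks_file <- file.path(out_dir, "tracks.csv")
  write_tracks_csv(tracks, tracks_file)
  manifest["tracks"] <- tracks_file

  ssc <- config$stepsize
  delays <- if (!is.null(ssc$delays)) unlist(ssc$delays) else 1:4
  fit <- stage("stepsize", fit_stepsize_distribution(
    tracks, delays = delays,
    n_components = if (!is.null(ssc$n_components)) ssc$n_components else 3,
    bin_width = if (!is.null(ssc$bin_width)) ssc$bin_width else 0.05,
    r_max = if (!is.null(ssc$r_max)) ssc$r_max else 2.5))
  hist_rows <- do.call(rbind, lapply(delays, function(k) {
    h <- build_histogram(compute_steps(tracks, k),
                         bin_width = if (!is.null(ssc$bin_width)) ssc$bin_width else 0.05,
                         r_max = if (!is.null(ssc$r_max)) ssc$r_max else 2.5)
    data.frame(tau_s = h$tau,
               bin_lo_um = h$bin_edges[-length(h$bin_edges)],
               bin_hi_um = h$bin_edges[-1],
               count = h$counts, density = h$density)
  }))
  hist_file <- file.path(out_dir, "step_histograms.csv")
  utils::write.csv(hist_rows, hist_file, row.names = FALSE, quote = FALSE)
  manifest["step_histograms"] <- hist_file
  fit_file <- file.path(out_dir, "stepsize_fit.json")
  jsonlite::write_json(list(
    components = fit$components, chi_square = fit$chi_square,
    delays_used_s = fit$delays_used, n_steps_per_delay = fit$n_steps_per_delay
  ), fit_file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest["stepsize_fit"] <- fit_file

  dwc <- config$dwell
  dw <- stage("dwell", compute_dwell_times(tracks, sim_cfg$n_frames))
  dwell_file <- file.path(out_dir, "dwell_times.csv")
  utils::write.csv(dw, dwell_file, row.names = FALSE, quote = FALSE)
  manifest["dwell_times"] <- dwell_file
  dw_fit <- stage("dwell", fit_dwell(
    dw, n_components = if (!is.null(dwc$n_components)) dwc$n_components else 2,
    truncation = config$frame_interval))
  dwfit_file <- file.path(out_dir, "dwell_fit.json")
  jsonlite::write_json(list(
    components = dw_fit$components, log_likelihood = dw_fit$log_likelihood,
    n_used = dw_fit$n_used, n_censored_excluded = dw_fit$n_censored_excluded
  ), dwfit_file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest["dwell_fit"] <- dwfit_file

  rc <- config$recruit
  if (!is.null(rc)) {
    traces <- stage("recruit", lapply(seq_len(rc$n_replicates), function(i) {
      difference_intensity(simulate_recruitment_trace(
        baseline_level = rc$baseline_level, plateau_delta = rc$plateau_delta,
        rate_per_s = rc$rate_per_s, addition_frame = rc$addition_frame,
        noise_sigma = rc$noise_sigma, n_frames = rc$n_frames,
        seed = config$seed + 100L + i, replicate = i))
    }))
    agg <- stage("recruit", aggregate_replicates(traces))
    rec_file <- file.path(out_dir, "recruitment_mean.csv")
    utils::write.csv(agg, rec_file, row.names = FALSE, quote = FALSE)
    manifest["recruitment_mean"] <- rec_file
  }

  cfg_file <- file.path(out_dir, "config_used.yaml")
  yaml::write_yaml(config, cfg_file)
  prov <- list(
    package = "memtrack",
    version = as.character(utils::packageVersion("memtrack")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    artifacts = as.list(manifest)
  )
  prov_file <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, prov_file, auto_unbox = TRUE, pretty = TRUE)
  manifest["config"] <- cfg_file
  manifest["provenance"] <- prov_file
  invisible(manifest)
}
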