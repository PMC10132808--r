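# shared fixtures and oracle helpers, all built in code

# an adsorption trace from raw intensities on a 15 s grid
make_trace <- function(intensity, addition_index = 10, dt = 15, rep = 1L) {
  adsorption_trace((seq_along(intensity) - 1) * dt, intensity,
                   addition_index = addition_index, replicate = rep)
}

# a step_sample data frame from raw displacement magnitudes
steps_from_r <- function(r, delay_frames, dt = 0.02) {
  s <- data.frame(track_id = rep(1L, length(r)), r = r,
                  delay_frames = rep(as.integer(delay_frames), length(r)),
                  tau = rep(delay_frames * dt, length(r)))
  class(s) <- c("step_sample", "data.frame")
  s
}

# a gap-free straight-line track of given length
line_track <- function(track_id, length, dx = 0.1, start_frame = 0L) {
  data.frame(track_id = track_id, frame = start_frame + seq_len(length) - 1L,
             x_um = dx * (seq_len(length) - 1L), y_um = 0)
}

# does a linked trajectory_set reproduce the hidden truth partition exactly?
# matches localizations back to detections by (frame, x, y)
partition_matches_truth <- function(tracks, detections) {
  df <- as.data.frame(tracks)
  key <- function(d) paste(d$frame, d$x_um, d$y_um)
  truth <- detections$truth_id[match(key(df), key(detections))]
  if (any(is.na(truth))) return(FALSE)
  tab <- table(df$track_id, truth)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# minimum distance between co-present particles across all frames
min_pair_separation <- function(tracks) {
  df <- as.data.frame(tracks)
  mins <- vapply(split(df, df$frame), function(fr) {
    if (nrow(fr) < 2L) return(Inf)
    min(stats::dist(cbind(fr$x_um, fr$y_um)))
  }, numeric(1))
  min(mins)
}

# sparse noiseless simulation used by the tracker-oracle tests; at this
# density and mobility the seeds below keep particles > 1 um apart, so the
# ground-truth partition is the unique unambiguous assignment
sparse_sim <- function(seed, n_particles = 12, d = 0.5) {
  cfg <- sim_config(n_particles = n_particles, n_frames = 40,
                    states = c(free = d), fov = c(60, 60),
                    boundary = "reflecting", seed = seed)
  simulate_trajectories(cfg)
}
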