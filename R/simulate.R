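#' Stationary distribution of the switching CTMC
#'
#' @param switch_rates square matrix of per-second off-diagonal transition
#'   rates (diagonal ignored).
#' @return Probability vector over states. With no switching the uniform
#'   distribution is returned.
#' @keywords internal
ctmc_stationary <- function(switch_rates) {
  k <- nrow(switch_rates)
  if (all(switch_rates == 0)) return(rep(1 / k, k))
  gen <- switch_rates
  diag(gen) <- 0
  diag(gen) <- -rowSums(gen)
  # solve pi %*% gen = 0 with sum(pi) = 1 by least squares
  a <- rbind(t(gen), rep(1, k))
  b <- c(rep(0, k), 1)
  p <- as.vector(qr.solve(a, b))
  p[p < 0] <- 0
  p / sum(p)
}

# piecewise-constant state path of one particle from birth to desorption,
# simulated with exact exponential waiting times (no per-frame approximation)
simulate_state_path <- function(t0, t_end, init_state, switch_rates, desorb_rate) {
  seg_t <- numeric(0)
  seg_s <- integer(0)
  t <- t0
  s <- init_state
  desorbed <- FALSE
  repeat {
    seg_t <- c(seg_t, t)
    seg_s <- c(seg_s, s)
    rate_sw <- sum(switch_rates[s, ])
    rate_out <- rate_sw + desorb_rate[s]
    dt_ev <- if (rate_out > 0) stats::rexp(1L, rate_out) else Inf
    if (t + dt_ev >= t_end) {
      t_death <- t_end
      break
    }
    t <- t + dt_ev
    if (stats::runif(1L) < desorb_rate[s] / rate_out) {
      t_death <- t
      desorbed <- TRUE
      break
    }
    s <- sample.int(ncol(switch_rates), 1L, prob = switch_rates[s, ])
  }
  list(seg_t = seg_t, seg_s = seg_s, t_death = t_death, desorbed = desorbed)
}

apply_boundary <- function(x, width, boundary) {
  if (boundary == "periodic") {
    x %% width
  } else {
    # reflect into [0, width] by folding over a period of 2*width
    y <- x %% (2 * width)
    ifelse(y > width, 2 * width - y, y)
  }
}

#' Simulate membrane-bound particle trajectories
#'
#' Generates ground-truth-labeled trajectories of particles diffusing on a
#' supported membrane. Each particle performs 2D Brownian motion whose
#' diffusion coefficient is set by a hidden state evolving as a continuous-time
#' Markov chain (exact exponential waiting times, not a per-frame
#' approximation); particles leave the membrane with a per-state exponential
#' desorption rate, and (optionally) new particles adsorb at a constant rate.
#' Per frame, the position advances by independent Gaussian increments with
#' per-axis variance `2 * D(state) * frame_interval`, where the state is the
#' hidden state at the start of the frame. Positions wrap (periodic, default)
#' or reflect at the field-of-view boundary. Output is fully determined by the
#' configuration seed.
#'
#' @param config a [sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{`tracks`}{a [trajectory_set()] with a ground-truth `state` column;}
#'     \item{`truth`}{a list with `states` (the true D per state label),
#'       `occupancy` (fraction of recorded frames per state), `dwell`
#'       (per-particle birth/death times, dwell durations in seconds, and a
#'       censoring flag for particles alive at the end of the movie), and
#'       `config` (the configuration used).}
#'   }
#' @export
simulate_trajectories <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  set.seed(config$seed)
  k <- length(config$states)
  d_states <- as.numeric(config$states)
  dt <- config$frame_interval
  t_end <- config$n_frames * dt
  pi0 <- ctmc_stationary(config$switch_rates)

  n_ads <- if (config$adsorb_rate > 0) stats::rpois(1L, config$adsorb_rate * t_end) else 0L
  birth <- c(rep(0, config$n_particles),
             if (n_ads > 0L) sort(stats::runif(n_ads, 0, t_end)) else numeric(0))
  n_total <- length(birth)

  pts <- vector("list", n_total)
  death <- numeric(n_total)
  desorbed <- logical(n_total)
  occ_counts <- stats::setNames(rep(0, k), names(config$states))

  for (i in seq_len(n_total)) {
    s0 <- sample.int(k, 1L, prob = pi0)
    path <- simulate_state_path(birth[i], t_end, s0,
                                config$switch_rates, config$desorb_rate)
    death[i] <- path$t_death
    desorbed[i] <- path$desorbed
    # frames at which the particle is on the membrane
    j0 <- ceiling(birth[i] / dt - 1e-12)
    j1 <- ceiling(path$t_death / dt - 1e-12) - 1L
    j1 <- min(j1, config$n_frames - 1L)
    if (j1 < j0) next
    frames <- j0:j1
    nf <- length(frames)
    st <- path$seg_s[findInterval(frames * dt + 1e-12, path$seg_t)]
    x <- numeric(nf)
    y <- numeric(nf)
    x[1] <- stats::runif(1L, 0, config$fov[1])
    y[1] <- stats::runif(1L, 0, config$fov[2])
    if (nf > 1L) {
      sd_step <- sqrt(2 * d_states[st[-nf]] * dt)
      x[-1] <- x[1] + cumsum(stats::rnorm(nf - 1L, 0, sd_step))
      y[-1] <- y[1] + cumsum(stats::rnorm(nf - 1L, 0, sd_step))
      x <- apply_boundary(x, config$fov[1], config$boundary)
      y <- apply_boundary(y, config$fov[2], config$boundary)
    }
    pts[[i]] <- data.frame(track_id = i, frame = frames, x_um = x, y_um = y,
                           state = names(config$states)[st])
    occ_tab <- table(factor(names(config$states)[st], levels = names(config$states)))
    occ_counts <- occ_counts + as.numeric(occ_tab)
  }

  dwell <- data.frame(track_id = seq_len(n_total), birth_s = birth,
                      death_s = death, dwell_s = death - birth,
                      censored = !desorbed)
  points <- do.call(rbind, pts[!vapply(pts, is.null, logical(1))])
  if (is.null(points)) {
    points <- data.frame(track_id = integer(0), frame = integer(0),
                         x_um = numeric(0), y_um = numeric(0),
                         state = character(0))
  }
  tracks <- trajectory_set(points, frame_interval = dt)
  occupancy <- if (sum(occ_counts) > 0) occ_counts / sum(occ_counts) else occ_counts
  list(tracks = tracks,
       truth = list(states = config$states, occupancy = occupancy,
                    dwell = dwell, config = config))
}

#' Render a detection table from trajectories
#'
#' Applies the camera model to ground-truth trajectories: isotropic Gaussian
#' localization noise and independent missed detections. The ground-truth
#' particle identity is retained in a `truth_id` column so that tracker output
#' can be scored against it.
#'
#' @param tracks a [trajectory_set()].
#' @param loc_noise_sigma localization noise s.d. in micrometres (>= 0).
#' @param p_missed_detection probability in [0, 1] of dropping a localization.
#' @param seed integer seed.
#' @return A `detection_table` data frame with columns
#'   `frame, x_um, y_um, intensity, truth_id`, sorted by frame.
#' @export
render_detections <- function(tracks, loc_noise_sigma = 0,
                              p_missed_detection = 0, seed = 1L) {
  if (loc_noise_sigma < 0) stop("loc_noise_sigma must be >= 0")
  if (p_missed_detection < 0 || p_missed_detection > 1) {
    stop("p_missed_detection must be in [0, 1]")
  }
  set.seed(seed)
  df <- as.data.frame(tracks)
  n <- nrow(df)
  keep <- if (p_missed_detection > 0) stats::runif(n) >= p_missed_detection else rep(TRUE, n)
  det <- data.frame(
    frame = df$frame,
    x_um = df$x_um + if (loc_noise_sigma > 0) stats::rnorm(n, 0, loc_noise_sigma) else 0,
    y_um = df$y_um + if (loc_noise_sigma > 0) stats::rnorm(n, 0, loc_noise_sigma) else 0,
    intensity = 100,
    truth_id = df$track_id
  )
  det <- det[keep, , drop = FALSE]
  det <- det[order(det$frame, det$truth_id), , drop = FALSE]
  rownames(det) <- NULL
  class(det) <- c("detection_table", "data.frame")
  det
}

#' Simulate a TIRF recruitment (adsorption) trace
#'
#' Intensity is flat at `baseline_level` before ligand addition, then rises to
#' `baseline_level + plateau_delta` with a single-exponential approach at
#' `rate_per_s`, plus Gaussian noise. Time is measured so that the first
#' post-addition frame lies one frame interval after addition, so in the
#' instantaneous-binding limit (`rate_per_s = Inf`) the trace is a step
#' function at `addition_frame`.
#'
#' @param baseline_level pre-addition intensity (arbitrary units).
#' @param plateau_delta intensity gain at the plateau (may be negative for a
#'   washout step-down).
#' @param rate_per_s exponential approach rate in 1/s (>= 0; `Inf` allowed).
#' @param addition_frame 1-based index of the first frame after addition;
#'   must be >= 5 so that a four-frame baseline exists.
#' @param frame_interval_s time between frames in seconds (default 15, the
#'   usual adsorption-series interval).
#' @param noise_sigma Gaussian noise s.d. (intensity units).
#' @param n_frames total number of frames.
#' @param seed integer seed.
#' @param condition,replicate labels stored on the trace.
#' @return An [adsorption_trace()].
#' @export
simulate_recruitment_trace <- function(baseline_level, plateau_delta, rate_per_s,
                                       addition_frame, frame_interval_s = 15,
                                       noise_sigma = 0, n_frames = 60, seed = 1L,
                                       condition = "sim", replicate = 1L) {
  if (addition_frame < 5) stop("addition_frame must be >= 5 so that 4 baseline frames exist")
  if (rate_per_s < 0) stop("rate_per_s must be >= 0")
  if (n_frames < addition_frame) stop("n_frames must cover the addition frame")
  set.seed(seed)
  idx <- seq_len(n_frames)
  time_s <- (idx - 1) * frame_interval_s
  t_since <- (idx - addition_frame + 1) * frame_interval_s
  rise <- ifelse(idx >= addition_frame,
                 plateau_delta * (1 - exp(-rate_per_s * t_since)), 0)
  rise[idx >= addition_frame & is.infinite(rate_per_s)] <- plateau_delta
  intensity <- baseline_level + rise +
    if (noise_sigma > 0) stats::rnorm(n_frames, 0, noise_sigma) else 0
  adsorption_trace(time_s, intensity, addition_index = addition_frame,
                   condition = condition, replicate = replicate)
}
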