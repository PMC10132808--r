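#' Simulation configuration
#'
#' Describes the generative model for synthetic membrane-bound particle
#' trajectories: a set of diffusive states (each a 2D Brownian diffusion
#' coefficient in um^2/s), continuous-time Markov switching between states,
#' exponential membrane desorption, optional new-particle adsorption, a finite
#' field of view, and a simple camera model (localization noise and missed
#' detections). Units are micrometres and seconds throughout.
#'
#' @param n_particles number of particles present at frame 0.
#' @param n_frames number of recorded frames (> 0).
#' @param states named numeric vector of diffusion coefficients in um^2/s,
#'   one per diffusive state, e.g. `c(fast = 2, slow = 0.5, immobile = 0.01)`.
#'   All values must be >= 0.
#' @param frame_interval frame interval in seconds (default 0.02, i.e. 20 ms
#'   exposure-limited acquisition).
#' @param fov field of view as `c(width, height)` in micrometres.
#' @param switch_rates square matrix of per-second transition rates between
#'   states (off-diagonals >= 0; the diagonal is ignored). `NULL` means no
#'   switching.
#' @param desorb_rate per-second rate(s) of leaving the membrane: a scalar or
#'   one value per state. 0 means particles never desorb.
#' @param adsorb_rate per-second appearance rate of new particles over the
#'   whole field of view (0, the default, disables adsorption).
#' @param loc_noise_sigma localization noise s.d. in micrometres (applied by
#'   [render_detections()]).
#' @param p_missed_detection probability in [0, 1] that a localization is
#'   missed (applied by [render_detections()]).
#' @param boundary `"periodic"` (default; keeps particle density constant) or
#'   `"reflecting"` behaviour at the field-of-view edge.
#' @param seed integer seed; identical configurations with identical seeds
#'   reproduce identical output.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_particles, n_frames, states,
                       frame_interval = 0.02, fov = c(25, 25),
                       switch_rates = NULL, desorb_rate = 0,
                       adsorb_rate = 0, loc_noise_sigma = 0,
                       p_missed_detection = 0,
                       boundary = c("periodic", "reflecting"),
                       seed) {
  boundary <- match.arg(boundary)
  if (missing(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("an integer 'seed' is required")
  }
  n_states <- length(states)
  if (n_states < 1L) stop("at least one diffusive state is required")
  if (is.null(names(states))) names(states) <- paste0("state", seq_len(n_states))
  if (any(states < 0) || any(!is.finite(states))) stop("all D must be finite and >= 0")
  if (n_particles < 0) stop("n_particles must be >= 0")
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (length(fov) != 2L || any(fov <= 0)) stop("fov must be c(width, height) in um, > 0")
  if (is.null(switch_rates)) {
    switch_rates <- matrix(0, n_states, n_states)
  }
  switch_rates <- as.matrix(switch_rates)
  if (nrow(switch_rates) != n_states || ncol(switch_rates) != n_states) {
    stop("switch_rates must be a square ", n_states, "x", n_states, " matrix")
  }
  off <- switch_rates[row(switch_rates) != col(switch_rates)]
  if (any(off < 0)) stop("switch_rates off-diagonals must be >= 0")
  diag(switch_rates) <- 0
  if (length(desorb_rate) == 1L) desorb_rate <- rep(desorb_rate, n_states)
  if (length(desorb_rate) != n_states) {
    stop("desorb_rate must be a scalar or one value per state")
  }
  if (any(desorb_rate < 0)) stop("desorb_rate must be >= 0")
  if (adsorb_rate < 0) stop("adsorb_rate must be >= 0")
  if (loc_noise_sigma < 0) stop("loc_noise_sigma must be >= 0")
  if (p_missed_detection < 0 || p_missed_detection > 1) {
    stop("p_missed_detection must be in [0, 1]")
  }
  structure(list(
    n_particles = as.integer(n_particles),
    n_frames = as.integer(n_frames),
    states = states,
    frame_interval = frame_interval,
    fov = as.numeric(fov),
    switch_rates = switch_rates,
    desorb_rate = desorb_rate,
    adsorb_rate = adsorb_rate,
    loc_noise_sigma = loc_noise_sigma,
    p_missed_detection = p_missed_detection,
    boundary = boundary,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d particles, %d frames @ %g s, FOV %g x %g um, seed %d\n",
              x$n_particles, x$n_frames, x$frame_interval,
              x$fov[1], x$fov[2], x$seed))
  cat("  states (D um^2/s):",
      paste(sprintf("%s=%g", names(x$states), x$states), collapse = ", "), "\n")
  if (any(x$switch_rates > 0)) cat("  with state switching\n")
  if (any(x$desorb_rate > 0))
    cat("  desorption rate(s):", paste(x$desorb_rate, collapse = ", "), "/s\n")
  invisible(x)
}

#' Read a simulation configuration from YAML
#'
#' Every field of [sim_config()] is addressable in the YAML file; `states` is
#' a mapping of state label to diffusion coefficient and `switch_rates` a list
#' of rows. A `seed` entry is required.
#'
#' @param file path to a YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(file) {
  y <- yaml::read_yaml(file)
  if (is.null(y$seed)) stop("config file must set 'seed'")
  states <- unlist(y$states)
  sw <- if (!is.null(y$switch_rates)) do.call(rbind, y$switch_rates) else NULL
  sim_config(
    n_particles = y$n_particles,
    n_frames = y$n_frames,
    states = states,
    frame_interval = if (!is.null(y$frame_interval)) y$frame_interval else 0.02,
    fov = if (!is.null(y$fov)) unlist(y$fov) else c(25, 25),
    switch_rates = sw,
    desorb_rate = if (!is.null(y$desorb_rate)) unlist(y$desorb_rate) else 0,
    adsorb_rate = if (!is.null(y$adsorb_rate)) y$adsorb_rate else 0,
    loc_noise_sigma = if (!is.null(y$loc_noise_sigma)) y$loc_noise_sigma else 0,
    p_missed_detection = if (!is.null(y$p_missed_detection)) y$p_missed_detection else 0,
    boundary = if (!is.null(y$boundary)) y$boundary else "periodic",
    seed = y$seed
  )
}
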