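test_that("zero-diffusion particles stay put and D controls the MSD", {
  cfg0 <- sim_config(n_particles = 10, n_frames = 20, states = c(pinned = 0),
                     desorb_rate = 0, seed = 3)
  sim0 <- simulate_trajectories(cfg0)
  spans <- tapply(seq_len(nrow(sim0$tracks)), sim0$tracks$track_id, function(i) {
    max(diff(range(sim0$tracks$x_um[i])), diff(range(sim0$tracks$y_um[i])))
  })
  expect_true(all(spans == 0))

  # 2D Brownian motion: mean squared single-frame displacement = 4*D*dt
  cfg <- sim_config(n_particles = 300, n_frames = 60, states = c(free = 1),
                    fov = c(1e6, 1e6), seed = 7)
  st <- compute_steps(simulate_trajectories(cfg)$tracks, 1,
                      non_overlapping = FALSE)
  expect_gt(nrow(st), 1e4)
  msd <- mean(st$r^2)
  se <- stats::sd(st$r^2) / sqrt(nrow(st))
  expect_lt(abs(msd - 4 * 1 * 0.02), 3 * se)
})

test_that("per-axis step variance scales linearly with the lag", {
  cfg <- sim_config(n_particles = 200, n_frames = 61, states = c(free = 0.8),
                    fov = c(1e6, 1e6), seed = 21)
  tracks <- simulate_trajectories(cfg)$tracks
  for (k in c(2L, 5L)) {
    st <- compute_steps(tracks, k, non_overlapping = FALSE)
    msd <- mean(st$r^2)   # = 2 axes * 2*D*k*dt
    se <- stats::sd(st$r^2) / sqrt(nrow(st))
    expect_lt(abs(msd - 4 * 0.8 * k * 0.02), 3 * se)
  }
})

test_that("state occupancy follows the CTMC stationary distribution", {
  q <- matrix(c(0, 3, 3, 0), 2, 2, byrow = TRUE)
  cfg <- sim_config(n_particles = 150, n_frames = 400,
                    states = c(a = 1, b = 0.1), switch_rates = q, seed = 5)
  sim <- simulate_trajectories(cfg)
  # symmetric rates: stationary occupancy 1/2 per state; frames are
  # correlated over ~1/(2k) s, so allow a generous sampling band
  expect_equal(unname(sim$truth$occupancy[["a"]]), 0.5, tolerance = 0.04)

  # asymmetric rates: pi solves pi Q = 0
  q2 <- matrix(c(0, 4, 1, 0), 2, 2, byrow = TRUE)
  cfg2 <- sim_config(n_particles = 150, n_frames = 400,
                     states = c(a = 1, b = 0.1), switch_rates = q2, seed = 6)
  sim2 <- simulate_trajectories(cfg2)
  expect_equal(unname(sim2$truth$occupancy[["a"]]), 0.2, tolerance = 0.04)
})

test_that("ground-truth dwell times average 1/lambda", {
  cfg <- sim_config(n_particles = 4000, n_frames = 400, states = c(free = 0.2),
                    desorb_rate = 2, seed = 31)
  dwell <- simulate_trajectories(cfg)$truth$dwell
  u <- dwell$dwell_s[!dwell$censored]
  se <- stats::sd(u) / sqrt(length(u))
  expect_lt(abs(mean(u) - 0.5), 3 * se)
})

test_that("identical configs and seeds reproduce byte-identical artifacts", {
  cfg <- sim_config(n_particles = 40, n_frames = 50,
                    states = c(fast = 1, slow = 0.05),
                    switch_rates = matrix(c(0, 1, 1, 0), 2), desorb_rate = 0.5,
                    seed = 12)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_tracks_csv(simulate_trajectories(cfg)$tracks, f1)
  write_tracks_csv(simulate_trajectories(cfg)$tracks, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("render_detections applies the camera model it claims", {
  sim <- sparse_sim(2)
  # identity case
  det <- render_detections(sim$tracks, 0, 0, seed = 1)
  expect_equal(nrow(det), nrow(sim$tracks))
  expect_setequal(det$x_um, sim$tracks$x_um)
  # p = 1 drops everything
  expect_equal(nrow(render_detections(sim$tracks, 0, 1, seed = 1)), 0L)
  # Gaussian noise: mean squared deviation from truth = 2*sigma^2 per point
  cfg <- sim_config(n_particles = 500, n_frames = 25, states = c(free = 0.5),
                    seed = 8)
  tracks <- simulate_trajectories(cfg)$tracks
  sigma <- 0.02
  detn <- render_detections(tracks, sigma, 0, seed = 9)
  detn <- detn[order(detn$truth_id, detn$frame), , drop = FALSE]  # align rows
  dev2 <- (detn$x_um - tracks$x_um)^2 + (detn$y_um - tracks$y_um)^2
  expect_gt(length(dev2), 1e4)
  se <- stats::sd(dev2) / sqrt(length(dev2))
  expect_lt(abs(mean(dev2) - 2 * sigma^2), 3 * se)
  # invalid probability
  expect_error(render_detections(tracks, 0, 1.2, seed = 1), "0, 1")
})

test_that("simulated recruitment traces follow the exponential-approach form", {
  # plateau_delta = 0: statistically flat
  tr0 <- simulate_recruitment_trace(100, 0, 0.05, 10, noise_sigma = 0,
                                    n_frames = 40, seed = 2)
  expect_true(all(tr0$intensity == 100))
  # instantaneous binding: step function at the addition frame
  trs <- simulate_recruitment_trace(100, 50, Inf, 10, noise_sigma = 0,
                                    n_frames = 40, seed = 2)
  expect_true(all(trs$intensity[1:9] == 100))
  expect_true(all(trs$intensity[10:40] == 150))
  # finite rate, no noise: closed form exactly
  tr <- simulate_recruitment_trace(100, 50, 0.01, 10, frame_interval_s = 15,
                                   noise_sigma = 0, n_frames = 40, seed = 2)
  i <- 25
  t_since <- (i - 10 + 1) * 15
  expect_equal(tr$intensity[i], 100 + 50 * (1 - exp(-0.01 * t_since)))
  expect_error(simulate_recruitment_trace(100, 50, 0.01, 3, n_frames = 40),
               "addition_frame")
})

test_that("configuration invariants are enforced and YAML round-trips", {
  expect_error(sim_config(10, 10, states = c(a = -1), seed = 1), ">= 0")
  expect_error(sim_config(10, 0, states = c(a = 1), seed = 1), "n_frames")
  expect_error(sim_config(10, 10, states = c(a = 1, b = 2),
                          switch_rates = matrix(0, 3, 3), seed = 1), "square")
  expect_error(sim_config(10, 10, states = c(a = 1),
                          p_missed_detection = 2, seed = 1), "0, 1")
  expect_error(sim_config(10, 10, states = c(a = 1, b = 1),
                          switch_rates = matrix(c(0, -1, 1, 0), 2), seed = 1),
               "off-diagonal")

  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "n_particles: 5", "n_frames: 10", "frame_interval: 0.02",
    "states:", "  fast: 2.0", "  slow: 0.1",
    "switch_rates:", "  - [0.0, 1.0]", "  - [2.0, 0.0]",
    "desorb_rate: 0.5", "seed: 99"), yml)
  cfg <- read_sim_config(yml)
  expect_s3_class(cfg, "sim_config")
  expect_equal(unname(cfg$states), c(2.0, 0.1))
  expect_equal(cfg$switch_rates[1, 2], 1.0)
  expect_equal(cfg$seed, 99L)
  # seed is mandatory
  writeLines(c("n_particles: 5", "n_frames: 10", "states:", "  a: 1"), yml)
  expect_error(read_sim_config(yml), "seed")
})
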