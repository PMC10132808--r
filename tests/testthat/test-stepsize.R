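test_that("step magnitudes and the skip rule are computed as stated", {
  # 3-4-5 triangle
  tr <- trajectory_set(data.frame(track_id = 1, frame = 0:1,
                                  x_um = c(0, 0.3), y_um = c(0, 0.4)), 0.02)
  st <- compute_steps(tr, 1)
  expect_equal(st$r, 0.5)
  expect_equal(st$tau, 0.02)

  # 5-point gap-free track at delay 2: 2 disjoint steps, 3 sliding ones
  tr5 <- trajectory_set(line_track(1, 5), 0.02)
  expect_equal(nrow(compute_steps(tr5, 2, non_overlapping = TRUE)), 2L)
  expect_equal(nrow(compute_steps(tr5, 2, non_overlapping = FALSE)), 3L)
  expect_error(compute_steps(tr5, 0), "delay_frames")

  # a gap yields no step across the missing interval unless the exact
  # spacing exists on both sides
  pts <- line_track(1, 10)
  pts <- pts[pts$frame != 3, ]
  trg <- trajectory_set(pts, 0.02)
  st1 <- compute_steps(trg, 1, non_overlapping = FALSE)
  expect_equal(nrow(st1), 7L)   # pairs (2,3) and (3,4) lost
})

test_that("non-overlapping step counts equal floor((L-1)/k) for all L and k", {
  # one trajectory_set holding gap-free tracks of every length 2..200
  pts <- do.call(rbind, lapply(2:200, function(len) {
    line_track(len, len, start_frame = 0L)
  }))
  tracks <- trajectory_set(pts, 0.02)
  for (k in 1:10) {
    st <- compute_steps(tracks, k)
    counts <- table(factor(st$track_id, levels = 2:200))
    expect_equal(unname(as.vector(counts)), floor((2:200 - 1) / k),
                 info = paste("delay", k))
  }
})

test_that("histograms bin, normalize and flag overflow correctly", {
  st <- steps_from_r(rep(0.25, 40), 1)
  h <- build_histogram(st, bin_width = 0.1, r_max = 1)
  expect_equal(sum(h$counts), 40)
  expect_equal(h$counts[3], 40)   # bin [0.2, 0.3)
  expect_equal(sum(h$density * diff(h$bin_edges)), 1)

  ho <- suppressMessages(build_histogram(steps_from_r(c(0.1, 0.2, 9), 1),
                                         bin_width = 0.05, r_max = 2.5))
  expect_equal(ho$n_overflow, 1L)
  expect_equal(ho$n_total, 2L)

  expect_error(build_histogram(steps_from_r(numeric(0), 1)), "empty")
  mixed <- rbind(steps_from_r(0.1, 1), steps_from_r(0.1, 2))
  class(mixed) <- c("step_sample", "data.frame")
  expect_error(build_histogram(mixed), "delay time")
})

test_that("sampled histograms match the closed-form density bin by bin", {
  set.seed(42)
  n <- 1e5
  r <- sample_steps(n, 0.02, D = 1)
  h <- build_histogram(steps_from_r(r, 1), bin_width = 0.05, r_max = 2.5)
  mids <- (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
  w <- diff(h$bin_edges)
  p <- model_density(mids, 0.02, 1) * w
  se <- sqrt(p * (1 - p) / n) / w
  dev <- abs(h$density - p / w)
  expect_true(all(dev <= 3 * se + 1e-12))
})

test_that("the mixture density is a proper density with the stated mode", {
  expect_equal(model_density(0, 0.02, c(2, 0.5), c(0.6, 0.4)), 0)
  expect_error(model_density(0.1, 0.02, c(1, 0)), "degenerate")
  expect_error(model_density(0.1, 0, 1), "tau")
  expect_error(model_density(0.1, 0.02, c(1, 2), c(0.7, 0.7)), "sum to 1")

  # single-component mode at sqrt(2*D*tau)
  opt <- stats::optimize(function(r) -model_density(r, 0.02, 1), c(0, 1))
  expect_equal(opt$minimum, sqrt(2 * 1 * 0.02), tolerance = 1e-4)

  # integrates to 1 for random valid parameter sets
  set.seed(11)
  for (i in 1:20) {
    k <- sample(1:3, 1)
    d <- stats::runif(k, 0.01, 5)
    a <- stats::runif(k); a <- a / sum(a)
    tau <- stats::runif(1, 0.01, 0.1)
    q <- stats::integrate(model_density, 0, Inf, tau = tau, D = d, alpha = a,
                          rel.tol = 1e-9)
    expect_lt(abs(q$value - 1), 1e-6)
  }
})

test_that("global_fit recovers exact single-component input to high precision", {
  for (d_true in c(0.3, 1.3, 4)) {
    h <- histogram_from_density(0.02, function(r) model_density(r, 0.02, d_true),
                                bin_width = 0.02, r_max = 2.5)
    fit <- global_fit(list(h), n_components = 1)
    expect_lt(abs(fit$components$D - d_true) / d_true, 1e-6)
    expect_equal(fit$components$alpha, 1)
  }
})

test_that("global_fit recovers a seeded three-component mixture", {
  set.seed(123)
  d_true <- c(2.0, 0.5, 0.02)
  a_true <- c(0.5, 0.3, 0.2)
  hists <- lapply(1:4, function(k) {
    r <- sample_steps(2e4, k * 0.02, d_true, a_true)
    build_histogram(steps_from_r(r, k), bin_width = 0.01, r_max = 2.5)
  })
  fit <- global_fit(hists, n_components = 3)
  expect_equal(fit$components$D, d_true, tolerance = 0.15)
  expect_lt(max(abs(fit$components$alpha - a_true)), 0.05)
  # fit invariants
  expect_equal(sum(fit$components$alpha), 1, tolerance = 1e-6)
  expect_true(all(diff(fit$components$D) <= 0))
  expect_true(all(fit$components$D_sd >= 0, na.rm = TRUE))
})

test_that("global_fit validates its inputs", {
  expect_error(global_fit(list(), 3), "non-empty")
  expect_error(global_fit(list(1), 3), "step_histogram")
  tiny <- build_histogram(steps_from_r(stats::runif(20, 0, 1), 1))
  expect_error(global_fit(list(tiny), 3), "too few steps")
})

test_that("the fitted D is invariant to which delay is analyzed", {
  # samples at delay k*dt are sqrt(k)-scaled copies of delay-dt samples,
  # so each delay alone must yield the same D
  set.seed(9)
  fits <- lapply(c(1L, 4L), function(k) {
    r <- sample_steps(4e4, k * 0.02, D = 1.5)
    global_fit(list(build_histogram(steps_from_r(r, k), bin_width = 0.02)),
               n_components = 1)
  })
  d_vals <- vapply(fits, function(f) f$components$D, numeric(1))
  expect_equal(d_vals[1], d_vals[2], tolerance = 0.05)
})

test_that("fastest_component selects the largest D and reports ties", {
  fit <- structure(list(components = data.frame(
    D = c(2, 0.5, 0.02), alpha = c(0.5, 0.3, 0.2),
    D_sd = c(0.1, 0.05, 0.01), alpha_sd = c(0.01, 0.01, 0.01)),
    tied_D = FALSE), class = "diffusion_fit")
  fc <- fastest_component(fit)
  expect_equal(fc$D, 2)
  expect_equal(fc$sd, 0.1)

  set.seed(10)
  r <- sample_steps(5e3, 0.02, D = 1)
  single <- global_fit(list(build_histogram(steps_from_r(r, 1))), 1)
  expect_equal(fastest_component(single)$D, single$components$D[1])

  # equal-D components keep the deterministic sort and are flagged
  h <- histogram_from_density(0.02, function(r) model_density(r, 0.02, 1),
                              bin_width = 0.05)
  fit2 <- global_fit(list(h), n_components = 1)
  fit2$components <- rbind(fit2$components, fit2$components)
  fit2$tied_D <- any(diff(fit2$components$D) == 0)
  expect_true(fit2$tied_D)
  expect_equal(fastest_component(fit2)$D, fit2$components$D[1])
})

test_that("identical simulated conditions give statistically equal fastest D", {
  make_cond <- function(seed) {
    cfg <- sim_config(n_particles = 250, n_frames = 120,
                      states = c(fast = 2, slow = 0.5, immobile = 0.01),
                      fov = c(300, 300), boundary = "reflecting", seed = seed)
    simulate_trajectories(cfg)$tracks
  }
  res <- concentration_series(list(a = make_cond(201), b = make_cond(202)),
                              bin_width = 0.02)
  expect_lt(abs(diff(res$D_fast)), 2 * sqrt(sum(res$D_sd^2)))
  expect_error(concentration_series(list(a = make_cond(201))), ">= 2")
})
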