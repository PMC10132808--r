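#' Compute step sizes at a fixed delay
#'
#' For every track, computes displacement magnitudes between localizations
#' separated by exactly `delay_frames` frames. With `non_overlapping = TRUE`
#' (the default) steps are drawn from disjoint frame pairs anchored at each
#' track's first frame (positions 0 -> k, k -> 2k, ...), so a gap-free track
#' of L points yields `floor((L - 1) / k)` steps and no displacement is
#' counted twice across delays drawn from skips of the same dataset. Frame
#' gaps introduced by gap closing yield no step across the missing interval
#' unless both endpoints exist at the exact spacing.
#'
#' @param tracks a [trajectory_set()].
#' @param delay_frames delay in frames (k >= 1).
#' @param non_overlapping if `TRUE`, use the disjoint-pair skip rule; if
#'   `FALSE`, use all (sliding-window) pairs at the given spacing.
#' @return A data frame of class `step_sample` with columns
#'   `track_id, r` (displacement in um), `delay_frames`, `tau` (delay in s).
#' @export
compute_steps <- function(tracks, delay_frames, non_overlapping = TRUE) {
  if (delay_frames < 1) stop("delay_frames must be >= 1")
  k <- as.integer(delay_frames)
  dt <- frame_interval(tracks)
  df <- as.data.frame(tracks)
  out <- lapply(split(df, df$track_id), function(tr) {
    fr <- tr$frame
    if (non_overlapping) {
      anchors <- seq(min(fr), max(fr), by = k)
      i0 <- match(anchors, fr)
      i1 <- match(anchors + k, fr)
      ok <- !is.na(i0) & !is.na(i1)
      # disjoint pairs: anchor grid fixed at the first frame, so pairs
      # (a, a+k) never share an endpoint
      i0 <- i0[ok]; i1 <- i1[ok]
    } else {
      i0 <- seq_along(fr)
      i1 <- match(fr + k, fr)
      ok <- !is.na(i1)
      i0 <- i0[ok]; i1 <- i1[ok]
    }
    if (length(i0) == 0L) return(NULL)
    data.frame(track_id = tr$track_id[1],
               r = sqrt((tr$x_um[i1] - tr$x_um[i0])^2 +
                        (tr$y_um[i1] - tr$y_um[i0])^2))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(track_id = integer(0), r = numeric(0))
  rownames(out) <- NULL
  out$delay_frames <- k
  out$tau <- k * dt
  class(out) <- c("step_sample", "data.frame")
  out
}

#' Bin step sizes into a step-size histogram
#'
#' @param steps a `step_sample` data frame from [compute_steps()]; all rows
#'   must share one delay time.
#' @param bin_width bin width in micrometres (default 0.05).
#' @param r_max upper edge of the binned range in micrometres (default 2.5,
#'   which covers >99.9% of the displacement mass for D <= 3 um^2/s and
#'   tau <= 0.1 s). Steps beyond `r_max` are counted as overflow and logged.
#' @return A `step_histogram`: list with `tau`, `bin_edges`, `counts`,
#'   `density` (normalized to unit area over the binned range), `n_total`
#'   (in-range steps) and `n_overflow`.
#' @export
build_histogram <- function(steps, bin_width = 0.05, r_max = 2.5) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (nrow(steps) == 0L) stop("empty step list")
  if (length(unique(steps$tau)) != 1L) {
    stop("all steps in one histogram must share one delay time; got taus: ",
         paste(sort(unique(steps$tau)), collapse = ", "))
  }
  edges <- seq(0, r_max, by = bin_width)
  if (abs(edges[length(edges)] - r_max) > 1e-12) edges <- c(edges, r_max)
  r <- steps$r
  n_overflow <- sum(r >= r_max)
  r_in <- r[r < r_max]
  counts <- tabulate(findInterval(r_in, edges), nbins = length(edges) - 1L)
  n_total <- sum(counts)
  widths <- diff(edges)
  density <- if (n_total > 0) counts / (n_total * widths) else counts * 0
  if (n_overflow > 0) {
    message(sprintf("build_histogram: %d of %d steps beyond r_max = %g um (overflow)",
                    n_overflow, length(r), r_max))
  }
  structure(list(tau = steps$tau[1], bin_edges = edges, counts = counts,
                 density = density, n_total = n_total, n_overflow = n_overflow),
            class = "step_histogram")
}

#' @export
print.step_histogram <- function(x, ...) {
  cat(sprintf("step_histogram: tau = %g s, %d bins of %g um, n = %d (+%d overflow)\n",
              x$tau, length(x$counts), diff(x$bin_edges)[1], x$n_total,
              x$n_overflow))
  invisible(x)
}

#' Idealized step-size histogram from a density function
#'
#' Builds a `step_histogram` whose density column is a supplied density
#' evaluated at bin midpoints (no sampling), with expected (real-valued)
#' pseudo-counts `n_effective * density * width`. Useful for self-consistency
#' checks of the fitting route on exact input.
#'
#' @param tau delay time in seconds.
#' @param density_fun function of r returning the step-size density.
#' @param bin_width,r_max binning as in [build_histogram()].
#' @param n_effective pseudo-count total used for the chi-square weights.
#' @return A `step_histogram`.
#' @export
histogram_from_density <- function(tau, density_fun, bin_width = 0.05,
                                   r_max = 2.5, n_effective = 1e5) {
  edges <- seq(0, r_max, by = bin_width)
  if (abs(edges[length(edges)] - r_max) > 1e-12) edges <- c(edges, r_max)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  dens <- density_fun(mids)
  counts <- n_effective * dens * diff(edges)
  structure(list(tau = tau, bin_edges = edges, counts = counts,
                 density = dens, n_total = sum(counts), n_overflow = 0L),
            class = "step_histogram")
}

#' Two-dimensional Brownian step-size mixture density
#'
#' The probability density of the displacement magnitude r after a delay tau
#' for a mixture of 2D Brownian diffusive components:
#' \deqn{\rho(r, \tau) = \sum_i \alpha_i \frac{r}{2 D_i \tau}
#'       \exp\!\left(-\frac{r^2}{4 D_i \tau}\right)}
#' Each component is a Rayleigh-form density (scale \eqn{\sqrt{2 D_i \tau}})
#' that integrates to 1; the mixture therefore does too. The density vanishes
#' at r = 0 and a single component peaks at \eqn{r = \sqrt{2 D \tau}}.
#'
#' @param r displacement magnitude(s) in micrometres (vectorized).
#' @param tau delay time in seconds (> 0).
#' @param D diffusion coefficients in um^2/s, all > 0 (a zero-D component
#'   makes the density degenerate and is rejected).
#' @param alpha component weights summing to 1 (default: single component).
#' @return Density value(s), per micrometre.
#' @export
model_density <- function(r, tau, D, alpha = rep(1 / length(D), length(D))) {
  if (tau <= 0) stop("tau must be > 0")
  if (any(D <= 0)) stop("all component D must be > 0 (zero-D is degenerate)")
  if (length(alpha) != length(D)) stop("alpha and D must have equal length")
  if (abs(sum(alpha) - 1) > 1e-6) stop("component weights must sum to 1")
  out <- numeric(length(r))
  for (i in seq_along(D)) {
    out <- out + alpha[i] * r / (2 * D[i] * tau) * exp(-r^2 / (4 * D[i] * tau))
  }
  out
}

#' Draw step sizes from the mixture by inverse-CDF sampling
#'
#' For component i, \eqn{r = \sqrt{-4 D_i \tau \log U}} with U uniform;
#' components are chosen with probabilities `alpha`. This sampler is the
#' independent route used to validate the fitting machinery.
#'
#' @param n number of draws.
#' @param tau delay time in seconds.
#' @param D,alpha mixture components as in [model_density()].
#' @return Numeric vector of n displacement magnitudes in micrometres.
#' @export
sample_steps <- function(n, tau, D, alpha = rep(1 / length(D), length(D))) {
  comp <- sample.int(length(D), n, replace = TRUE, prob = alpha)
  sqrt(-4 * D[comp] * tau * log(stats::runif(n)))
}

softmax <- function(eta) {
  z <- exp(c(eta, 0) - max(c(eta, 0)))
  z / sum(z)
}

# standardized chi-square residuals of one parameter vector against all
# histograms; theta = c(log D_1..K, eta_1..K-1)
fit_residuals <- function(theta, k, hists) {
  d <- exp(theta[seq_len(k)])
  alpha <- if (k > 1L) softmax(theta[k + seq_len(k - 1L)]) else 1
  unlist(lapply(hists, function(h) {
    mids <- (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
    w <- diff(h$bin_edges)
    model <- model_density(mids, h$tau, d, alpha)
    n <- max(h$n_total, 1)
    (h$density - model) * n * w / sqrt(pmax(h$counts, 1))
  }))
}

#' Global fit of step-size histograms to a diffusion mixture
#'
#' Fits a single set of component diffusion coefficients and weights to
#' step-size histograms at all delay times simultaneously (a global fit: the
#' same D_i and alpha_i describe every delay, as required for Brownian
#' mixtures). The objective is a chi-square over all bins of all histograms,
#' with per-bin weights 1 / max(count, 1) on the density residuals (scaled to
#' standardized Poisson residuals); the model density is evaluated at bin
#' midpoints. D is optimized on a log scale within [1e-4, 50] um^2/s and the
#' weights through a softmax parameterization enforcing sum(alpha) = 1, from
#' 10 deterministic multi-starts at log-spaced D values; the best chi-square
#' wins (ties by first start).
#'
#' Component uncertainties are the square roots of the diagonal of twice the
#' inverse curvature (Hessian) of the chi-square at the optimum — the
#' standard deviations determined from the fit — scaled by the reduced
#' chi-square when it exceeds 1 (delays are drawn from the same tracks, so
#' per-bin weights are relative rather than absolute). Localization noise is not part
#' of the model; with noise s.d. sigma the fitted D of a component inflates by
#' about sigma^2 / tau.
#'
#' @param histograms list of `step_histogram`s (one or more delay times).
#' @param n_components number of diffusive components (default 3; a fast, an
#'   intermediate and a quasi-immobile population are typical for
#'   membrane-bound kinases on supported bilayers).
#' @return A `diffusion_fit`: list with `components` (data frame with `D`,
#'   `alpha`, `D_sd`, `alpha_sd`, sorted by descending D), `chi_square`,
#'   `delays_used` (s), `n_steps_per_delay`, `n_starts_converged`, and
#'   `tied_D` (TRUE when two components have equal D after sorting).
#' @export
global_fit <- function(histograms, n_components = 3) {
  if (inherits(histograms, "step_histogram")) histograms <- list(histograms)
  if (!is.list(histograms) || length(histograms) == 0L ||
      !all(vapply(histograms, inherits, logical(1), "step_histogram"))) {
    stop("histograms must be a non-empty list of step_histogram objects")
  }
  k <- as.integer(n_components)
  if (k < 1L) stop("n_components must be >= 1")
  n_steps <- vapply(histograms, function(h) as.numeric(h$n_total), numeric(1))
  n_par <- 2L * k - 1L
  if (sum(n_steps) < 10 * n_par) {
    stop("too few steps (", sum(n_steps), ") for ", n_par, " free parameters")
  }

  obj <- function(theta) sum(fit_residuals(theta, k, histograms)^2)

  lo <- c(rep(log(1e-4), k), rep(-20, max(k - 1L, 0L)))
  hi <- c(rep(log(50), k), rep(20, max(k - 1L, 0L)))
  starts <- lapply(seq_len(10), function(s) {
    d0 <- 10^seq(-3 + 0.25 * (s - 1), 0.2 + 0.05 * (s - 1), length.out = k)
    c(log(rev(d0)), rep(0, max(k - 1L, 0L)))
  })

  best <- NULL
  n_conv <- 0L
  for (st in starts) {
    res <- tryCatch(
      stats::nlminb(st, obj, lower = lo, upper = hi,
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || res$objective < best$objective - 1e-12) best <- res
  }
  if (is.null(best)) stop("global_fit failed to converge from all starts")
  # high-precision polish of the winning start
  best <- stats::nlminb(best$par, obj, lower = lo, upper = hi,
                        control = list(iter.max = 1000, eval.max = 2000,
                                       rel.tol = 1e-15, x.tol = 1e-14))

  theta <- best$par
  d_hat <- exp(theta[seq_len(k)])
  a_hat <- if (k > 1L) softmax(theta[k + seq_len(k - 1L)]) else 1

  # covariance of theta ~ 2 * H^{-1} for a chi-square objective, scaled by
  # the reduced chi-square (the weights are relative: delays share tracks,
  # so residuals are overdispersed and the raw curvature understates error)
  n_bins <- sum(vapply(histograms, function(h) length(h$counts), numeric(1)))
  dof <- max(n_bins - n_par, 1)
  red_chi2 <- best$objective / dof
  d_sd <- rep(NA_real_, k)
  a_sd <- rep(NA_real_, k)
  hess <- tryCatch(pracma::hessian(obj, theta), error = function(e) NULL)
  if (!is.null(hess)) {
    cov_theta <- tryCatch(2 * max(red_chi2, 1) * solve(hess),
                          error = function(e) NULL)
    if (!is.null(cov_theta) && all(is.finite(diag(cov_theta)))) {
      v <- diag(cov_theta)
      v[v < 0] <- NA_real_
      d_sd <- d_hat * sqrt(v[seq_len(k)])       # delta method for D = exp(logD)
      if (k > 1L) {
        # delta method through the softmax Jacobian
        jac <- matrix(0, k, k - 1L)
        for (j in seq_len(k - 1L)) {
          jac[, j] <- a_hat * ((seq_len(k) == j) - a_hat[j])
        }
        cov_eta <- cov_theta[k + seq_len(k - 1L), k + seq_len(k - 1L), drop = FALSE]
        va <- diag(jac %*% cov_eta %*% t(jac))
        va[va < 0] <- NA_real_
        a_sd <- sqrt(va)
      } else {
        a_sd <- 0
      }
    }
  }

  ord <- order(-d_hat, seq_len(k))   # descending D, ties by original index
  comps <- data.frame(D = d_hat[ord], alpha = as.numeric(a_hat)[ord],
                      D_sd = d_sd[ord], alpha_sd = a_sd[ord])
  structure(list(
    components = comps,
    chi_square = best$objective,
    reduced_chi_square = red_chi2,
    delays_used = vapply(histograms, function(h) h$tau, numeric(1)),
    n_steps_per_delay = n_steps,
    n_starts_converged = n_conv,
    tied_D = any(diff(comps$D) == 0)
  ), class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("diffusion_fit: %d components, chi-square %.4g, delays {%s} s\n",
              nrow(x$components), x$chi_square,
              paste(signif(x$delays_used, 3), collapse = ", ")))
  comps <- x$components
  for (i in seq_len(nrow(comps))) {
    cat(sprintf("  D%d = %.4g +/- %.2g um^2/s  (alpha = %.3f +/- %.3f)\n",
                i, comps$D[i], comps$D_sd[i], comps$alpha[i], comps$alpha_sd[i]))
  }
  if (isTRUE(x$tied_D)) cat("  note: tied D values; order follows the deterministic sort\n")
  invisible(x)
}

#' Fastest diffusion component of a fit
#'
#' The fastest coefficient is the conventionally reported one: the slower
#' components (including the quasi-immobile fraction) typically stay constant
#' across conditions while the fast, freely-diffusing population responds to
#' e.g. dimerization. Ties in D are resolved by the fit's deterministic sort
#' and flagged on the fit object.
#'
#' @param fit a `diffusion_fit`.
#' @return A list with `D`, `sd` and `alpha` of the largest-D component.
#' @export
fastest_component <- function(fit) {
  if (!inherits(fit, "diffusion_fit") || nrow(fit$components) < 1L) {
    stop("fit must be a diffusion_fit with at least one component")
  }
  list(D = fit$components$D[1], sd = fit$components$D_sd[1],
       alpha = fit$components$alpha[1])
}

#' Full step-size analysis of one track set
#'
#' Convenience chain: non-overlapping steps at each requested delay, one
#' histogram per delay, then a [global_fit()].
#'
#' @param tracks a [trajectory_set()].
#' @param delays integer vector of delays in frames (default 1:4, i.e.
#'   20-80 ms at a 20 ms frame interval; use 2:5 for the every-2nd-to-5th
#'   frame variant).
#' @param n_components number of mixture components.
#' @param bin_width,r_max histogram binning (see [build_histogram()]).
#' @param non_overlapping apply the anti-overcounting skip rule (default).
#' @return A `diffusion_fit`.
#' @export
fit_stepsize_distribution <- function(tracks, delays = 1:4, n_components = 3,
                                      bin_width = 0.05, r_max = 2.5,
                                      non_overlapping = TRUE) {
  hists <- lapply(delays, function(k) {
    build_histogram(compute_steps(tracks, k, non_overlapping = non_overlapping),
                    bin_width = bin_width, r_max = r_max)
  })
  global_fit(hists, n_components = n_components)
}

#' Fastest diffusion coefficient across experimental conditions
#'
#' Runs the full step -> histogram -> global fit chain independently for each
#' condition (e.g. each bulk concentration of unlabeled protein, with or
#' without an adaptor) and tabulates the fastest fitted component per
#' condition.
#'
#' @param track_sets named list of [trajectory_set()]s (names are condition
#'   labels), or a list of `list(label =, tracks =)` pairs.
#' @param delays,n_components,bin_width,r_max passed to
#'   [fit_stepsize_distribution()].
#' @return Data frame with one row per condition: `label`, `D_fast`, `D_sd`,
#'   `alpha_fast`, `chi_square`, `n_steps`.
#' @export
concentration_series <- function(track_sets, delays = 1:4, n_components = 3,
                                 bin_width = 0.05, r_max = 2.5) {
  if (length(track_sets) < 2L) stop("a series needs >= 2 conditions")
  labels <- names(track_sets)
  if (is.null(labels)) labels <- paste0("condition", seq_along(track_sets))
  rows <- lapply(seq_along(track_sets), function(i) {
    fit <- fit_stepsize_distribution(track_sets[[i]], delays = delays,
                                     n_components = n_components,
                                     bin_width = bin_width, r_max = r_max)
    fc <- fastest_component(fit)
    data.frame(label = labels[i], D_fast = fc$D, D_sd = fc$sd,
               alpha_fast = fc$alpha, chi_square = fit$chi_square,
               n_steps = sum(fit$n_steps_per_delay))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overlay a step-size histogram and a fitted mixture
#'
#' @param x a `step_histogram`.
#' @param fit optional `diffusion_fit` whose density is overlaid.
#' @param ... passed to [graphics::plot()].
#' @export
plot.step_histogram <- function(x, fit = NULL, ...) {
  mids <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  graphics::plot(mids, x$density, type = "h", lwd = 3, col = "grey60",
                 xlab = "step size r (um)", ylab = "density (1/um)",
                 main = sprintf("tau = %g s", x$tau), ...)
  if (!is.null(fit)) {
    rr <- seq(0, max(x$bin_edges), length.out = 400)
    graphics::lines(rr, model_density(rr, x$tau, fit$components$D,
                                      fit$components$alpha),
                    col = "firebrick", lwd = 2)
  }
  invisible(x)
}
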