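#' TIRF adsorption/recruitment trace
#'
#' A scalar intensity time series from a TIRF recruitment experiment, with
#' the index of the first frame after ligand addition. The four frames
#' immediately preceding addition define the baseline, so `addition_index`
#' must be at least 5 (1-based).
#'
#' @param time_s frame times in seconds, strictly increasing (adsorption
#'   series are typically acquired at 15 s intervals).
#' @param intensity intensities in arbitrary units.
#' @param addition_index 1-based index of the first post-addition frame.
#' @param condition,replicate labels.
#' @return An object of class `adsorption_trace` (a data frame with columns
#'   `time_s`, `intensity` and attributes `addition_index`, `condition`,
#'   `replicate`, `baseline_subtracted`).
#' @export
adsorption_trace <- function(time_s, intensity, addition_index,
                             condition = "unknown", replicate = 1L) {
  if (length(time_s) != length(intensity)) {
    stop("time_s and intensity must have equal length")
  }
  if (any(diff(time_s) <= 0)) stop("times must be strictly increasing")
  if (addition_index < 5) {
    stop("addition_index must be >= 5: the baseline is the average of the ",
         "four frames preceding addition")
  }
  if (addition_index > length(time_s)) stop("addition_index beyond trace end")
  structure(data.frame(time_s = time_s, intensity = intensity),
            addition_index = as.integer(addition_index),
            condition = condition, replicate = replicate,
            baseline_subtracted = FALSE,
            class = c("adsorption_trace", "data.frame"))
}

#' @export
print.adsorption_trace <- function(x, ...) {
  cat(sprintf("adsorption_trace '%s' (rep %s): %d frames, addition at frame %d%s\n",
              attr(x, "condition"), attr(x, "replicate"), nrow(x),
              attr(x, "addition_index"),
              if (attr(x, "baseline_subtracted")) ", baseline-subtracted" else ""))
  invisible(x)
}

#' Difference intensity (baseline subtraction)
#'
#' Subtracts the baseline — the average of the four frames immediately
#' preceding ligand addition — from every point of the trace. By construction
#' the mean of those four baseline frames is exactly 0 afterwards, and the
#' operation is idempotent because the baseline window is fixed to the
#' pre-addition frames.
#'
#' @param trace an [adsorption_trace()].
#' @return The trace with baseline subtracted (`baseline_subtracted`
#'   attribute set and `baseline` attribute recording the subtracted value).
#' @export
difference_intensity <- function(trace) {
  ai <- attr(trace, "addition_index")
  if (is.null(ai)) stop("not an adsorption_trace")
  if (ai < 5) {
    stop("need at least 4 frames before addition: the baseline is the ",
         "average of the four frames preceding addition")
  }
  baseline <- mean(trace$intensity[(ai - 4L):(ai - 1L)])
  out <- trace
  out$intensity <- trace$intensity - baseline
  attr(out, "baseline_subtracted") <- TRUE
  attr(out, "baseline") <- baseline
  out
}

#' Aggregate replicate recruitment traces
#'
#' Pointwise mean and standard deviation across replicates, aligned on time
#' since addition. Replicates must share the same time-since-addition grid;
#' mismatched grids are refused (no silent resampling).
#'
#' @param traces list of [adsorption_trace()]s (typically
#'   baseline-subtracted).
#' @return Data frame with columns `t_since_addition_s`, `mean_intensity`,
#'   `sd_intensity` (NA when only one replicate), `n`.
#' @export
aggregate_replicates <- function(traces) {
  if (length(traces) < 1L) stop("need >= 1 trace")
  grids <- lapply(traces, function(tr) {
    ai <- attr(tr, "addition_index")
    tr$time_s - tr$time_s[ai]
  })
  g0 <- grids[[1]]
  for (i in seq_along(grids)[-1]) {
    if (length(grids[[i]]) != length(g0) || any(abs(grids[[i]] - g0) > 1e-9)) {
      stop("replicate ", i, " has a mismatched time grid; resampling is not ",
           "performed — align acquisitions on the addition frame")
    }
  }
  mat <- vapply(traces, function(tr) tr$intensity, numeric(length(g0)))
  mat <- matrix(mat, nrow = length(g0))
  data.frame(
    t_since_addition_s = g0,
    mean_intensity = rowMeans(mat),
    sd_intensity = if (ncol(mat) > 1L) apply(mat, 1, stats::sd) else NA_real_,
    n = ncol(mat)
  )
}

#' Washout (reversibility) comparison
#'
#' Compares a baseline-subtracted recruitment trace before a wash with the
#' trace after it: reports the fraction of the pre-wash plateau intensity
#' retained at the end of the post-wash segment, and whether the post-wash
#' intensity decays monotonically (one-sided Spearman rank correlation of
#' intensity against time on the post-wash segment).
#'
#' @param pre baseline-subtracted [adsorption_trace()] before the wash.
#' @param post_wash baseline-subtracted trace after the wash; its
#'   `addition_index` marks the wash. Must have >= 5 post-wash points.
#' @param level significance level for the decay test (default 0.05).
#' @return List with `retained_fraction` (final post-wash plateau / pre-wash
#'   plateau, both as means of the last four frames), `decay_seen` (logical),
#'   `p_value` of the rank test, and the two plateau values.
#' @export
washout_comparison <- function(pre, post_wash, level = 0.05) {
  for (tr in list(pre, post_wash)) {
    if (!isTRUE(attr(tr, "baseline_subtracted"))) {
      stop("both traces must be baseline-subtracted (difference_intensity)")
    }
  }
  ai <- attr(post_wash, "addition_index")
  post_seg <- post_wash[seq(ai, nrow(post_wash)), , drop = FALSE]
  if (nrow(post_seg) < 5L) stop("post-wash segment shorter than 5 points")
  plateau_pre <- mean(utils::tail(pre$intensity, 4L))
  plateau_post <- mean(utils::tail(post_seg$intensity, 4L))
  retained <- plateau_post / plateau_pre
  ct <- suppressWarnings(
    stats::cor.test(post_seg$time_s, post_seg$intensity,
                    method = "spearman", alternative = "less"))
  list(retained_fraction = retained,
       decay_seen = is.finite(ct$p.value) && ct$p.value < level,
       p_value = ct$p.value,
       plateau_pre = plateau_pre, plateau_post = plateau_post)
}

#' Plot aggregated recruitment traces
#'
#' @param agg output of [aggregate_replicates()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_recruitment <- function(agg, ...) {
  graphics::plot(agg$t_since_addition_s, agg$mean_intensity, type = "l",
                 lwd = 2, xlab = "time since addition (s)",
                 ylab = "difference intensity (a.u.)", ...)
  if (any(is.finite(agg$sd_intensity))) {
    graphics::arrows(agg$t_since_addition_s,
                     agg$mean_intensity - agg$sd_intensity,
                     agg$t_since_addition_s,
                     agg$mean_intensity + agg$sd_intensity,
                     angle = 90, code = 3, length = 0.02, col = "grey50")
  }
  invisible(agg)
}
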