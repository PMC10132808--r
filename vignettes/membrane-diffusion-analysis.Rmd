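---
title: "Methods: single-molecule membrane diffusion and dwell-time analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-molecule membrane diffusion and dwell-time analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memtrack)
```

## The measurement and its model

A molecule bound to a supported lipid bilayer and imaged by TIRF performs,
to good approximation, two-dimensional Brownian motion. For a single
diffusive state with coefficient $D$, the magnitude $r$ of the displacement
over a delay $\tau$ follows the Rayleigh-form jump-distance density

$$\rho(r,\tau) = \frac{r}{2 D \tau}\, e^{-r^2/4D\tau},$$

which integrates to 1, vanishes at $r=0$, and peaks at $r^\ast=\sqrt{2D\tau}$.
Real samples are heterogeneous: monomers and dimers diffuse at different
speeds, and a surface-pinned (quasi-immobile) fraction is essentially always
present on supported bilayers. The package therefore fits a finite mixture

$$\rho(r,\tau) = \sum_{i} \alpha_i\, \frac{r}{2 D_i \tau}\,
  e^{-r^2/4D_i\tau}, \qquad \sum_i \alpha_i = 1,$$

with three components by default. Crucially the fit is *global over delay
times*: histograms at $\tau = k\,\Delta t$ for several integer delays $k$
are fit with a single shared set of $(D_i, \alpha_i)$. For genuine Brownian
mixtures the same parameters must describe every delay; comparing delays is
also the standard control that camera pixelation and frame-rate artifacts
are not shaping the distribution. Per-delay weights are deliberately not
allowed.

Two-dimensional diffusion has no simple Stokes–Einstein relation to complex
size, but membrane diffusion slows measurably upon dimerization, so the
*fastest* fitted coefficient is the reported readout (`fastest_component()`);
the intermediate and immobile components typically stay constant across
conditions. The dwell-time side is modeled as a mixture of exponentials
(two components by default), and recruitment kinetics are reported as
baseline-subtracted "difference intensity" curves rather than fitted rate
constants.

## The synthetic-data generator

`sim_config()` / `simulate_trajectories()` generate the data this analysis
assumes, with known ground truth:

- **Diffusive states.** A named vector of $D$ values in µm²/s. The default
  study conditions used throughout the tests are a fast state near
  2 µm²/s (free lipid-anchored protein), an intermediate state near
  0.5 µm²/s, and a quasi-immobile state. The immobile state is given a small
  *positive* $D$ (0.01 µm²/s) rather than zero: a zero-$D$ component has a
  degenerate (delta-function) jump density and cannot be part of a fittable
  mixture, and `model_density()` rejects $D=0$ for the same reason.
- **State switching.** The hidden state evolves as a continuous-time Markov
  chain simulated with exact exponential waiting times, not a per-frame
  Bernoulli approximation, so the path law is exact at any frame interval.
  Each frame's displacement uses the state at the start of the frame with
  per-axis variance $2D\Delta t$. The initial state is drawn from the
  switching chain's stationary distribution (with no switching, uniform).
- **Membrane exchange.** Desorption is exponential with a per-state rate;
  adsorption of new particles (a constant appearance rate over the field of
  view) is available but off by default — parameter-recovery tests use
  closed populations, while dwell-time tests enable adsorption so that
  tracks begin away from frame 0 and uncensored residence times exist.
- **Field of view.** 25 × 25 µm by default, with periodic wrapping (keeps
  density constant, as on an effectively unbounded bilayer) or reflecting
  boundaries. Tests that score tracker identity use reflecting boundaries,
  because a periodic wrap looks like a teleporting particle to any tracker.
- **Camera model.** 20 ms frame interval by default; `render_detections()`
  adds isotropic Gaussian localization noise and drops localizations with a
  fixed missed-detection probability. No blinking kinetics, bleaching
  lifetimes, or image rendering are modeled: the simulation stops at
  detection tables, which is where the analysis starts.

What passing tests show, and what they do not: parameter recovery on these
simulations demonstrates that the estimator chain is correct *under the
model's assumptions* (Brownian states, exponential dwells, isotropic noise).
Real data add photophysics, drift, anomalous subdiffusion inside condensed
phases, and localization error — none of which the fit model includes, so
agreement on synthetic data bounds implementation error, not model error.

## Tracking

`link_detections()` is a two-pass linear-assignment tracker. Frame-to-frame
links minimize total squared displacement among pairs within the 1.5 µm
gate, solved exactly as a Hungarian assignment on a cost matrix augmented
with per-point birth/death alternatives (priced just above the gate, so an
over-gate link is never forced). A second pass closes gaps: terminated track
ends are matched to later track starts across up to 2 skipped frames within
1.5 µm, shortest gaps first, merging segments through a union–find. Ties are
broken by row order and final track ids are renumbered by first appearance,
making the output deterministic; for generic (noiseless, distinct) positions
the optimum is unique, so the partition is invariant to detection row order.

Identity recovery is only well-posed when trajectories never approach within
the assignment-ambiguity scale (roughly the step size): two molecules
passing within tens of nanometres are interchangeable to any tracker. The
oracle tests therefore verify, before asserting exact recovery, that the
simulated movie keeps co-present particles separated by more than 1 µm.

## Numerical choices in the diffusion fit

- **Steps.** The non-overlapping skip rule anchors disjoint frame pairs at
  each track's first frame: a gap-free track of $L$ points at delay $k$
  yields exactly $\lfloor (L-1)/k \rfloor$ steps, and no displacement is
  counted twice. Gap-closed intervals contribute no step unless both
  endpoints exist at the exact spacing.
- **Delays.** Default $k \in \{1,2,3,4\}$ (20–80 ms at 20 ms frames); the
  $\{2,3,4,5\}$ variant is equally supported via the `delays` argument.
  Neither is privileged; the scaling-law test verifies the fitted $D$ is
  invariant to the choice.
- **Binning.** Default bin width 0.05 µm up to $r_{\max} = 2.5$ µm, which
  covers >99.9% of the mass for $D \le 3$ µm²/s and $\tau \le 0.1$ s;
  overflow steps are counted and logged, never silently dropped. When a
  quasi-immobile component must be resolved, finer bins are appropriate:
  its density peaks at $\sqrt{2 \cdot 0.02 \cdot 0.01} \approx 0.03$ µm,
  so the recovery tests use 0.01–0.02 µm bins (bins must be finer than the
  narrowest component's peak).
- **Objective.** A chi-square over all bins of all delay histograms:
  residuals are (observed − model) density at bin midpoints, weighted by
  $1/\max(\text{count}, 1)$ and scaled by the constant $(N w)^2$ so they are
  standardized Poisson residuals. The midpoint rule is adequate at these bin
  widths; the exact weighting of the original implementations of this kind
  of fit is generally unpublished, so this choice is documented rather than
  reconstructed.
- **Optimization.** $D_i$ on a log scale bounded to $[10^{-4}, 50]$ µm²/s,
  weights through a softmax parameterization that enforces the simplex
  constraint exactly. Ten deterministic multi-starts from log-spaced $D$
  ladders; best chi-square wins, ties to the first start; the winner is
  polished at `rel.tol = 1e-15`, which is what lets exact (closed-form)
  single-component input come back with relative error below $10^{-6}$.
- **Uncertainties.** Twice the inverse Hessian of the chi-square at the
  optimum, scaled by the reduced chi-square when it exceeds 1 (delays are
  computed from the same tracks, so the per-bin weights are relative, and
  unscaled curvature understates the error — the same convention as
  MINPACK-style least-squares tools). $D$ errors are mapped from the log
  scale and $\alpha$ errors through the softmax Jacobian by the delta
  method. Components are returned sorted by descending $D$; exact ties keep
  the pre-sort order and set a `tied_D` flag.
- **Consistency of two estimates.** Two conditions are judged statistically
  indistinguishable when their fastest-$D$ difference is within twice the
  combined fitted standard deviation (a ~95% band; a one-sigma band on a
  *difference* would reject a third of genuinely identical pairs).
- **Localization noise** is not part of the density (the fit model has no
  noise term). With noise s.d. $\sigma$ the fitted $D$ of a component is
  inflated by approximately $\sigma^2/\tau$; at $\sigma = 20$ nm and
  $\tau = 20$ ms that is 0.02 µm²/s — negligible for the fast component,
  comparable to the immobile one. The simulator exposes noise precisely so
  this bias can be measured.

## Dwell times

Track duration is $(\text{last} - \text{first} + 1)\,\Delta t$, with
gap-closed frames counting as present. Tracks touching frame 0 or the final
frame are censored — their residence extends beyond the window — and are
excluded from fitting, with the excluded count reported. Because sub-frame
visits are unobservable, the likelihood is left-truncated at one frame
interval; by memorylessness the truncated exponential M-step simply
subtracts the truncation point, so EM stays closed-form. Five deterministic
initializations from scaled quantile splits guard against local optima, and
the EM's monotone-likelihood property is asserted in the tests. If all
durations are equal the fit degenerates; this is flagged and a single
effective component returned rather than an error. A least-squares fit to
the empirical survival curve is provided as an alternative mode
(`method = "survival_ls"`), since histogram-, survival- and
likelihood-based exponential fitting all circulate in this field; the two
modes agree on well-sampled mixtures.

The discretized duration convention biases a single-exponential mean upward
by roughly half a frame; at a 2 s⁻¹ off-rate and 20 ms frames the bias is
about +0.01 s, within the Monte-Carlo band the oracle tests use. Fitted
rates are *apparent* off-rates: photobleaching is not corrected, so mean
dwells are lower bounds on true residence.

## Recruitment traces

"Difference intensity" is additive baseline subtraction — the baseline being
the mean of the four frames immediately preceding addition — not ratio
normalization. The four baseline frames of a difference trace average to
exactly zero (to machine precision), and the operation is idempotent because
the window is fixed to pre-addition frames. Replicates are aggregated
pointwise on the time-since-addition grid; mismatched grids are refused
rather than resampled. Washout reversibility is operationalized as (i) the
retained fraction — final post-wash plateau over pre-wash plateau, each a
mean of the last four frames — and (ii) a one-sided Spearman rank
correlation of intensity against time on the post-wash segment at level
0.05 for monotone decay. The underlying experimental claim is qualitative,
so the test level is a documented choice, not a reconstruction.

## Problem sizes

The test suite and acceptance script run at deliberately desk-scale sizes,
chosen so each statistical check is comfortably powered: $2\times 10^5$
inverse-CDF samples for three-component recovery (each $D$ within 15%, each
$\alpha$ within 0.05), 350 particles × 140 frames per condition for the
concentration-series trend, $2\times 10^4$ draws for the dwell mixture
(means within 10%, fractions within 0.05), and ~10⁴ adsorbing tracks for the
single-rate dwell oracle. Larger runs sharpen the same estimates but do not
change any conclusion the tests draw.

## Known limitations

- No photophysics: blinking and bleaching are neither simulated (beyond
  missed detections) nor corrected for; dwell times are apparent.
- No anomalous-diffusion exponents, and no per-trajectory hidden-state
  segmentation: heterogeneity is modeled at the population level only.
- The tracker does not split or merge tracks and applies no drift
  correction.
- Spot detection from raw images is out of scope; the pipeline starts at
  detection tables (e.g. TrackMate exports, via `read_trackmate_csv()`).
- Mixture identifiability degrades when component $D$s approach within a
  factor of ~2 at the available sample sizes; the multi-start fit then
  merges components, which is visible as a large reduced chi-square or a
  weight near zero.
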