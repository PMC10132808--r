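# memtrack

Single-molecule membrane diffusion and dwell-time analysis for supported
lipid bilayer TIRF experiments.

When a fluorescently labeled protein (a kinase recruited by a signaling
lipid, say) is tracked one molecule at a time on a supported bilayer, the
biology is read out of three quantities: how fast the molecules diffuse
(dimerization and condensate capture slow them down), how long they stay on
the membrane (the off-rate), and how much bulk material the membrane recruits
after a binding partner is added. `memtrack` implements that analysis chain
as a tested R package:

- a **synthetic-data generator** for membrane-bound trajectories — 2D
  Brownian motion with hidden-state (CTMC) switching between diffusive
  states, exponential desorption, optional adsorption, localization noise and
  missed detections — so every downstream stage can be validated against a
  known ground truth;
- a **linear assignment problem (LAP) tracker** that links per-frame
  detections into trajectories (1.5 µm link gate, 2-frame gap closing at
  1.5 µm, the common single-molecule TrackMate settings) and imports
  TrackMate spot exports;
- **step-size (jump-distance) distribution analysis**: displacement
  histograms at multiple delay times τ, computed with a non-overlapping skip
  rule to prevent over-counting, fit *globally* (one parameter set for all
  delays) to a mixture of 2D Brownian components

  $$\rho(r,\tau) = \sum_i \alpha_i \,\frac{r}{2 D_i \tau}\, e^{-r^2 / 4 D_i \tau},$$

  with three components by default (fast, intermediate, quasi-immobile) and
  curvature-based standard deviations on each $D_i$;
- **dwell-time analysis**: membrane residence times from track spans, with
  boundary-censoring flags, fit by EM to a two-component exponential mixture
  (left-truncated at one frame interval);
- **TIRF recruitment processing**: difference intensity (baseline = mean of
  the four frames preceding addition), replicate aggregation (mean ± sd), and
  washout/reversibility comparison.

All lengths are micrometres, times seconds, diffusion coefficients µm²/s.

## Worked example

Simulate 350 molecules in three diffusive states (2.0, 0.5 and 0.01 µm²/s —
a fast monomer-like population, an intermediate one, and a quasi-immobile
pinned fraction) at 20 ms frames, re-detect and re-link them, and fit the
step-size distributions at delays of 1–4 frames:

```r
library(memtrack)

cfg <- sim_config(n_particles = 350, n_frames = 140,
                  states = c(fast = 2.0, slow = 0.5, immobile = 0.01),
                  fov = c(300, 300), boundary = "reflecting", seed = 1)
sim    <- simulate_trajectories(cfg)
det    <- render_detections(sim$tracks, seed = 2)
tracks <- link_detections(det, frame_interval = 0.02)
fit    <- fit_stepsize_distribution(tracks, delays = 1:4,
                                    n_components = 3, bin_width = 0.02)
print(fit)
#> diffusion_fit: 3 components, chi-square 333.4, delays {0.02, 0.04, 0.06, 0.08} s
#>   D1 = 1.973 +/- 0.023 um^2/s  (alpha = 0.297 +/- 0.006)
#>   D2 = 0.5089 +/- 0.0084 um^2/s  (alpha = 0.343 +/- 0.006)
#>   D3 = 0.01043 +/- 7.1e-05 um^2/s  (alpha = 0.360 +/- 0.002)

fastest_component(fit)$D
#> [1] 1.972596
```

The three fitted coefficients recover the simulated truth; the *fastest*
component is the conventionally reported number (the slower two typically
stay constant across experimental conditions, while the fast population
slows when molecules dimerize or get trapped). `concentration_series()`
repeats the chain across conditions and tabulates the fastest D with its
fitted standard deviation; `compute_dwell_times()` + `fit_dwell()` do the
residence-time side; `difference_intensity()`, `aggregate_replicates()` and
`washout_comparison()` handle recruitment traces.

An end-to-end run from a single YAML file (simulation → detections →
tracking → diffusion fit → dwell fit → recruitment, with a provenance
record beside every artifact):

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "memtrack"))
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/memtrack.R` (subcommands `pipeline`, `stepsize`, `dwell`,
`validate`).

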