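# End-to-end demo: simulate, detect, track, fit diffusion mixture and dwell
# times, and process a recruitment series, all from the seed below.
seed: 42
out_dir: memtrack_demo
frame_interval: 0.02
simulate:
  n_particles: 300
  n_frames: 300
  fov: [25, 25]
  states:
    fast: 2.0
    slow: 0.5
    immobile: 0.01
  switch_rates:
    - [0.0, 0.5, 0.1]
    - [0.5, 0.0, 0.1]
    - [0.2, 0.2, 0.0]
  desorb_rate: 0.5
  adsorb_rate: 40
track:
  max_link_dist: 1.5
  max_gap: 2
  max_gap_dist: 1.5
stepsize:
  delays: [1, 2, 3, 4]
  n_components: 3
  bin_width: 0.05
  r_max: 2.5
dwell:
  n_components: 2
recruit:
  n_replicates: 3
  baseline_level: 100
  plateau_delta: 50
  rate_per_s: 0.01
  addition_frame: 10
  noise_sigma: 2
  n_frames: 60
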