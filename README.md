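# hydropore

Trajectory analysis of **hydrophobic gating** in ion channel pores: water
occupancy and lipid-tail penetration statistics for molecular dynamics
simulations of membrane channels, built around the K2P channel TWIK-1 use
case in which a leucine "hydrophobic cuff" below the selectivity filter
dewets stochastically while lipid acyl chains reach through lateral
fenestrations into the pore lining.

It is written for simulators who have a structure (PDB/GRO) and a
trajectory (multi-model PDB or DCD) of a channel in a bilayer with
explicit water and want reproducible, scriptable numbers rather than
viewer screenshots.

## What it computes

All counting happens in a pore-centered coordinate system with z = 0 at
the centroid of an anchor selection — the threonines of the filter's
innermost K⁺ site (S4) — and negative z pointing intracellularly:

* **Occupancy time series** — per-frame counts of water oxygens in a
  20 × 20 × 5 Å box across the hydrophobic constriction
  (−10 Å < z ≤ −5 Å) and of lipid carbons in a 20 × 20 × 20 Å box below
  the S4 site (−20 Å < z ≤ 0 Å); both boxes configurable.
* **Percent occupancy** — fraction of frames with at least one (or
  `min_count`) atoms in a box: `100 · #{frames: n ≥ min_count} / #frames`,
  pooled over replicates.
* **Wet/dry segmentation and rates** — two-threshold hysteresis on the
  water count, then maximum-likelihood telegraph-process rates
  `k = transitions / exposure time` with `SE = k/√n`.
* **Joint occupancy heat maps** (percent of time per
  (n_water, n_carbon) cell), **Spearman rank correlation** with a
  permutation p-value, and **condition comparisons** (e.g. WT vs L146N)
  with bootstrap intervals.
* **Water density grids** — 0.5 Å voxels, normalized to bulk water
  density, thresholded at an isovalue of 0.5; OpenDX output.
* **Pore radius profiles** — HOLE-style radius-versus-z of the conduction
  pathway (straight-axis, deterministic) and the constriction minimum.
* **A synthetic generator** — toy channel/bilayer systems and
  telegraph-process trajectories with planted, closed-form ground truth,
  used to validate the entire pipeline end to end.

## Worked example

Generate one 200 ns-like wild-type trajectory (2,000 frames at 0.1 ns),
run the occupancy pipeline on the written file, and summarize:

```r
library(hydropore)

toy <- build_toy_system(toy_system_spec())
dyn <- dynamics_preset("WT", n_frames = 2000, seed = 1)
traj <- tempfile(fileext = ".pdb")
truth <- simulate_trajectory(toy, dyn, traj)

frames <- iterate_frames(toy$system, traj)
ts <- occupancy_series(frames, toy$system, occupancy_config(label = "WT"))
ts
#> <occupancy_ts 'WT'> 2000 frames, dt = 0.1 ns; mean n_water = 5.36, mean n_carbon = 2.15

all(ts$n_water == truth$ground_truth$n_water)  # the generator contract
#> [1] TRUE

percent_occupancy(ts, "carbon")   # % of frames with >= 1 lipid carbon in the pore
#> [1] 52.3

seg <- classify_wetting(ts, min_dwell = 1)
estimate_rates(seg, dt = 0.1)     # planted truth: k_wd = 0.5, k_dw = 1.0 /ns
#> <rate_estimate> k(wet->dry) = 0.548 /ns (se 0.065), k(dry->wet) = 1.05 /ns (se 0.12), wet fraction 0.657

inverse_correlation(ts, seed = 1)$rho   # lipids enter preferentially when dry
#> [1] -0.444
```

The percent occupancy is the single-seed estimate of the condition's
closed-form expectation (55% for the WT-like preset); the rates and the
wet fraction recover the planted telegraph parameters within their
standard errors, and the negative Spearman rho reflects the built-in
wet/dry–insertion coupling. Comparing against an L146N-like run
(expected occupancy 35%, mostly wet):

```r
dyn2 <- dynamics_preset("L146N", n_frames = 2000, seed = 1)
traj2 <- tempfile(fileext = ".pdb")
simulate_trajectory(toy, dyn2, traj2)
ts2 <- occupancy_series(iterate_frames(toy$system, traj2), toy$system,
                        occupancy_config(label = "L146N"))
compare_conditions(ts, ts2, labels = c("WT", "L146N"), seed = 1)
#> <comparison_report> WT vs L146N
#>   WT       carbon occupancy  52.3%  water occupancy  73.9%  mean n_water  5.36  mean n_carbon  2.15
#>   L146N    carbon occupancy  33.8%  water occupancy  91.9%  mean n_water  7.17  mean n_carbon  1.08
#>   difference (carbon occupancy) 18.5 points, 95% CI [15.6, 21.5]
#>   water-carbon Spearman rho = -0.444 (p = 0.000999)
#>   water-carbon Spearman rho = -0.197 (p = 0.000999)
```

For real trajectories, point `read_structure()` / `iterate_frames()` at
your own files and adapt `occupancy_config()` (anchor and orientation
selections, lipid residue names, boxes). See the vignette
(`vignettes/hydrophobic-gating.Rmd`) for the model, the parameter
defaults and their rationale, and known limitations.

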