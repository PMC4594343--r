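---
title: "Quantifying hydrophobic gating and lipid penetration in channel pores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hydrophobic gating and lipid penetration in channel pores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydropore)
```

## The scientific problem

Narrow hydrophobic sections of ion channel pores can spontaneously empty of
water. In a two-pore-domain (K2P) potassium channel such as TWIK-1, a ring
of leucines — the *hydrophobic cuff* — below the selectivity filter forms
such a constriction: in simulation its water content flickers between a
*wet* (liquid) and a *dry* (vapor) state, and a dry cuff is an energetic
barrier to ion conduction even when the channel is not sterically closed.
Lateral fenestrations connect this inner pore to the bilayer core, and
acyl tails of membrane lipids can reach through them into the pore lining.
hydropore quantifies both phenomena, and their coupling, from MD
trajectories:

* per-frame counts of water oxygens and lipid carbons in boxes fixed to a
  pore-centered coordinate system,
* percent-occupancy summaries and wild-type-versus-mutant comparisons,
* wet/dry segmentation of the hydration trace with transition-rate
  estimates,
* joint water–lipid occupancy heat maps and rank-correlation statistics,
* bulk-normalized 3-D water density grids (OpenDX), and
* pore-radius-versus-z profiles locating the constriction.

Because the analysis, not the simulation, is the deliverable, the package
also ships a synthetic trajectory generator with planted, closed-form
ground truth against which every stage is validated.

## The pore-centered coordinate system

All counting happens in a frame whose origin is the centroid of an
*anchor* selection — in TWIK-1 the two threonines (Thr117/Thr225 in each
subunit) of the innermost K⁺ site (S4) of the selectivity filter — with
the pore axis pointing from that centroid toward an extracellular
*orientation* selection. z = 0 at the S4 site and negative z is
intracellular, so the water counting box, the 20 × 20 × 5 Å region
spanning −10 Å < z ≤ −5 Å, sits across the hydrophobic cuff, and the
lipid-carbon box, 20 × 20 × 20 Å spanning −20 Å < z ≤ 0 Å, covers the
inner cavity below the filter. (The interval −10 < z < −5 is the only
consistent reading of the constriction's placement; both boxes are
config-exposed through `counting_box()`.)

Three numerical choices matter here:

* **The frame is recomputed every trajectory frame** from the anchor
  atoms, rather than fixed once. For a run with restrained Cα atoms the
  two are equivalent; recomputation makes the method valid for
  unrestrained runs too.
* **The lateral axes are seeded from a molecule-fixed direction** (the
  first anchor atom's offset from the anchor centroid, orthonormalized
  against the axis), falling back to the laboratory x/y axes only in
  degenerate cases. Seeding from a laboratory axis would make lateral
  coordinates depend on the system's overall orientation; with a
  molecule-fixed seed, every pore-frame coordinate is invariant under
  rigid-body motion of the whole system (tested to 10⁻⁶ Å), which is the
  property the analysis actually needs.
* **The z interval of a counting box is half-open**, (zmin, zmax], so two
  stacked boxes can never double-count a boundary atom. The lateral
  faces are closed; a continuous coordinate lies exactly on a face with
  probability zero, so the convention only matters for reproducibility.

Periodic images are handled by wrapping every atom into the orthorhombic
cell centered on the anchor centroid before the frame is built, so lipids
broken across the boundary are counted on the correct side. Triclinic
cells are rejected outright rather than mis-wrapped.

## Occupancy, segmentation and rates

`occupancy_series()` produces the per-frame counts; everything downstream
is a pure function of them.

**Percent occupancy** is the percentage of frames with at least
`min_count` (default 1) atoms in the box. The threshold behind the
headline "percent occupancy of carbons" is not standardized; presence of
any carbon is the natural reading and the default, with `min_count`
exposed. Replicate simulations are pooled at the frame level before the
ratio — identical to averaging per-replicate percentages when replicates
have equal length, which is the usual design (e.g. two 200 ns runs).

**Wet/dry segmentation** uses two-threshold hysteresis: dry when the
water count falls to `dry_max` (default 1) or below, wet at `wet_min`
(default 4) or above, holding the previous state in between. A single
threshold would chatter on shot noise; the defaults bracket the gap of
the strongly bimodal count distribution a dewetting pore produces
(Poisson-like around ~8 when wet, near 0 when dry). Segments shorter than
`min_dwell` frames (default 5, i.e. 0.5 ns at the 0.1 ns sampling the
analysis assumes) are merged into the longer neighbour, shortest first,
ties to the preceding segment — a guard against counting flickers as
transitions. For rate estimation from densely sampled synthetic data we
use `min_dwell = 1`, since merging deliberately censors short dwells and
would bias rates downward.

**Rates** are maximum-likelihood for a two-state telegraph process
observed at fixed stride: exits from a state divided by total time in it,
with standard error rate/√(number of transitions). A rate with no
observed transition is 0 with an `NA` standard error and a flag, not a
pretend-precise number. Note the finite-sample boundary effect: on a
strictly alternating trace only the state the trace does not end in has
exactly rate 1/dt; the other has (k−1)/k of it.

## Density maps and pore profiles

Water density is accumulated on a regular grid (default 0.5 Å spacing) by
floor binning in the pore frame. Nearest-voxel binning was chosen over
kernel spreading because it conserves counts exactly — the voxel sum
equals the mean number of in-region atoms per frame, which is both an
invariant the tests assert and what "number density" means. Normalization
divides by the mean over a designated bulk region (default: voxel centers
more than 15 Å from the pore axis laterally and |z| > 15 Å; any explicit
region can be given, and must contain at least 100 voxels for the mean to
be meaningful). After normalization, thresholding at an isovalue of 0.5 —
half bulk density — classifies voxels as wetted/dewetted and reports the
dewetted volume fraction of a cavity region.

The pore profile is HOLE-like but deliberately simpler: at each z slice
the accessible radius at a lateral point is the minimum over protein
heavy atoms of the 3-D distance minus the atom's van der Waals radius
(Bondi-style defaults, overridable), and the slice center maximizes this
radius by a Nelder–Mead search seeded from the nearest already-solved
slice, walking from the middle of the range outward. No Monte-Carlo
sphere squeeze and no bendable pathway: for an essentially straight
channel axis the deterministic variant is adequate, testable against a
dense grid-search oracle (agreement to 0.01 Å on analytic rings), and
reproducible. When the local search fails to improve on its seed, the
seed value is kept and the slice flagged `"fallback"`. Hydrogens are
excluded by default (crystal structures have none; simulations may).
Exact numerical agreement with the HOLE program is not claimed.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes —
not the physics. A toy system (`build_toy_system()`) provides a
cylinder-with-constriction of pseudo-protein atoms, a four-atom anchor
ring whose centroid defines z = 0, two leaflets of pseudo-POPC (40
carbons, 8 oxygens, N and P per lipid) standing laterally clear of the
counting boxes, a relocatable cavity-water pool and bulk water, in a
60 × 60 × 80 Å orthorhombic box (~1,100 atoms).

`simulate_trajectory()` then evolves a discrete-time telegraph hydration
state (switch probability k·dt per frame, valid for k·dt < 0.5), draws a
Poisson water count per frame (λ_wet = 8, λ_dry = 0.3 by default) and
moves exactly that many pool waters uniformly into the water box; each
insertion-eligible lipid (the lower leaflet) independently moves 1–4 tail
carbons into the carbon box with state-dependent probability, p_dry >
p_wet, reproducing the inverse water–lipid coupling. Planted atoms are
placed 0.3 Å clear of every box face so that coordinate rounding in any
supported output format (3-decimal PDB, float32 DCD) can never flip a
count: **the defining contract is that `occupancy_series()` on the
emitted files returns the planted counts exactly, frame by frame**, and
the tests assert precisely that, across both the text (multi-model PDB)
and binary (DCD) reader paths.

Closed forms (`ground_truth_stats()`): stationary wet fraction
π_wet = k_dw/(k_dw + k_wd); expected carbon percent occupancy
100·[π_wet(1−(1−p_wet)^L) + π_dry(1−(1−p_dry)^L)] with L eligible
lipids; expected mean water count π_wet·λ_wet + π_dry·λ_dry.

Two presets pin the study's design points, choosing the per-state
presence probabilities q = 1−(1−p)^L first and solving for p:

* `dynamics_preset("WT")`: k_wd = 0.5 ns⁻¹, k_dw = 1.0 ns⁻¹ (π_wet =
  2/3), q_wet = 0.40, q_dry = 0.85 → expected carbon occupancy exactly
  55%;
* `dynamics_preset("L146N")`: k_wd = 0.1, k_dw = 0.9 (π_wet = 0.9 — the
  polar mutant stays hydrated), q_wet = 0.30, q_dry = 0.80 → exactly 35%.

Defaults are 2,000 frames at dt = 0.1 ns, i.e. one 200 ns trajectory
sampled every 0.1 ns. Randomness uses per-frame seed substreams derived
from one integer seed, so regenerating a trajectory is byte-identical and
stride-read subsets stay consistent.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: force-field energetics, water structure and
hydrogen bonding, lipid conformational realism, protein flexibility
beyond rigid jitter, autocorrelated water counts within a hydration state
(emissions are conditionally independent given the state), and any real
TWIK-1 geometry beyond "a constricted cylinder in a planar bilayer".
Recovery of planted counts validates the measurement pipeline; it cannot
validate the biological conclusions of any particular simulation.

## Statistical choices

* **Spearman, not Pearson**, for the water–carbon association: the counts
  are small, discrete and non-normal; only the monotone association is
  claimed. The permutation p-value uses the +1-corrected two-sided form
  (1 + #{|ρ_perm| ≥ |ρ|})/(1 + N), which can never be exactly zero, and
  is reproducible from a seed. Constant series get ρ reported as 0 with
  an explicit flag rather than NA propagation.
* **Condition comparison** reports the difference in carbon percent
  occupancy with a frame-level bootstrap percentile interval (1,000
  resamples, seeded). Frame bootstrap ignores autocorrelation, so a
  moving-block variant (`block_length`, ~10 frames = 1 ns is a reasonable
  default for this sampling) is provided; for the planted generator,
  whose insertions are conditionally independent per frame, the
  frame-level interval is correctly calibrated.
* All internal RNG use saves and restores the caller's `.Random.seed`.

## Problem sizes used in validation

The test-suite and acceptance scales are desk scales chosen to make
Monte-Carlo tolerances meaningful: counting oracles on 200 random frames;
planted-count recovery over 10 seeds × 500 frames through written files;
rate recovery over 10 seeds × 10,000 frames; density normalization on 20
frames of 10,000 ideal-gas points (bulk mean within 1.00 ± 0.02); and the
two design-point occupancies as 10-seed means of 2,000-frame runs, which
carry a per-seed standard deviation of about 2 percentage points and a
seed-mean deviation well inside ±3 points (the condition-comparison check
uses 3-seed means for the same reason).

## Known limitations

* Orthorhombic periodic boxes only; triclinic trajectories are rejected.
* GROMACS XTC/TRR binary formats are not read; convert to multi-model
  PDB or DCD first (`gmx trjconv`, `mdconvert`).
* The straight-axis pore profile understates the radius of strongly
  curved or branched pathways.
* No free-energy estimates of wetting, no per-lipid identity tracking,
  and no causal claim about lipids driving dewetting: the statistics are
  descriptive.

## A worked miniature

```{r example, eval = FALSE}
toy <- build_toy_system(toy_system_spec())
dyn <- dynamics_preset("WT", n_frames = 500, seed = 1)
traj <- tempfile(fileext = ".pdb")
truth <- simulate_trajectory(toy, dyn, traj)

frames <- iterate_frames(toy$system, traj)
ts <- occupancy_series(frames, toy$system, occupancy_config(label = "WT"))

all(ts$n_water == truth$ground_truth$n_water)   # TRUE: the defining contract
percent_occupancy(ts, "carbon")                  # ~55
seg <- classify_wetting(ts)
estimate_rates(seg, dt = 0.1)
inverse_correlation(ts, seed = 1)$rho            # < 0
```
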