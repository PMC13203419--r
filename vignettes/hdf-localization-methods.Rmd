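---
title: "Methods: localizing stable highest-dominant-frequency areas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: localizing stable highest-dominant-frequency areas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During catheter ablation of persistent atrial fibrillation (AF), an
operator drags a multi-electrode catheter across the left atrium and
records bipolar electrograms point by point, each sample tagged with a 3D
position and a timestamp ("sequential mapping"). Regions whose local
activation rate — summarized by the *dominant frequency* (DF) of the
electrogram spectrum — stays high across the whole mapping session are
candidate ablation targets. The difficulty is that each location is
observed only during the seconds the catheter happens to dwell there, the
sampling density is wildly uneven, and individual 2-s windows are noisy.
`hdfmap` implements an automatic pipeline that turns such a stream into a
voxel-level map of *highest-DF (HDF) areas* that are stable in both space
and time.

## Pipeline

1. **Fibrillation gating** (`detect_activations()`, `locate_af_periods()`).
   A reference rhythm channel (coronary-sinus-like) is scanned for
   activation peaks; stretches where the running-median cycle length drops
   below 250 ms for at least 5 s are treated as fibrillatory. Analysis
   windows outside these periods are discarded.
2. **Per-point DF + OI** (`compute_df_points()`). For each mapping point,
   the 2-s electrogram window centered on its timestamp is screened by
   amplitude rules (peak < 0.2 mV = poor contact, > 16 mV = artifact) and a
   power-line energy rule, then preprocessed with the Botteron sequence —
   zero-phase 4th-order Butterworth 40–250 Hz bandpass, full-wave
   rectification, zero-phase 20 Hz low-pass — which converts sharp
   activation deflections into a low-frequency activation-rate envelope.
   A Welch periodogram of the envelope (1-s Hamming segments, 50% overlap,
   zero-padded to a 0.05 Hz grid) gives the spectrum; the DF is its peak in
   4–10 Hz, and the *Organization Index* (OI) — the fraction of 0–20 Hz
   power within ±0.375 Hz of the DF and its harmonics — must reach 0.2 for
   the point to count.
3. **Voxel aggregation** (`build_voxel_model()`). Points are binned into
   2 mm cubic voxels of a 100 mm working volume. Each voxel's time-ordered
   points are *sparse-sampled*: a balanced binary search tree over the rank
   sequence is traversed breadth-first until 31 nodes are queued, giving a
   deterministic, approximately equally spaced subsample that spans the
   whole observation interval — long-term stability is probed at a fraction
   of the DF computations. The voxel DF is the trimmed mean (α = 0.2,
   k = ⌊αn⌋ values cut from each tail) of the sampled valid DFs; voxels
   with fewer than 3 valid DFs are dropped.
4. **Neighborhood smoothing** (`smooth_model()`). A kd-tree over voxel
   centroids (axes cycling x → y → z, median splits) finds each voxel's 10
   nearest neighbors; the voxel DF is replaced by the 11-term arithmetic
   mean of itself and those neighbors, all computed from the pre-smoothing
   snapshot.
5. **Personalized labeling** (`label_hdf()`). The HDF threshold is the
   patient's own mean voxel DF plus one sample standard deviation; voxels
   strictly above it are labeled 1.

`run_pipeline()` chains all stages and reports per-stage counts, including
the sparse-sampling reduction fraction.

## Key parameters

| Parameter | Default | Why |
|---|---|---|
| window length | 2 s | stated acquisition window per mapping point |
| Botteron bands | 40–250 Hz, 20 Hz LP | classic activation-envelope recipe |
| Welch grid | 0.05 Hz | stated spectral step; realized by zero-padding |
| Welch segments | 1 s, 50% overlap | unstated; 3 segments balance variance and resolution |
| DF band | 4–10 Hz | physiological fibrillatory range |
| OI band half-width | 0.375 Hz | stated DF width threshold |
| OI range / threshold | 0–20 Hz / 0.2 | stated operating point |
| voxel size / volume | 2 mm / 100 mm cube | stated grid |
| sparse queue | 31 | stated empirical value |
| trimming α | 0.2 | unstated; trims one in five per tail |
| neighbors k | 10 | stated smoothing neighborhood |
| HDF rule | mean + 1 sample SD, strict > | stated personalized threshold |

Every unstated choice above is configurable (`spectral_config()`,
`aggregation_config()`, `run_config()`), and the reasoning for each is
recorded in the function documentation.

## Numerical choices worth knowing

- **Per-segment mean removal in Welch.** The rectified envelope has a large
  DC component. Without removing each segment's mean before windowing, the
  DC lobe dominates the 0–20 Hz denominator of the OI and the index loses
  its meaning as a peak-significance measure. Mean removal per segment is
  the conventional Welch default and is applied here.
- **DF tie-break.** Equal spectral maxima resolve to the lowest frequency,
  which avoids capture by harmonics.
- **Harmonic band centers.** Each harmonic band is centered on the local
  spectral maximum within ±0.5 Hz of the integer multiple of the DF; on a
  flat plateau the maximal bin closest to the exact multiple is used, and
  when no local maximum exists the band falls back to the exact multiple.
  Overlapping bands are unioned before summation so power is never counted
  twice, which also guarantees OI ≤ 1.
- **Sparse-sampling conventions.** Midpoint splits take the lower middle on
  even counts and breadth-first traversal visits left children first; the
  sampler is therefore a pure function of (n, queue length).
- **kd-tree determinism.** Median splits send boundary-equal points left;
  distance ties in the k-NN frontier resolve by the lexicographic voxel
  rank. The tree's neighbor sets equal brute-force search exactly, which
  the test suite verifies on random instances.
- **Half-open everything.** Voxel cells are [lo, hi), so each point belongs
  to exactly one voxel; time intervals are half-open; voxel indices are
  0-based.

## The synthetic generator, its realism and its limits

Clinical mapping exports are proprietary, so the package ships a simulator
(`simulate_dataset()`) that reproduces the *statistical structure* the
pipeline relies on, not atrial electrophysiology:

- **True DF field** (`df_field()`): base rate + linear gradient + Gaussian
  focal bumps, clipped to 4–10 Hz, evaluated on a 100 mm cube.
- **Surface and trajectory** (`simulate_trajectory()`): the catheter moves
  on an ellipsoidal shell of left-atrial scale (semi-axes 30/27/24 mm).
  Mapping is simulated the way sequential mapping is actually acquired —
  point by point: sites follow a deterministic area-uniform Fibonacci
  covering of the surface, the catheter dwells 2.5–5 s per site with a
  small random drift, repositions in 0.3 s, and 15% of sites revisit
  previously mapped locations, so individual voxels accumulate
  observations separated by long time spans. Dwells longer than the 2-s
  analysis window keep windows spatially stationary — an early
  continuous-sweep version of the generator moved the catheter ~100 mm
  within single analysis windows, which made per-point DF reflect a path
  average rather than local tissue; that is a physics failure of the
  stand-in, not of the method, and is why the site-hop model is used.
- **Electrograms** (`simulate_egm()`): per channel, a train of biphasic
  ~20 ms deflections whose instantaneous inter-activation interval is the
  reciprocal of the local true DF, with truncated multiplicative
  cycle-length jitter, Gaussian noise, >16 mV artifacts, sub-0.2 mV dropout
  segments, and a mains sinusoid. A reference channel alternates between
  rapid (170 ms) cycles inside fibrillation spans and slow (600 ms) cycles
  outside.
- **Ground truth** (`emit_ground_truth()`): the noiseless field is
  evaluated at every coordinate sample; per-voxel true DF is the mean over
  member points, and the true HDF mask applies the same mean + 1 SD rule.
  Only voxels observed at least 3 times enter the truth, mirroring the
  model's notion of an effective voxel.

Limits: no fibrillatory conduction physics, no anatomy, no wavefront
propagation between channels (each channel's train is independent given
the field), and the mapping-density knobs (dwell lengths, revisit rate)
are free parameters rather than calibrated clinical values.

## Problem sizes

The clinical setting behind the method (15 bipolar channels, ~30 min of
mapping, hundreds of thousands of points) is not desk-tractable. The
package's own default study condition is 6 channels × 90 s at 40 Hz
(≈ 21,600 mapping points, ≈ 600 effective voxels), which runs the full
pipeline in under a minute while preserving the regime the method cares
about: saturated voxels (> 31 points) where sparse sampling actually
reduces work (~40–50% reduction), uneven density, and long per-voxel time
spans. These sizes are the package's choice, not values from the source
material.

## Validation experiments

- `recover_df_points()` — DF estimation error on clean stationary points
  (event-time rounding plus spectral grid only).
- `hdf_patch_experiment()` — end-to-end localization of a single focal
  patch (+2.5 Hz, 8 mm) on a uniform base field, scored by Dice/recall/
  precision against the ground-truth mask.
- `voxel_size_sweep()` — the model rebuilt at 1/2/3/4 mm from one dataset,
  reusing per-point DF results through a cache.
- `sweep_f1()` + `simulate_oi_segments()` — the OI-threshold sensitivity
  analysis on a labeled segment table.

```{r}
library(hdfmap)
ex <- hdf_patch_experiment(seed = 1)
c(dice = ex$dice, recall = ex$recall, precision = ex$precision)
```

See the README for a complete worked example with printed output.
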