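# hdfmap

Automatic localization of spatiotemporally stable **highest-dominant-frequency
(HDF) areas** of the left atrium from sequentially mapped bipolar
intracardiac electrograms — with a synthetic sequential-mapping generator so
the entire pipeline can be exercised and validated without clinical data.

## The science in one paragraph

During persistent atrial fibrillation, regions that activate faster than the
rest of the atrium are candidate ablation targets. The local activation rate
is summarized by the **dominant frequency (DF)**: the peak, within 4–10 Hz,
of the Welch power spectrum of the Botteron-preprocessed electrogram
(40–250 Hz bandpass → rectification → 20 Hz low-pass), computed on the 2-s
window centered on each mapping point and accepted only when its
**Organization Index** (the fraction of 0–20 Hz spectral power within
±0.375 Hz of the DF and its harmonics) reaches 0.2. Because sequential
mapping visits each site only briefly and unevenly, single windows are not
trustworthy: points are pooled into **2 mm voxels** of a 100 mm working
volume, each voxel's time-ordered points are sparse-sampled by breadth-first
traversal of a balanced binary search tree (queue length 31) so that the
retained windows span the whole observation interval, and the voxel DF is a
trimmed mean (α = 0.2) of the sampled valid DFs. A kd-tree supplies each
voxel's 10 nearest neighbors for an 11-term arithmetic smoothing, and voxels
whose smoothed DF lies strictly above the patient's own **mean + 1 SD**
threshold are labeled HDF. The result is a map of high-rate areas that are
stable across both space and the mapping session.

## Worked example

Simulate a small mapping session on a uniform 6 Hz field with one focal
patch (+2.5 Hz, 8 mm radius) placed on the atrial shell, run the full
pipeline, and compare the extracted HDF voxels with the generator's ground
truth:

```r
library(hdfmap)

field <- df_field(base_df = 6, gradient = c(0, 0, 0),
                  patches = list(focal_patch(center = c(74, 59, 50),
                                             radius_mm = 8, peak_df = 8.5)))
ds <- simulate_dataset(sim_config(seed = 11, duration_s = 20,
                                  n_channels = 3), field = field)
res <- run_pipeline(ds$recording, ds$stream, run_config(), verbose = TRUE)
#> AF gating: 1 interval(s), 19.8 s total
#> voxelization: 2400 points in bounds, 0 dropped
#> sparse sampling: 1091 of 2400 points retained (reduction 54.5%)
#> DF estimation: 904 valid of 1091 sampled points
#> aggregation: 50 effective voxel(s), 16 saturated
#> HDF extraction: threshold 6.305 Hz, 9 voxel(s) labeled

truth_hdf <- ds$truth$voxels[ds$truth$voxels$hdf, ]
ov <- mask_overlap(res$hdf$hdf_voxels, truth_hdf)
sprintf("dice %.3f  recall %.3f  precision %.3f",
        ov$dice, ov$recall, ov$precision)
#> [1] "dice 1.000  recall 1.000  precision 1.000"

head(res$model[, c("ix", "iy", "iz", "n_points", "df_raw", "df_smoothed")], 3)
#>   ix iy iz n_points df_raw df_smoothed
#> 1 12 21 16        6 6.0375    6.061862
#> 2 12 22 16        4 6.0500    6.061862
#> 3 12 24 15       15 6.0500    6.061862
```

At the full default study condition (90 s, 6 channels,
`hdf_patch_experiment(seed = 1)`) the same comparison yields Dice ≈ 0.88
with ≈ 580 effective voxels and a ~42% sparse-sampling reduction; one run
takes under a minute.

The same workflow is available from the shell via the thin CLI in
`inst/scripts/hdfmap`:

```sh
Rscript inst/scripts/hdfmap simulate --out data/ --seed 11
Rscript inst/scripts/hdfmap run --data data/ --out model/ --verbose
Rscript inst/scripts/hdfmap calibrate-oi --seed 3 --out oi.json
Rscript inst/scripts/hdfmap inspect --data data/
```

`simulate` writes a plain-text dataset directory (`signals.csv`,
`coords.csv`, `truth.json`, `manifest.json`); `run` writes `voxels.csv`,
`hdf_summary.json` and an ASCII `model.ply` point cloud for external
viewers.

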