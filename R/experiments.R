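# Reusable validation experiments built on the simulator: DF-recovery on
# clean stationary points and the voxel-size sensitivity rerun.

#' DF recovery on clean stationary points
#'
#' Simulates `n` independent clean points (no noise, jitter, artifacts or
#' mains interference) with true DFs drawn uniformly from `df_range`, runs
#' the full per-point estimation chain on each 2-s window, and reports true
#' versus estimated DF. The residual error comes only from event-time
#' rounding and the spectral grid.
#'
#' @param n number of points.
#' @param df_range true-DF sampling range, Hz.
#' @param seed RNG seed.
#' @param cfg a [spectral_config()].
#' @return data.frame with `df_true`, `df_est`, `oi`, `valid` per point.
#' @export
recover_df_points <- function(n = 200L, df_range = c(4.5, 9.5), seed = 1L,
                              cfg = spectral_config()) {
  set.seed(seed)
  fs <- 1000
  dur_s <- 4
  df_true <- runif(n, df_range[1], df_range[2])
  df_est <- oi <- rep(NA_real_, n)
  valid <- logical(n)
  for (i in seq_len(n)) {
    x <- numeric(dur_s * fs)
    wv <- biphasic_wavelet()
    for (ev in pulse_train_times(dur_s * 1000,
                                 function(t) df_true[i], 0)) {
      x <- add_at(x, as.integer(round(ev)) + 1L, wv)
    }
    res <- df_point_core(x, fs, dur_s / 2 * 1000, cfg, NULL)
    df_est[i] <- res$df_hz
    oi[i] <- res$oi
    valid[i] <- res$valid
  }
  data.frame(df_true = df_true, df_est = df_est, oi = oi, valid = valid)
}

#' Focal-patch recovery experiment
#'
#' End-to-end check on a two-component field: a uniform base rate plus one
#' focal high-DF patch (no background gradient, so the true HDF mask is the
#' patch neighborhood and recall is not dominated by threshold knife-edge
#' voxels on a shallow gradient). Simulates a dataset, runs the full
#' pipeline at default settings, and compares the extracted HDF set with
#' the ground-truth mask.
#'
#' @param seed simulation seed.
#' @param delta_hz patch peak elevation above the base rate, Hz.
#' @param radius_mm patch Gaussian radius, mm.
#' @param base_df base rate, Hz.
#' @param config a [run_config()].
#' @return list with `dice`, `recall`, `precision`, `counts`, `result`,
#'   `dataset`.
#' @export
hdf_patch_experiment <- function(seed = 1L, delta_hz = 2.5, radius_mm = 8,
                                 base_df = 6, config = run_config()) {
  field <- df_field(base_df = base_df, gradient = c(0, 0, 0),
                    patches = list(focal_patch(radius_mm = radius_mm,
                                               peak_df = base_df + delta_hz)))
  ds <- simulate_dataset(sim_config(seed = seed), field = field)
  res <- run_pipeline(ds$recording, ds$stream, config)
  tr <- ds$truth
  ov <- mask_overlap(res$hdf$hdf_voxels,
                     tr$voxels[tr$voxels$hdf, , drop = FALSE])
  c(ov[c("dice", "recall", "precision")],
    list(counts = res$counts, result = res, dataset = ds))
}

#' Voxel-size sensitivity rerun
#'
#' Rebuilds the model at several voxel sizes from one simulated dataset,
#' reporting the voxel bookkeeping (nonempty / effective / saturated
#' counts) and the overlap of the extracted HDF set with the ground-truth
#' mask recomputed on each grid. Per-point DF results are shared across
#' sizes through a cache, since they do not depend on the grid.
#'
#' @param dataset an `hdf_dataset` from [simulate_dataset()].
#' @param sizes voxel edge lengths to evaluate, mm.
#' @param config a [run_config()] (its `grid$voxel_size` is overridden).
#' @return data.frame with one row per size: `voxel_size`, `nonempty`,
#'   `effective`, `saturated`, `n_hdf`, `dice`, `recall`, `threshold_hz`.
#' @export
voxel_size_sweep <- function(dataset, sizes = c(1, 2, 3, 4),
                             config = run_config()) {
  stopifnot(inherits(dataset, "hdf_dataset"))
  cache <- new.env(parent = emptyenv())
  rows <- lapply(sizes, function(s) {
    cfg <- config
    cfg$grid$voxel_size <- s
    res <- run_pipeline(dataset$recording, dataset$stream, cfg,
                        df_cache = cache)
    truth <- emit_ground_truth(dataset$config, dataset$stream,
                               dataset$field, grid = res$grid)
    ov <- mask_overlap(res$hdf$hdf_voxels,
                       truth$voxels[truth$voxels$hdf, , drop = FALSE])
    data.frame(voxel_size = s,
               nonempty = res$counts$voxels_nonempty,
               effective = res$counts$voxels_effective,
               saturated = res$counts$voxels_saturated,
               n_hdf = res$counts$n_hdf,
               dice = ov$dice, recall = ov$recall,
               threshold_hz = res$hdf$threshold_hz)
  })
  do.call(rbind, rows)
}
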