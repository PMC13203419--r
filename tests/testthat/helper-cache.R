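# Session-wide cache for expensive simulated objects so several test files
# can share one pipeline run / dataset instead of recomputing it.

test_cache_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(test_cache_env[[key]]))
    assign(key, expr, envir = test_cache_env)
  test_cache_env[[key]]
}

# full-scale focal-patch experiment at default study conditions (slow)
patch_run <- function(seed) {
  cached(paste0("patch_", seed), hdf_patch_experiment(seed = seed))
}

# small dataset for cheap end-to-end unit tests
small_dataset <- function() {
  cached("small_ds",
         simulate_dataset(sim_config(seed = 11, duration_s = 20,
                                     n_channels = 3L)))
}

small_pipeline <- function() {
  cached("small_pipe", {
    ds <- small_dataset()
    run_pipeline(ds$recording, ds$stream, run_config())
  })
}

# clean 4-s pulse-train recording at a given rate (no noise/jitter/artifacts)
clean_recording <- function(df_hz = 6, dur_s = 4, fs = 1000, seed = 5) {
  cached(paste0("clean_", df_hz, "_", dur_s, "_", seed), {
    set.seed(seed)
    x <- numeric(dur_s * fs)
    wv <- hdfmap:::biphasic_wavelet()
    for (ev in hdfmap:::pulse_train_times(dur_s * 1000,
                                          function(t) df_hz, 0)) {
      x <- hdfmap:::add_at(x, as.integer(round(ev)) + 1L, wv)
    }
    structure(list(fs = fs, channels = "ch_01",
                   signals = matrix(x, ncol = 1L,
                                    dimnames = list(NULL, "ch_01")),
                   ref_channel = NULL, t0 = 0),
              class = "egm_recording")
  })
}

# minimal hand-built voxel model (bypasses aggregation) for smoothing and
# labeling arithmetic tests
fake_voxel_model <- function(centroids, df_raw) {
  n <- nrow(centroids)
  structure(data.frame(ix = seq_len(n) - 1L, iy = 0L, iz = 0L,
                       x_mm = centroids[, 1], y_mm = centroids[, 2],
                       z_mm = centroids[, 3],
                       n_points = 1L, n_sampled = 1L, n_valid = 1L,
                       df_raw = df_raw, oi_mean = 0.5),
            class = c("voxel_model", "data.frame"))
}
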