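# Generator: DF field evaluation, trajectory, electrograms, ground truth.

test_that("constant field evaluates to the base rate everywhere", {
  f <- df_field(base_df = 6, gradient = c(0, 0, 0), patches = list())
  expect_equal(sample_df_field(f, c(0, 0, 0)), 6)
  expect_equal(sample_df_field(f, c(50, 50, 50)), 6)
  expect_equal(sample_df_field(f, c(100, 100, 100)), 6)
})

test_that("focal bump is maximal at its center", {
  ctr <- c(50, 50, 50)
  f <- df_field(base_df = 6, gradient = c(0, 0, 0),
                patches = list(focal_patch(center = ctr, radius_mm = 5,
                                           peak_df = 9)))
  at_center <- sample_df_field(f, ctr)
  far <- rbind(ctr + c(16, 0, 0), ctr + c(0, -20, 0), ctr + c(0, 0, 30))
  expect_true(all(at_center >= sample_df_field(f, far)))
  expect_equal(at_center, 9)
})

test_that("linear gradient term evaluates by hand", {
  f <- df_field(base_df = 6, gradient = c(0.02, 0, 0), patches = list())
  d <- sample_df_field(f, c(50, 0, 0)) - sample_df_field(f, c(0, 0, 0))
  expect_equal(d, 1.0)
})

test_that("field values are clipped to the DF range", {
  f <- df_field(base_df = 6, gradient = c(0.2, 0, 0), patches = list())
  expect_equal(sample_df_field(f, c(100, 0, 0)), 10)
  f2 <- df_field(base_df = 6, gradient = c(-0.2, 0, 0), patches = list())
  expect_equal(sample_df_field(f2, c(100, 0, 0)), 4)
})

test_that("out-of-cube queries and invalid fields are rejected", {
  f <- df_field()
  expect_error(sample_df_field(f, c(-1, 0, 0)), "outside")
  expect_error(sample_df_field(f, c(0, 0, 101)), "outside")
  expect_error(df_field(patches = list(
    focal_patch(center = c(50, 50, 50), peak_df = 5))), "exceed")
  expect_error(df_field(patches = list(
    focal_patch(center = c(200, 0, 0)))), "outside")
})

test_that("trajectory has one 40 Hz sample per channel per tick", {
  cfg <- sim_config(seed = 2, duration_s = 60, n_channels = 2L)
  st <- simulate_trajectory(cfg)
  expect_equal(nrow(st), 60 * 40 * 2)
  expect_equal(sum(st$channel == "ch_01"), 2400)
  expect_equal(sort(unique(st$channel)), c("ch_01", "ch_02"))
  t1 <- st$time_ms[st$channel == "ch_01"]
  expect_equal(diff(t1), rep(25, length(t1) - 1L))
})

test_that("trajectory is reproducible from the seed and varies across seeds", {
  cfg <- sim_config(seed = 3, duration_s = 12, n_channels = 2L)
  a <- simulate_trajectory(cfg)
  b <- simulate_trajectory(cfg)
  expect_identical(a, b)
  c2 <- simulate_trajectory(sim_config(seed = 4, duration_s = 12,
                                       n_channels = 2L))
  expect_false(isTRUE(all.equal(a$x_mm, c2$x_mm)))
})

test_that("trajectory points lie on the ellipsoidal shell", {
  cfg <- sim_config(seed = 5, duration_s = 12, n_channels = 2L)
  sh <- shell_spec()
  st <- simulate_trajectory(cfg, sh)
  u <- sweep(sweep(as.matrix(st[, c("x_mm", "y_mm", "z_mm")]),
                   2L, sh$center), 2L, sh$semi_axes, "/")
  expect_equal(unname(rowSums(u^2)), rep(1, nrow(st)), tolerance = 1e-8)
})

test_that("default trajectory covers a substantial part of the shell", {
  st <- cached("traj_default",
               simulate_trajectory(sim_config(seed = 3)))
  g <- default_grid(st, voxel_size = 2)
  idx <- hdfmap:::voxel_index(g, as.matrix(st[, c("x_mm", "y_mm", "z_mm")]))
  n_visited <- length(unique(hdfmap:::voxel_key(idx)))
  expect_gte(n_visited, 300)
  # the sweep reaches both hemispheres on every axis
  rng <- apply(st[, c("x_mm", "y_mm", "z_mm")], 2L, range)
  expect_true(all(rng[2, ] - rng[1, ] > shell_spec()$semi_axes))
})

test_that("electrogram generation is reproducible and matches duration", {
  cfg <- sim_config(seed = 6, duration_s = 8, n_channels = 1L)
  st <- simulate_trajectory(cfg)
  f <- df_field()
  a <- simulate_egm(cfg, st, f)
  b <- simulate_egm(cfg, st, f)
  expect_identical(a$signals, b$signals)
  expect_equal(nrow(a$signals), 8000)
  expect_equal(a$channels, c("ch_01", "cs"))
  expect_equal(a$fs, 1000)
})

test_that("a stream shorter than the configured duration is rejected", {
  cfg_short <- sim_config(seed = 6, duration_s = 8, n_channels = 1L)
  st_short <- simulate_trajectory(cfg_short)
  cfg_long <- sim_config(seed = 6, duration_s = 20, n_channels = 1L)
  expect_error(simulate_egm(cfg_long, st_short, df_field()), "shorter")
})

test_that("clean constant-rate signal carries round(10 * DF) activations per 10 s", {
  cfg <- sim_config(seed = 7, duration_s = 12, n_channels = 1L,
                    noise_sd = 0, artifact_rate = 0, dropout_rate = 0,
                    powerline_amp = 0, cycle_jitter_frac = 0)
  st <- simulate_trajectory(cfg)
  f <- df_field(base_df = 6, gradient = c(0, 0, 0), patches = list())
  rec <- simulate_egm(cfg, st, f)
  act <- detect_activations(rec$signals[, "ch_01"], rec$fs)
  in_win <- act[act >= 1000 & act < 11000]
  expect_true(abs(length(in_win) - 60) <= 1)
})

test_that("artifact injection produces at least one > 16 mV window", {
  cfg <- sim_config(seed = 8, duration_s = 10, n_channels = 1L,
                    artifact_rate = 30)
  st <- simulate_trajectory(cfg)
  rec <- simulate_egm(cfg, st, df_field())
  x <- rec$signals[, "ch_01"]
  peaks <- vapply(seq(1, length(x) - 1999, by = 2000),
                  function(s) max(abs(x[s:(s + 1999)])), numeric(1))
  expect_true(any(peaks > 16))
})

test_that("ground truth of a constant field has an empty HDF mask", {
  cfg <- sim_config(seed = 9, duration_s = 12, n_channels = 2L)
  st <- simulate_trajectory(cfg)
  f <- df_field(base_df = 6, gradient = c(0, 0, 0), patches = list())
  tr <- emit_ground_truth(cfg, st, f)
  expect_true(all(tr$voxels$df_true == 6))
  expect_false(any(tr$voxels$hdf))
})

test_that("stored HDF mask is recomputable from per-point true DF", {
  ds <- small_dataset()
  tr <- ds$truth
  st <- ds$stream
  idx <- hdfmap:::voxel_index(tr$grid,
                              as.matrix(st[, c("x_mm", "y_mm", "z_mm")]))
  keep <- hdfmap:::voxel_in_bounds(tr$grid, idx)
  key <- hdfmap:::voxel_key(idx[keep, , drop = FALSE])
  agg <- split(tr$df_at_point[keep], key)
  agg <- agg[vapply(agg, length, integer(1)) >= 3L]
  agg <- agg[order(names(agg))]
  df_true <- vapply(agg, mean, numeric(1))
  expect_equal(unname(df_true), tr$voxels$df_true)
  thr <- mean(df_true) + sd(df_true)
  expect_equal(thr, tr$threshold_hz)
  expect_equal(unname(df_true > thr), tr$voxels$hdf)
})

test_that("identical configurations give bit-identical datasets", {
  cfg <- sim_config(seed = 11, duration_s = 20, n_channels = 3L)
  ds1 <- small_dataset()
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds1$recording$signals, ds2$recording$signals)
  expect_equal(as.data.frame(ds1$stream), as.data.frame(ds2$stream))
  expect_equal(ds1$truth$voxels, ds2$truth$voxels)
})

test_that("simulation configuration is validated", {
  expect_error(sim_config(duration_s = 3))
  expect_error(sim_config(powerline_hz = 55))
  expect_error(sim_config(cycle_jitter_frac = 0.7))
  expect_error(sim_config(site_dwell_s = c(5, 2)))
  expect_error(sim_config(af_spans = list(c(5, 200))))
})
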