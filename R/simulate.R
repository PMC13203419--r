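# Synthetic sequential-mapping generator: catheter trajectory on an
# ellipsoidal shell, activation pulse-train electrograms driven by a true DF
# field, a reference rhythm channel, and the matching ground truth.

project_to_shell <- function(p, shell) {
  # p: n x 3 matrix -> nearest-direction point on the ellipsoid
  u <- sweep(sweep(p, 2L, shell$center), 2L, shell$semi_axes, "/")
  nrm <- sqrt(rowSums(u^2))
  nrm[nrm == 0] <- 1
  u <- u / nrm
  sweep(sweep(u, 2L, shell$semi_axes, "*"), 2L, shell$center, "+")
}

#' Simulate a sequential-mapping catheter trajectory
#'
#' Moves a multi-electrode catheter over an ellipsoidal shell the way an
#' operator acquires a point-by-point map: the catheter dwells several
#' seconds at each mapping site (so the 2-s analysis windows around the
#' central samples are spatially stationary), then repositions to the next
#' site. Fresh sites follow a deterministic area-uniform covering of the
#' surface (a Fibonacci sphere sequence), so whole-chamber coverage does not
#' depend on chance; with probability `revisit_prob` a site instead returns
#' to a previously mapped location, giving individual voxels observations
#' separated by long time spans. Dwell lengths vary and the catheter drifts
#' slightly while dwelling, producing the uneven sampling density typical of
#' sequential mapping.
#'
#' @param cfg a [sim_config()].
#' @param shell a [shell_spec()] describing the surface.
#' @return a `mapping_stream`: data.frame with columns `time_ms`, `channel`,
#'   `x_mm`, `y_mm`, `z_mm`, sampled at `cfg$coord_fs`, ordered by time then
#'   channel. Reproducible given `cfg$seed`.
#' @export
simulate_trajectory <- function(cfg, shell = shell_spec()) {
  stopifnot(inherits(cfg, "sim_config"), inherits(shell, "shell_spec"))
  set.seed(cfg$seed)
  nt <- round(cfg$duration_s * cfg$coord_fs)
  t_ms <- (seq_len(nt) - 1L) / cfg$coord_fs * 1000

  # plan the site sequence until the recording is filled
  mean_site <- mean(cfg$site_dwell_s) + cfg$site_transition_s
  n_total <- max(1L, ceiling(cfg$duration_s / mean_site))
  n_sweep <- max(1L, round(n_total * (1 - cfg$revisit_prob)))
  golden <- pi * (3 - sqrt(5))
  fib_site <- function(k) { # k in 1..n_sweep, area-uniform on the sphere
    z <- 1 - (2 * k - 1) / n_sweep
    rho <- sqrt(pmax(0, 1 - z^2))
    th <- golden * k
    c(rho * cos(th), rho * sin(th), z)
  }

  dwell_n <- function() round(runif(1, cfg$site_dwell_s[1],
                                    cfg$site_dwell_s[2]) * cfg$coord_fs)
  trans_n <- round(cfg$site_transition_s * cfg$coord_fs)

  centers <- matrix(NA_real_, nt, 3L)
  filled <- 0L
  k_sweep <- 0L
  visited <- list()
  prev_u <- NULL
  while (filled < nt) {
    if (k_sweep < n_sweep &&
        (length(visited) < 3L || runif(1) >= cfg$revisit_prob)) {
      k_sweep <- k_sweep + 1L
      u_site <- fib_site(k_sweep)
    } else {
      u_site <- visited[[sample.int(length(visited), 1L)]]
    }
    visited[[length(visited) + 1L]] <- u_site
    if (!is.null(prev_u) && trans_n > 0L && filled < nt) {
      # straight-line repositioning, projected back to the surface
      m <- min(trans_n, nt - filled)
      frac <- seq_len(m) / (trans_n + 1L)
      seg <- outer(1 - frac, prev_u) + outer(frac, u_site)
      centers[filled + seq_len(m), ] <- seg
      filled <- filled + m
    }
    if (filled < nt) {
      m <- min(dwell_n(), nt - filled)
      drift <- matrix(rnorm(3L * m, sd = cfg$trajectory_step_mm /
                              mean(shell$semi_axes)), m, 3L)
      drift <- apply(drift, 2L, cumsum)
      centers[filled + seq_len(m), ] <-
        matrix(u_site, m, 3L, byrow = TRUE) + drift
      filled <- filled + m
    }
    prev_u <- u_site
  }
  center_path <- project_to_shell(
    sweep(sweep(centers, 2L, shell$semi_axes, "*"), 2L, shell$center, "+"),
    shell)

  # fixed electrode offsets around the catheter center, plus contact jitter
  nch <- cfg$n_channels
  dirs <- matrix(rnorm(3L * nch), nch, 3L)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  radii <- seq(2, 12, length.out = nch)
  chans <- sprintf("ch_%02d", seq_len(nch))

  out <- vector("list", nch)
  for (j in seq_len(nch)) {
    p <- center_path +
      matrix(dirs[j, ] * radii[j], nt, 3L, byrow = TRUE) +
      matrix(rnorm(3L * nt, sd = 0.2), nt, 3L)
    p <- project_to_shell(p, shell)
    out[[j]] <- data.frame(time_ms = t_ms, channel = chans[j],
                           x_mm = p[, 1], y_mm = p[, 2], z_mm = p[, 3],
                           stringsAsFactors = FALSE)
  }
  stream <- do.call(rbind, out)
  stream <- stream[order(stream$time_ms, stream$channel), , drop = FALSE]
  rownames(stream) <- NULL
  structure(stream, coord_fs = cfg$coord_fs, shell = shell,
            class = c("mapping_stream", "data.frame"))
}

biphasic_wavelet <- function() {
  half <- sin(pi * (0:9) / 9)
  c(half, -half) # ~20 ms at 1000 Hz, energy concentrated near 50 Hz
}

# add a short waveform into x at 1-based sample s, clipped to bounds
add_at <- function(x, s, w) {
  n <- length(x); m <- length(w)
  lo <- max(1L, s); hi <- min(n, s + m - 1L)
  if (lo > hi) return(x)
  x[lo:hi] <- x[lo:hi] + w[(lo - s + 1L):(hi - s + 1L)]
  x
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# event times (ms) of an activation train whose instantaneous rate follows
# rate_of(t) [Hz], with truncated multiplicative cycle jitter
pulse_train_times <- function(dur_ms, rate_of, jitter_frac) {
  t <- runif(1) * 1000 / rate_of(0)
  out <- numeric(0)
  while (t < dur_ms) {
    out <- c(out, t)
    eps <- if (jitter_frac > 0)
      clamp(rnorm(1, 0, jitter_frac), -3 * jitter_frac, 3 * jitter_frac)
    else 0
    t <- t + (1000 / rate_of(t)) * (1 + eps)
  }
  out
}

#' Simulate bipolar electrograms along a mapping trajectory
#'
#' Each channel receives a train of biphasic activation deflections whose
#' instantaneous inter-activation interval is the reciprocal of the true DF
#' at the electrode's current position, perturbed by multiplicative cycle
#' jitter. Additive Gaussian noise, sparse large artifacts (> 16 mV),
#' poor-contact dropout segments (scaled below 0.2 mV) and a mains sinusoid
#' are superimposed. A reference rhythm channel (`cs`) is appended for
#' fibrillation gating.
#'
#' @param cfg a [sim_config()].
#' @param stream a `mapping_stream` from [simulate_trajectory()].
#' @param field a [df_field()] sharing the cube's coordinate frame.
#' @return an `egm_recording`: list with `fs`, `channels`, `signals`
#'   (samples x channels matrix, mV), `ref_channel`, `t0`.
#' @export
simulate_egm <- function(cfg, stream, field) {
  stopifnot(inherits(cfg, "sim_config"), inherits(stream, "mapping_stream"),
            inherits(field, "df_field"))
  set.seed(cfg$seed + 1L)
  fs <- cfg$signal_fs
  dur_ms <- cfg$duration_s * 1000
  n <- round(cfg$duration_s * fs)
  coord_dt <- 1000 / cfg$coord_fs
  chans <- sort(unique(stream$channel))
  if (max(stream$time_ms) < dur_ms - coord_dt - 1e-9)
    stop("mapping stream is shorter than the configured duration")

  sig <- matrix(0, n, length(chans) + 1L,
                dimnames = list(NULL, c(chans, "cs")))
  t_s <- (seq_len(n) - 1L) / fs
  line <- cfg$powerline_amp * sin(2 * pi * cfg$powerline_hz * t_s)
  dur_min <- cfg$duration_s / 60

  for (ch in chans) {
    rows <- stream$channel == ch
    pos <- as.matrix(stream[rows, c("x_mm", "y_mm", "z_mm")])
    df_t <- sample_df_field(field, pos)
    nt <- nrow(pos)
    rate_of <- function(t_ms)
      df_t[min(nt, floor(t_ms / coord_dt) + 1L)]

    x <- numeric(n)
    wv <- biphasic_wavelet()
    for (ev in pulse_train_times(dur_ms, rate_of, cfg$cycle_jitter_frac)) {
      amp <- cfg$deflection_amp_mv * runif(1, 0.8, 1.2)
      x <- add_at(x, as.integer(round(ev)) + 1L, amp * wv)
    }
    if (cfg$noise_sd > 0) x <- x + rnorm(n, 0, cfg$noise_sd)

    for (k in seq_len(rpois(1, cfg$dropout_rate * dur_min))) {
      s <- sample.int(n, 1L)
      len <- as.integer(runif(1, 0.5, 2) * fs)
      hi <- min(n, s + len - 1L)
      x[s:hi] <- x[s:hi] * 0.05
    }
    art <- 20 * sin(pi * (0:29) / 29)
    for (k in seq_len(rpois(1, cfg$artifact_rate * dur_min))) {
      x <- add_at(x, sample.int(n, 1L), sample(c(-1, 1), 1L) * art)
    }
    sig[, ch] <- x + line
  }

  sig[, "cs"] <- simulate_reference_signal(cfg, n)
  structure(list(fs = fs, channels = colnames(sig), signals = sig,
                 ref_channel = "cs", t0 = 0),
            class = "egm_recording")
}

# reference (coronary-sinus-like) rhythm channel: regular rapid activations
# inside fibrillation spans, slow activations outside
simulate_reference_signal <- function(cfg, n) {
  fs <- cfg$signal_fs
  dur_ms <- cfg$duration_s * 1000
  spans <- cfg$af_spans
  if (is.null(spans)) spans <- list(c(0, cfg$duration_s))
  in_af <- function(t_ms) {
    for (sp in spans) if (t_ms >= sp[1] * 1000 && t_ms < sp[2] * 1000)
      return(TRUE)
    FALSE
  }
  rate_of <- function(t_ms)
    1000 / if (in_af(t_ms)) cfg$cs_cycle_ms else cfg$non_af_cycle_ms
  x <- numeric(n)
  wv <- 1.5 * biphasic_wavelet()
  for (ev in pulse_train_times(dur_ms, rate_of, 0.05)) {
    x <- add_at(x, as.integer(round(ev)) + 1L, wv)
  }
  x + rnorm(n, 0, 0.02)
}

#' Ground truth for a simulated dataset
#'
#' Evaluates the noiseless DF field at every coordinate sample and derives
#' the true HDF voxel mask with the same personalized rule the pipeline uses
#' (strictly above mean + 1 sample SD of per-voxel true DF). Per-voxel true
#' DF is the mean of the member points' true DF, so the stored mask is
#' recomputable from `df_at_point` alone. Only voxels observed at least
#' `min_points` times enter the truth: a voxel sampled once or twice is not
#' a candidate for a stability statistic, matching the aggregation module's
#' notion of an effective voxel unit.
#'
#' @param cfg a [sim_config()] (unused except for validation; kept so truth
#'   and data are generated from the same configuration).
#' @param stream a `mapping_stream`.
#' @param field the [df_field()] used to generate the electrograms.
#' @param grid optional [voxel_grid()]; defaults to the same
#'   data-derived 100 mm grid the pipeline builds at `voxel_size` mm.
#' @param voxel_size voxel edge length in mm when `grid` is `NULL`.
#' @param min_points minimum member points for a voxel to enter the truth.
#' @return a `ground_truth`: list with `df_at_point` (Hz, aligned to stream
#'   rows), `voxels` (data.frame `ix, iy, iz, n, df_true, hdf`),
#'   `threshold_hz`, `grid`, `field`.
#' @export
emit_ground_truth <- function(cfg, stream, field, grid = NULL,
                              voxel_size = 2, min_points = 3L) {
  stopifnot(inherits(stream, "mapping_stream"), inherits(field, "df_field"))
  pts <- as.matrix(stream[, c("x_mm", "y_mm", "z_mm")])
  df_at_point <- sample_df_field(field, pts)
  if (is.null(grid)) grid <- default_grid(pts, voxel_size = voxel_size)
  idx <- voxel_index(grid, pts)
  keep <- voxel_in_bounds(grid, idx)
  key <- voxel_key(idx[keep, , drop = FALSE])
  df_split <- split(df_at_point[keep], key)
  df_split <- df_split[order(names(df_split))]
  df_split <- df_split[vapply(df_split, length, integer(1)) >= min_points]
  if (!length(df_split)) stop("no voxel observed at least ", min_points,
                              " times")
  vox <- key_to_index(names(df_split))
  df_true <- vapply(df_split, mean, numeric(1))
  nper <- vapply(df_split, length, integer(1))
  thr <- if (length(df_true) >= 2L) mean(df_true) + sd(df_true) else Inf
  voxels <- data.frame(vox, n = as.integer(nper), df_true = df_true,
                       hdf = df_true > thr, row.names = NULL)
  structure(list(df_at_point = df_at_point, voxels = voxels,
                 threshold_hz = thr, grid = grid, field = field),
            class = "ground_truth")
}

#' Simulate a complete sequential-mapping dataset
#'
#' Convenience wrapper running [simulate_trajectory()], [simulate_egm()] and
#' [emit_ground_truth()] with one configuration. The result is bit-identical
#' for identical configurations (including the seed).
#'
#' @param cfg a [sim_config()].
#' @param field a [df_field()].
#' @param shell a [shell_spec()].
#' @return an `hdf_dataset`: list with `recording`, `stream`, `truth`,
#'   `field`, `shell`, `config`.
#' @export
#' @examples
#' ds <- simulate_dataset(sim_config(seed = 7, duration_s = 6, n_channels = 2))
#' str(ds$stream[1:3, ])
simulate_dataset <- function(cfg = sim_config(), field = df_field(),
                             shell = shell_spec()) {
  stream <- simulate_trajectory(cfg, shell)
  recording <- simulate_egm(cfg, stream, field)
  truth <- emit_ground_truth(cfg, stream, field)
  structure(list(recording = recording, stream = stream, truth = truth,
                 field = field, shell = shell, config = cfg),
            class = "hdf_dataset")
}
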