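# Per-point dominant-frequency estimation: Botteron preprocessing, Welch
# power spectral density, DF peak picking in the physiological band, and the
# Organization Index significance gate.

#' Spectral analysis configuration
#'
#' All tunable parameters of the per-point DF estimator. Defaults are the
#' published operating point: a 2-s analysis window, 40-250 Hz bandpass /
#' rectification / 20 Hz low-pass preprocessing, Welch estimation with
#' Hamming windows, 50% overlap and a 0.05 Hz frequency step, DF search in
#' 4-10 Hz, and an Organization Index over 0-20 Hz with a 0.375 Hz band
#' half-width and a 0.2 acceptance threshold.
#'
#' @param window_s analysis window length, s.
#' @param band_lo,band_hi bandpass edges, Hz.
#' @param env_lp envelope low-pass cutoff, Hz.
#' @param df_lo,df_hi DF search band, Hz.
#' @param freq_step spectral grid step, Hz (finer than the intrinsic window
#'   resolution; realized by zero-padded transforms).
#' @param seg_s Welch segment length, s.
#' @param overlap Welch segment overlap fraction in (0, 1).
#' @param oi_k half-width of the DF/harmonic integration bands, Hz.
#' @param oi_wl,oi_wh total-power integration range, Hz.
#' @param oi_threshold minimum OI for a DF to count as significant.
#' @param harmonic_search_hz half-width of the window in which each harmonic
#'   peak is located around integer multiples of the DF, Hz.
#' @param spec_max_hz upper frequency retained in returned spectra, Hz.
#' @param amp_lo,amp_hi window amplitude usability bounds, mV.
#' @param line_hz,line_frac mains frequency and maximum tolerated fraction
#'   of window energy near it.
#' @return an object of class `spectral_config`.
#' @export
spectral_config <- function(window_s = 2, band_lo = 40, band_hi = 250,
                            env_lp = 20, df_lo = 4, df_hi = 10,
                            freq_step = 0.05, seg_s = 1, overlap = 0.5,
                            oi_k = 0.375, oi_wl = 0, oi_wh = 20,
                            oi_threshold = 0.2, harmonic_search_hz = 0.5,
                            spec_max_hz = 30, amp_lo = 0.2, amp_hi = 16,
                            line_hz = 50, line_frac = 0.5) {
  cfg <- list(window_s = window_s, band_lo = band_lo, band_hi = band_hi,
              env_lp = env_lp, df_lo = df_lo, df_hi = df_hi,
              freq_step = freq_step, seg_s = seg_s, overlap = overlap,
              oi_k = oi_k, oi_wl = oi_wl, oi_wh = oi_wh,
              oi_threshold = oi_threshold,
              harmonic_search_hz = harmonic_search_hz,
              spec_max_hz = spec_max_hz, amp_lo = amp_lo, amp_hi = amp_hi,
              line_hz = line_hz, line_frac = line_frac)
  stopifnot(cfg$df_lo >= cfg$oi_wl, cfg$df_hi <= cfg$oi_wh,
            cfg$overlap > 0, cfg$overlap < 1, cfg$freq_step > 0,
            cfg$band_lo < cfg$band_hi, cfg$env_lp > 0,
            cfg$spec_max_hz >= cfg$oi_wh, cfg$window_s > 0,
            cfg$seg_s <= cfg$window_s)
  structure(cfg, class = "spectral_config")
}

.spectral_cache <- new.env(parent = emptyenv())

botteron_filters <- function(fs, cfg) {
  key <- paste("flt", fs, cfg$band_lo, cfg$band_hi, cfg$env_lp, sep = "|")
  got <- .spectral_cache[[key]]
  if (!is.null(got)) return(got)
  if (fs < 2 * cfg$band_hi)
    stop("sampling rate ", fs, " Hz too low for a ", cfg$band_hi,
         " Hz bandpass edge")
  ny <- fs / 2
  val <- list(bp = butter(4, c(cfg$band_lo, cfg$band_hi) / ny, type = "pass"),
              lp = butter(4, cfg$env_lp / ny, type = "low"))
  assign(key, val, envir = .spectral_cache)
  val
}

#' Botteron activation-envelope preprocessing
#'
#' Classic three-step envelope extraction for fibrillatory electrograms:
#' zero-phase 4th-order Butterworth bandpass (40-250 Hz), full-wave
#' rectification, then zero-phase 4th-order Butterworth low-pass (20 Hz).
#' The output is a low-frequency envelope whose fundamental tracks the local
#' activation rate.
#'
#' @param window numeric signal window, mV, of length `window_s * fs`.
#' @param fs sampling rate, Hz (must exceed twice the bandpass upper edge).
#' @param cfg a [spectral_config()].
#' @return numeric envelope, same length as the input.
#' @export
botteron_filter <- function(window, fs, cfg = spectral_config()) {
  if (length(window) != round(cfg$window_s * fs))
    stop("window must be ", cfg$window_s, " s at ", fs, " Hz")
  flt <- botteron_filters(fs, cfg)
  env <- filtfilt(flt$lp, abs(filtfilt(flt$bp, window)))
  as.numeric(env)
}

welch_plan <- function(fs, cfg) {
  key <- paste("welch", fs, cfg$seg_s, cfg$overlap, cfg$freq_step,
               cfg$spec_max_hz, sep = "|")
  got <- .spectral_cache[[key]]
  if (!is.null(got)) return(got)
  nseg <- round(cfg$seg_s * fs)
  hop <- round(nseg * (1 - cfg$overlap))
  nfft <- round(fs / cfg$freq_step)
  nbins <- floor(cfg$spec_max_hz / cfg$freq_step) + 1L
  val <- list(nseg = nseg, hop = hop, nfft = nfft, nbins = nbins,
              win = as.numeric(hamming(nseg)),
              freq = (seq_len(nbins) - 1L) * cfg$freq_step)
  assign(key, val, envir = .spectral_cache)
  val
}

#' Welch power spectral density of an activation envelope
#'
#' Averaged modified periodogram: the window is cut into `seg_s`-long
#' segments with `overlap` fractional overlap, each segment is mean-removed,
#' Hamming-windowed and zero-padded so the spectral grid has `freq_step`
#' spacing, and the squared transforms are averaged.
#'
#' @param envelope numeric series of length `window_s * fs`.
#' @param fs sampling rate, Hz.
#' @param cfg a [spectral_config()].
#' @return a `power_spectrum`: list with `freq` (Hz, uniform grid from 0 to
#'   `spec_max_hz`) and `power` (nonnegative, one-sided density).
#' @export
welch_psd <- function(envelope, fs, cfg = spectral_config()) {
  if (length(envelope) != round(cfg$window_s * fs))
    stop("envelope must be ", cfg$window_s, " s at ", fs, " Hz")
  pl <- welch_plan(fs, cfg)
  starts <- seq.int(1L, length(envelope) - pl$nseg + 1L, by = pl$hop)
  segs <- matrix(0, pl$nfft, length(starts))
  for (j in seq_along(starts)) {
    s <- envelope[starts[j]:(starts[j] + pl$nseg - 1L)]
    segs[seq_len(pl$nseg), j] <- (s - mean(s)) * pl$win
  }
  sp <- mvfft(segs)[seq_len(pl$nbins), , drop = FALSE]
  p <- rowMeans(Mod(sp)^2) / (fs * sum(pl$win^2))
  p[-1L] <- 2 * p[-1L] # one-sided below Nyquist
  structure(list(freq = pl$freq, power = p), class = "power_spectrum")
}

#' Pick the dominant frequency from a power spectrum
#'
#' The DF is the frequency of the maximum power on the spectral grid
#' restricted to the physiological band (`df_lo` to `df_hi`). Ties break to
#' the lowest frequency, which avoids capture by harmonics.
#'
#' @param spec a `power_spectrum`.
#' @param cfg a [spectral_config()].
#' @return DF in Hz, or `NA_real_` when the band carries no power.
#' @export
pick_df <- function(spec, cfg = spectral_config()) {
  eps <- 1e-9
  band <- spec$freq >= cfg$df_lo - eps & spec$freq <= cfg$df_hi + eps
  if (!any(band)) stop("spectrum does not cover the DF band")
  p <- spec$power[band]
  if (max(p) <= 0) return(NA_real_)
  spec$freq[band][which.max(p)]
}

# indices of the numerator bands (DF +/- k plus harmonic bands), unioned
oi_band_mask <- function(spec, df_hz, cfg) {
  eps <- 1e-9
  mask <- abs(spec$freq - df_hz) <= cfg$oi_k + eps
  m <- 2L
  while (m * df_hz <= cfg$oi_wh + eps) {
    center <- m * df_hz
    w <- which(abs(spec$freq - center) <= cfg$harmonic_search_hz + eps)
    h <- center
    if (length(w)) {
      # argmax within the window; on plateaus take the bin closest to the
      # exact multiple so a symmetric peak keeps a centered band
      cand <- w[spec$power[w] >= max(spec$power[w])]
      j <- cand[which.min(abs(spec$freq[cand] - center))]
      pl <- if (j > 1L) spec$power[j - 1L] else -Inf
      pr <- if (j < length(spec$power)) spec$power[j + 1L] else -Inf
      if (spec$power[j] >= pl && spec$power[j] >= pr) h <- spec$freq[j]
    }
    mask <- mask | abs(spec$freq - h) <= cfg$oi_k + eps
    m <- m + 1L
  }
  mask
}

#' Organization Index of a DF peak
#'
#' Ratio of the spectral power inside narrow bands around the DF and its
#' harmonics to the total power in the 0-20 Hz range. Harmonic band centers
#' are the local spectral maxima within +/- `harmonic_search_hz` of integer
#' multiples of the DF (on plateaus, the maximal bin closest to the exact
#' multiple; falling back to the exact multiple when no local maximum
#' exists); overlapping bands are unioned before summation so power is
#' never double-counted.
#'
#' @param spec a `power_spectrum` covering at least `oi_wl` to `oi_wh`.
#' @param df_hz the dominant frequency, Hz (inside the DF band).
#' @param cfg a [spectral_config()].
#' @return OI in `[0, 1]`, or `NA_real_` when the 0-20 Hz power is zero.
#' @export
organization_index <- function(spec, df_hz, cfg = spectral_config()) {
  eps <- 1e-9
  stopifnot(df_hz >= cfg$df_lo - eps, df_hz <= cfg$df_hi + eps)
  if (max(spec$freq) < cfg$oi_wh - eps)
    stop("spectrum does not cover the OI range")
  den_mask <- spec$freq >= cfg$oi_wl - eps & spec$freq <= cfg$oi_wh + eps
  den <- sum(spec$power[den_mask])
  if (den <= 0) return(NA_real_)
  num <- sum(spec$power[oi_band_mask(spec, df_hz, cfg) & den_mask])
  num / den
}

#' DF and OI of the electrogram window at one mapping point
#'
#' Extracts the 2-s window centered on the mapping time, screens it with the
#' quality rules (and, when supplied, the fibrillation gate), runs the
#' Botteron/Welch/DF-pick/OI chain, and reports a validity verdict. A point
#' is valid only when the window passes quality screening, a DF exists, and
#' its OI reaches `oi_threshold`.
#'
#' @param recording an `egm_recording`.
#' @param channel channel id present in the recording.
#' @param time_ms mapping time, ms from recording start (at least half a
#'   window from both ends).
#' @param position length-3 numeric position in mm (carried through).
#' @param cfg a [spectral_config()].
#' @param af_periods optional `af_periods`; windows not fully inside a
#'   fibrillation interval are rejected with reason `non_af`.
#' @return one-row data.frame with `channel`, `time_ms`, `x_mm`, `y_mm`,
#'   `z_mm`, `df_hz`, `oi`, `valid`, `reason`.
#' @export
compute_df_point <- function(recording, channel, time_ms,
                             position = c(NA_real_, NA_real_, NA_real_),
                             cfg = spectral_config(), af_periods = NULL) {
  stopifnot(inherits(recording, "egm_recording"))
  if (!channel %in% recording$channels) stop("unknown channel: ", channel)
  res <- df_point_core(recording$signals[, channel], recording$fs,
                       time_ms, cfg, af_periods)
  data.frame(channel = channel, time_ms = time_ms,
             x_mm = position[1], y_mm = position[2], z_mm = position[3],
             df_hz = res$df_hz, oi = res$oi, valid = res$valid,
             reason = res$reason, stringsAsFactors = FALSE)
}

# core of compute_df_point on a raw signal vector (hot path)
df_point_core <- function(sig, fs, time_ms, cfg, af_periods) {
  bad <- function(reason) list(df_hz = NA_real_, oi = NA_real_,
                               valid = FALSE, reason = reason)
  n_win <- round(cfg$window_s * fs)
  half <- n_win %/% 2L
  c0 <- as.integer(round(time_ms * fs / 1000)) + 1L
  lo <- c0 - half + 1L
  hi <- lo + n_win - 1L
  if (lo < 1L || hi > length(sig)) return(bad("bounds"))
  half_ms <- cfg$window_s / 2 * 1000
  if (!is.null(af_periods) &&
      !window_in_af(af_periods, time_ms - half_ms, time_ms + half_ms))
    return(bad("non_af"))
  win <- sig[lo:hi]
  q <- apply_quality_filters(win, fs, cfg$window_s, cfg$amp_lo, cfg$amp_hi,
                             cfg$line_hz, cfg$line_frac)
  if (!q$valid) return(bad(q$reason))
  env <- botteron_filter(win, fs, cfg)
  spec <- welch_psd(env, fs, cfg)
  df <- pick_df(spec, cfg)
  if (is.na(df)) return(bad("no_df"))
  oi <- organization_index(spec, df, cfg)
  if (is.na(oi)) return(bad("no_df"))
  if (oi < cfg$oi_threshold)
    return(list(df_hz = df, oi = oi, valid = FALSE, reason = "low_oi"))
  list(df_hz = df, oi = oi, valid = TRUE, reason = NA_character_)
}

#' DF/OI for a set of mapping points
#'
#' Vectorized driver over [compute_df_point()] for rows of a mapping stream.
#'
#' @param recording an `egm_recording`.
#' @param coords data.frame with columns `channel`, `time_ms`, `x_mm`,
#'   `y_mm`, `z_mm` (e.g. a subset of a `mapping_stream`).
#' @param cfg a [spectral_config()].
#' @param af_periods optional `af_periods` gate.
#' @param cache optional environment; results are memoized under
#'   `"<channel>|<time_ms>"` keys so repeated analyses of the same recording
#'   (e.g. across voxel sizes) reuse per-point spectra verdicts.
#' @return a `df_points` data.frame, one row per input point.
#' @export
compute_df_points <- function(recording, coords, cfg = spectral_config(),
                              af_periods = NULL, cache = NULL) {
  stopifnot(inherits(recording, "egm_recording"),
            all(c("channel", "time_ms", "x_mm", "y_mm", "z_mm") %in%
                  names(coords)))
  unknown <- setdiff(unique(coords$channel), recording$channels)
  if (length(unknown))
    stop("coords reference unknown channel(s): ",
         paste(unknown, collapse = ", "))
  n <- nrow(coords)
  df_hz <- oi <- rep(NA_real_, n)
  valid <- logical(n)
  reason <- rep(NA_character_, n)
  fs <- recording$fs
  for (ch in unique(coords$channel)) {
    sig <- recording$signals[, ch]
    for (i in which(coords$channel == ch)) {
      key <- if (is.null(cache)) NULL else
        paste(ch, coords$time_ms[i], sep = "|")
      res <- if (!is.null(key) && !is.null(cache[[key]])) cache[[key]] else
        df_point_core(sig, fs, coords$time_ms[i], cfg, af_periods)
      if (!is.null(key)) cache[[key]] <- res
      df_hz[i] <- res$df_hz; oi[i] <- res$oi
      valid[i] <- res$valid; reason[i] <- res$reason
    }
  }
  structure(data.frame(channel = coords$channel, time_ms = coords$time_ms,
                       x_mm = coords$x_mm, y_mm = coords$y_mm,
                       z_mm = coords$z_mm, df_hz = df_hz, oi = oi,
                       valid = valid, reason = reason,
                       stringsAsFactors = FALSE),
            class = c("df_points", "data.frame"))
}
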