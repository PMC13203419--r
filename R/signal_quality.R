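# Fibrillation gating from the reference channel and per-window quality
# screening of the mapping electrograms.

#' Detect activation peaks in a bipolar electrogram
#'
#' Rectifies the signal, estimates a local amplitude scale with a moving RMS,
#' and picks local maxima exceeding `threshold_factor` times that scale,
#' enforcing a refractory period. Peaks are accepted in decreasing amplitude
#' order so that, within a refractory conflict, the larger deflection wins.
#'
#' @param x numeric signal in mV.
#' @param fs sampling rate, Hz.
#' @param min_refractory_ms minimum spacing between detections, ms.
#' @param threshold_factor multiple of the moving-RMS scale a peak must
#'   exceed.
#' @param rms_window_s moving-RMS window length, s.
#' @return strictly increasing activation times in ms from signal start
#'   (empty for flat or too-short signals).
#' @export
detect_activations <- function(x, fs, min_refractory_ms = 100,
                               threshold_factor = 3, rms_window_s = 2) {
  n <- length(x)
  if (n < 2 * fs) return(numeric(0))
  r <- abs(x)
  w <- min(n, as.integer(rms_window_s * fs))
  ms2 <- stats::filter(r^2, rep(1 / w, w), sides = 2)
  ms2 <- as.numeric(ms2)
  # extend the moving average to the edges
  ok <- which(!is.na(ms2))
  if (!length(ok)) return(numeric(0))
  ms2[seq_len(ok[1] - 1L)] <- ms2[ok[1]]
  ms2[seq.int(ok[length(ok)] + 1L, length.out = n - ok[length(ok)])] <-
    ms2[ok[length(ok)]]
  thr <- threshold_factor * sqrt(ms2)

  i <- 2:(n - 1L)
  cand <- i[r[i] >= r[i - 1L] & r[i] > r[i + 1L] & r[i] > thr[i]]
  if (!length(cand)) return(numeric(0))
  cand <- cand[order(r[cand], decreasing = TRUE)]
  refr <- min_refractory_ms / 1000 * fs
  keep <- logical(0)
  acc <- numeric(0)
  for (s in cand) {
    if (!length(acc) || all(abs(acc - s) >= refr)) acc <- c(acc, s)
  }
  sort(acc - 1) / fs * 1000
}

#' Locate fibrillation periods from activation times
#'
#' Flags cycles whose running-median cycle length falls below `cl_max_ms`
#' and merges maximal runs of such cycles into intervals, keeping those at
#' least `min_duration_ms` long.
#'
#' @param activations sorted activation times in ms.
#' @param cl_max_ms cycle-length ceiling for fibrillation, ms.
#' @param min_duration_ms minimum interval duration, ms.
#' @param median_k running-median window (cycles, odd).
#' @return an `af_periods` data.frame with half-open columns
#'   `start_ms`, `end_ms` (disjoint, sorted).
#' @export
locate_af_periods <- function(activations, cl_max_ms = 250,
                              min_duration_ms = 5000, median_k = 9) {
  empty <- structure(data.frame(start_ms = numeric(0), end_ms = numeric(0)),
                     class = c("af_periods", "data.frame"))
  if (length(activations) < 3L) return(empty)
  if (is.unsorted(activations)) stop("activations must be sorted")
  cl <- diff(activations)
  k <- min(median_k, length(cl))
  if (k %% 2L == 0L) k <- k - 1L
  med <- if (k >= 3L) runmed(cl, k) else cl
  ok <- med < cl_max_ms
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (j in seq_along(runs$values)) {
    if (!runs$values[j]) next
    s <- activations[starts[j]]
    e <- activations[ends[j] + 1L]
    if (e - s >= min_duration_ms) out[[length(out) + 1L]] <- c(s, e)
  }
  if (!length(out)) return(empty)
  m <- do.call(rbind, out)
  structure(data.frame(start_ms = m[, 1], end_ms = m[, 2]),
            class = c("af_periods", "data.frame"))
}

# is the closed interval [lo, hi] (ms) fully inside some fibrillation period?
window_in_af <- function(periods, lo, hi) {
  if (is.null(periods)) return(rep(TRUE, length(lo)))
  res <- logical(length(lo))
  for (j in seq_len(nrow(periods))) {
    res <- res | (lo >= periods$start_ms[j] & hi <= periods$end_ms[j])
  }
  res
}

#' Per-window signal quality screening
#'
#' Applies the amplitude and power-line usability rules to one 2-s analysis
#' window: reject as `low_amp` when the peak absolute amplitude is below
#' 0.2 mV (poor contact), as `artifact` when it exceeds 16 mV, and as
#' `powerline` when the spectral energy within +/- 1 Hz of the mains
#' frequency exceeds `line_frac` of the total 0 to fs/2 energy.
#'
#' @param window numeric signal window, mV.
#' @param fs sampling rate, Hz.
#' @param window_s required window length, s.
#' @param amp_lo,amp_hi amplitude bounds, mV.
#' @param line_hz mains frequency, Hz.
#' @param line_frac maximum tolerated fraction of energy near `line_hz`.
#' @return list with `valid` (logical) and `reason`
#'   (`NA`, `"low_amp"`, `"artifact"` or `"powerline"`). Idempotent: the
#'   verdict depends only on the window content.
#' @export
apply_quality_filters <- function(window, fs = 1000, window_s = 2,
                                  amp_lo = 0.2, amp_hi = 16,
                                  line_hz = 50, line_frac = 0.5) {
  if (length(window) != round(window_s * fs))
    stop("window must be ", window_s, " s at ", fs, " Hz")
  peak <- max(abs(window))
  if (peak < amp_lo) return(list(valid = FALSE, reason = "low_amp"))
  if (peak > amp_hi) return(list(valid = FALSE, reason = "artifact"))
  n <- length(window)
  p <- Mod(fft(window - mean(window)))^2
  nb <- n %/% 2L + 1L
  p <- p[seq_len(nb)]
  freqs <- (seq_len(nb) - 1L) * fs / n
  tot <- sum(p)
  if (tot > 0) {
    e_line <- sum(p[abs(freqs - line_hz) <= 1])
    if (e_line > line_frac * tot)
      return(list(valid = FALSE, reason = "powerline"))
  }
  list(valid = TRUE, reason = NA_character_)
}
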