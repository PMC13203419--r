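# OI-threshold sensitivity analysis: precision / recall / F1 over a grid of
# candidate thresholds against a table of labeled segments.

#' Confusion counts at one OI threshold
#'
#' A segment is predicted positive when its OI is greater than or equal to
#' the threshold (consistent with the pipeline's "OI below threshold is
#' filtered out" gate).
#'
#' @param segments data.frame with columns `oi` (in `[0, 1]`) and `label`
#'   (logical or 0/1; `TRUE` = significant DF).
#' @param threshold OI threshold.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#'   Degenerate 0/0 ratios are defined as 0.
#' @export
confusion_at <- function(segments, threshold) {
  stopifnot(nrow(segments) > 0L, all(segments$oi >= 0 & segments$oi <= 1))
  lab <- as.logical(segments$label)
  pred <- segments$oi >= threshold
  tp <- sum(pred & lab)
  fp <- sum(pred & !lab)
  fn <- sum(!pred & lab)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall /
    (precision + recall) else 0
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1)
}

#' F1 sweep over OI thresholds
#'
#' Evaluates precision, recall and F1 on a grid of thresholds from 0 to 1
#' and reports the F1-maximizing threshold (lowest threshold on ties).
#'
#' @param segments labeled segment table (see [confusion_at()]); both
#'   classes must be present.
#' @param step threshold grid spacing.
#' @return an `oi_sweep`: data.frame with one row per threshold
#'   (`threshold, tp, fp, fn, precision, recall, f1`) and attributes
#'   `best_threshold`, `best_f1`.
#' @export
sweep_f1 <- function(segments, step = 0.05) {
  lab <- as.logical(segments$label)
  if (all(lab) || !any(lab))
    stop("both positive and negative segments are required; F1 is ",
         "degenerate on a single class")
  thr <- seq(0, 1, by = step)
  rows <- lapply(thr, function(t) as.data.frame(confusion_at(segments, t)))
  out <- cbind(threshold = thr, do.call(rbind, rows))
  best <- which.max(out$f1) # which.max takes the first (lowest) maximum
  structure(out, best_threshold = thr[best], best_f1 = out$f1[best],
            class = c("oi_sweep", "data.frame"))
}

#' Synthetic labeled OI segments
#'
#' Mixture emulating a manually labeled segment table: negative
#' (non-significant DF) segments draw OI uniformly-shaped below a generative
#' boundary, positive segments concentrate above it, and a small fraction of
#' labels is flipped to mimic annotation noise. The F1-optimal threshold of
#' the generative process is the boundary itself.
#'
#' @param n number of segments.
#' @param boundary generative OI boundary separating the classes.
#' @param flip fraction of segments whose label is flipped.
#' @param prop_positive fraction of positive segments.
#' @return data.frame with columns `oi` and `label`.
#' @export
simulate_oi_segments <- function(n = 600L, boundary = 0.2, flip = 0.05,
                                 prop_positive = 0.5) {
  stopifnot(n >= 2L, boundary > 0, boundary < 1, flip >= 0, flip < 0.5)
  n_pos <- round(n * prop_positive)
  n_neg <- n - n_pos
  draw_neg <- function(m) boundary * rbeta(m, 1.2, 1.2)
  draw_pos <- function(m) boundary + (1 - boundary) * rbeta(m, 1.2, 3)
  oi <- c(draw_pos(n_pos), draw_neg(n_neg))
  label <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
  swap <- runif(n) < flip
  oi[swap] <- ifelse(label[swap], draw_neg(sum(swap)),
                     draw_pos(sum(swap)))[seq_len(sum(swap))]
  data.frame(oi = oi, label = label)
}
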