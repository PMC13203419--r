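# Personalized thresholding of the smoothed DF model and binary HDF
# labeling.

#' Personalized HDF threshold
#'
#' The HDF cutoff is tied to the patient's own DF distribution: the mean of
#' the (smoothed) voxel DF values plus `sd_mult` standard deviations.
#'
#' @param df numeric voxel DF values (at least 2).
#' @param sd_mult multiplier on the standard deviation.
#' @param sd_type `"sample"` (n - 1 denominator, default) or
#'   `"population"`.
#' @return the threshold in Hz.
#' @export
#' @examples
#' personalized_threshold(c(6, 6, 6, 9)) # 6.75 + 1.5 = 8.25
personalized_threshold <- function(df, sd_mult = 1, sd_type = "sample") {
  df <- df[!is.na(df)]
  if (length(df) < 2L)
    stop("at least 2 voxel DF values are needed to form a threshold")
  s <- sd(df)
  if (identical(sd_type, "population"))
    s <- s * sqrt((length(df) - 1) / length(df))
  mean(df) + sd_mult * s
}

#' Binary HDF labeling of the voxel model
#'
#' Labels a voxel 1 when its smoothed DF lies strictly above the threshold
#' ("higher than" is read strictly: a voxel exactly at the threshold is 0).
#'
#' @param model a `voxel_model`, normally after [smooth_model()]. When the
#'   `df_smoothed` column is absent the raw trimmed-mean DF is used.
#' @param threshold_hz threshold in Hz; defaults to
#'   [personalized_threshold()] of the model's DF values.
#' @param sd_mult,sd_type forwarded to [personalized_threshold()].
#' @return an `hdf_result`: list with `threshold_hz`, `labels` (0/1 per
#'   model row), `hdf_voxels` (the labeled rows), and a `summary` list
#'   (count, fraction, mean DF inside/outside).
#' @export
label_hdf <- function(model, threshold_hz = NULL, sd_mult = 1,
                      sd_type = "sample") {
  stopifnot(inherits(model, "voxel_model"))
  df <- if ("df_smoothed" %in% names(model)) model$df_smoothed else
    model$df_raw
  if (is.null(threshold_hz))
    threshold_hz <- personalized_threshold(df, sd_mult, sd_type)
  stopifnot(is.finite(threshold_hz))
  labels <- as.integer(df > threshold_hz)
  inside <- labels == 1L
  summary <- list(n_hdf = sum(inside),
                  fraction = mean(inside),
                  mean_df_hdf = if (any(inside)) mean(df[inside]) else
                    NA_real_,
                  mean_df_rest = if (any(!inside)) mean(df[!inside]) else
                    NA_real_)
  structure(list(threshold_hz = threshold_hz, labels = labels,
                 hdf_voxels = model[inside, , drop = FALSE],
                 summary = summary),
            class = "hdf_result")
}

#' Group HDF voxels into 26-connected components
#'
#' Convenience reporting extension (the labeling itself is per voxel):
#' groups labeled voxels whose integer indices differ by at most 1 on every
#' axis.
#'
#' @param hdf_voxels data.frame with `ix, iy, iz` columns.
#' @return integer component id per row (ordered by decreasing component
#'   size).
#' @export
hdf_components <- function(hdf_voxels) {
  n <- nrow(hdf_voxels)
  if (!n) return(integer(0))
  key <- voxel_key(as.matrix(hdf_voxels[, c("ix", "iy", "iz")]))
  lookup <- setNames(seq_len(n), key)
  comp <- integer(n)
  cur <- 0L
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0L) > 0L, , drop = FALSE]
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nbr <- cbind(hdf_voxels$ix[v] + offs[, 1],
                   hdf_voxels$iy[v] + offs[, 2],
                   hdf_voxels$iz[v] + offs[, 3])
      nbr <- nbr[nbr[, 1] >= 0L & nbr[, 2] >= 0L & nbr[, 3] >= 0L, ,
                 drop = FALSE]
      hit <- lookup[voxel_key(nbr)]
      hit <- hit[!is.na(hit)]
      new <- hit[comp[hit] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  # relabel by decreasing size
  sizes <- table(comp)
  rank <- setNames(seq_along(sizes), names(sort(sizes, decreasing = TRUE)))
  as.integer(rank[as.character(comp)])
}

#' Overlap between a predicted and a reference voxel set
#'
#' Dice coefficient, recall and precision between two sets of voxel indices.
#'
#' @param pred,truth data.frames with `ix, iy, iz` columns.
#' @return list with `dice`, `recall`, `precision`, and the set sizes.
#' @export
mask_overlap <- function(pred, truth) {
  a <- voxel_key(as.matrix(pred[, c("ix", "iy", "iz")]))
  b <- voxel_key(as.matrix(truth[, c("ix", "iy", "iz")]))
  inter <- length(intersect(a, b))
  list(dice = if (length(a) + length(b) > 0)
    2 * inter / (length(a) + length(b)) else NA_real_,
    recall = if (length(b)) inter / length(b) else NA_real_,
    precision = if (length(a)) inter / length(a) else NA_real_,
    n_pred = length(a), n_truth = length(b), n_common = inter)
}
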