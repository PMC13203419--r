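# Voxel-level spatial aggregation: a 100 mm cubic grid of small voxel units,
# time-domain sparse sampling of each voxel's mapping points, and the
# trimmed-mean DF statistic per voxel.

#' Voxel grid over the mapping volume
#'
#' Axis-aligned cubic grid. Cells are half-open `[lo, hi)` so every in-bounds
#' point belongs to exactly one voxel; a point on a shared face goes to the
#' higher-index cell.
#'
#' @param origin length-3 numeric, minimum corner in mm.
#' @param voxel_size voxel edge length, mm.
#' @param extent_mm cube side length, mm. When not divisible by
#'   `voxel_size`, the grid covers the next whole number of cells
#'   (`ceiling(extent_mm / voxel_size)` per axis), so the working volume is
#'   never smaller than requested.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(origin = c(0, 0, 0), voxel_size = 2, extent_mm = 100) {
  stopifnot(length(origin) == 3L, voxel_size > 0, extent_mm > 0)
  ncell <- as.integer(ceiling(extent_mm / voxel_size - 1e-9))
  structure(list(origin = as.numeric(origin), voxel_size = voxel_size,
                 extent_mm = extent_mm, n_cells = ncell),
            class = "voxel_grid")
}

#' Data-derived default grid
#'
#' Centers the bounding box of the mapped points and expands it symmetrically
#' to a cube of `extent_mm` per side, mirroring the fixed 100 mm working
#' volume with a placement driven by the data.
#'
#' @param points n x 3 matrix (or data.frame with `x_mm`, `y_mm`, `z_mm`).
#' @param voxel_size voxel edge length, mm.
#' @param extent_mm cube side length, mm.
#' @return a [voxel_grid()].
#' @export
default_grid <- function(points, voxel_size = 2, extent_mm = 100) {
  p <- as_xyz_matrix(points)
  ctr <- (apply(p, 2L, min) + apply(p, 2L, max)) / 2
  voxel_grid(origin = ctr - extent_mm / 2, voxel_size = voxel_size,
             extent_mm = extent_mm)
}

as_xyz_matrix <- function(points) {
  if (is.matrix(points)) return(points)
  as.matrix(points[, c("x_mm", "y_mm", "z_mm")])
}

# 0-based integer voxel addresses, n x 3
voxel_index <- function(grid, points) {
  p <- as_xyz_matrix(points)
  idx <- floor(sweep(p, 2L, grid$origin) / grid$voxel_size)
  storage.mode(idx) <- "integer"
  colnames(idx) <- c("ix", "iy", "iz")
  idx
}

voxel_in_bounds <- function(grid, idx) {
  rowSums(idx >= 0L & idx < grid$n_cells) == 3L
}

# sortable string key; zero-padded so lexicographic order == index order
voxel_key <- function(idx) {
  sprintf("%04d_%04d_%04d", idx[, 1], idx[, 2], idx[, 3])
}

key_to_index <- function(keys) {
  m <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
  data.frame(ix = as.integer(m[, 1]), iy = as.integer(m[, 2]),
             iz = as.integer(m[, 3]))
}

voxel_centroid <- function(grid, idx) {
  sweep((as.matrix(idx) + 0.5) * grid$voxel_size, 2L, grid$origin, "+")
}

#' Assign mapping points to voxel units
#'
#' Partitions in-bounds points over the grid (half-open cells). Out-of-bounds
#' points are dropped; their count is attached as attribute `n_dropped`.
#'
#' @param points data.frame with `x_mm`, `y_mm`, `z_mm` columns.
#' @param grid a [voxel_grid()].
#' @return the input rows restricted to the cube, with integer columns
#'   `ix`, `iy`, `iz` appended.
#' @export
assign_to_voxels <- function(points, grid) {
  idx <- voxel_index(grid, points)
  keep <- voxel_in_bounds(grid, idx)
  out <- cbind(points[keep, , drop = FALSE],
               as.data.frame(idx[keep, , drop = FALSE]))
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Sparse-sampling ranks by BST breadth-first traversal
#'
#' Builds (implicitly) a balanced binary search tree over the ranks
#' `1..n` by recursive midpoint splitting (lower middle on even splits),
#' traverses it breadth-first (left child before right), and returns the
#' visited ranks until the queue holds `queue_len` entries or the tree is
#' exhausted. The result is an approximately equally spaced, deterministic
#' subsample of the rank sequence that always spans its extremes at the
#' deepest retained level.
#'
#' @param n number of time-ordered points.
#' @param queue_len maximum number of sampled ranks.
#' @return integer vector of 1-based ranks in visit order, of length
#'   `min(n, queue_len)`.
#' @export
sparse_sample_ranks <- function(n, queue_len = 31L) {
  n <- as.integer(n)
  stopifnot(n >= 0L, queue_len >= 1L)
  if (n == 0L) return(integer(0))
  qlo <- integer(n); qhi <- integer(n)
  qlo[1L] <- 1L; qhi[1L] <- n
  head <- 1L; tail <- 1L
  out <- integer(min(n, queue_len)); got <- 0L
  while (head <= tail && got < queue_len) {
    lo <- qlo[head]; hi <- qhi[head]; head <- head + 1L
    mid <- (lo + hi) %/% 2L
    got <- got + 1L
    out[got] <- mid
    if (mid - 1L >= lo) { tail <- tail + 1L; qlo[tail] <- lo; qhi[tail] <- mid - 1L }
    if (mid + 1L <= hi) { tail <- tail + 1L; qlo[tail] <- mid + 1L; qhi[tail] <- hi }
  }
  out[seq_len(got)]
}

#' Sparse-sample a voxel's points in time
#'
#' @param points data.frame of one voxel's points, sorted ascending by
#'   mapping time.
#' @param queue_len queue length (default 31, the published empirical
#'   value).
#' @return the sampled subset of rows, in original (time) order.
#' @export
sparse_sample_times <- function(points, queue_len = 31L) {
  if (!nrow(points)) return(points)
  if (is.unsorted(points$time_ms)) stop("points must be sorted by time")
  r <- sort(sparse_sample_ranks(nrow(points), queue_len))
  points[r, , drop = FALSE]
}

#' Trimmed mean of a DF sequence
#'
#' Discards the `k = floor(alpha * n)` smallest and largest values of the
#' sequence and averages the remainder; the voxel unit's robust DF
#' statistic.
#'
#' @param x numeric DF values (any order; sorted internally).
#' @param alpha trimming proportion in `[0, 0.5)`.
#' @return the trimmed mean.
#' @export
#' @examples
#' trimmed_mean_df(c(4.0, 6.0, 6.1, 6.2, 9.9), alpha = 0.2) # 6.1
trimmed_mean_df <- function(x, alpha = 0.2) {
  stopifnot(alpha >= 0, alpha < 0.5)
  n <- length(x)
  if (n == 0L) stop("empty DF sequence")
  x <- sort(x)
  k <- floor(alpha * n)
  mean(x[(k + 1L):(n - k)])
}

#' Aggregation configuration
#'
#' @param alpha trimming proportion for the per-voxel trimmed mean.
#' @param queue_len sparse-sampling queue length.
#' @param min_points minimum number of valid DF values for a voxel to enter
#'   the model.
#' @return an object of class `aggregation_config`.
#' @export
aggregation_config <- function(alpha = 0.2, queue_len = 31L,
                               min_points = 3L) {
  stopifnot(alpha >= 0, alpha < 0.5, queue_len >= 1L, min_points >= 1L)
  structure(list(alpha = alpha, queue_len = as.integer(queue_len),
                 min_points = as.integer(min_points)),
            class = "aggregation_config")
}

#' Build the voxel-level DF model
#'
#' Per voxel: assign points, sparse-sample them in time, keep the valid DF
#' values, sort them and take the trimmed mean. Voxels with fewer than
#' `min_points` valid DFs are excluded. Bookkeeping counts (total possible,
#' nonempty, effective, saturated voxels) are attached as attribute
#' `counts`.
#'
#' @param df_points a `df_points` data.frame (see [compute_df_points()]).
#'   Points may already be a sparse-sampled subset; the per-voxel sampling
#'   is idempotent in that case. The optional `occupancy` argument restores
#'   the pre-sampling point counts for bookkeeping.
#' @param grid a [voxel_grid()].
#' @param cfg an [aggregation_config()].
#' @param occupancy optional data.frame `ix, iy, iz, n_points` with the full
#'   per-voxel point counts before any upstream sparse sampling.
#' @return a `voxel_model`: data.frame with one row per effective voxel
#'   (`ix, iy, iz, x_mm, y_mm, z_mm, n_points, n_sampled, n_valid, df_raw,
#'   oi_mean`), ordered by voxel index, with attributes `grid`, `cfg`,
#'   `counts`.
#' @export
build_voxel_model <- function(df_points, grid, cfg = aggregation_config(),
                              occupancy = NULL) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(cfg, "aggregation_config"))
  pts <- assign_to_voxels(df_points, grid)
  n_dropped <- attr(pts, "n_dropped")
  if (!nrow(pts)) stop("no mapping points inside the voxel grid")
  pts <- pts[order(pts$ix, pts$iy, pts$iz, pts$time_ms, pts$channel), ,
             drop = FALSE]
  key <- voxel_key(as.matrix(pts[, c("ix", "iy", "iz")]))
  groups <- split(seq_len(nrow(pts)), key)

  nvox <- length(groups)
  df_raw <- oi_mean <- rep(NA_real_, nvox)
  n_points <- n_sampled <- n_valid <- integer(nvox)
  for (g in seq_len(nvox)) {
    rows <- groups[[g]]
    n_points[g] <- length(rows)
    samp <- rows[sort(sparse_sample_ranks(length(rows), cfg$queue_len))]
    n_sampled[g] <- length(samp)
    ok <- samp[pts$valid[samp] & !is.na(pts$df_hz[samp])]
    n_valid[g] <- length(ok)
    if (n_valid[g] >= cfg$min_points) {
      df_raw[g] <- trimmed_mean_df(pts$df_hz[ok], cfg$alpha)
      oi_mean[g] <- mean(pts$oi[ok])
    }
  }

  occ <- n_points
  if (!is.null(occupancy)) {
    okey <- voxel_key(as.matrix(occupancy[, c("ix", "iy", "iz")]))
    m <- match(names(groups), okey)
    occ <- ifelse(is.na(m), n_points, occupancy$n_points[m])
  }

  eff <- !is.na(df_raw)
  if (!any(eff))
    stop("no voxel has at least ", cfg$min_points,
         " valid DF values; the model is empty")
  vox <- key_to_index(names(groups))
  cent <- voxel_centroid(grid, vox)
  model <- data.frame(vox, x_mm = cent[, 1], y_mm = cent[, 2],
                      z_mm = cent[, 3], n_points = as.integer(occ),
                      n_sampled = n_sampled, n_valid = n_valid,
                      df_raw = df_raw, oi_mean = oi_mean)[eff, , drop = FALSE]
  rownames(model) <- NULL
  counts <- list(possible = as.double(grid$n_cells)^3,
                 nonempty = nvox,
                 effective = sum(eff),
                 saturated = sum(occ >= cfg$queue_len),
                 points_in = nrow(pts) + n_dropped,
                 points_in_bounds = nrow(pts),
                 points_sampled = sum(n_sampled),
                 points_dropped = n_dropped)
  structure(model, grid = grid, cfg = cfg, counts = counts,
            class = c("voxel_model", "data.frame"))
}
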