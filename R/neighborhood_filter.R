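# kd-tree spatial index over voxel centroids and the 10-nearest-neighbor
# arithmetic smoothing of the voxel DF model.

#' Build a kd-tree over voxel centroids
#'
#' Split axes cycle x, y, z with depth; each node is the median point along
#' the current axis (lower middle for even counts), points equal to the
#' boundary go to the left subtree, and leaves hold a single point. The
#' `tie_rank` vector defines a total order used for deterministic handling
#' of coordinate ties (lexicographic voxel index in the pipeline).
#'
#' @param points n x 3 numeric matrix of centroids, mm.
#' @param tie_rank integer vector of tie-break ranks, one per point.
#' @return an object of class `kdtree`.
#' @export
build_kdtree <- function(points, tie_rank = seq_len(nrow(points))) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, nrow(points) >= 1L,
            length(tie_rank) == nrow(points))
  n <- nrow(points)
  pt <- left <- right <- axis <- integer(n)
  cnt <- 0L
  rec <- function(idx, depth) {
    if (!length(idx)) return(0L)
    a <- depth %% 3L + 1L
    idx <- idx[order(points[idx, a], tie_rank[idx])]
    m <- (length(idx) + 1L) %/% 2L
    cnt <<- cnt + 1L
    node <- cnt
    pt[node] <<- idx[m]
    axis[node] <<- a
    l <- rec(idx[seq_len(m - 1L)], depth + 1L)
    r <- rec(if (m < length(idx)) idx[(m + 1L):length(idx)] else integer(0),
             depth + 1L)
    left[node] <<- l
    right[node] <<- r
    node
  }
  root <- rec(seq_len(n), 0L)
  structure(list(points = points, tie = as.numeric(tie_rank), pt = pt,
                 left = left, right = right, axis = axis, root = root,
                 n = n),
            class = "kdtree")
}

#' k nearest neighbors from a kd-tree
#'
#' Exact Euclidean k-NN with branch pruning. Distance ties at the k-th slot
#' are broken by the tree's `tie_rank` (smaller rank wins), so the result is
#' a deterministic function of the point set.
#'
#' @param tree a [build_kdtree()] result.
#' @param query length-3 numeric position, mm.
#' @param k number of neighbors.
#' @param exclude optional point index (into the tree's point matrix) to
#'   omit, typically the query point itself.
#' @return integer vector of point indices, ordered by increasing distance
#'   (tie rank within equal distances), of length `min(k, n - excluded)`.
#' @export
kdtree_knn <- function(tree, query, k = 10L, exclude = 0L) {
  stopifnot(inherits(tree, "kdtree"), length(query) == 3L)
  P <- tree$points
  tie <- tree$tie
  cap <- as.integer(k)
  if (cap < 1L) return(integer(0))
  bd <- rep(Inf, cap); bt <- rep(Inf, cap); bi <- integer(cap)
  cnt <- 0L
  consider <- function(i) {
    if (i == exclude) return(invisible())
    d <- (P[i, 1L] - query[1L])^2 + (P[i, 2L] - query[2L])^2 +
      (P[i, 3L] - query[3L])^2
    t <- tie[i]
    if (cnt == cap && (d > bd[cap] || (d == bd[cap] && t > bt[cap])))
      return(invisible())
    j <- cnt
    while (j >= 1L && (d < bd[j] || (d == bd[j] && t < bt[j]))) j <- j - 1L
    if (cnt < cap) cnt <<- cnt + 1L
    if (j + 2L <= cnt) {
      sh <- cnt:(j + 2L)
      bd[sh] <<- bd[sh - 1L]; bt[sh] <<- bt[sh - 1L]; bi[sh] <<- bi[sh - 1L]
    }
    bd[j + 1L] <<- d; bt[j + 1L] <<- t; bi[j + 1L] <<- i
    invisible()
  }
  search <- function(node) {
    if (node == 0L) return(invisible())
    a <- tree$axis[node]
    split <- P[tree$pt[node], a]
    consider(tree$pt[node])
    if (query[a] <= split) {
      search(tree$left[node])
      if (cnt < cap || (query[a] - split)^2 <= bd[cap])
        search(tree$right[node])
    } else {
      search(tree$right[node])
      if (cnt < cap || (query[a] - split)^2 <= bd[cap])
        search(tree$left[node])
    }
    invisible()
  }
  search(tree$root)
  bi[seq_len(cnt)]
}

#' Local neighborhood spatial filtering of the voxel model
#'
#' Replaces each voxel's DF with the arithmetic mean of its own value and
#' the values of its `k` nearest neighboring voxel units (Euclidean distance
#' between centroids). All smoothed values are computed from the
#' pre-smoothing snapshot, so the result does not depend on any update
#' order; when fewer than `k` other voxels exist, all of them are used.
#'
#' @param model a `voxel_model` from [build_voxel_model()].
#' @param k neighborhood size (default 10, i.e. an 11-term mean).
#' @return the model with columns `df_smoothed` and `neighbors` (list of
#'   integer row indices) appended.
#' @export
smooth_model <- function(model, k = 10L) {
  stopifnot(inherits(model, "voxel_model"))
  n <- nrow(model)
  raw <- model$df_raw
  if (n == 1L) {
    warning("single-voxel model: smoothing leaves the DF unchanged")
    model$df_smoothed <- raw
    model$neighbors <- list(integer(0))
    return(model)
  }
  cent <- as.matrix(model[, c("x_mm", "y_mm", "z_mm")])
  # rows are ordered by voxel index, so row number is the lexicographic rank
  tree <- build_kdtree(cent, tie_rank = seq_len(n))
  kk <- min(k, n - 1L)
  sm <- numeric(n)
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    nbi <- kdtree_knn(tree, cent[i, ], k = kk, exclude = i)
    nb[[i]] <- nbi
    sm[i] <- mean(c(raw[i], raw[nbi]))
  }
  model$df_smoothed <- sm
  model$neighbors <- nb
  attr(model, "smoothing_k") <- k
  model
}
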