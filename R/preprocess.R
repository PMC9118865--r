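#' Pass filter along a coordinate axis
#'
#' Keeps the points whose coordinate on `axis` lies in the closed interval
#' `[lo, hi]`; used to crop the survey background away from the plot of
#' interest. Point order is preserved.
#'
#' @param cloud a point cloud tibble.
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param lo,hi interval bounds in metres, `lo <= hi`.
#' @return The filtered point cloud.
#' @export
pass_filter <- function(cloud, axis = c("z", "x", "y"), lo, hi) {
  cloud <- as_pointcloud(cloud)
  axis <- match.arg(axis)
  if (lo > hi) stop("pass_filter: lo > hi")
  dplyr::filter(cloud, .data[[axis]] >= lo, .data[[axis]] <= hi)
}

#' Voxel-grid downsampling
#'
#' Partitions space into `leaf`-sized cubes and replaces each occupied voxel's
#' points by their centroid. The default leaf of 8 mm matches the spatial
#' sampling distance used on plantation-scale TLS scans. Centroids (rather
#' than voxel centres) preserve thin surfaces such as the pseudo-stem shell.
#' Extra columns are reduced by voxel too: `label`/`plant_id` keep the first
#' value seen in the voxel.
#'
#' @param cloud a point cloud tibble.
#' @param leaf voxel edge length in metres.
#' @return The downsampled point cloud (one point per occupied voxel).
#' @export
voxel_downsample <- function(cloud, leaf = 0.008) {
  cloud <- as_pointcloud(cloud)
  if (leaf <= 0) stop("voxel_downsample: leaf must be > 0")
  if (nrow(cloud) == 0) return(cloud)
  key <- paste(floor(cloud$x / leaf), floor(cloud$y / leaf),
               floor(cloud$z / leaf))
  sums <- rowsum(cbind(cloud$x, cloud$y, cloud$z, 1), key)
  out <- tibble::tibble(
    x = unname(sums[, 1] / sums[, 4]),
    y = unname(sums[, 2] / sums[, 4]),
    z = unname(sums[, 3] / sums[, 4])
  )
  extra <- setdiff(names(cloud), c("x", "y", "z"))
  if (length(extra) > 0) {
    first_idx <- which(!duplicated(key))
    ord <- match(rownames(sums), key[first_idx])
    for (col in extra) out[[col]] <- cloud[[col]][first_idx][ord]
  }
  as_pointcloud(out)
}

#' Statistical outlier removal
#'
#' Computes each point's mean distance to its `k` nearest neighbours and
#' removes the points whose mean distance exceeds the global mean plus
#' `std_mult` standard deviations — the standard statistical filter for
#' stray returns around foliage and stems.
#'
#' @param cloud a point cloud tibble with more than `k` points.
#' @param k neighbour count (default 50, the common TLS community setting).
#' @param std_mult standard-deviation multiplier on the global mean-distance
#'   distribution (default 1.0).
#' @return A list with `kept` and `removed` point clouds; together they
#'   partition the input.
#' @export
statistical_outlier_removal <- function(cloud, k = 50, std_mult = 1.0) {
  cloud <- as_pointcloud(cloud)
  if (k < 1) stop("statistical_outlier_removal: k must be >= 1")
  if (nrow(cloud) <= k) {
    stop("statistical_outlier_removal: cloud must have more than k points")
  }
  mean_d <- cpp_knn_mean_dist(cloud_matrix(cloud), as.integer(k))
  thresh <- mean(mean_d) + std_mult * stats::sd(mean_d)
  # relative epsilon so ties at the threshold (e.g. perfectly regular grids,
  # where all mean distances are equal up to rounding) are kept
  keep <- mean_d <= thresh * (1 + 1e-9) + 1e-12
  list(kept = cloud[keep, , drop = FALSE], removed = cloud[!keep, , drop = FALSE])
}

# least-squares plane through points: centroid + smallest principal direction
fit_plane_lsq <- function(m) {
  ctr <- colMeans(m)
  sv <- svd(sweep(m, 2, ctr), nu = 0)
  normal <- sv$v[, 3]
  if (normal[3] < 0) normal <- -normal
  list(normal = normal, offset = -sum(normal * ctr))
}

#' Construct a plane model
#'
#' The plane is the zero set of `normal . p + offset`; the stored normal is
#' unit length with a non-negative z-component (canonical upward
#' orientation), so signed distances are positive above ground.
#'
#' @param normal plane normal (any length, normalised internally).
#' @param offset plane offset, metres.
#' @param inlier_count supporting point count (informational).
#' @return A `plane_model`.
#' @export
plane_model <- function(normal, offset, inlier_count = 0L) {
  nn <- sqrt(sum(normal^2))
  stopifnot(nn > 0)
  normal <- normal / nn
  offset <- offset / nn
  if (normal[3] < 0) {
    normal <- -normal
    offset <- -offset
  }
  structure(
    list(normal = as.double(normal), offset = as.double(offset),
         inlier_count = as.integer(inlier_count)),
    class = "plane_model"
  )
}

new_plane_model <- plane_model

#' @export
print.plane_model <- function(x, ...) {
  cat(sprintf(
    "<plane_model> normal = (%.4f, %.4f, %.4f), offset = %.4f m, %d inliers\n",
    x$normal[1], x$normal[2], x$normal[3], x$offset, x$inlier_count
  ))
  invisible(x)
}

#' RANSAC ground-plane segmentation
#'
#' Finds the dominant plane by random sample consensus: `iters` random
#' 3-point samples, each scored by the number of points within `dist` of its
#' plane; the winner is refined by a least-squares fit to its inliers and
#' re-scored. The plane normal is canonically oriented with a non-negative
#' z-component so signed distances are positive above ground.
#'
#' @param cloud a point cloud with at least 3 non-collinear points.
#' @param dist inlier distance tolerance in metres (default 0.03, which
#'   tolerates plot-scale ground roughness).
#' @param iters number of random samples (default 1000).
#' @param seed RNG seed for reproducibility.
#' @return A list with `plane` (a `plane_model`), `ground` (inlier cloud) and
#'   `nonground` (the rest).
#' @export
ransac_plane <- function(cloud, dist = 0.03, iters = 1000, seed = 1) {
  cloud <- as_pointcloud(cloud)
  n <- nrow(cloud)
  if (n < 3) stop("ransac_plane: need at least 3 points")
  m <- cloud_matrix(cloud)

  best <- NULL
  best_count <- -1L
  local_rng(seed)

  for (i in seq_len(iters)) {
    idx <- sample.int(n, 3)
    p1 <- m[idx[1], ]; p2 <- m[idx[2], ]; p3 <- m[idx[3], ]
    nrm <- cross3(p2 - p1, p3 - p1)
    nn <- sqrt(sum(nrm^2))
    if (nn < 1e-12) next # collinear sample
    nrm <- nrm / nn
    off <- -sum(nrm * p1)
    cnt <- sum(abs(m %*% nrm + off) <= dist)
    if (cnt > best_count) {
      best_count <- cnt
      best <- list(normal = nrm, offset = off)
    }
  }
  if (is.null(best)) stop("ransac_plane: degenerate geometry, all samples collinear")

  # least-squares refinement on the consensus set, then re-score
  inl <- abs(m %*% best$normal + best$offset) <= dist
  if (sum(inl) >= 3) {
    ref <- fit_plane_lsq(m[inl, , drop = FALSE])
    ref_inl <- abs(m %*% ref$normal + ref$offset) <= dist
    if (sum(ref_inl) >= sum(inl)) {
      best <- ref
      inl <- ref_inl
    }
  }
  if (best$normal[3] < 0) {
    best$normal <- -best$normal
    best$offset <- -best$offset
  }
  plane <- new_plane_model(best$normal, best$offset, sum(inl))
  list(
    plane = plane,
    ground = cloud[inl, , drop = FALSE],
    nonground = cloud[!inl, , drop = FALSE]
  )
}

#' Signed height of points above a fitted plane
#'
#' `normal . p + offset`, positive above ground under the canonical upward
#' normal. Vectorised over the rows of `cloud`.
#'
#' @param cloud a point cloud tibble (or any data frame with x, y, z).
#' @param plane a `plane_model`.
#' @return Numeric vector of signed distances in metres.
#' @export
height_above_plane <- function(cloud, plane) {
  stopifnot(inherits(plane, "plane_model"))
  cloud <- as_pointcloud(cloud)
  as.vector(cloud_matrix(cloud) %*% plane$normal + plane$offset)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @importFrom generics tidy
NULL

#' Tidy a fitted ground plane
#'
#' @param x a `plane_model`.
#' @param ... unused.
#' @return One-row tibble with the normal components, offset and inlier count.
#' @method tidy plane_model
#' @export
tidy.plane_model <- function(x, ...) {
  tibble::tibble(
    normal_x = x$normal[1], normal_y = x$normal[2], normal_z = x$normal[3],
    offset = x$offset, inlier_count = x$inlier_count
  )
}
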