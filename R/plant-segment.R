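#' Seeded K-means single-plant segmentation
#'
#' Splits the closed-canopy plant cloud into single plants by Lloyd's
#' algorithm on the XY projection, with K fixed to the detected stem count
#' and centroids initialised at the stem cluster centroids. Seeding in 2D
#' avoids the vertical bias a 3D seed (taken from a 1 m slice) would impose
#' on canopy points near 2.5 m. A cluster that loses all its points keeps
#' its previous centroid, so every seed yields a (possibly empty) segment.
#'
#' @param cloud the non-ground plant cloud.
#' @param seeds data frame of seed centroids with columns `x`, `y` (one row
#'   per plant; K = number of rows, must be >= 1).
#' @param max_iter maximum Lloyd iterations.
#' @param tol convergence threshold on the maximum centroid shift, metres.
#' @return A list with `cloud` (input plus integer `plant_id` column, 1..K in
#'   seed order; an existing `plant_id` column — e.g. the generator's truth
#'   ids — is overwritten), `centroids` (final centroid tibble), `objective` (vector of
#'   the within-cluster sum of squared XY distances per iteration, which is
#'   non-increasing) and `iterations`.
#' @export
seeded_kmeans <- function(cloud, seeds, max_iter = 100, tol = 1e-4) {
  cloud <- as_pointcloud(cloud)
  seeds <- as.data.frame(seeds)
  k <- nrow(seeds)
  if (k < 1) stop("seeded_kmeans: need at least one seed")
  if (nrow(cloud) == 0) stop("seeded_kmeans: empty plant cloud")
  cx <- as.double(seeds$x)
  cy <- as.double(seeds$y)
  px <- cloud$x
  py <- cloud$y
  n <- length(px)

  assign_pts <- function(cx, cy) {
    d2 <- matrix(0, n, k)
    for (j in seq_len(k)) d2[, j] <- (px - cx[j])^2 + (py - cy[j])^2
    list(id = max.col(-d2, ties.method = "first"),
         obj = sum(d2[cbind(seq_len(n), max.col(-d2, ties.method = "first"))]))
  }

  obj_trace <- double()
  it <- 0L
  repeat {
    it <- it + 1L
    a <- assign_pts(cx, cy)
    obj_trace <- c(obj_trace, a$obj)
    new_cx <- cx
    new_cy <- cy
    for (j in seq_len(k)) {
      sel <- a$id == j
      if (any(sel)) {
        new_cx[j] <- mean(px[sel])
        new_cy[j] <- mean(py[sel])
      }
    }
    shift <- max(sqrt((new_cx - cx)^2 + (new_cy - cy)^2))
    cx <- new_cx
    cy <- new_cy
    if (shift < tol || it >= max_iter) break
  }
  final <- assign_pts(cx, cy)
  cloud$plant_id <- final$id
  list(
    cloud = cloud,
    centroids = tibble::tibble(plant_id = seq_len(k), x = cx, y = cy),
    objective = obj_trace,
    iterations = it
  )
}

#' Extract the ground patch under a plant segment
#'
#' Ground points whose (x, y) fall inside the closed XY bounding box of the
#' segment's cloud. Patches of adjacent plants may overlap and their union
#' need not cover all ground.
#'
#' @param ground the ground point cloud from [ransac_plane()].
#' @param segment_cloud one plant's point cloud (non-empty).
#' @return The ground patch point cloud (possibly empty).
#' @export
attach_ground <- function(ground, segment_cloud) {
  ground <- as_pointcloud(ground)
  segment_cloud <- as_pointcloud(segment_cloud)
  if (nrow(segment_cloud) == 0) stop("attach_ground: empty segment cloud")
  bb <- bounding_box(segment_cloud)
  dplyr::filter(ground, .data$x >= bb$xmin, .data$x <= bb$xmax,
                .data$y >= bb$ymin, .data$y <= bb$ymax)
}

#' Split a segmented cloud into per-plant segments
#'
#' Convenience wrapper pairing each K-means segment with its ground patch.
#'
#' @param km result of [seeded_kmeans()].
#' @param ground the ground point cloud.
#' @return A list of `plant_segment` lists with `plant_id`, `cloud`,
#'   `ground_patch` and `seed`.
#' @export
split_plants <- function(km, ground) {
  lapply(seq_len(nrow(km$centroids)), function(j) {
    seg_cloud <- km$cloud[km$cloud$plant_id == j, , drop = FALSE]
    patch <- if (nrow(seg_cloud) > 0) attach_ground(ground, seg_cloud) else
      ground[0, , drop = FALSE]
    structure(
      list(plant_id = j, cloud = seg_cloud, ground_patch = patch,
           seed = c(x = km$centroids$x[j], y = km$centroids$y[j])),
      class = "plant_segment"
    )
  })
}
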