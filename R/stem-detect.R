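#' Counting parameters
#'
#' Thresholds for fixed-height band extraction, Euclidean clustering and
#' bounding-box classification. Defaults are the plantation-scale values:
#' the 1.0--1.1 m fixed-height band above the fitted ground plane, a 0.10 m
#' Euclidean clustering tolerance, and the 0.25--0.6 m X+Y extent-sum window
#' that separates banana pseudo-stems from thinner bamboo poles and wider
#' broken leaves.
#'
#' @param band_lo,band_hi fixed-height band above the ground plane, metres.
#' @param cluster_tol Euclidean clustering distance tolerance, metres.
#' @param min_cluster_size minimum surviving cluster size in points.
#' @param stem_sum_lo,stem_sum_hi closed extent-sum window classified as
#'   pseudo-stem, metres.
#' @param extent_mode `"sum"` classifies on extent_x + extent_y (default);
#'   `"each"` requires each axis extent inside the window independently.
#' @param band_sor_k,band_sor_std statistical-outlier-removal settings applied
#'   to the extracted band before clustering.
#' @return A `counting_params` list.
#' @export
counting_params <- function(band_lo = 1.0, band_hi = 1.1, cluster_tol = 0.10,
                            min_cluster_size = 30, stem_sum_lo = 0.25,
                            stem_sum_hi = 0.60, extent_mode = c("sum", "each"),
                            band_sor_k = 20, band_sor_std = 2.0) {
  stopifnot(band_lo < band_hi, stem_sum_lo < stem_sum_hi, cluster_tol > 0)
  structure(
    list(band_lo = band_lo, band_hi = band_hi, cluster_tol = cluster_tol,
         min_cluster_size = min_cluster_size, stem_sum_lo = stem_sum_lo,
         stem_sum_hi = stem_sum_hi, extent_mode = match.arg(extent_mode),
         band_sor_k = band_sor_k, band_sor_std = band_sor_std),
    class = c("counting_params", "list")
  )
}

#' Extract the fixed-height band above the ground plane
#'
#' Keeps the points whose signed distance to the plane lies in the closed
#' interval `[band_lo, band_hi]`, then statistically filters the slice to
#' remove stray points around the pseudo-stems. The band follows the fitted
#' plane, not raw z, so tilted plots behave correctly.
#'
#' @param nonground point cloud of non-ground points.
#' @param plane a `plane_model` from [ransac_plane()].
#' @param params a [counting_params()].
#' @return The filtered band point cloud (possibly empty).
#' @export
extract_band <- function(nonground, plane, params = counting_params()) {
  nonground <- as_pointcloud(nonground)
  if (nrow(nonground) == 0) return(nonground)
  h <- height_above_plane(nonground, plane)
  band <- nonground[h >= params$band_lo & h <= params$band_hi, , drop = FALSE]
  if (nrow(band) > params$band_sor_k) {
    band <- statistical_outlier_removal(band, k = params$band_sor_k,
                                        std_mult = params$band_sor_std)$kept
  }
  band
}

#' Euclidean clustering
#'
#' Partitions a cloud into connected components of the graph that links
#' points at distance at most `tol`; components smaller than `min_size` are
#' discarded. Cluster ids are deterministic: 1, 2, ... by descending size,
#' ties broken by lexicographic centroid.
#'
#' @param cloud a point cloud tibble.
#' @param tol connection distance tolerance, metres.
#' @param min_size minimum cluster size in points.
#' @return The eligible points with an integer `cluster` column; points in
#'   discarded components are absent from the result.
#' @export
euclidean_cluster <- function(cloud, tol = 0.10, min_size = 1) {
  cloud <- as_pointcloud(cloud)
  if (tol <= 0) stop("euclidean_cluster: tol must be > 0")
  if (nrow(cloud) == 0) {
    cloud$cluster <- integer()
    return(cloud)
  }
  raw <- cpp_cluster_labels(cloud_matrix(cloud), tol)
  sizes <- tabulate(raw)
  keep_comp <- which(sizes >= min_size)
  keep <- raw %in% keep_comp
  out <- cloud[keep, , drop = FALSE]
  raw <- raw[keep]
  if (nrow(out) == 0) {
    out$cluster <- integer()
    return(out)
  }
  stats_tbl <- dplyr::arrange(
    dplyr::summarise(
      dplyr::group_by(tibble::tibble(comp = raw, x = out$x, y = out$y,
                                     z = out$z), .data$comp),
      n = dplyr::n(), cx = mean(.data$x), cy = mean(.data$y),
      cz = mean(.data$z), .groups = "drop"
    ),
    dplyr::desc(.data$n), .data$cx, .data$cy, .data$cz
  )
  remap <- stats::setNames(seq_len(nrow(stats_tbl)), stats_tbl$comp)
  out$cluster <- unname(remap[as.character(raw)])
  out
}

classify_extents <- function(extent_x, extent_y, params) {
  if (params$extent_mode == "sum") {
    s <- extent_x + extent_y
    dplyr::case_when(
      s < params$stem_sum_lo ~ "pole",
      s <= params$stem_sum_hi ~ "stem",
      TRUE ~ "leaf"
    )
  } else {
    mx <- pmax(extent_x, extent_y)
    mn <- pmin(extent_x, extent_y)
    dplyr::case_when(
      mx < params$stem_sum_lo ~ "pole",
      mn >= params$stem_sum_lo & mx <= params$stem_sum_hi ~ "stem",
      TRUE ~ "leaf"
    )
  }
}

#' Classify a fixed-height cluster by its bounding-box extents
#'
#' The discriminant is the sum of the axis-aligned X and Y extents of the
#' cluster: below the stem window it is a bamboo pole, inside the closed
#' window `[stem_sum_lo, stem_sum_hi]` a banana pseudo-stem, above it a
#' (broken) leaf.
#'
#' @param cluster a non-empty point cloud (one cluster).
#' @param params a [counting_params()].
#' @return One-row tibble: centroid, extents, `extent_sum` and `label`.
#' @export
classify_cluster <- function(cluster, params = counting_params()) {
  cluster <- as_pointcloud(cluster)
  if (nrow(cluster) == 0) stop("classify_cluster: empty cluster")
  bb <- bounding_box(cluster)
  tibble::tibble(
    n = nrow(cluster),
    x = mean(cluster$x), y = mean(cluster$y), z = mean(cluster$z),
    extent_x = bb$extent_x, extent_y = bb$extent_y,
    extent_sum = bb$extent_x + bb$extent_y,
    label = classify_extents(bb$extent_x, bb$extent_y, params)
  )
}

#' Count banana plants in the fixed-height band
#'
#' Euclidean-clusters the band, classifies every cluster by its extent sum,
#' and takes the number of pseudo-stem clusters as the plant count K. The
#' stem cluster centroids are the seeds for single-plant K-means
#' segmentation.
#'
#' @param band the fixed-height band cloud from [extract_band()].
#' @param params a [counting_params()].
#' @return A list with `K` (stem count), `seeds` (tibble of stem centroids),
#'   `clusters` (classified cluster summary, one row per cluster) and
#'   `clustered` (the band points with their `cluster` id).
#' @export
count_plants <- function(band, params = counting_params()) {
  band <- as_pointcloud(band)
  clustered <- euclidean_cluster(band, tol = params$cluster_tol,
                                 min_size = params$min_cluster_size)
  if (nrow(clustered) == 0) {
    empty <- tibble::tibble(
      cluster = integer(), n = integer(), x = double(), y = double(),
      z = double(), extent_x = double(), extent_y = double(),
      extent_sum = double(), label = character()
    )
    return(list(K = 0L, seeds = empty[, c("cluster", "x", "y")],
                clusters = empty, clustered = clustered))
  }
  clusters <- dplyr::summarise(
    dplyr::group_by(clustered, .data$cluster),
    n = dplyr::n(),
    extent_x = max(.data$x) - min(.data$x),
    extent_y = max(.data$y) - min(.data$y),
    x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
    .groups = "drop"
  )
  clusters$extent_sum <- clusters$extent_x + clusters$extent_y
  clusters$label <- classify_extents(clusters$extent_x, clusters$extent_y,
                                     params)
  clusters <- dplyr::arrange(clusters, .data$cluster)
  seeds <- clusters[clusters$label == "stem", c("cluster", "x", "y")]
  list(K = nrow(seeds), seeds = seeds, clusters = clusters,
       clustered = clustered)
}
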