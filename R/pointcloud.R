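#' Point clouds as tibbles
#'
#' Throughout stalkscan a point cloud is an ordinary tibble with numeric
#' columns `x`, `y`, `z` in metres (Z up, right-handed). Optional integer
#' columns `label` (true class, from the synthetic generator) and `plant_id`
#' ride along untouched; the measurement pipeline never consumes them, they
#' exist so tests can compare results against ground truth. An empty tibble
#' (zero rows) is a valid cloud everywhere.
#'
#' @param x,y,z numeric coordinate vectors of equal length, metres.
#' @param ... further equal-length columns (e.g. `label`, `plant_id`).
#' @return A tibble with class `c("pointcloud", ...)`.
#' @examples
#' pointcloud(x = c(0, 1), y = c(0, 0), z = c(0, 2))
#' @export
pointcloud <- function(x = double(), y = double(), z = double(), ...) {
  out <- tibble::tibble(x = as.double(x), y = as.double(y), z = as.double(z), ...)
  as_pointcloud(out)
}

#' Coerce a data frame to a point cloud
#'
#' Validates the `x`, `y`, `z` columns (present, numeric, finite) and returns
#' the tibble with the `pointcloud` class prepended.
#'
#' @param df a data frame with numeric `x`, `y`, `z` columns.
#' @return A `pointcloud` tibble.
#' @export
as_pointcloud <- function(df) {
  stopifnot(is.data.frame(df))
  miss <- setdiff(c("x", "y", "z"), names(df))
  if (length(miss) > 0) {
    stop("point cloud is missing column(s): ", paste(miss, collapse = ", "))
  }
  out <- tibble::as_tibble(df)
  for (col in c("x", "y", "z")) {
    v <- out[[col]]
    if (!is.numeric(v)) stop("point cloud column '", col, "' must be numeric")
    if (nrow(out) > 0 && !all(is.finite(v))) {
      stop("point cloud column '", col, "' contains non-finite values")
    }
  }
  if (!inherits(out, "pointcloud")) class(out) <- c("pointcloud", class(out))
  out
}

# bare n x 3 coordinate matrix, the currency of the C++ spatial kernels
cloud_matrix <- function(cloud) {
  cbind(cloud$x, cloud$y, cloud$z)
}

#' Axis-aligned bounding box of a point cloud
#'
#' Per-axis minima and maxima plus the extents and the X+Y extent sum used to
#' classify fixed-height clusters into pseudo-stems, bamboo poles and leaves.
#'
#' @param cloud a point cloud tibble (non-empty).
#' @return One-row tibble with `xmin`, `xmax`, `ymin`, `ymax`, `zmin`, `zmax`,
#'   `extent_x`, `extent_y`, `extent_z`, `extent_sum` (= extent_x + extent_y),
#'   all in metres.
#' @export
bounding_box <- function(cloud) {
  cloud <- as_pointcloud(cloud)
  if (nrow(cloud) == 0) stop("bounding_box: empty point cloud")
  tibble::tibble(
    xmin = min(cloud$x), xmax = max(cloud$x),
    ymin = min(cloud$y), ymax = max(cloud$y),
    zmin = min(cloud$z), zmax = max(cloud$z),
    extent_x = max(cloud$x) - min(cloud$x),
    extent_y = max(cloud$y) - min(cloud$y),
    extent_z = max(cloud$z) - min(cloud$z),
    extent_sum = (max(cloud$x) - min(cloud$x)) + (max(cloud$y) - min(cloud$y))
  )
}

#' Plot a point cloud projection
#'
#' Quick-look scatter of a cloud in a chosen coordinate plane, coloured by a
#' column when present (e.g. the generator's `label` or the pipeline's
#' `plant_id`).
#'
#' @param cloud a point cloud tibble.
#' @param axes two of `"x"`, `"y"`, `"z"` naming the projection plane.
#' @param colour optional column name to map to colour.
#' @param sample_n cap on plotted points (random subsample above it).
#' @return A ggplot object.
#' @export
plot_cloud <- function(cloud, axes = c("x", "y"), colour = NULL, sample_n = 5e4) {
  cloud <- as_pointcloud(cloud)
  stopifnot(length(axes) == 2, all(axes %in% c("x", "y", "z")))
  if (nrow(cloud) > sample_n) {
    cloud <- dplyr::slice_sample(cloud, n = sample_n)
  }
  p <- ggplot2::ggplot(cloud, ggplot2::aes(
    x = .data[[axes[1]]], y = .data[[axes[2]]]
  ))
  if (!is.null(colour) && colour %in% names(cloud)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(colour = factor(.data[[colour]])), size = 0.3
    ) + ggplot2::labs(colour = colour)
  } else {
    p <- p + ggplot2::geom_point(size = 0.3, alpha = 0.5)
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = paste(axes[1], "(m)"), y = paste(axes[2], "(m)")) +
    ggplot2::theme_minimal()
}
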