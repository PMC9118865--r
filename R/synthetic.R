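#' Scene specification for the synthetic banana plot
#'
#' Parametric description of a closed-canopy banana plot as scanned by a
#' levelled terrestrial laser scanner: a jittered planting grid of
#' near-vertical cylindrical pseudo-stems, leaf blades fanning out from the
#' top of each stem, optional wilted petioles below the leaf junction, thin
#' bamboo support poles beside stems, low horizontal broken-leaf patches, a
#' rough ground plane, Gaussian range noise and uniform point dropout.
#'
#' Defaults mirror a plantation in late vegetative growth: 2.5 m plant
#' spacing, stem radii 0.09--0.14 m (fixed-height extent sums then fall
#' strictly inside the 0.25--0.6 m pseudo-stem window rather than on its
#' upper boundary), leaf-junction heights 1.8--2.6 m centred near 2.2 m,
#' 15 mm-radius bamboo poles, 2 mm range noise.
#'
#' @param n_rows,n_cols planting grid dimensions.
#' @param spacing plant spacing in metres.
#' @param jitter uniform positional jitter of plant bases, metres.
#' @param radius_range min/max stem radius, metres (within (0, 0.3]).
#' @param height_range min/max leaf-junction height = true pseudo-stem
#'   height, metres.
#' @param tilt_max maximum stem lean, degrees.
#' @param canopy_span horizontal reach of a leaf blade, metres.
#' @param n_leaves_per_plant leaf blades per plant.
#' @param leaf_width blade width, metres.
#' @param leaf_droop quadratic droop coefficient of blades (m drop per m^2).
#' @param petiole_prob probability a plant carries a wilted petiole attached
#'   0.1--0.4 m below its leaf junction.
#' @param pole_prob probability a bamboo pole stands beside a stem.
#' @param pole_radius bamboo pole radius, metres.
#' @param broken_leaf_count number of low horizontal broken-leaf patches.
#' @param ground_roughness standard deviation of ground height, metres.
#' @param point_spacing target surface sampling distance, metres.
#' @param noise_sigma Gaussian coordinate noise, metres.
#' @param dropout fraction of points removed uniformly at random.
#' @param seed RNG seed; generation is a pure function of (spec, seed).
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(n_rows = 3, n_cols = 3, spacing = 2.5, jitter = 0.15,
                       radius_range = c(0.09, 0.14),
                       height_range = c(1.8, 2.6), tilt_max = 3,
                       canopy_span = 2.0, n_leaves_per_plant = 8,
                       leaf_width = 0.35, leaf_droop = 0.12,
                       petiole_prob = 0.5, pole_prob = 0.5,
                       pole_radius = 0.015, broken_leaf_count = 2,
                       ground_roughness = 0.01, point_spacing = 0.03,
                       noise_sigma = 0.002, dropout = 0.1, seed = 1) {
  spec <- list(
    n_rows = n_rows, n_cols = n_cols, spacing = spacing, jitter = jitter,
    radius_range = radius_range, height_range = height_range,
    tilt_max = tilt_max, canopy_span = canopy_span,
    n_leaves_per_plant = n_leaves_per_plant, leaf_width = leaf_width,
    leaf_droop = leaf_droop, petiole_prob = petiole_prob,
    pole_prob = pole_prob, pole_radius = pole_radius,
    broken_leaf_count = broken_leaf_count,
    ground_roughness = ground_roughness, point_spacing = point_spacing,
    noise_sigma = noise_sigma, dropout = dropout, seed = seed
  )
  stopifnot(
    spacing > 0, point_spacing > 0,
    all(radius_range > 0), all(radius_range <= 0.3),
    diff(radius_range) >= 0, diff(height_range) >= 0,
    petiole_prob >= 0, petiole_prob <= 1,
    pole_prob >= 0, pole_prob <= 1,
    dropout >= 0, dropout <= 1
  )
  class(spec) <- c("scene_spec", "list")
  spec
}

# class codes carried in the generator's `label` column
CLASS_GROUND <- 0L
CLASS_STEM <- 1L
CLASS_LEAF <- 2L
CLASS_POLE <- 3L
CLASS_PETIOLE <- 4L
CLASS_BROKEN <- 5L

# orthonormal frame perpendicular to a unit axis
axis_frame <- function(axis) {
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- cross3(ref, axis)
  u <- u / sqrt(sum(u^2))
  v <- cross3(axis, u)
  list(u = u, v = v)
}

#' Sample the lateral surface of a cylinder
#'
#' Points at approximately uniform areal density on the shell; every point is
#' at exactly `radius` from the axis line (noise is applied later, by the
#' scene assembler).
#'
#' @param base axis base point, length-3 numeric.
#' @param axis unit axis direction.
#' @param radius,length cylinder radius and length, metres.
#' @param point_spacing target sampling distance, metres.
#' @return A point cloud tibble.
#' @export
sample_cylinder <- function(base, axis, radius, length, point_spacing) {
  stopifnot(radius > 0, length > 0, point_spacing > 0)
  axis <- axis / sqrt(sum(axis^2))
  n <- max(1L, as.integer(ceiling(2 * pi * radius * length / point_spacing^2)))
  t <- stats::runif(n, 0, length)
  phi <- stats::runif(n, 0, 2 * pi)
  fr <- axis_frame(axis)
  radial <- outer(cos(phi), fr$u) + outer(sin(phi), fr$v)
  pts <- matrix(base, n, 3, byrow = TRUE) + outer(t, axis) + radius * radial
  pointcloud(x = pts[, 1], y = pts[, 2], z = pts[, 3])
}

#' Sample a drooping leaf blade
#'
#' A parabolic strip leaving `attach` along the horizontal projection of
#' `direction`: at arc parameter t (0..span) and lateral offset u
#' (-width/2..width/2) the point is `attach + t*dir + u*lateral` with z
#' lowered by `droop * t^2`. With `droop = 0` the strip is planar at the
#' attachment height; the XY footprint always has length `span`.
#'
#' @param attach attachment point, length-3 numeric.
#' @param direction direction of growth (its XY projection is used).
#' @param span blade length, metres.
#' @param width blade width, metres.
#' @param droop quadratic droop coefficient (m per m^2).
#' @param point_spacing target sampling distance, metres.
#' @return A point cloud tibble.
#' @export
sample_leaf_blade <- function(attach, direction, span, width, droop,
                              point_spacing) {
  stopifnot(span > 0, width > 0, point_spacing > 0)
  dxy <- c(direction[1], direction[2])
  nd <- sqrt(sum(dxy^2))
  if (nd < 1e-12) stop("sample_leaf_blade: direction has no XY component")
  dxy <- dxy / nd
  lat <- c(-dxy[2], dxy[1])
  n <- max(1L, as.integer(ceiling(span * width / point_spacing^2)))
  t <- stats::runif(n, 0, span)
  u <- stats::runif(n, -width / 2, width / 2)
  pointcloud(
    x = attach[1] + t * dxy[1] + u * lat[1],
    y = attach[2] + t * dxy[2] + u * lat[2],
    z = attach[3] - droop * t^2
  )
}

# horizontal rectangular patch (broken leaf lying low in the canopy gap)
sample_patch <- function(center, yaw, len, wid, point_spacing) {
  n <- max(1L, as.integer(ceiling(len * wid / point_spacing^2)))
  t <- stats::runif(n, -len / 2, len / 2)
  u <- stats::runif(n, -wid / 2, wid / 2)
  dxy <- c(cos(yaw), sin(yaw))
  lat <- c(-dxy[2], dxy[1])
  pointcloud(
    x = center[1] + t * dxy[1] + u * lat[1],
    y = center[2] + t * dxy[2] + u * lat[2],
    z = rep(center[3], n)
  )
}

#' Generate a synthetic banana plot with exact ground truth
#'
#' Assembles the scene described by a [scene_spec()]: sampled ground, stems
#' (cylindrical shells from the ground to the leaf junction), leaf blades,
#' optional wilted petioles and bamboo poles, and broken-leaf patches.
#' Gaussian noise and uniform dropout are applied last. Each point carries a
#' `label` class code (0 ground, 1 stem, 2 leaf, 3 pole, 4 petiole, 5 broken
#' leaf) and a `plant_id` (NA for ground and broken leaves); labels exist for
#' verification only and are never consumed by the measurement pipeline.
#'
#' @param spec a [scene_spec()].
#' @return A list with `cloud` (labelled point cloud) and `truth`, itself a
#'   list with `plants` (per-plant id, base, unit axis, radius and
#'   junction_height = true pseudo-stem height), `poles`, `broken_leaves`
#'   and `plane` (ground-plane normal and offset).
#' @export
generate_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  local_rng(spec$seed)

  n_plants <- spec$n_rows * spec$n_cols
  margin <- 1.0
  field_x <- c(-margin, (spec$n_cols - 1) * spec$spacing + margin)
  field_y <- c(-margin, (spec$n_rows - 1) * spec$spacing + margin)

  parts <- list()
  add <- function(cloud, label, plant_id = NA_integer_) {
    if (nrow(cloud) == 0) return(invisible(NULL))
    cloud$label <- label
    cloud$plant_id <- as.integer(plant_id)
    parts[[length(parts) + 1]] <<- cloud
    invisible(NULL)
  }

  # ground: uniform random surface sample (same sampling statistics as the
  # other surfaces, so statistical filtering treats all classes alike) with
  # Gaussian height roughness about z = 0; a zero-plant spec is an empty
  # field with an empty (but valid) truth record set
  if (n_plants > 0) {
    ng <- as.integer(ceiling(diff(field_x) * diff(field_y) /
                               spec$point_spacing^2))
    ground <- pointcloud(
      x = stats::runif(ng, field_x[1], field_x[2]),
      y = stats::runif(ng, field_y[1], field_y[2]),
      z = stats::rnorm(ng, 0, spec$ground_roughness)
    )
    add(ground, CLASS_GROUND)
  }

  plants <- tibble::tibble(
    plant_id = integer(), x = double(), y = double(), z = double(),
    axis_x = double(), axis_y = double(), axis_z = double(),
    radius = double(), junction_height = double()
  )
  poles <- tibble::tibble(plant_id = integer(), x = double(), y = double(),
                          radius = double())
  patches <- tibble::tibble(x = double(), y = double(), z = double())

  if (n_plants > 0) {
    grid <- expand.grid(row = seq_len(spec$n_rows), col = seq_len(spec$n_cols))
    for (i in seq_len(n_plants)) {
      base <- c(
        (grid$col[i] - 1) * spec$spacing + stats::runif(1, -1, 1) * spec$jitter,
        (grid$row[i] - 1) * spec$spacing + stats::runif(1, -1, 1) * spec$jitter,
        0
      )
      radius <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
      hgt <- stats::runif(1, spec$height_range[1], spec$height_range[2])
      tilt <- stats::runif(1, 0, spec$tilt_max) * pi / 180
      azim <- stats::runif(1, 0, 2 * pi)
      axis <- c(sin(tilt) * cos(azim), sin(tilt) * sin(azim), cos(tilt))

      add(sample_cylinder(base, axis, radius, hgt, spec$point_spacing),
          CLASS_STEM, i)

      attach <- base + hgt * axis
      leaf_az <- seq(0, 2 * pi, length.out = spec$n_leaves_per_plant + 1)
      leaf_az <- leaf_az[-length(leaf_az)] +
        stats::runif(spec$n_leaves_per_plant, -0.2, 0.2)
      for (a in leaf_az) {
        add(sample_leaf_blade(attach, c(cos(a), sin(a), 0), spec$canopy_span,
                              spec$leaf_width, spec$leaf_droop,
                              spec$point_spacing),
            CLASS_LEAF, i)
      }

      if (stats::runif(1) < spec$petiole_prob) {
        below <- stats::runif(1, 0.1, 0.4)
        pa <- stats::runif(1, 0, 2 * pi)
        pat <- base + (hgt - below) * axis +
          radius * c(cos(pa), sin(pa), 0)
        add(sample_leaf_blade(pat, c(cos(pa), sin(pa), 0), 0.5, 0.10, 0.8,
                              spec$point_spacing),
            CLASS_PETIOLE, i)
      }

      if (stats::runif(1) < spec$pole_prob) {
        po_az <- stats::runif(1, 0, 2 * pi)
        po_base <- base + stats::runif(1, 0.35, 0.45) *
          c(cos(po_az), sin(po_az), 0)
        po_tilt <- stats::runif(1, 0, 2) * pi / 180
        po_azim <- stats::runif(1, 0, 2 * pi)
        po_axis <- c(sin(po_tilt) * cos(po_azim), sin(po_tilt) * sin(po_azim),
                     cos(po_tilt))
        add(sample_cylinder(po_base, po_axis, spec$pole_radius,
                            hgt * stats::runif(1, 0.9, 1.05),
                            spec$point_spacing),
            CLASS_POLE, i)
        poles <- dplyr::bind_rows(poles, tibble::tibble(
          plant_id = i, x = po_base[1], y = po_base[2],
          radius = spec$pole_radius
        ))
      }

      plants <- dplyr::bind_rows(plants, tibble::tibble(
        plant_id = i, x = base[1], y = base[2], z = base[3],
        axis_x = axis[1], axis_y = axis[2], axis_z = axis[3],
        radius = radius, junction_height = hgt
      ))
    }

    # broken leaves: horizontal patches in canopy gaps, clear of the stems
    if (spec$broken_leaf_count > 0) {
      placed <- 0
      guard <- 0
      while (placed < spec$broken_leaf_count && guard < 200) {
        guard <- guard + 1
        cx <- stats::runif(1, field_x[1] + 0.5, field_x[2] - 0.5)
        cy <- stats::runif(1, field_y[1] + 0.5, field_y[2] - 0.5)
        if (nrow(plants) > 0 &&
            min(sqrt((plants$x - cx)^2 + (plants$y - cy)^2)) < 0.9) next
        cz <- stats::runif(1, 0.8, 1.3)
        yaw <- stats::runif(1, 0, 2 * pi)
        # banana-leaf sized: statistical filtering trims island edges, and
        # the surviving core must stay above the 0.6 m leaf threshold
        add(sample_patch(c(cx, cy, cz), yaw, 0.9, 0.5, spec$point_spacing),
            CLASS_BROKEN)
        patches <- dplyr::bind_rows(patches,
                                    tibble::tibble(x = cx, y = cy, z = cz))
        placed <- placed + 1
      }
    }
  }

  cloud <- if (length(parts) > 0) {
    as_pointcloud(dplyr::bind_rows(parts))
  } else {
    pointcloud(label = integer(), plant_id = integer())
  }

  n <- nrow(cloud)
  if (n > 0 && spec$noise_sigma > 0) {
    cloud$x <- cloud$x + stats::rnorm(n, 0, spec$noise_sigma)
    cloud$y <- cloud$y + stats::rnorm(n, 0, spec$noise_sigma)
    cloud$z <- cloud$z + stats::rnorm(n, 0, spec$noise_sigma)
  }
  if (n > 0 && spec$dropout > 0) {
    cloud <- cloud[stats::runif(n) >= spec$dropout, , drop = FALSE]
  }

  list(
    cloud = cloud,
    truth = list(
      plants = plants,
      poles = poles,
      broken_leaves = patches,
      plane = list(normal = c(0, 0, 1), offset = 0)
    )
  )
}
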