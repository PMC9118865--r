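#' Morphometry parameters
#'
#' Numeric controls for the per-plant diameter and height measurements: MLS
#' smoothing, RANSAC cylinder fitting, the near-axis retention slack, the
#' sliding-window junction scan, and the height sanity limit. The window
#' thickness `window_d` doubles as the slide step so windows are consecutive
#' non-overlapping slabs along the fitted stem axis, which keeps the
#' "longest run of flagged windows" well defined; the re-entry offset after
#' a spurious (petiole) run is fixed at `3 * window_d`.
#'
#' @param mls_radius MLS neighbourhood radius, metres.
#' @param mls_order MLS polynomial order (1 = plane, 2 = quadric).
#' @param cyl_dist cylinder RANSAC inlier tolerance, metres.
#' @param cyl_radius_bounds admissible cylinder radius range, metres;
#'   the default (0.04, 0.30) brackets banana pseudo-stems and excludes
#'   bamboo poles.
#' @param cyl_iters cylinder RANSAC iterations.
#' @param normals_k neighbours used for PCA surface normals.
#' @param axis_slack near-axis retention slack added to the stem radius,
#'   metres (the "r + 0.15 m" rule).
#' @param window_d sliding-window thickness and step, metres.
#' @param window_w width-slack threshold on the window extent sum, metres:
#'   a window is flagged as leafy when extent_x + extent_y > 4 r + window_w.
#' @param height_limit maximum credible pseudo-stem height, metres;
#'   measurements above it fail with status `exceeds_limit`.
#' @param seed RNG seed for the cylinder RANSAC.
#' @return A `morph_params` list.
#' @export
morph_params <- function(mls_radius = 0.05, mls_order = 2, cyl_dist = 0.01,
                         cyl_radius_bounds = c(0.04, 0.30), cyl_iters = 500,
                         normals_k = 10, axis_slack = 0.15, window_d = 0.05,
                         window_w = 0.10, height_limit = 5, seed = 1) {
  stopifnot(window_d > 0, window_w >= 0, mls_radius > 0,
            cyl_radius_bounds[1] < cyl_radius_bounds[2])
  structure(
    list(mls_radius = mls_radius, mls_order = mls_order, cyl_dist = cyl_dist,
         cyl_radius_bounds = cyl_radius_bounds, cyl_iters = cyl_iters,
         normals_k = normals_k, axis_slack = axis_slack, window_d = window_d,
         window_w = window_w, height_limit = height_limit, seed = seed),
    class = c("morph_params", "list")
  )
}

#' Construct a cylinder model
#'
#' Axis point, unit axis direction (canonically oriented with z >= 0) and
#' radius of a cylinder; the geometric carrier of a fitted pseudo-stem.
#'
#' @param axis_point a point on the axis, length-3 numeric.
#' @param axis_dir axis direction (normalised internally).
#' @param radius cylinder radius, metres (> 0).
#' @param inlier_count supporting point count (informational).
#' @return A `cylinder_model`.
#' @export
cylinder_model <- function(axis_point, axis_dir, radius, inlier_count = 0L) {
  stopifnot(radius > 0)
  axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
  if (axis_dir[3] < 0) axis_dir <- -axis_dir
  structure(
    list(axis_point = as.double(axis_point), axis_dir = as.double(axis_dir),
         radius = as.double(radius), inlier_count = as.integer(inlier_count)),
    class = "cylinder_model"
  )
}

new_cylinder_model <- cylinder_model

#' @export
print.cylinder_model <- function(x, ...) {
  cat(sprintf(
    "<cylinder_model> r = %.4f m, axis (%.3f, %.3f, %.3f) through (%.2f, %.2f, %.2f), %d inliers\n",
    x$radius, x$axis_dir[1], x$axis_dir[2], x$axis_dir[3],
    x$axis_point[1], x$axis_point[2], x$axis_point[3], x$inlier_count
  ))
  invisible(x)
}

#' Tidy a fitted cylinder
#'
#' @param x a `cylinder_model`.
#' @param ... unused.
#' @return One-row tibble with radius, diameter, axis point and direction.
#' @method tidy cylinder_model
#' @export
tidy.cylinder_model <- function(x, ...) {
  tibble::tibble(
    radius = x$radius, diameter = 2 * x$radius,
    axis_x = x$axis_dir[1], axis_y = x$axis_dir[2], axis_z = x$axis_dir[3],
    point_x = x$axis_point[1], point_y = x$axis_point[2],
    point_z = x$axis_point[3],
    inlier_count = x$inlier_count
  )
}

# distances from the rows of matrix m to the line (q, unit u)
point_line_dist <- function(m, q, u) {
  v <- sweep(m, 2, q)
  proj <- as.vector(v %*% u)
  w <- v - outer(proj, u)
  sqrt(rowSums(w^2))
}

# along-axis coordinate of points relative to the cylinder's axis point
axis_coord <- function(cloud, cyl) {
  m <- cloud_matrix(as_pointcloud(cloud))
  as.vector(sweep(m, 2, cyl$axis_point) %*% cyl$axis_dir)
}

# PCA surface normals from the neighbourhood within `radius` of each point
estimate_normals <- function(m, radius) {
  nb <- cpp_radius_neighbors(m, radius)
  n <- nrow(m)
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    idx <- nb[[i]]
    if (length(idx) < 3) next
    local <- m[idx, , drop = FALSE]
    ctr <- colMeans(local)
    cv <- crossprod(sweep(local, 2, ctr)) / length(idx)
    ev <- eigen(cv, symmetric = TRUE)
    out[i, ] <- ev$vectors[, 3]
  }
  out
}

#' Moving-least-squares smoothing
#'
#' Projects each point onto a polynomial surface fitted to its
#' radius-neighbourhood: a PCA plane (order 1) or a bivariate quadric over
#' the plane (order 2). Points whose neighbourhood is too small for the fit
#' pass through unchanged. Output has exactly one (moved) point per input
#' point; extra columns are preserved.
#'
#' @param cloud a point cloud tibble.
#' @param search_radius neighbourhood radius, metres.
#' @param poly_order 1 or 2.
#' @return The smoothed point cloud.
#' @export
mls_smooth <- function(cloud, search_radius = 0.05, poly_order = 2) {
  cloud <- as_pointcloud(cloud)
  if (search_radius <= 0) stop("mls_smooth: search_radius must be > 0")
  n <- nrow(cloud)
  if (n == 0) return(cloud)
  m <- cloud_matrix(cloud)
  nb <- cpp_radius_neighbors(m, search_radius)
  min_pts <- if (poly_order >= 2) 8 else 4
  out <- m
  for (i in seq_len(n)) {
    idx <- nb[[i]]
    if (length(idx) < min_pts) next
    local <- m[idx, , drop = FALSE]
    ctr <- colMeans(local)
    ev <- eigen(crossprod(sweep(local, 2, ctr)), symmetric = TRUE)
    e1 <- ev$vectors[, 1]
    e2 <- ev$vectors[, 2]
    nrm <- ev$vectors[, 3]
    cen <- sweep(local, 2, ctr)
    u <- as.vector(cen %*% e1)
    v <- as.vector(cen %*% e2)
    h <- as.vector(cen %*% nrm)
    X <- if (poly_order >= 2) cbind(1, u, v, u^2, u * v, v^2) else cbind(1, u, v)
    coef <- tryCatch(qr.coef(qr(X), h), error = function(e) NULL)
    if (is.null(coef) || anyNA(coef)) next
    p_cen <- m[i, ] - ctr
    pu <- sum(p_cen * e1)
    pv <- sum(p_cen * e2)
    ph <- if (poly_order >= 2) {
      sum(coef * c(1, pu, pv, pu^2, pu * pv, pv^2))
    } else {
      sum(coef * c(1, pu, pv))
    }
    out[i, ] <- ctr + pu * e1 + pv * e2 + ph * nrm
  }
  cloud$x <- out[, 1]
  cloud$y <- out[, 2]
  cloud$z <- out[, 3]
  cloud
}

# Gauss-Newton refinement of a near-vertical cylinder.
# Parameters: (a, b, x0, y0, r) with axis direction ~ (a, b, 1) and axis
# point (x0, y0, z_ref). Returns NULL when the initial axis is too far from
# vertical for this chart.
cylinder_gn <- function(m, init_point, init_dir, init_r, max_iter = 50) {
  if (abs(init_dir[3]) < 0.2) return(NULL)
  d <- init_dir / init_dir[3]
  z_ref <- mean(m[, 3])
  t0 <- (z_ref - init_point[3]) / init_dir[3]
  p0 <- init_point + t0 * init_dir
  theta <- c(d[1], d[2], p0[1], p0[2], init_r)

  resid <- function(th) {
    u <- c(th[1], th[2], 1)
    u <- u / sqrt(sum(u^2))
    point_line_dist(m, c(th[3], th[4], z_ref), u) - th[5]
  }

  r0 <- resid(theta)
  lambda <- 1e-8
  for (it in seq_len(max_iter)) {
    # numerical Jacobian, central differences
    J <- matrix(0, nrow(m), 5)
    for (j in 1:5) {
      hstep <- max(1e-7, 1e-7 * abs(theta[j]))
      tp <- theta; tp[j] <- tp[j] + hstep
      tm <- theta; tm[j] <- tm[j] - hstep
      J[, j] <- (resid(tp) - resid(tm)) / (2 * hstep)
    }
    g <- crossprod(J, r0)
    Hm <- crossprod(J)
    delta <- tryCatch(
      solve(Hm + lambda * diag(diag(Hm) + 1e-12), -g),
      error = function(e) NULL
    )
    if (is.null(delta)) break
    cand <- theta + as.vector(delta)
    r_new <- resid(cand)
    if (sum(r_new^2) <= sum(r0^2)) {
      moved <- max(abs(cand - theta))
      theta <- cand
      r0 <- r_new
      lambda <- max(lambda / 4, 1e-12)
      if (moved < 1e-12) break
    } else {
      lambda <- lambda * 10
      if (lambda > 1e6) break
    }
  }
  u <- c(theta[1], theta[2], 1)
  u <- u / sqrt(sum(u^2))
  list(axis_point = c(theta[3], theta[4], z_ref), axis_dir = u,
       radius = theta[5], rss = sum(r0^2))
}

#' RANSAC cylinder fitting
#'
#' Robustly fits a cylinder: PCA surface normals are estimated first, then
#' each RANSAC draw takes two points with normals, intersects the two
#' normal lines to propose an axis (direction = cross product of the
#' normals), and scores points by `|distance to axis - radius| <= dist`.
#' The best candidate with radius inside `radius_bounds` is refined by
#' damped Gauss-Newton least squares on its inliers. The returned axis has
#' a non-negative z-component.
#'
#' @param cloud a point cloud with at least 6 points.
#' @param dist inlier tolerance on the radial residual, metres.
#' @param radius_bounds admissible radius interval (closed), metres.
#' @param iters RANSAC iterations.
#' @param seed RNG seed.
#' @param normal_radius neighbourhood radius for normal estimation; default
#'   3x the cloud's mean nearest-neighbour spacing.
#' @param min_inlier_frac minimum fraction of points the winning cylinder
#'   must explain; below it the fit fails (distinguishes a real stem from,
#'   e.g., a bamboo pole that no in-bounds cylinder can describe).
#' @return A `cylinder_model`.
#' @export
ransac_cylinder <- function(cloud, dist = 0.01, radius_bounds = c(0.04, 0.30),
                            iters = 500, seed = 1, normal_radius = NULL,
                            min_inlier_frac = 0.5) {
  cloud <- as_pointcloud(cloud)
  n <- nrow(cloud)
  if (n < 6) stop("ransac_cylinder: need at least 6 points")
  m <- cloud_matrix(cloud)
  if (is.null(normal_radius)) {
    spacing <- mean(cpp_knn_mean_dist(m, 1L))
    normal_radius <- max(3 * spacing, 1e-6)
  }
  normals <- estimate_normals(m, normal_radius)
  ok_n <- which(stats::complete.cases(normals))
  if (length(ok_n) < 2) stop("ransac_cylinder: too few points with normals")

  local_rng(seed)
  best <- NULL
  best_count <- -1L
  for (i in seq_len(iters)) {
    idx <- ok_n[sample.int(length(ok_n), 2)]
    p1 <- m[idx[1], ]; n1 <- normals[idx[1], ]
    p2 <- m[idx[2], ]; n2 <- normals[idx[2], ]
    d3 <- cross3(n1, n2)
    nd <- sqrt(sum(d3^2))
    if (nd < 0.05) next # near-parallel normals pin no axis
    u <- d3 / nd
    # closest approach of the two normal lines
    b <- sum(n1 * n2)
    w0 <- p1 - p2
    d0 <- sum(n1 * w0)
    e0 <- sum(n2 * w0)
    denom <- 1 - b^2
    t1 <- (b * e0 - d0) / denom
    s1 <- (e0 - b * d0) / denom
    q <- ((p1 + t1 * n1) + (p2 + s1 * n2)) / 2
    r_cand <- mean(c(
      sqrt(sum(cross3(p1 - q, u)^2)),
      sqrt(sum(cross3(p2 - q, u)^2))
    ))
    if (r_cand < radius_bounds[1] || r_cand > radius_bounds[2]) next
    res <- point_line_dist(m, q, u) - r_cand
    cnt <- sum(abs(res) <= dist)
    if (cnt > best_count) {
      best_count <- cnt
      best <- list(q = q, u = u, r = r_cand)
    }
  }
  if (is.null(best) || best_count < max(6, ceiling(min_inlier_frac * n))) {
    stop("ransac_cylinder: no adequately supported candidate with ",
         "radius inside bounds (", radius_bounds[1], ", ", radius_bounds[2],
         ")")
  }

  inl <- abs(point_line_dist(m, best$q, best$u) - best$r) <= dist
  fit <- list(axis_point = best$q, axis_dir = best$u, radius = best$r)
  if (sum(inl) >= 6) {
    ref <- cylinder_gn(m[inl, , drop = FALSE], best$q, best$u, best$r)
    if (!is.null(ref) && ref$radius >= radius_bounds[1] &&
        ref$radius <= radius_bounds[2]) {
      fit <- ref
      inl <- abs(point_line_dist(m, fit$axis_point, fit$axis_dir) -
                   fit$radius) <= dist
    }
  }
  new_cylinder_model(fit$axis_point, fit$axis_dir, fit$radius, sum(inl))
}

#' Extract the fixed-height band clusters of one plant
#'
#' Band-extracts the plant's segment between `band_lo` and `band_hi` above
#' the plane, statistically filters it, and Euclidean-clusters the slice.
#' Normally one cluster survives; zero means the stem was occluded at the
#' fixed height (the plant is skipped downstream) and more than one means
#' the K-means segment actually holds several merged stems, each of which
#' is measured.
#'
#' @param segment a `plant_segment` (or a bare point cloud).
#' @param plane a `plane_model`.
#' @param params a [counting_params()].
#' @return List of band-cluster point clouds, largest first.
#' @export
extract_plant_band <- function(segment, plane, params = counting_params()) {
  cloud <- if (inherits(segment, "plant_segment")) segment$cloud else segment
  band <- extract_band(cloud, plane, params)
  clustered <- euclidean_cluster(band, tol = params$cluster_tol,
                                 min_size = params$min_cluster_size)
  if (nrow(clustered) == 0) return(list())
  lapply(sort(unique(clustered$cluster)), function(k) {
    dplyr::select(clustered[clustered$cluster == k, , drop = FALSE],
                  -dplyr::all_of("cluster"))
  })
}

#' Measure the pseudo-stem diameter of one band cluster
#'
#' MLS-smooths the fixed-height cluster, RANSAC-fits a cylinder and returns
#' twice the fitted radius.
#'
#' @param band_cluster one cluster from [extract_plant_band()].
#' @param params a [morph_params()].
#' @return Diameter in metres. The fitted `cylinder_model` is attached as
#'   attribute `"cylinder"`.
#' @export
measure_diameter <- function(band_cluster, params = morph_params()) {
  sm <- mls_smooth(band_cluster, search_radius = params$mls_radius,
                   poly_order = params$mls_order)
  cyl <- ransac_cylinder(sm, dist = params$cyl_dist,
                         radius_bounds = params$cyl_radius_bounds,
                         iters = params$cyl_iters, seed = params$seed)
  out <- 2 * cyl$radius
  attr(out, "cylinder") <- cyl
  out
}

# cylinder-fit one flanking slab, restricted near the band cluster's column
fit_slab <- function(plant_cloud, plane, lo, hi, center_xy, params) {
  h <- height_above_plane(plant_cloud, plane)
  slab <- plant_cloud[h >= lo & h <= hi, , drop = FALSE]
  if (nrow(slab) > 0) {
    near <- sqrt((slab$x - center_xy[1])^2 + (slab$y - center_xy[2])^2) <= 0.4
    slab <- slab[near, , drop = FALSE]
  }
  if (nrow(slab) < 12) return(NULL)
  sm <- mls_smooth(slab, search_radius = params$mls_radius,
                   poly_order = params$mls_order)
  cyl <- tryCatch(
    ransac_cylinder(sm, dist = params$cyl_dist,
                    radius_bounds = params$cyl_radius_bounds,
                    iters = params$cyl_iters, seed = params$seed),
    error = function(e) NULL
  )
  if (is.null(cyl)) return(NULL)
  # axis point at the slab's mid height
  s_mid <- mean(axis_coord(sm, cyl))
  list(cyl = cyl, center = cyl$axis_point + s_mid * cyl$axis_dir)
}

#' Estimate the pseudo-stem axis of one plant
#'
#' Cylinder-fits the two slabs flanking the fixed-height band (0.1 m below
#' and 0.1 m above it); the axis direction is the unit vector from the lower
#' fitted axis centre to the upper one and the axis point is the lower
#' centre. If either slab cannot be fitted, a single cylinder fit over the
#' combined 0.3 m slab is used instead; if that fails too the axis fit
#' fails.
#'
#' @param segment a `plant_segment` (or bare point cloud).
#' @param band_cluster the plant's band cluster (fixes the stem column when
#'   a segment holds several merged stems).
#' @param plane a `plane_model`.
#' @param cparams a [counting_params()] (for the band interval).
#' @param mparams a [morph_params()].
#' @param radius stem radius carried into the returned model (from the band
#'   fit); defaults to the slab fit's radius.
#' @return A `cylinder_model` whose axis is the stem axis.
#' @export
estimate_axis <- function(segment, band_cluster, plane,
                          cparams = counting_params(),
                          mparams = morph_params(), radius = NULL) {
  cloud <- if (inherits(segment, "plant_segment")) segment$cloud else segment
  cloud <- as_pointcloud(cloud)
  center_xy <- c(mean(band_cluster$x), mean(band_cluster$y))
  lo_fit <- fit_slab(cloud, plane, cparams$band_lo - 0.1, cparams$band_lo,
                     center_xy, mparams)
  hi_fit <- fit_slab(cloud, plane, cparams$band_hi, cparams$band_hi + 0.1,
                     center_xy, mparams)
  if (!is.null(lo_fit) && !is.null(hi_fit)) {
    dirv <- hi_fit$center - lo_fit$center
    nv <- sqrt(sum(dirv^2))
    if (nv > 1e-9) {
      r <- if (is.null(radius)) mean(c(lo_fit$cyl$radius, hi_fit$cyl$radius))
           else radius
      return(new_cylinder_model(lo_fit$center, dirv / nv, r,
                                lo_fit$cyl$inlier_count +
                                  hi_fit$cyl$inlier_count))
    }
  }
  # fallback: one fit over the whole 0.3 m slab
  comb <- fit_slab(cloud, plane, cparams$band_lo - 0.1, cparams$band_hi + 0.1,
                   center_xy, mparams)
  if (is.null(comb)) stop("estimate_axis: both slab fits failed")
  r <- if (is.null(radius)) comb$cyl$radius else radius
  new_cylinder_model(comb$center, comb$cyl$axis_dir, r,
                     comb$cyl$inlier_count)
}

#' Retain points near the stem axis
#'
#' Keeps the points whose distance to the infinite axis line is below
#' `r + slack` (the half-diameter + 0.15 m rule).
#'
#' @param cloud a point cloud tibble.
#' @param axis a `cylinder_model` giving the axis line.
#' @param r stem radius, metres.
#' @param slack additive slack, metres (default 0.15).
#' @return The filtered point cloud.
#' @export
filter_near_axis <- function(cloud, axis, r, slack = 0.15) {
  cloud <- as_pointcloud(cloud)
  if (nrow(cloud) == 0) return(cloud)
  d <- point_line_dist(cloud_matrix(cloud), axis$axis_point, axis$axis_dir)
  cloud[d < r + slack, , drop = FALSE]
}

#' Sliding-window detection of the leaf/pseudo-stem junction
#'
#' Partitions the along-axis range of the near-axis upper-stem cloud into
#' consecutive windows of thickness `d` starting at the lowest point. Each
#' window's X and Y extents a and b are compared with the bare-stem
#' footprint: a window is flagged leafy when `a + b > 4 r + w` (an empty
#' window is never flagged). The longest run of consecutive flagged windows
#' is selected (ties: the lowest run). If that run does not reach the
#' topmost non-empty window — a wilted petiole can produce a low spurious
#' run — the scan re-enters on the sub-cloud above the run start plus
#' `3 d` and iterates until the selected run reaches the top of the cloud
#' (at most 20 re-entries). Returns the along-axis start height of the
#' final run.
#'
#' @param upper_stem near-axis points from the band minimum upward.
#' @param axis a `cylinder_model` (stem axis).
#' @param r stem radius, metres.
#' @param params a [morph_params()] (`window_d`, `window_w`).
#' @return A list: `found` (logical), `junction_s` (along-axis start height
#'   of the junction run, relative to the axis point), `region` (points of
#'   the first flagged window plus the window below, for the upper
#'   projection) and `n_scans`.
#' @export
sliding_window_junction <- function(upper_stem, axis, r,
                                    params = morph_params()) {
  upper_stem <- as_pointcloud(upper_stem)
  d <- params$window_d
  w <- params$window_w
  thresh <- 4 * r + w

  s_all <- if (nrow(upper_stem) > 0) axis_coord(upper_stem, axis) else double()

  scan_once <- function(keep) {
    s <- s_all[keep]
    if (length(s) == 0) return(NULL)
    s0 <- min(s)
    win <- floor((s - s0) / d)
    n_win <- max(win) + 1
    idx_by_win <- split(which(keep)[order(win)], sort(win))
    flags <- rep(FALSE, n_win)
    occupied <- rep(FALSE, n_win)
    for (nm in names(idx_by_win)) {
      j <- as.integer(nm) + 1
      occupied[j] <- TRUE
      ii <- idx_by_win[[nm]]
      a <- max(upper_stem$x[ii]) - min(upper_stem$x[ii])
      b <- max(upper_stem$y[ii]) - min(upper_stem$y[ii])
      flags[j] <- (a + b) > thresh
    }
    list(s0 = s0, flags = flags, occupied = occupied)
  }

  keep <- rep(TRUE, nrow(upper_stem))
  found <- FALSE
  junction_s <- NA_real_
  n_scans <- 0L

  repeat {
    n_scans <- n_scans + 1L
    sc <- scan_once(keep)
    if (is.null(sc)) break
    runs <- rle(sc$flags)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    flagged <- which(runs$values)
    if (length(flagged) == 0) break
    # longest flagged run; ties -> the lowest
    best <- flagged[which.max(runs$lengths[flagged])]
    run_start <- starts[best]
    run_end <- ends[best]
    h <- sc$s0 + (run_start - 1) * d
    found <- TRUE
    junction_s <- h
    top_occ <- max(which(sc$occupied))
    if (run_end >= top_occ) break # the run reaches the cloud top: canopy
    if (n_scans >= 20) break
    new_keep <- keep & (s_all > h + 3 * d)
    if (sum(new_keep) < 2 || sum(new_keep) == sum(keep)) break
    keep <- new_keep
  }

  region <- if (found) {
    upper_stem[s_all >= junction_s - d & s_all < junction_s + d, ,
               drop = FALSE]
  } else {
    upper_stem[0, , drop = FALSE]
  }
  list(found = found, junction_s = junction_s, region = region,
       n_scans = n_scans)
}

#' Project the junction's highest point onto the stem axis
#'
#' Takes the largest-z point of the junction region and returns its signed
#' along-axis coordinate relative to the axis point (the upper pseudo-stem
#' length). The radial component of the point is orthogonal to the axis and
#' drops out of the projection.
#'
#' @param junction_region near-axis points in the junction window(s).
#' @param axis a `cylinder_model`.
#' @return Upper length in metres.
#' @export
upper_projection <- function(junction_region, axis) {
  junction_region <- as_pointcloud(junction_region)
  if (nrow(junction_region) == 0) stop("upper_projection: empty region")
  p_max <- junction_region[which.max(junction_region$z), , drop = FALSE]
  axis_coord(p_max, axis)
}

#' Locate the ground junction of the pseudo-stem
#'
#' Retains the ground points within `r + slack` of the axis line (the stem
#' foot) and projects the smallest-z retained point onto the axis: the
#' signed lower pseudo-stem length.
#'
#' @param ground_patch the plant's ground patch.
#' @param axis a `cylinder_model`.
#' @param r stem radius, metres.
#' @param slack additive slack, metres.
#' @return Lower length in metres (negative when the axis point sits above
#'   the ground under the canonical upward axis).
#' @export
ground_junction <- function(ground_patch, axis, r, slack = 0.15) {
  near <- filter_near_axis(ground_patch, axis, r, slack)
  if (nrow(near) == 0) stop("ground_junction: no ground point near the axis")
  p_min <- near[which.min(near$z), , drop = FALSE]
  axis_coord(p_min, axis)
}

#' Measure pseudo-stem height (and diameter) of one plant
#'
#' Full per-plant morphometry: extract the fixed-height band cluster(s),
#' measure the diameter of each by cylinder segmentation, estimate the stem
#' axis from the flanking slabs, retain near-axis points above the band
#' minimum, detect the leaf junction with the sliding-window scan, project
#' the junction's top point and the lowest near-axis ground point onto the
#' axis, and report `H = |upper - lower|`. Heights above the limit fail
#' with status `exceeds_limit`; a missing junction gives `no_junction`.
#' All failures are statuses, never errors, so field-level batches
#' complete.
#'
#' @param segment a `plant_segment` from [split_plants()].
#' @param plane a `plane_model`.
#' @param cparams a [counting_params()].
#' @param mparams a [morph_params()].
#' @return A tibble with one row per band cluster of the segment (a single
#'   `no_band` row when none): plant_id, band cluster index and centroid,
#'   `diameter_m`, `junction_height` (junction z), `upper_length`,
#'   `lower_length`, `height_m` and `status`.
#' @export
measure_height <- function(segment, plane, cparams = counting_params(),
                           mparams = morph_params()) {
  empty_row <- function(status, band_idx = NA_integer_,
                        bx = NA_real_, by = NA_real_) {
    tibble::tibble(
      plant_id = segment$plant_id, band = band_idx, x = bx, y = by,
      diameter_m = NA_real_, junction_height = NA_real_,
      upper_length = NA_real_, lower_length = NA_real_,
      height_m = NA_real_, status = status
    )
  }
  bands <- extract_plant_band(segment, plane, cparams)
  if (length(bands) == 0) return(empty_row("no_band"))

  purrr::map_dfr(seq_along(bands), function(bi) {
    b <- bands[[bi]]
    bx <- mean(b$x)
    by <- mean(b$y)
    dia <- tryCatch(measure_diameter(b, mparams), error = function(e) NULL)
    if (is.null(dia)) return(empty_row("fit_failed", bi, bx, by))
    r <- as.numeric(dia) / 2
    axis <- tryCatch(
      estimate_axis(segment, b, plane, cparams, mparams, radius = r),
      error = function(e) NULL
    )
    if (is.null(axis)) {
      out <- empty_row("axis_failed", bi, bx, by)
      out$diameter_m <- as.numeric(dia)
      return(out)
    }
    near <- filter_near_axis(segment$cloud, axis, r, mparams$axis_slack)
    upper_stem <- near[near$z >= min(b$z), , drop = FALSE]
    sw <- sliding_window_junction(upper_stem, axis, r, mparams)
    if (!sw$found) {
      out <- empty_row("no_junction", bi, bx, by)
      out$diameter_m <- as.numeric(dia)
      return(out)
    }
    upper_len <- upper_projection(sw$region, axis)
    lower_len <- tryCatch(
      ground_junction(segment$ground_patch, axis, r, mparams$axis_slack),
      error = function(e) NULL
    )
    if (is.null(lower_len)) {
      out <- empty_row("ground_failed", bi, bx, by)
      out$diameter_m <- as.numeric(dia)
      return(out)
    }
    H <- abs(upper_len - lower_len)
    status <- if (H > mparams$height_limit) "exceeds_limit" else "ok"
    tibble::tibble(
      plant_id = segment$plant_id, band = bi, x = bx, y = by,
      diameter_m = as.numeric(dia),
      junction_height = axis$axis_point[3] + sw$junction_s * axis$axis_dir[3],
      upper_length = upper_len, lower_length = lower_len,
      height_m = if (status == "ok") H else NA_real_,
      status = status
    )
  })
}
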