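# shared fixtures and independent oracles for the test suite

# cache for expensive scene/pipeline computations shared between test files
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# exact cylinder surface sample with optional Gaussian noise (independent of
# the package generator, for fitting tests)
make_cylinder <- function(n, base = c(0, 0, 0), axis = c(0, 0, 1), r = 0.1,
                          len = 1, sigma = 0, seed = 1) {
  set.seed(seed)
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(ref[2] * axis[3] - ref[3] * axis[2],
         ref[3] * axis[1] - ref[1] * axis[3],
         ref[1] * axis[2] - ref[2] * axis[1])
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  t <- runif(n, 0, len)
  phi <- runif(n, 0, 2 * pi)
  m <- matrix(base, n, 3, byrow = TRUE) + outer(t, axis) +
    r * (outer(cos(phi), u) + outer(sin(phi), v))
  if (sigma > 0) m <- m + matrix(rnorm(3 * n, 0, sigma), n, 3)
  pointcloud(x = m[, 1], y = m[, 2], z = m[, 3])
}

# O(n^2) union-find over all point pairs: the clustering oracle
brute_cluster <- function(cloud, tol) {
  n <- nrow(cloud)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  m <- cbind(cloud$x, cloud$y, cloud$z)
  d <- as.matrix(dist(m))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] <= tol) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# canonical form of a partition: sorted list of sorted member index sets
canonical_partition <- function(ids, index) {
  parts <- unname(lapply(split(index, ids), sort))
  parts[order(vapply(parts, min, numeric(1)))]
}

# direct nonlinear least-squares cylinder fit over ALL points (no RANSAC,
# no Gauss-Newton reuse): the fitting oracle. Near-vertical chart.
nls_cylinder_oracle <- function(cloud, init_r = 0.1) {
  m <- cbind(cloud$x, cloud$y, cloud$z)
  z_ref <- mean(m[, 3])
  obj <- function(th) {
    u <- c(th[1], th[2], 1)
    u <- u / sqrt(sum(u^2))
    q <- c(th[3], th[4], z_ref)
    v <- sweep(m, 2, q)
    proj <- as.vector(v %*% u)
    w <- v - outer(proj, u)
    sum((sqrt(rowSums(w^2)) - th[5])^2)
  }
  init <- c(0, 0, mean(m[, 1]), mean(m[, 2]), init_r)
  fit <- optim(init, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  fit2 <- optim(fit$par, obj, method = "BFGS",
                control = list(maxit = 500, reltol = 1e-14,
                               ndeps = rep(1e-8, 5)))
  list(radius = fit2$par[5], par = fit2$par, value = fit2$value)
}

# a minimal single-plant segment: tilted or vertical stem on a flat ground
# patch, leaf disc at the stem top, optional petiole patch
make_plant_segment <- function(stem_h = 2.2, r = 0.11, axis = c(0, 0, 1),
                               leaf = TRUE, petiole_at = NA, seed = 7,
                               spacing = 0.025, sigma = 0) {
  set.seed(seed)
  axis <- axis / sqrt(sum(axis^2))
  stem <- make_cylinder(ceiling(2 * pi * r * stem_h / spacing^2),
                        axis = axis, r = r, len = stem_h, sigma = sigma,
                        seed = seed)
  parts <- list(stem)
  if (leaf) {
    attach <- stem_h * axis
    for (a in seq(0, 2 * pi, length.out = 9)[-9]) {
      parts[[length(parts) + 1]] <- sample_leaf_blade(
        attach, c(cos(a), sin(a), 0), span = 1.5, width = 0.3,
        droop = 0.12, point_spacing = spacing
      )
    }
  }
  if (!is.na(petiole_at)) {
    pa <- 0.3
    att <- petiole_at * axis + r * c(cos(pa), sin(pa), 0)
    parts[[length(parts) + 1]] <- sample_leaf_blade(
      att, c(cos(pa), sin(pa), 0), span = 0.5, width = 0.1, droop = 0.8,
      point_spacing = spacing / 2
    )
  }
  cloud <- as_pointcloud(dplyr::bind_rows(parts))
  if (sigma > 0) {
    cloud$x <- cloud$x + rnorm(nrow(cloud), 0, sigma)
    cloud$y <- cloud$y + rnorm(nrow(cloud), 0, sigma)
    cloud$z <- cloud$z + rnorm(nrow(cloud), 0, sigma)
  }
  g <- expand.grid(x = seq(-1, 1, by = 0.03), y = seq(-1, 1, by = 0.03))
  ground <- pointcloud(x = g$x, y = g$y, z = rnorm(nrow(g), 0, 0.003))
  structure(
    list(plant_id = 1L, cloud = cloud, ground_patch = ground,
         seed = c(x = 0, y = 0)),
    class = "plant_segment"
  )
}

flat_plane <- function() plane_model(c(0, 0, 1), 0, 0L)
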