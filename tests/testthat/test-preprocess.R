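test_that("pass_filter keeps exactly the closed-interval points in order", {
  cl <- pointcloud(x = 1:3, y = 1:3, z = c(0, 1, 2))
  expect_equal(pass_filter(cl, "z", 0.5, 1.5)$z, 1)
  expect_equal(pass_filter(cl, "z", -10, 10), cl)
  expect_error(pass_filter(cl, "z", 2, 1), "lo > hi")

  set.seed(3)
  r <- pointcloud(x = runif(300), y = runif(300), z = runif(300))
  got <- pass_filter(r, "x", 0.2, 0.7)
  want <- r[r$x >= 0.2 & r$x <= 0.7, ]
  expect_equal(got, want)
})

test_that("voxel_downsample returns occupied-voxel centroids", {
  rep_pt <- pointcloud(x = rep(1.23, 1000), y = rep(4.56, 1000),
                       z = rep(0.78, 1000))
  one <- voxel_downsample(rep_pt, 0.008)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$x, one$y, one$z), c(1.23, 4.56, 0.78))

  two <- voxel_downsample(pointcloud(x = c(0, 1), y = c(0, 0), z = c(0, 0)),
                          0.008)
  expect_equal(nrow(two), 2)

  # occupied-voxel count against an independent voxel hash
  set.seed(8)
  g <- expand.grid(x = seq(0, 0.02, by = 0.002),
                   y = seq(0, 0.02, by = 0.002),
                   z = seq(0, 0.02, by = 0.002))
  cl <- as_pointcloud(g)
  leaf <- 0.008
  n_occupied <- nrow(unique(floor(g / leaf)))
  out <- voxel_downsample(cl, leaf)
  expect_equal(nrow(out), n_occupied)
  # every output point lies within half a voxel diagonal of an input point
  dmin <- apply(cbind(out$x, out$y, out$z), 1, function(p) {
    min(sqrt((g$x - p[1])^2 + (g$y - p[2])^2 + (g$z - p[3])^2))
  })
  expect_true(all(dmin <= leaf * sqrt(3) / 2 + 1e-12))
})

test_that("statistical outlier removal drops isolated points and partitions", {
  set.seed(10)
  blob <- pointcloud(x = rnorm(200, 0, 0.05), y = rnorm(200, 0, 0.05),
                     z = rnorm(200, 0, 0.05))
  lone <- pointcloud(x = 5, y = 5, z = 5)
  cl <- dplyr::bind_rows(blob, lone)
  res <- statistical_outlier_removal(cl, k = 10, std_mult = 1.0)
  expect_equal(nrow(res$kept) + nrow(res$removed), nrow(cl))
  expect_true(any(res$removed$x == 5))

  # on a uniform grid every nearest-neighbour distance equals the pitch, so
  # with k = 1 all mean distances are identical and nothing is removed
  grid <- as_pointcloud(expand.grid(x = seq(0, 1, 0.1), y = seq(0, 1, 0.1),
                                    z = 0))
  unif <- statistical_outlier_removal(grid, k = 1, std_mult = 1)
  expect_equal(nrow(unif$removed), 0)

  # std_mult -> Inf removes nothing
  inf <- statistical_outlier_removal(cl, k = 10, std_mult = 1e9)
  expect_equal(nrow(inf$removed), 0)
  expect_error(statistical_outlier_removal(lone, k = 5), "more than k")
})

test_that("knn mean distances match a brute-force computation", {
  set.seed(12)
  cl <- pointcloud(x = runif(80), y = runif(80), z = runif(80))
  m <- cbind(cl$x, cl$y, cl$z)
  got <- stalkscan:::cpp_knn_mean_dist(m, 5L)
  d <- as.matrix(dist(m))
  want <- vapply(seq_len(80), function(i) {
    mean(sort(d[i, -i])[1:5])
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("ransac_plane recovers planes and splits ground from plants", {
  set.seed(2)
  ground <- pointcloud(x = runif(500, 0, 10), y = runif(500, 0, 10), z = 0)
  plants <- pointcloud(x = runif(200, 0, 10), y = runif(200, 0, 10),
                       z = runif(200, 0.5, 3))
  res <- ransac_plane(dplyr::bind_rows(ground, plants), dist = 0.03,
                      iters = 400, seed = 5)
  ang <- acos(min(1, sum(res$plane$normal * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 1)
  expect_gte(nrow(res$ground), 500)
  expect_true(all(res$nonground$z > 0.4))

  flat <- pointcloud(x = runif(100), y = runif(100), z = 1)
  rf <- ransac_plane(flat, seed = 1)
  expect_equal(rf$plane$offset, -1, tolerance = 1e-9)
  expect_equal(nrow(rf$nonground), 0)
  expect_identical(ransac_plane(flat, seed = 3)$plane,
                   ransac_plane(flat, seed = 3)$plane)
})

test_that("a tilted noisy plane is recovered within 2 degrees across seeds", {
  true_n <- c(0, 0.1, 1)
  true_n <- true_n / sqrt(sum(true_n^2))
  worst <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    x <- runif(600, 0, 10)
    y <- runif(600, 0, 10)
    z <- (-true_n[1] * x - true_n[2] * y) / true_n[3] + rnorm(600, 0, 0.002)
    res <- ransac_plane(pointcloud(x = x, y = y, z = z), dist = 0.02,
                        iters = 300, seed = s)
    ang <- acos(min(1, abs(sum(res$plane$normal * true_n)))) * 180 / pi
    worst <- max(worst, ang)
  }
  expect_lt(worst, 2)
})

test_that("height_above_plane is the signed plane distance", {
  pl <- plane_model(c(0, 0, 1), 0)
  expect_equal(height_above_plane(pointcloud(0, 0, 1.05), pl), 1.05)
  expect_equal(height_above_plane(pointcloud(3, -2, 0), pl), 0)

  set.seed(4)
  n <- c(0.2, -0.3, 0.9)
  pl2 <- plane_model(n, 0.7)
  p <- pointcloud(x = rnorm(20), y = rnorm(20), z = rnorm(20))
  want <- (cbind(p$x, p$y, p$z) %*% (n / sqrt(sum(n^2))))[, 1] +
    0.7 / sqrt(sum(n^2))
  expect_equal(height_above_plane(p, pl2), want, tolerance = 1e-12)
})
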