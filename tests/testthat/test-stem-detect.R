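test_that("extract_band follows the plane, not raw z", {
  set.seed(21)
  stem <- make_cylinder(3000, r = 0.1, len = 2.2, seed = 21)
  flat_band <- extract_band(stem, flat_plane(),
                            counting_params(band_sor_k = 10))
  expect_true(all(flat_band$z >= 1.0 & flat_band$z <= 1.1))
  expect_gt(nrow(flat_band), 50)

  # rotate scene and plane together: the band must follow the plane distance
  ang <- 5 * pi / 180
  R <- matrix(c(1, 0, 0, 0, cos(ang), -sin(ang), 0, sin(ang), cos(ang)),
              3, 3, byrow = TRUE)
  m <- cbind(stem$x, stem$y, stem$z) %*% t(R)
  rot <- pointcloud(x = m[, 1], y = m[, 2], z = m[, 3])
  n_rot <- as.vector(R %*% c(0, 0, 1))
  rot_band <- extract_band(rot, plane_model(n_rot, 0),
                           counting_params(band_sor_k = 10))
  h <- m %*% n_rot
  expect_equal(nrow(rot_band),
               nrow(extract_band(stem, flat_plane(),
                                 counting_params(band_sor_k = 10))))

  expect_equal(nrow(extract_band(pointcloud(), flat_plane())), 0)
})

test_that("euclidean_cluster matches the O(n^2) union-find oracle", {
  for (s in 1:4) {
    set.seed(s)
    n <- 300
    cl <- pointcloud(x = runif(n), y = runif(n), z = runif(n))
    cl$idx <- seq_len(n)
    got <- euclidean_cluster(cl, tol = 0.12, min_size = 1)
    oracle <- brute_cluster(cl, 0.12)
    expect_equal(canonical_partition(got$cluster, got$idx),
                 canonical_partition(oracle, seq_len(n)))
  }
})

test_that("euclidean_cluster separates blobs, chains chains, drops specks", {
  set.seed(30)
  b1 <- pointcloud(x = rnorm(50, 0, 0.02), y = rnorm(50, 0, 0.02), z = 0)
  b2 <- pointcloud(x = rnorm(50, 0.5, 0.02), y = rnorm(50, 0, 0.02), z = 0)
  two <- euclidean_cluster(dplyr::bind_rows(b1, b2), tol = 0.10, min_size = 1)
  expect_equal(length(unique(two$cluster)), 2)

  chain <- pointcloud(x = seq(0, 1, by = 0.05), y = 0, z = 0)
  one <- euclidean_cluster(chain, tol = 0.10, min_size = 1)
  expect_equal(unique(one$cluster), 1L)

  specks <- euclidean_cluster(dplyr::bind_rows(b1, pointcloud(5, 5, 5)),
                              tol = 0.10, min_size = 5)
  expect_equal(nrow(specks), 50) # the lone point is discarded

  # cluster ids are ordered by descending size
  sz <- table(two$cluster)
  expect_true(all(diff(as.vector(sz)) <= 0))
})

test_that("shrinking the tolerance only refines clusters", {
  set.seed(31)
  cl <- pointcloud(x = runif(200, 0, 2), y = runif(200, 0, 2), z = 0)
  cl$idx <- seq_len(200)
  fine <- euclidean_cluster(cl, tol = 0.06, min_size = 1)
  coarse <- euclidean_cluster(cl, tol = 0.15, min_size = 1)
  # each fine cluster must sit entirely inside one coarse cluster
  coarse_of <- coarse$cluster[match(fine$idx, coarse$idx)]
  per_fine <- split(coarse_of, fine$cluster)
  expect_true(all(vapply(per_fine, function(v) length(unique(v)) == 1,
                         logical(1))))
})

test_that("clusters classify as pole / stem / leaf by extent sum", {
  params <- counting_params()
  mk <- function(ex, ey) {
    pointcloud(x = c(0, ex, 0, ex), y = c(0, 0, ey, ey), z = 1)
  }
  expect_equal(classify_cluster(mk(0.15, 0.15), params)$label, "stem")
  expect_equal(classify_cluster(mk(0.04, 0.05), params)$label, "pole")
  expect_equal(classify_cluster(mk(0.50, 0.40), params)$label, "leaf")
  # closed boundaries
  expect_equal(classify_cluster(mk(0.10, 0.15), params)$label, "stem") # 0.25
  expect_equal(classify_cluster(mk(0.30, 0.30), params)$label, "stem") # 0.60
  expect_equal(classify_cluster(mk(0.10, 0.1499), params)$label, "pole")
  expect_error(classify_cluster(pointcloud(), params), "empty")
})

test_that("count_plants recovers K on a clean synthetic plot", {
  sc <- cached("scene_clean", generate_scene(
    scene_spec(noise_sigma = 0, dropout = 0, seed = 40)
  ))
  band <- extract_band(sc$cloud, plane_model(c(0, 0, 1), 0))
  cnt <- count_plants(band)
  expect_equal(cnt$K, 9)
  ev <- evaluate_count(cnt$seeds, sc$truth)
  expect_equal(ev$precision, 100)
  expect_equal(ev$recall, 100)

  empty <- count_plants(pointcloud())
  expect_equal(empty$K, 0L)
  expect_equal(nrow(empty$seeds), 0)
})

test_that("counting is robust to 30% dropout across noise seeds", {
  for (s in c(51, 52, 53)) {
    sc <- generate_scene(scene_spec(dropout = 0.3, seed = s))
    cnt <- count_plants(extract_band(sc$cloud, plane_model(c(0, 0, 1), 0)))
    expect_equal(cnt$K, 9)
  }
})

test_that("band clusters partition the eligible points with unique labels", {
  sc <- cached("scene_clean", generate_scene(
    scene_spec(noise_sigma = 0, dropout = 0, seed = 40)
  ))
  band <- extract_band(sc$cloud, plane_model(c(0, 0, 1), 0))
  cnt <- count_plants(band)
  clustered <- cnt$clustered
  expect_false(any(duplicated(clustered[, c("x", "y", "z")])))
  expect_equal(sort(unique(clustered$cluster)),
               seq_len(nrow(cnt$clusters)))
  expect_true(all(cnt$clusters$label %in% c("stem", "pole", "leaf")))
  expect_equal(cnt$clusters$extent_sum,
               cnt$clusters$extent_x + cnt$clusters$extent_y)
})
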