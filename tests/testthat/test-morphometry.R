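test_that("MLS leaves planar clouds untouched and denoises cylinders", {
  set.seed(80)
  plane_pts <- pointcloud(x = runif(300, 0, 0.3), y = runif(300, 0, 0.3),
                          z = 0.5)
  sm <- mls_smooth(plane_pts, search_radius = 0.05, poly_order = 2)
  expect_equal(cbind(sm$x, sm$y, sm$z),
               cbind(plane_pts$x, plane_pts$y, plane_pts$z),
               tolerance = 1e-9)

  expect_equal(nrow(mls_smooth(pointcloud())), 0)

  noisy <- make_cylinder(3000, r = 0.12, len = 0.5, sigma = 0.003, seed = 81)
  sm2 <- mls_smooth(noisy, search_radius = 0.05, poly_order = 2)
  rms <- function(cl) {
    sqrt(mean((sqrt(cl$x^2 + cl$y^2) - 0.12)^2))
  }
  expect_lt(rms(sm2), rms(noisy))
})

test_that("ransac_cylinder is exact on noise-free data", {
  exact <- make_cylinder(2000, r = 0.10, len = 1, seed = 82)
  cyl <- ransac_cylinder(exact, dist = 0.01, seed = 1)
  expect_equal(cyl$radius, 0.10, tolerance = 1e-6)
  ang <- acos(min(1, cyl$axis_dir[3])) * 180 / pi
  expect_lt(ang, 0.1)
  # bit-reproducible for a fixed seed
  expect_identical(cyl, ransac_cylinder(exact, dist = 0.01, seed = 1))
})

test_that("ransac_cylinder matches the NLS oracle on noisy data", {
  noisy <- make_cylinder(2000, r = 0.12, len = 0.5, sigma = 0.002, seed = 83)
  cyl <- ransac_cylinder(noisy, dist = 0.01, seed = 2)
  expect_lt(abs(cyl$radius - 0.12), 0.004)
  oracle <- nls_cylinder_oracle(noisy, init_r = 0.12)
  expect_lt(abs(cyl$radius - oracle$radius), 1e-3)
})

test_that("ransac_cylinder rejects planar contamination", {
  set.seed(84)
  stem <- make_cylinder(1400, r = 0.12, len = 0.5, sigma = 0.002, seed = 84)
  leaf <- pointcloud(x = runif(600, 0.1, 0.8), y = runif(600, -0.3, 0.3),
                     z = runif(600, 0, 0.5))
  cyl <- ransac_cylinder(dplyr::bind_rows(stem, leaf), dist = 0.008,
                         seed = 3)
  expect_lt(abs(cyl$radius - 0.12), 0.01)
})

test_that("ransac_cylinder enforces its radius bounds", {
  pole <- make_cylinder(500, r = 0.015, len = 0.5, seed = 85)
  expect_error(
    ransac_cylinder(pole, dist = 0.005, radius_bounds = c(0.04, 0.30),
                    seed = 1),
    "radius inside bounds"
  )
  expect_error(ransac_cylinder(pointcloud(1:3, 1:3, 1:3)), "at least 6")
})

test_that("measure_diameter recovers the stem diameter from a band cluster", {
  seg <- make_plant_segment(stem_h = 2.2, r = 0.11, sigma = 0.002, seed = 86)
  bands <- extract_plant_band(seg, flat_plane())
  expect_equal(length(bands), 1)
  d <- measure_diameter(bands[[1]])
  expect_equal(as.numeric(d), 0.22, tolerance = 0.002 / 0.22)
  expect_s3_class(attr(d, "cylinder"), "cylinder_model")
})

test_that("a merged two-stem segment yields two band clusters", {
  seg1 <- make_plant_segment(stem_h = 2.0, r = 0.10, seed = 87)
  seg2 <- make_plant_segment(stem_h = 2.4, r = 0.12, seed = 88)
  seg2$cloud$x <- seg2$cloud$x + 2.5
  merged <- seg1
  merged$cloud <- dplyr::bind_rows(seg1$cloud, seg2$cloud)
  bands <- extract_plant_band(merged, flat_plane())
  expect_equal(length(bands), 2)

  # fully occluded band: no clusters, plant skipped
  occluded <- seg1
  occluded$cloud <- occluded$cloud[occluded$cloud$z < 0.9 |
                                     occluded$cloud$z > 1.2, ]
  expect_equal(length(extract_plant_band(occluded, flat_plane())), 0)
})

test_that("estimate_axis recovers vertical and tilted stem axes", {
  seg <- make_plant_segment(stem_h = 2.2, r = 0.11, sigma = 0.002, seed = 89)
  b <- extract_plant_band(seg, flat_plane())[[1]]
  axis <- estimate_axis(seg, b, flat_plane(), radius = 0.11)
  ang <- acos(min(1, axis$axis_dir[3])) * 180 / pi
  expect_lt(ang, 0.5)

  tilt <- 5 * pi / 180
  dir5 <- c(sin(tilt), 0, cos(tilt))
  seg5 <- make_plant_segment(stem_h = 2.2, r = 0.11, axis = dir5,
                             sigma = 0.002, seed = 90)
  b5 <- extract_plant_band(seg5, flat_plane())[[1]]
  axis5 <- estimate_axis(seg5, b5, flat_plane(), radius = 0.11)
  got_tilt <- acos(min(1, axis5$axis_dir[3])) * 180 / pi
  expect_lt(abs(got_tilt - 5), 1)
})

test_that("estimate_axis falls back to a combined slab when one is missing", {
  seg <- make_plant_segment(stem_h = 2.2, r = 0.11, sigma = 0.002, seed = 91)
  # delete the upper flanking slab [1.1, 1.2]
  seg$cloud <- seg$cloud[seg$cloud$z < 1.1 | seg$cloud$z > 1.2, ]
  b <- extract_plant_band(seg, flat_plane())[[1]]
  axis <- expect_no_error(estimate_axis(seg, b, flat_plane(), radius = 0.11))
  ang <- acos(min(1, axis$axis_dir[3])) * 180 / pi
  expect_lt(ang, 2)
})

test_that("filter_near_axis equals the brute-force point-to-line filter", {
  set.seed(92)
  cl <- pointcloud(x = runif(500, -1, 1), y = runif(500, -1, 1),
                   z = runif(500, 0, 3))
  ax <- cylinder_model(c(0.1, -0.2, 0), c(0.05, 0.02, 1), 0.1)
  got <- filter_near_axis(cl, ax, r = 0.1, slack = 0.15)
  u <- ax$axis_dir
  v <- cbind(cl$x - ax$axis_point[1], cl$y - ax$axis_point[2],
             cl$z - ax$axis_point[3])
  proj <- v %*% u
  d <- sqrt(rowSums((v - proj %*% t(u))^2))
  expect_equal(got, cl[d < 0.25, ])

  # stem surface kept, canopy tip removed
  ax0 <- cylinder_model(c(0, 0, 0), c(0, 0, 1), 0.1)
  near <- filter_near_axis(pointcloud(0.1, 0, 1), ax0, 0.1)
  expect_equal(nrow(near), 1)
  far <- filter_near_axis(pointcloud(1.0, 0, 2), ax0, 0.1)
  expect_equal(nrow(far), 0)
})

test_that("sliding window finds the canopy junction and skips petioles", {
  ax <- cylinder_model(c(0, 0, 0), c(0, 0, 1), 0.1)

  # bare stem: nothing flagged
  bare <- make_cylinder(3000, r = 0.10, len = 1.2, base = c(0, 0, 1),
                        seed = 93)
  res0 <- sliding_window_junction(bare, ax, r = 0.10)
  expect_false(res0$found)

  # canopy from 2.2 m: junction within one window of the truth
  seg <- make_plant_segment(stem_h = 2.2, r = 0.10, seed = 94)
  near <- filter_near_axis(seg$cloud, ax, 0.10)
  upper <- near[near$z >= 1.0, ]
  res1 <- sliding_window_junction(upper, ax, r = 0.10)
  expect_true(res1$found)
  expect_equal(res1$junction_s, 2.2, tolerance = 0.05 / 2.2)

  # a wilted petiole at 1.8 m must not win over the canopy at 2.2 m
  segp <- make_plant_segment(stem_h = 2.2, r = 0.10, petiole_at = 1.8,
                             seed = 95)
  nearp <- filter_near_axis(segp$cloud, ax, 0.10)
  upperp <- nearp[nearp$z >= 1.0, ]
  resp <- sliding_window_junction(upperp, ax, r = 0.10)
  expect_true(resp$found)
  expect_gt(resp$junction_s, 2.1)
  expect_equal(resp$junction_s, 2.2, tolerance = 0.06 / 2.2)

  # empty input
  resv <- sliding_window_junction(pointcloud(), ax, r = 0.1)
  expect_false(resv$found)
})

test_that("junction height shifts by at most one window under 45-degree rotation", {
  ax <- cylinder_model(c(0, 0, 0), c(0, 0, 1), 0.1)
  seg <- make_plant_segment(stem_h = 2.2, r = 0.10, seed = 96)
  near <- filter_near_axis(seg$cloud, ax, 0.10)
  upper <- near[near$z >= 1.0, ]
  th <- pi / 4
  rot <- upper
  rot$x <- cos(th) * upper$x - sin(th) * upper$y
  rot$y <- sin(th) * upper$x + cos(th) * upper$y
  a <- sliding_window_junction(upper, ax, r = 0.10)
  b <- sliding_window_junction(rot, ax, r = 0.10)
  expect_true(a$found && b$found)
  expect_lte(abs(a$junction_s - b$junction_s), 0.05 + 1e-9)
})

test_that("upper_projection is the along-axis coordinate of the top point", {
  ax <- cylinder_model(c(0, 0, 0), c(0, 0, 1), 0.1)
  expect_equal(upper_projection(pointcloud(0, 0, 2.2), ax), 2.2)

  tilt <- 10 * pi / 180
  dirt <- c(sin(tilt), 0, cos(tilt))
  axt <- cylinder_model(c(0, 0, 0), dirt, 0.1)
  p_on_axis <- 2.2 * dirt
  expect_equal(upper_projection(pointcloud(p_on_axis[1], p_on_axis[2],
                                           p_on_axis[3]), axt),
               2.2, tolerance = 1e-9)
  # radial displacement is orthogonal to the axis and does not project
  radial <- c(dirt[3], 0, -dirt[1]) * 0.1
  p_off <- p_on_axis + radial
  two <- pointcloud(x = c(p_on_axis[1], p_off[1]),
                    y = c(p_on_axis[2], p_off[2]),
                    z = c(p_on_axis[3], p_off[3]))
  expect_equal(upper_projection(two[2, ], axt), 2.2, tolerance = 1e-9)
  expect_error(upper_projection(pointcloud(), ax), "empty")
})

test_that("ground_junction projects the lowest near-axis ground point", {
  ax <- cylinder_model(c(0, 0, 1), c(0, 0, 1), 0.1)
  g <- expand.grid(x = seq(-1, 1, 0.05), y = seq(-1, 1, 0.05))
  flat <- pointcloud(x = g$x, y = g$y, z = 0)
  expect_equal(ground_junction(flat, ax, r = 0.1), -1.0, tolerance = 1e-9)

  # sloped ground: matches the analytic plane/axis intersection
  slope <- tan(3 * pi / 180)
  sloped <- pointcloud(x = g$x, y = g$y, z = slope * g$x)
  got <- ground_junction(sloped, ax, r = 0.1)
  # lowest retained point is at x ~ -0.25 (edge of the near-axis disc)
  expect_equal(got, -1 + slope * (-0.25), tolerance = 0.01)

  far <- pointcloud(x = 5, y = 5, z = 0)
  expect_error(ground_junction(far, ax, r = 0.1), "no ground point")
})

test_that("measure_height returns ok heights near the truth", {
  seg <- make_plant_segment(stem_h = 2.3, r = 0.11, sigma = 0.002, seed = 97)
  res <- measure_height(seg, flat_plane())
  expect_equal(res$status, "ok")
  expect_equal(res$height_m, 2.3, tolerance = 0.05 / 2.3)
  expect_equal(res$diameter_m, 0.22, tolerance = 0.01)
})

test_that("measure_height is invariant under vertical scene translation", {
  seg <- make_plant_segment(stem_h = 2.3, r = 0.11, sigma = 0.002, seed = 97)
  seg_up <- seg
  seg_up$cloud$z <- seg_up$cloud$z + 3
  seg_up$ground_patch$z <- seg_up$ground_patch$z + 3
  up_plane <- plane_model(c(0, 0, 1), -3)
  a <- measure_height(seg, flat_plane())
  b <- measure_height(seg_up, up_plane)
  expect_equal(b$height_m, a$height_m, tolerance = 1e-6)
})

test_that("failure statuses are reported, never raised", {
  # canopy removed: no junction can be found
  seg <- make_plant_segment(stem_h = 2.3, r = 0.11, leaf = FALSE, seed = 98)
  res <- measure_height(seg, flat_plane())
  expect_equal(res$status, "no_junction")
  expect_true(is.na(res$height_m))

  # 5.6 m stem: upper - lower projection exceeds the 5 m limit
  tall <- make_plant_segment(stem_h = 5.6, r = 0.11, seed = 99)
  res2 <- measure_height(tall, flat_plane())
  expect_equal(res2$status, "exceeds_limit")
  expect_true(is.na(res2$height_m))

  # band fully occluded
  occ <- make_plant_segment(stem_h = 2.3, r = 0.11, seed = 100)
  occ$cloud <- occ$cloud[occ$cloud$z < 0.95 | occ$cloud$z > 1.25, ]
  res3 <- measure_height(occ, flat_plane())
  expect_equal(res3$status, "no_band")
})
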