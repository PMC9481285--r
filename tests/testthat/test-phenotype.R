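test_that("scale calibration is the real/virtual ratio and scales distances", {
  expect_equal(calibrate_scale(25, 25)$k, 1)
  expect_equal(calibrate_scale(25, 5)$k, 5)
  expect_error(calibrate_scale(25, 0), "positive")
  expect_error(calibrate_scale(-1, 5), "positive")

  pc <- random_cloud(40, seed = 2)
  cal <- calibrate_scale(25, 10) # k = 2.5
  scaled <- apply_scale(pc, cal)
  expect_equal(unit_scale(scaled), 2.5)
  expect_identical(scaled$r, pc$r)
  withr::with_seed(1, {
    for (q in 1:10) {
      ij <- sample(40, 2)
      d0 <- euclidean_distance(positions_of(pc)[ij[1], ], positions_of(pc)[ij[2], ])
      d1 <- euclidean_distance(positions_of(scaled)[ij[1], ], positions_of(scaled)[ij[2], ])
      expect_equal(d1, 2.5 * d0)
    }
  })
  # bounding box volume scales by k^3
  vol <- function(p) prod(apply(positions_of(p), 2, function(v) diff(range(v))))
  expect_equal(vol(scaled), 2.5^3 * vol(pc))
  # k = 1 is the identity
  expect_equal(as.data.frame(apply_scale(pc, 1)), as.data.frame(pc))
  expect_equal(positions_of(apply_scale(point_cloud(x = 1, y = 2, z = 3,
                                                    r = 0, g = 0, b = 0), 2))[1, ],
               c(2, 4, 6), ignore_attr = TRUE)
})

test_that("alignment recovers the stem axis and returns a usable transform", {
  sc <- generate_plant(plant_params(), seed = 8)
  al0 <- align_to_z(sc$cloud, seed = 8)
  # already upright: rotation close to identity up to z-rotation; axis error small
  expect_lt(acos(min(1, abs(al0$rotation[3, 3]))) * 180 / pi, 1)

  # known rotation applied, then aligned: recovered axis within 1 degree
  th <- 0.8
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  pos <- positions_of(sc$cloud) %*% t(R)
  df <- as.data.frame(sc$cloud); df[, 1:3] <- pos
  al <- align_to_z(as_point_cloud(df), seed = 8)
  rotated_axis <- R %*% c(0, 0, 1)
  recovered <- t(al$rotation) %*% c(0, 0, 1)
  expect_lt(acos(min(1, abs(sum(recovered * rotated_axis)))) * 180 / pi, 1)

  # the returned transform reproduces the output exactly
  redo <- pos %*% t(al$rotation) + matrix(al$translation, nrow(pos), 3, byrow = TRUE)
  expect_equal(redo, positions_of(al$cloud), ignore_attr = TRUE)
  expect_equal(min(al$cloud$z), 0)
  # canopy (leafy top) sits at +z: stem base near origin
  expect_gt(mean(abs(al$cloud$x[al$cloud$z > median(al$cloud$z)])),
            mean(abs(al$cloud$x[al$cloud$z < 0.1 * max(al$cloud$z)])))

  expect_error(align_to_z(point_cloud(x = c(1, 1, 1), y = c(1, 1, 1),
                                      z = c(1, 1, 1), r = 0:2, g = 0:2, b = 0:2)),
               "coincident")
})

test_that("plant height is the z extent and carries the expected invariances", {
  pc <- point_cloud(x = c(0, 5), y = c(0, 5), z = c(20, 100),
                    r = c(0L, 0L), g = c(0L, 0L), b = c(0L, 0L))
  expect_equal(plant_height(pc), 80)
  expect_equal(plant_height(point_cloud(x = 1, y = 1, z = 7, r = 0, g = 0, b = 0)), 0)
  expect_error(plant_height(point_cloud()), "empty")

  # invariant under rotation about z and translation in x-y
  sc <- generate_plant(plant_params(), seed = 4)
  h0 <- plant_height(sc$cloud)
  a <- 1.1
  Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  pos <- positions_of(sc$cloud) %*% t(Rz)
  df <- as.data.frame(sc$cloud)
  df$x <- pos[, 1] + 42; df$y <- pos[, 2] - 17; df$z <- pos[, 3]
  expect_equal(plant_height(as_point_cloud(df)), h0)
})

test_that("the minimal RANSAC iteration bound matches its closed form", {
  expect_identical(ransac_min_iterations(0.99, 2), 7L)
  expect_identical(ransac_min_iterations(0.99, 2),
                   as.integer(ceiling(log(1 - 0.99) / log(1 - 1 / 2))))
  expect_identical(ransac_min_iterations(0.999, 2), 10L)
  expect_error(ransac_params(confidence = 1), "\\(0, 1\\)")
  expect_error(ransac_params(sample_size = 1), "at least 2")
})

test_that("stem line fitting is exact on collinear points and robust to outliers", {
  t <- seq(0, 10, length.out = 100)
  dir_true <- c(1, 2, 3) / sqrt(14)
  pos <- outer(t, dir_true)
  fit <- fit_stem_line(pos, ransac_params(inlier_distance = 1e-6), seed = 1)
  expect_identical(length(fit$inlier_indices), 100L)
  expect_gt(abs(sum(fit$direction * dir_true)), 1 - 1e-9)
  expect_gte(fit$n_iterations, 7L) # never below the fixed bound

  # 20% uniform outliers: within 2 degrees of the least-squares fit on the
  # labeled true inliers
  withr::with_seed(33, {
    noise_pos <- pos + matrix(rnorm(300, sd = 0.02), 100, 3)
    outliers <- matrix(runif(75, -5, 15), 25, 3)
  })
  all_pos <- rbind(noise_pos, outliers)
  fit <- fit_stem_line(all_pos, ransac_params(inlier_distance = 0.1), seed = 5)
  ctr <- colMeans(noise_pos)
  ls_dir <- eigen(crossprod(sweep(noise_pos, 2, ctr)), symmetric = TRUE)$vectors[, 1]
  ang <- acos(min(1, abs(sum(fit$direction * ls_dir)))) * 180 / pi
  expect_lt(ang, 2)
  expect_error(fit_stem_line(matrix(1, 1, 3)), "at least 2")
  expect_error(fit_stem_line(matrix(1, 5, 3, byrow = TRUE)), "coincident")
})

test_that("direction recovery stays under half a degree over many seeds", {
  t <- seq(0, 50, length.out = 200)
  dir_true <- c(0.2, -0.1, 1); dir_true <- dir_true / sqrt(sum(dir_true^2))
  pos <- outer(t, dir_true)
  for (s in 1:20) {
    fit <- fit_stem_line(pos, ransac_params(inlier_distance = 0.05), seed = s)
    ang <- acos(min(1, abs(sum(fit$direction * dir_true)))) * 180 / pi
    expect_lt(ang, 0.5)
  }
})

test_that("stem height is the endpoint distance", {
  line <- list(inlier_indices = 1:2,
               endpoints = rbind(c(0, 0, 0), c(0, 0, 50)))
  class(line) <- "stem_line"
  expect_equal(stem_height(line), 50)
  line$endpoints <- rbind(c(1, 1, 1), c(1, 1, 1))
  expect_equal(stem_height(line), 0)
  line$inlier_indices <- 1L
  expect_error(stem_height(line), "degenerate")
})

test_that("leaf measurement is the chord/width product rule", {
  m <- measure_leaf(c(0, 0, 0), c(100, 0, 0), c(50, -5, 0), c(50, 5, 0))
  expect_equal(unlist(m), c(length = 100, width = 10, relative_area = 1000))
  z <- c(0, 0, 0)
  expect_equal(unlist(measure_leaf(z, z, z, z)),
               c(length = 0, width = 0, relative_area = 0))
  # bilinearity: doubling the width pair doubles the area
  m2 <- measure_leaf(c(0, 0, 0), c(100, 0, 0), c(50, -10, 0), c(50, 10, 0))
  expect_equal(m2$relative_area, 2 * m$relative_area)
  # measurements scale linearly in k
  k <- 3.7
  mk <- measure_leaf(k * c(0, 0, 0), k * c(100, 0, 0),
                     k * c(50, -5, 0), k * c(50, 5, 0))
  expect_equal(mk$length, k * m$length)
  expect_equal(mk$relative_area, k^2 * m$relative_area)
})

test_that("automatic leaf extremes recover ellipse axes and the max pair", {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  a <- 8; b <- 3
  pos <- cbind(a * cos(th), b * sin(th), 0 * th)
  ex <- auto_leaf_extremes(pos)
  expect_equal(euclidean_distance(ex$tip_a, ex$tip_b), 2 * a, tolerance = 1e-3)
  expect_equal(euclidean_distance(ex$edge_a, ex$edge_b), 2 * b, tolerance = 1e-2)

  # four-point rectangle: the tip pair is a diagonal (the true max pair)
  rect <- rbind(c(0, 0, 0), c(4, 0, 0), c(4, 1, 0), c(0, 1, 0))
  ex <- auto_leaf_extremes(rect)
  expect_equal(euclidean_distance(ex$tip_a, ex$tip_b), sqrt(17))
  expect_error(auto_leaf_extremes(rect[1:2, ]), "at least 4")

  # collinear leaf degenerates to zero width without error
  lin <- cbind(seq(0, 9, length.out = 10), 0, 0)
  ex <- auto_leaf_extremes(lin)
  expect_equal(euclidean_distance(ex$edge_a, ex$edge_b), 0)
})
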