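plane_cloud <- function(n, seed, normal_tilt = 0) {
  withr::with_seed(seed, {
    pos <- cbind(runif(n, 0, 10), runif(n, 0, 10), 0)
    point_cloud(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                r = rep(60L, n), g = rep(150L, n), b = rep(40L, n))
  })
}

test_that("geometry on a plane gives vertical normals and zero curvature", {
  pc <- plane_cloud(300, seed = 1)
  geom <- estimate_geometry(pc, 15)
  expect_equal(abs(geom$normals[, 3]), rep(1, 300), tolerance = 1e-6)
  expect_equal(geom$curvatures, rep(0, 300), tolerance = 1e-10)
  expect_error(estimate_geometry(pc, 300), "more points than")
  expect_error(estimate_geometry(pc, 2), "at least 3")
})

test_that("geometry on a sphere gives near-radial normals", {
  withr::with_seed(7, {
    v <- matrix(rnorm(3 * 800), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
  })
  pc <- point_cloud(x = v[, 1], y = v[, 2], z = v[, 3],
                    r = rep(60L, 800), g = rep(150L, 800), b = rep(40L, 800))
  geom <- estimate_geometry(pc, 10)
  ang <- acos(pmin(1, abs(rowSums(geom$normals * v)))) * 180 / pi
  expect_lt(max(ang), 10)
  expect_true(all(geom$curvatures >= 0 & geom$curvatures <= 1 / 3 + 1e-12))
})

test_that("normals and curvature match the brute-force eigen oracle", {
  pc <- random_cloud(150, seed = 17, extent = 4)
  k <- 12
  geom <- estimate_geometry(pc, k)
  want <- bf_geometry(positions_of(pc), k)
  expect_equal(geom$curvatures, want$curvatures, tolerance = 1e-10)
  # normals agree up to sign
  agree <- abs(rowSums(geom$normals * want$normals))
  expect_equal(agree, rep(1, 150), tolerance = 1e-8)
})

test_that("a single smooth plane grows into one region", {
  pc <- plane_cloud(400, seed = 2)
  seg <- region_grow(pc, params = region_growing_params(k_neighbors = 12,
                                                        min_region_size = 10))
  expect_identical(length(seg$region_sizes), 1L)
  expect_true(all(seg$labels == 0L))
})

test_that("two planes split exactly when the crease exceeds the angle threshold", {
  # dihedral sweep around a 30-degree threshold; the curvature gate must be
  # strict relative to the sampling (clean planes are curvature-free), or
  # blended crease normals seed a gradual bridge across any angle
  params <- region_growing_params(k_neighbors = 12,
                                  angle_threshold = 30 * pi / 180,
                                  curvature_threshold = 0.005,
                                  min_region_size = 20)
  for (dihedral in c(100, 120, 140, 165)) {
    pc <- two_plane_cloud(dihedral, n_side = 300, seed = dihedral)
    seg <- region_grow(pc, params = params)
    # normals differ by 180 - dihedral across the crease
    expected <- if (180 - dihedral > 30) 2L else 1L
    expect_identical(length(seg$region_sizes), expected)
  }
})

test_that("region count never increases as the angle threshold loosens", {
  pc <- two_plane_cloud(120, n_side = 250, seed = 5)
  counts <- vapply(c(10, 25, 45, 70) * pi / 180, function(ang) {
    seg <- region_grow(pc, params = region_growing_params(
      k_neighbors = 12, angle_threshold = ang, min_region_size = 10))
    length(seg$region_sizes)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("segmentation is a deterministic partition", {
  sc <- generate_plant(plant_params(point_density = 1), seed = 6)
  pv <- voxel_downsample(sc$cloud, 1)
  seg1 <- region_grow(pv)
  seg2 <- region_grow(pv)
  expect_identical(seg1$labels, seg2$labels)
  expect_identical(length(seg1$labels), nrow(pv))
  expect_true(all(seg1$labels >= -1L))
  assigned <- seg1$labels[seg1$labels >= 0L]
  expect_true(all(tabulate(assigned + 1L) >= 50))
  tib <- segmentation_tibble(seg1, pv)
  expect_identical(nrow(tib), nrow(pv))
  expect_true(all(c("label", "kind") %in% names(tib)))
})

test_that("classification finds the vertical thin cylinder among ribbons", {
  withr::with_seed(11, {
    nz <- 1500
    ang <- runif(nz, 0, 2 * pi)
    cyl <- cbind(2 * cos(ang), 2 * sin(ang), runif(nz, 0, 80))
    rib1 <- cbind(runif(800, 0, 60), runif(800, -6, 6), 40 + runif(800, 0, 1))
    rib2 <- cbind(-runif(800, 0, 60), runif(800, -6, 6), 60 + runif(800, 0, 1))
  })
  pos <- rbind(cyl, rib1, rib2)
  pc <- point_cloud(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    r = rep(60L, nrow(pos)), g = rep(150L, nrow(pos)),
                    b = rep(40L, nrow(pos)))
  labels <- c(rep(0L, nz), rep(1L, 800), rep(2L, 800))
  seg <- structure(list(labels = labels, region_sizes = c(nz, 800L, 800L),
                        region_kind = rep("unknown", 3),
                        params = region_growing_params()),
                   class = "plant_segmentation")
  seg <- classify_regions(seg, pc, seed = 3)
  expect_identical(seg$region_kind, c("stem", "leaf", "leaf"))
  expect_identical(count_leaves(seg), 2L)
})

test_that("leaf counting follows the region kinds", {
  seg <- structure(list(labels = integer(), region_sizes = integer(),
                        region_kind = character(), params = NULL),
                   class = "plant_segmentation")
  expect_identical(count_leaves(seg), 0L)
  seg$region_kind <- c("stem", "leaf", "leaf", "leaf")
  expect_identical(count_leaves(seg), 3L)
})

test_that("synthetic plants segment into stem plus the true leaf count", {
  for (s in 1:3) {
    sc <- generate_plant(plant_params(n_leaves = 2 + s), seed = 40 + s)
    # segment the generated cloud directly so indices map onto the truth
    seg <- classify_regions(region_grow(sc$cloud), sc$cloud, seed = s)
    expect_identical(count_leaves(seg), 2L + s)
    expect_identical(sum(seg$region_kind == "stem"), 1L)
    stem_lab <- which(seg$region_kind == "stem") - 1L
    got <- which(seg$labels == stem_lab)
    truth <- sc$truth$stem_indices
    recall <- length(intersect(got, truth)) / length(truth)
    precision <- length(intersect(got, truth)) / length(got)
    expect_gte(recall, 0.9)
    expect_gte(precision, 0.9)
  }
})
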