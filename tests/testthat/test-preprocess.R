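test_that("color_keep matches direct evaluation of the channel formulas", {
  # hand-derived: S=765 exceeds the max sum
  expect_false(color_keep(255, 255, 255))
  # S=250, abs_rg=90, abs_bg=110, R_rg=0.36, R_bg=0.44, g dominant
  expect_true(color_keep(60, 150, 40))
  # pure green: R_rg = 255/255 = 1 exceeds 0.697
  expect_false(color_keep(0, 255, 0))
  # grey: abs_rg = 0 below 35, and g not strictly dominant
  expect_false(color_keep(120, 120, 120))
  # pure black: ratios undefined, rejected
  expect_false(color_keep(0, 0, 0))
  expect_error(color_keep(-1, 10, 10), "\\[0, 255\\]")
  expect_error(color_keep(10.5, 10, 10), "\\[0, 255\\]")
})

test_that("color_keep honors custom ranges and the g-dominance switch", {
  th <- color_thresholds(require_g_dominant = FALSE)
  # red-dominant but inside all ranges when dominance is off
  expect_false(color_keep(150, 60, 40))          # default: g must dominate
  expect_true(color_keep(150, 60, 40, th))       # ranges alone admit it
  expect_error(color_thresholds(s_rgb = c(10, 5)), "min <= max")
})

test_that("color_filter keeps exactly the passing points, in order, idempotently", {
  pc <- random_cloud(400, seed = 5)
  keep <- color_keep(pc$r, pc$g, pc$b)
  filtered <- color_filter(pc)
  expect_identical(nrow(filtered), sum(keep))
  expect_equal(positions_of(filtered), positions_of(pc)[keep, , drop = FALSE])
  # idempotence
  expect_equal(as.data.frame(color_filter(filtered)), as.data.frame(filtered))

  white <- point_cloud(x = 1:5, y = 1:5, z = 1:5,
                       r = rep(255L, 5), g = rep(255L, 5), b = rep(255L, 5))
  expect_identical(nrow(color_filter(white)), 0L)
  green <- point_cloud(x = 1:5, y = 1:5, z = 1:5,
                       r = rep(60L, 5), g = rep(150L, 5), b = rep(40L, 5))
  expect_identical(nrow(color_filter(green)), 5L)
})

test_that("euclidean clustering equals brute-force connected components", {
  for (case in 1:30) {
    pc <- random_cloud(120, seed = 100 + case, extent = 6)
    d <- withr::with_seed(case, runif(1, 0.5, 1.5))
    got <- euclidean_cluster(pc, clustering_params(distance_threshold = d,
                                                   min_cluster_size = 1))
    want <- bf_components(positions_of(pc), d)
    expect_identical(length(got), length(want))
    want_sorted <- lapply(want, sort)
    for (cl in got) {
      match_found <- any(vapply(want_sorted, identical, logical(1), y = cl))
      expect_true(match_found)
    }
  }
})

test_that("clustering respects separation, chains, and size bounds", {
  withr::with_seed(9, {
    blob1 <- matrix(rnorm(300, sd = 0.3), ncol = 3)
    blob2 <- sweep(matrix(rnorm(300, sd = 0.3), ncol = 3), 2, c(30, 0, 0), "+")
  })
  pos <- rbind(blob1, blob2)
  pc <- point_cloud(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    r = rep(0L, 200), g = rep(0L, 200), b = rep(0L, 200))
  cl <- euclidean_cluster(pc, clustering_params(distance_threshold = 3,
                                                min_cluster_size = 1))
  expect_identical(lengths(cl), c(100L, 100L))

  # a chain with every hop at 0.9 x threshold stays one cluster
  chain <- point_cloud(x = 0.9 * (0:49), y = rep(0, 50), z = rep(0, 50),
                       r = rep(0L, 50), g = rep(0L, 50), b = rep(0L, 50))
  cl <- euclidean_cluster(chain, clustering_params(distance_threshold = 1,
                                                   min_cluster_size = 1))
  expect_identical(lengths(cl), 50L)

  # min size filters the smaller component
  cl <- euclidean_cluster(pc, clustering_params(distance_threshold = 3,
                                                min_cluster_size = 101))
  expect_identical(length(cl), 0L)
  expect_identical(euclidean_cluster(point_cloud()), structure(list(), distance_threshold = NULL))
})

test_that("plant cluster selection prefers green fraction, then size", {
  n <- 100
  green <- point_cloud(x = rnorm(n), y = rnorm(n), z = rnorm(n),
                       r = rep(60L, n), g = rep(150L, n), b = rep(40L, n))
  white <- point_cloud(x = rnorm(n) + 50, y = rnorm(n), z = rnorm(n),
                       r = rep(250L, n), g = rep(250L, n), b = rep(250L, n))
  both <- as_point_cloud(rbind(as.data.frame(green), as.data.frame(white)))
  picked <- select_plant_cluster(list(1:n, (n + 1):(2 * n)), both)
  expect_identical(picked, 1:n)
  # order of clusters must not matter
  picked <- select_plant_cluster(list((n + 1):(2 * n), 1:n), both)
  expect_identical(picked, 1:n)

  # two all-green clusters: bigger wins
  big <- 1:80; small <- 81:100
  picked <- select_plant_cluster(list(small, big), green)
  expect_identical(picked, big)
  expect_error(select_plant_cluster(list(), green), "no clusters")
})

test_that("voxel downsampling equals brute-force floor-division binning", {
  for (case in 1:10) {
    pc <- random_cloud(300, seed = 200 + case, extent = 5)
    leaf <- withr::with_seed(case, runif(1, 0.3, 1.2))
    got <- voxel_downsample(pc, voxel_params(leaf))
    bins <- bf_voxel_bins(positions_of(pc), leaf)
    expect_identical(nrow(got), length(unique(bins)))
    # centroid + half-up rounded mean color per occupied voxel
    for (b in unique(bins)[1:5]) {
      members <- which(bins == b)
      centroid <- colMeans(positions_of(pc)[members, , drop = FALSE])
      hit <- which(abs(got$x - centroid[1]) < 1e-9 &
                   abs(got$y - centroid[2]) < 1e-9 &
                   abs(got$z - centroid[3]) < 1e-9)
      expect_length(hit, 1)
      expect_identical(got$r[hit], as.integer(floor(mean(pc$r[members]) + 0.5)))
    }
  }
})

test_that("voxel downsampling degenerate cases behave", {
  pc <- random_cloud(50, seed = 3, extent = 0.4)
  one <- voxel_downsample(pc, voxel_params(10))
  expect_identical(nrow(one), 1L)
  expect_equal(c(one$x, one$y, one$z), unname(colMeans(positions_of(pc))))

  # grid-aligned points farther apart than the leaf survive unchanged
  grid <- expand.grid(x = 0:3, y = 0:3, z = 0)
  pc2 <- point_cloud(x = grid$x + 0.5, y = grid$y + 0.5, z = rep(0.5, 16),
                     r = rep(1L, 16), g = rep(2L, 16), b = rep(3L, 16))
  expect_identical(nrow(voxel_downsample(pc2, voxel_params(1))), 16L)
  # leaf smaller than minimal spacing is the identity on positions
  small <- voxel_downsample(pc2, voxel_params(0.05))
  expect_equal(sort(small$x), sort(pc2$x))
})

test_that("stage point counts never increase through the filter chain", {
  sc <- add_edge_noise(generate_plant(plant_params(point_density = 1), seed = 21), 0.08)
  n0 <- nrow(sc$cloud)
  f1 <- color_filter(sc$cloud)
  f2 <- voxel_downsample(f1, voxel_params(1.5))
  expect_lte(nrow(f1), n0)
  expect_lte(nrow(f2), nrow(f1))
})
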