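# brute-force geometric oracles, independent of the package internals

random_cloud <- function(n, seed, extent = 10) {
  withr::with_seed(seed, {
    point_cloud(
      x = runif(n, 0, extent), y = runif(n, 0, extent), z = runif(n, 0, extent),
      r = sample(0:255, n, replace = TRUE),
      g = sample(0:255, n, replace = TRUE),
      b = sample(0:255, n, replace = TRUE)
    )
  })
}

positions_of <- function(cloud) cbind(cloud$x, cloud$y, cloud$z)

bf_dists <- function(pos, q) sqrt(colSums((t(pos) - q)^2))

bf_knn <- function(pos, q, k) {
  d <- bf_dists(pos, q)
  ord <- order(d, seq_along(d))[seq_len(k)]
  list(idx = ord, dist = d[ord])
}

bf_radius <- function(pos, q, r) {
  sort(which(bf_dists(pos, q) <= r))
}

# connected components at distance threshold d via union-find over all pairs
bf_components <- function(pos, d) {
  n <- nrow(pos)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    dm <- as.matrix(dist(pos))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (dm[i, j] <= d) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), roots))
}

# voxel binning by floor division from the min corner, half-open intervals
bf_voxel_bins <- function(pos, leaf) {
  origin <- apply(pos, 2, min)
  bins <- floor(sweep(pos, 2, origin) / leaf)
  paste(bins[, 1], bins[, 2], bins[, 3])
}

# per-point normal + curvature by explicit covariance eigen-decomposition
bf_geometry <- function(pos, k) {
  n <- nrow(pos)
  normals <- matrix(0, n, 3)
  curv <- numeric(n)
  for (i in seq_len(n)) {
    nb <- pos[bf_knn(pos, pos[i, ], k)$idx, , drop = FALSE]
    cc <- sweep(nb, 2, colMeans(nb))
    eg <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
    normals[i, ] <- eg$vectors[, 3]
    curv[i] <- max(eg$values[3], 0) / sum(pmax(eg$values, 0))
  }
  list(normals = normals, curvatures = curv)
}

# two tilted planes meeting along the y axis at a given dihedral angle
two_plane_cloud <- function(dihedral_deg, n_side = 400, seed = 1) {
  withr::with_seed(seed, {
    half <- (180 - dihedral_deg) / 2 * pi / 180 # tilt of each plane from xy
    u <- runif(n_side, 0.05, 5); v <- runif(n_side, -5, 5)
    p1 <- cbind(-u * cos(half), v, u * sin(half))
    u2 <- runif(n_side, 0.05, 5); v2 <- runif(n_side, -5, 5)
    p2 <- cbind(u2 * cos(half), v2, u2 * sin(half))
    pos <- rbind(p1, p2)
    point_cloud(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                r = rep(60L, nrow(pos)), g = rep(150L, nrow(pos)),
                b = rep(40L, nrow(pos)))
  })
}

expect_same_sets <- function(a, b) expect_setequal(a, b)
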