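#' Per-point surface normals and curvature
#'
#' For each point, the covariance of its `k_neighbors` nearest neighbors
#' (the point included) is eigen-decomposed: the normal is the eigenvector of
#' the smallest eigenvalue, and the curvature is
#' \eqn{\lambda_{min} / (\lambda_1+\lambda_2+\lambda_3)} — 0 on a plane,
#' at most 1/3 for isotropic scatter. Normal signs are ambiguous and treated
#' as undirected lines downstream.
#'
#' @param cloud A [point_cloud()] with more points than `k_neighbors`.
#' @param k_neighbors Neighborhood size, at least 3 (default 30).
#' @return A `surface_geometry` list: `normals` (N x 3, unit rows),
#'   `curvatures` (length N, in `[0, 1/3]`), `k_neighbors`, and the N x k
#'   neighbor index matrix `knn` reused by [region_grow()].
#' @export
estimate_geometry <- function(cloud, k_neighbors = 30) {
  n <- nrow(cloud)
  k_neighbors <- as.integer(k_neighbors)
  if (k_neighbors < 3) stop("k_neighbors must be at least 3", call. = FALSE)
  if (n <= k_neighbors) {
    stop("cloud must hold more points than k_neighbors (", n, " <= ",
         k_neighbors, ")", call. = FALSE)
  }
  pos <- cloud_positions(cloud)
  knn <- RANN::nn2(pos, k = k_neighbors)$nn.idx
  normals <- matrix(0, n, 3)
  curv <- numeric(n)
  for (i in seq_len(n)) {
    nb <- pos[knn[i, ], , drop = FALSE]
    centered <- sweep(nb, 2, colMeans(nb))
    eg <- eigen(crossprod(centered) / nrow(nb), symmetric = TRUE)
    val <- pmax(eg$values, 0) # guard tiny negative eigenvalues
    normals[i, ] <- eg$vectors[, 3]
    tot <- sum(val)
    curv[i] <- if (tot > 0) val[3] / tot else 0
  }
  structure(list(normals = normals, curvatures = curv,
                 k_neighbors = k_neighbors, knn = knn),
            class = "surface_geometry")
}

#' Region-growing parameters
#'
#' @param k_neighbors Neighborhood size used for growth (default 30).
#' @param angle_threshold Maximum angle between a seed's and a neighbor's
#'   normals (undirected, radians) for the neighbor to join the region;
#'   default 10 degrees.
#' @param curvature_threshold Maximum curvature difference from the current
#'   seed for a joining point to itself become a seed (default 0.05).
#' @param min_region_size Regions smaller than this are relabeled unassigned
#'   (default 50).
#' @param curvature_mode `"difference"` compares a candidate's curvature to
#'   the current seed's (the growth criterion used here by default);
#'   `"absolute"` compares it to the threshold directly.
#' @return A `region_growing_params` list.
#' @export
region_growing_params <- function(k_neighbors = 30,
                                  angle_threshold = 10 * pi / 180,
                                  curvature_threshold = 0.05,
                                  min_region_size = 50,
                                  curvature_mode = c("difference", "absolute")) {
  if (angle_threshold <= 0 || angle_threshold >= pi / 2) {
    stop("angle_threshold must be in (0, pi/2) radians", call. = FALSE)
  }
  structure(list(k_neighbors = as.integer(k_neighbors),
                 angle_threshold = angle_threshold,
                 curvature_threshold = curvature_threshold,
                 min_region_size = as.integer(min_region_size),
                 curvature_mode = match.arg(curvature_mode)),
            class = "region_growing_params")
}

#' Region-growing segmentation into smooth surfaces
#'
#' Points are visited in ascending order of curvature: the unassigned point
#' of globally lowest curvature seeds a new region, and the region grows by a
#' seed queue. A neighbor of a seed joins the region when the angle between
#' their normals (sign-invariant, `acos(|n1 . n2|)`) is within
#' `angle_threshold`; the joining point additionally becomes a seed — and so
#' propagates growth — only when its curvature difference from the current
#' seed is within `curvature_threshold`. A point that satisfies only the
#' angle test is classified without seeding. Regions below `min_region_size`
#' are relabeled -1.
#'
#' @param cloud A [point_cloud()].
#' @param geom The [estimate_geometry()] of this cloud (recomputed when
#'   `NULL` or when its `k_neighbors` differs from `params$k_neighbors`).
#' @param params A [region_growing_params()] object.
#' @return A `plant_segmentation` list: integer `labels` (length N; -1 =
#'   unassigned, 0-based region ids otherwise), `region_sizes`,
#'   `region_kind` (all `"unknown"` until [classify_regions()]), `params`.
#' @export
region_grow <- function(cloud, geom = NULL, params = region_growing_params()) {
  n <- nrow(cloud)
  if (is.null(geom) || geom$k_neighbors != params$k_neighbors) {
    geom <- estimate_geometry(cloud, params$k_neighbors)
  }
  normals <- geom$normals
  curv <- geom$curvatures
  knn <- geom$knn
  cos_thr <- cos(params$angle_threshold)
  labels <- rep.int(-2L, n) # -2 = unvisited, becomes region id or stays
  order_by_curv <- order(curv, seq_len(n)) # ascending, index tie-break
  region <- -1L
  for (root in order_by_curv) {
    if (labels[root] != -2L) next
    region <- region + 1L
    labels[root] <- region
    seeds <- root # FIFO seed queue
    while (length(seeds) > 0) {
      s <- seeds[1]
      seeds <- seeds[-1]
      for (nb in knn[s, ]) {
        if (labels[nb] != -2L) next
        # undirected normal angle between seed and neighbor
        if (abs(sum(normals[s, ] * normals[nb, ])) < cos_thr) next
        labels[nb] <- region
        seed_ok <- switch(params$curvature_mode,
          difference = abs(curv[nb] - curv[s]) <= params$curvature_threshold,
          absolute = curv[nb] <= params$curvature_threshold
        )
        if (seed_ok) seeds <- c(seeds, nb)
      }
    }
  }
  # enforce minimum region size, then compact ids in order of first point
  sizes <- tabulate(labels + 1L, nbins = region + 1L)
  small <- which(sizes < params$min_region_size) - 1L
  labels[labels %in% small] <- -1L
  kept <- sort(unique(labels[labels >= 0L]))
  labels[labels >= 0L] <- match(labels[labels >= 0L], kept) - 1L
  region_sizes <- tabulate(labels + 1L, nbins = length(kept))
  structure(list(labels = labels,
                 region_sizes = as.integer(region_sizes),
                 region_kind = rep("unknown", length(kept)),
                 params = params),
            class = "plant_segmentation")
}

#' @export
print.plant_segmentation <- function(x, ...) {
  cat(sprintf("<plant_segmentation: %d regions (%s), %d unassigned points>\n",
              length(x$region_sizes),
              paste(x$region_kind, collapse = ", "),
              sum(x$labels == -1L)))
  invisible(x)
}

#' Label segmented regions as stem or leaf
#'
#' Heuristic organ labeling: each region is RANSAC line-fitted with an
#' inlier tolerance wide enough to swallow a stalk's cross-section (8% of
#' the region's largest extent). Among the regions whose fitted line is
#' predominantly vertical (within `max_tilt` of z — the cloud is aligned
#' before segmentation), the one with the highest inlier fraction is the
#' stem; every other region is a leaf. A lone region is a stem only when it
#' is decisively line-like (inlier fraction > 0.9).
#'
#' @param result A [region_grow()] result.
#' @param cloud The segmented cloud.
#' @param seed Seed for the per-region RANSAC fits.
#' @param max_tilt Maximum stem tilt from +z, radians (default 30 degrees).
#' @return `result` with `region_kind` filled in.
#' @export
classify_regions <- function(result, cloud, seed = 1, max_tilt = 30 * pi / 180) {
  n_regions <- length(result$region_sizes)
  if (n_regions == 0) return(result)
  frac <- numeric(n_regions)
  vertical <- logical(n_regions)
  pos <- cloud_positions(cloud)
  for (rg in seq_len(n_regions)) {
    idx <- which(result$labels == rg - 1L)
    if (length(idx) < 2) { frac[rg] <- 0; next }
    rp <- pos[idx, , drop = FALSE]
    extent <- max(apply(rp, 2, max) - apply(rp, 2, min))
    fit <- fit_stem_line(rp,
                         ransac_params(inlier_distance = 0.08 * extent,
                                       max_iterations = 300),
                         seed = seed + rg)
    frac[rg] <- length(fit$inlier_indices) / length(idx)
    vertical[rg] <- abs(fit$direction[3]) > cos(max_tilt)
  }
  kind <- rep("leaf", n_regions)
  if (n_regions == 1) {
    if (frac[1] > 0.9 && vertical[1]) kind[1] <- "stem"
  } else {
    stemlike <- which(vertical)
    if (length(stemlike) > 0) {
      kind[stemlike[which.max(frac[stemlike])]] <- "stem"
    }
  }
  result$region_kind <- kind
  result
}

#' Number of leaf regions in a classified segmentation
#'
#' @param result A [classify_regions()] result.
#' @return Integer leaf count.
#' @export
count_leaves <- function(result) {
  sum(result$region_kind == "leaf")
}

#' Segmentation labels as a per-point tibble
#'
#' @param result A `plant_segmentation`.
#' @param cloud Optionally, the segmented cloud; its columns are bound in.
#' @return A tibble with `label` (integer, -1 = unassigned) and `kind`
#'   per point, plus the cloud columns when supplied.
#' @export
segmentation_tibble <- function(result, cloud = NULL) {
  kind <- rep("unassigned", length(result$labels))
  assigned <- result$labels >= 0L
  kind[assigned] <- result$region_kind[result$labels[assigned] + 1L]
  out <- tibble::tibble(label = result$labels, kind = kind)
  if (!is.null(cloud)) out <- dplyr::bind_cols(tibble::as_tibble(cloud), out)
  out
}
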