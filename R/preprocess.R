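#' Green-vegetation color thresholds
#'
#' The color filter keeps a point when five quantities derived from its RGB
#' channels each fall inside a closed range, and (by default) green dominates
#' both other channels. With channel values r, g, b:
#' \deqn{S_{rgb} = r+g+b,\quad abs_{rg} = |r-g|,\quad abs_{bg} = |b-g|}
#' \deqn{R_{rg} = abs_{rg}/S_{rgb},\quad R_{bg} = abs_{bg}/S_{rgb}}
#' The defaults are the empirical ranges of maize-seedling green in
#' photogrammetric reconstructions. \eqn{|r-b|} and its ratio are computed for
#' inspection but carry no range, so they never reject a point.
#'
#' @param s_rgb,abs_rg,abs_bg,r_rg,r_bg Length-2 `c(min, max)` ranges.
#' @param require_g_dominant Require `g > r` and `g > b` (default `TRUE`).
#' @return A `color_thresholds` list.
#' @export
color_thresholds <- function(s_rgb = c(165, 642),
                             abs_rg = c(35, 255),
                             abs_bg = c(16, 255),
                             r_rg = c(0.098, 0.697),
                             r_bg = c(0.032, 0.670),
                             require_g_dominant = TRUE) {
  th <- list(s_rgb = as.double(s_rgb), abs_rg = as.double(abs_rg),
             abs_bg = as.double(abs_bg), r_rg = as.double(r_rg),
             r_bg = as.double(r_bg),
             require_g_dominant = isTRUE(require_g_dominant))
  for (nm in c("s_rgb", "abs_rg", "abs_bg", "r_rg", "r_bg")) {
    rng <- th[[nm]]
    if (length(rng) != 2 || any(!is.finite(rng)) || rng[1] > rng[2]) {
      stop("threshold range ", nm, " must be c(min, max) with min <= max",
           call. = FALSE)
    }
  }
  structure(th, class = "color_thresholds")
}

#' Does a color pass the vegetation filter?
#'
#' Vectorized over the three channels. A pure-black point (`S_rgb == 0`)
#' always fails: its color ratios are undefined.
#'
#' @param r,g,b Integer channel values in `[0, 255]` (recycled together).
#' @param thresholds A [color_thresholds()] object.
#' @return Logical vector.
#' @examples
#' color_keep(60, 150, 40)   # typical leaf green: TRUE
#' color_keep(255, 255, 255) # white noise: FALSE
#' @export
color_keep <- function(r, g, b, thresholds = color_thresholds()) {
  chan <- cbind(r, g, b)
  if (any(!is.finite(chan)) || any(chan != round(chan)) || any(chan < 0 | chan > 255)) {
    stop("color channels must be integers in [0, 255]", call. = FALSE)
  }
  s_rgb <- r + g + b
  abs_rg <- abs(r - g)
  abs_bg <- abs(b - g)
  # ratios undefined at s_rgb == 0; such points are rejected outright
  r_rg <- ifelse(s_rgb > 0, abs_rg / s_rgb, NA_real_)
  r_bg <- ifelse(s_rgb > 0, abs_bg / s_rgb, NA_real_)
  th <- thresholds
  in_range <- function(v, rng) !is.na(v) & v >= rng[1] & v <= rng[2]
  keep <- s_rgb > 0 &
    in_range(s_rgb, th$s_rgb) &
    in_range(abs_rg, th$abs_rg) &
    in_range(abs_bg, th$abs_bg) &
    in_range(r_rg, th$r_rg) &
    in_range(r_bg, th$r_bg)
  if (th$require_g_dominant) keep <- keep & (g > r) & (g > b)
  unname(keep)
}

#' Remove non-vegetation points by color
#'
#' Keeps exactly the points whose colors pass [color_keep()], preserving the
#' original order. This removes the near-white noise that photogrammetric
#' reconstruction scatters along leaf edges.
#'
#' @param cloud A [point_cloud()].
#' @param thresholds A [color_thresholds()] object.
#' @return The filtered `point_cloud`.
#' @export
color_filter <- function(cloud, thresholds = color_thresholds()) {
  keep <- color_keep(cloud$r, cloud$g, cloud$b, thresholds)
  new_point_cloud(tibble::as_tibble(cloud)[keep, , drop = FALSE],
                  unit_scale = unit_scale(cloud))
}

#' Euclidean clustering parameters
#'
#' @param distance_threshold Maximum hop distance for two points to share a
#'   cluster (position units). `NULL` (default) resolves at run time to twice
#'   the cloud's median nearest-neighbor spacing.
#' @param min_cluster_size Discard clusters smaller than this (default 50,
#'   suppressing stray specks).
#' @param max_cluster_size Discard clusters larger than this (default `Inf`).
#' @return A `clustering_params` list.
#' @export
clustering_params <- function(distance_threshold = NULL,
                              min_cluster_size = 50,
                              max_cluster_size = Inf) {
  if (!is.null(distance_threshold) &&
      (!is.finite(distance_threshold) || distance_threshold <= 0)) {
    stop("distance_threshold must be positive", call. = FALSE)
  }
  if (min_cluster_size < 1 || min_cluster_size > max_cluster_size) {
    stop("need 1 <= min_cluster_size <= max_cluster_size", call. = FALSE)
  }
  structure(list(distance_threshold = distance_threshold,
                 min_cluster_size = as.integer(min_cluster_size),
                 max_cluster_size = max_cluster_size),
            class = "clustering_params")
}

#' Euclidean cluster extraction
#'
#' Partitions the cloud into connected components of the graph joining every
#' pair of points within `distance_threshold`, using KD-tree radius queries to
#' grow each component. Components outside the size bounds are discarded.
#'
#' @param cloud A [point_cloud()].
#' @param params A [clustering_params()] object.
#' @return A list of integer index vectors (into `cloud` rows), sorted by
#'   descending cluster size; each vector sorted ascending. The resolved
#'   distance threshold is attached as attribute `distance_threshold`.
#' @export
euclidean_cluster <- function(cloud, params = clustering_params()) {
  n <- nrow(cloud)
  if (n == 0) return(structure(list(), distance_threshold = params$distance_threshold))
  d <- params$distance_threshold
  if (is.null(d)) {
    d <- 2 * median_nn_spacing(cloud)
    if (!is.finite(d) || d <= 0) d <- 1
  }
  # fixed-radius adjacency computed in one pass (single KD-tree build),
  # then connected components by flood fill over the lists
  adj <- radius_adjacency(cloud_positions(cloud), d)
  labels <- integer(n) # 0 = unvisited
  n_clusters <- 0L
  clusters <- list()
  for (start in seq_len(n)) {
    if (labels[start] != 0L) next
    n_clusters <- n_clusters + 1L
    frontier <- start
    labels[start] <- n_clusters
    members <- start
    while (length(frontier) > 0) {
      nbrs <- unique(unlist(adj[frontier], use.names = FALSE))
      new <- nbrs[labels[nbrs] == 0L]
      labels[new] <- n_clusters
      members <- c(members, new)
      frontier <- new
    }
    clusters[[n_clusters]] <- sort(members)
  }
  sizes <- lengths(clusters)
  keep <- sizes >= params$min_cluster_size & sizes <= params$max_cluster_size
  clusters <- clusters[keep]
  clusters <- clusters[order(-lengths(clusters), vapply(clusters, min, 1L))]
  structure(clusters, distance_threshold = d)
}

#' Pick the plant cluster among extracted clusters
#'
#' Scores each cluster by the fraction of its points passing [color_keep()]
#' and returns the best one. Ties on the green fraction are broken by larger
#' size, then by lower cluster position in `clusters`. Selecting by green
#' fraction rather than raw size matters because the table/pot cluster can
#' hold more points than the seedling.
#'
#' @param clusters List of index vectors from [euclidean_cluster()].
#' @param cloud The cloud the indices refer to.
#' @param thresholds A [color_thresholds()] object.
#' @return The winning integer index vector.
#' @export
select_plant_cluster <- function(clusters, cloud, thresholds = color_thresholds()) {
  if (length(clusters) == 0) stop("no clusters to select from", call. = FALSE)
  keep <- color_keep(cloud$r, cloud$g, cloud$b, thresholds)
  frac <- vapply(clusters, function(idx) mean(keep[idx]), numeric(1))
  sizes <- lengths(clusters)
  best <- order(-frac, -sizes, seq_along(clusters))[1]
  clusters[[best]]
}

#' Voxel-grid parameters
#'
#' @param leaf_size Voxel edge length in position units; must be positive.
#' @return A `voxel_params` list.
#' @export
voxel_params <- function(leaf_size) {
  if (!is.numeric(leaf_size) || length(leaf_size) != 1 ||
      !is.finite(leaf_size) || leaf_size <= 0) {
    stop("leaf_size must be a single positive number", call. = FALSE)
  }
  structure(list(leaf_size = as.double(leaf_size)), class = "voxel_params")
}

#' Voxel-grid downsampling
#'
#' Divides space into axis-aligned cubes of edge `leaf_size`, anchored at the
#' cloud's minimum corner, and replaces the points of each occupied voxel by
#' one point at their centroid. Intervals are half-open: a point exactly on a
#' boundary belongs to the higher-index voxel. Output colors are the per-voxel
#' channel means rounded half-up to the nearest integer.
#'
#' @param cloud A [point_cloud()].
#' @param params A [voxel_params()] object (or bare positive number).
#' @return The downsampled `point_cloud`; output voxels ordered by first
#'   member occurrence in the input.
#' @export
voxel_downsample <- function(cloud, params) {
  if (is.numeric(params)) params <- voxel_params(params)
  if (nrow(cloud) == 0) return(cloud)
  leaf <- params$leaf_size
  pos <- cloud_positions(cloud)
  origin <- apply(pos, 2, min)
  bins <- floor(sweep(pos, 2, origin) / leaf)
  key <- paste(bins[, 1], bins[, 2], bins[, 3])
  grp <- match(key, unique(key))
  half_up <- function(v) floor(v + 0.5)
  out <- tibble::as_tibble(cloud) |>
    dplyr::mutate(.voxel = grp) |>
    dplyr::summarise(
      x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
      r = half_up(mean(.data$r)), g = half_up(mean(.data$g)),
      b = half_up(mean(.data$b)),
      .by = ".voxel"
    ) |>
    dplyr::arrange(.data$.voxel) |>
    dplyr::select(-".voxel")
  new_point_cloud(out, unit_scale = unit_scale(cloud))
}
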