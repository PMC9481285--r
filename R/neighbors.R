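#' Build a spatial neighbor index over a point cloud
#'
#' Wraps a KD-tree (via \pkg{RANN}) over the cloud's positions. Queries return
#' exactly what a brute-force distance scan would: k-nearest results are
#' sorted by distance with ties broken by ascending point index, and radius
#' queries return every point within the radius (closed ball).
#'
#' @param cloud A [point_cloud()].
#' @return An object of class `nn_index`.
#' @export
build_index <- function(cloud) {
  structure(
    list(positions = cloud_positions(cloud), n = nrow(cloud)),
    class = "nn_index"
  )
}

#' @export
print.nn_index <- function(x, ...) {
  cat(sprintf("<nn_index over %d points>\n", x$n))
  invisible(x)
}

#' k-nearest-neighbor query
#'
#' @param index An [build_index()] result.
#' @param query A length-3 numeric point or an M x 3 matrix of query points.
#' @param k Number of neighbors (capped at the number of indexed points).
#' @return A list with integer matrix `idx` (M x k) and numeric matrix
#'   `dist` (M x k), rows sorted by distance then by point index.
#' @export
knn_search <- function(index, query, k) {
  query <- as_query_matrix(query)
  k <- min(as.integer(k), index$n)
  if (k < 1 || index$n == 0) {
    return(list(idx = matrix(integer(), nrow(query), 0),
                dist = matrix(numeric(), nrow(query), 0)))
  }
  res <- RANN::nn2(index$positions, query, k = k, treetype = "kd",
                   searchtype = "standard", eps = 0)
  # deterministic tie-break: re-sort each row by (distance, index); RANN's
  # order under exact ties is unspecified, and equal distances may also sit
  # just outside the returned k — re-rank against all candidates at the
  # boundary distance.
  out_idx <- res$nn.idx
  out_dist <- res$nn.dists
  for (i in seq_len(nrow(query))) {
    d <- out_dist[i, ]
    id <- out_idx[i, ]
    boundary <- max(d)
    # pull in every indexed point at exactly the boundary distance
    extra <- radius_candidates(index, query[i, ], boundary)
    keep <- union(id, extra$idx[abs(extra$dist - boundary) <= 1e-12 * max(1, boundary)])
    dd <- sqrt(rowSums((index$positions[keep, , drop = FALSE] -
                          matrix(query[i, ], length(keep), 3, byrow = TRUE))^2))
    ord <- order(dd, keep)[seq_len(k)]
    out_idx[i, ] <- keep[ord]
    out_dist[i, ] <- dd[ord]
  }
  list(idx = out_idx, dist = out_dist)
}

#' Fixed-radius query
#'
#' @inheritParams knn_search
#' @param radius Search radius (closed ball, same units as positions).
#' @return A list of integer vectors, one per query row, each sorted
#'   ascending; for a single query point, the vector itself.
#' @export
radius_search <- function(index, query, radius) {
  single <- is.null(dim(query))
  query <- as_query_matrix(query)
  out <- vector("list", nrow(query))
  for (i in seq_len(nrow(query))) {
    cand <- radius_candidates(index, query[i, ], radius)
    out[[i]] <- sort(cand$idx[cand$dist <= radius])
  }
  if (single) out[[1]] else out
}

# all indexed points within `radius` of one query point (unsorted), found by
# growing k until the kd-tree radius search is exhaustive
radius_candidates <- function(index, q, radius) {
  n <- index$n
  if (n == 0) return(list(idx = integer(), dist = numeric()))
  k <- min(n, 64L)
  repeat {
    res <- RANN::nn2(index$positions, matrix(q, 1, 3), k = k,
                     searchtype = "radius", radius = radius * (1 + 1e-12), eps = 0)
    hit <- res$nn.idx[1, ] > 0
    if (sum(hit) < k || k == n) {
      return(list(idx = res$nn.idx[1, hit], dist = res$nn.dists[1, hit]))
    }
    k <- min(n, k * 4L)
  }
}

# neighbor lists of every point within `radius`, self excluded: one radius
# nn2 over all points with k escalation for the few saturated rows
radius_adjacency <- function(pos, radius, k0 = 48L) {
  n <- nrow(pos)
  k <- min(n, max(2L, k0))
  adj <- vector("list", n)
  pending <- seq_len(n)
  repeat {
    idx <- RANN::nn2(pos, pos[pending, , drop = FALSE], k = k,
                     searchtype = "radius", radius = radius * (1 + 1e-12),
                     eps = 0)$nn.idx
    full <- idx[, k] > 0 & k < n
    for (j in which(!full)) {
      v <- idx[j, ]
      adj[[pending[j]]] <- v[v > 0 & v != pending[j]]
    }
    if (!any(full)) break
    pending <- pending[full]
    k <- min(n, k * 4L)
  }
  adj
}

# unique indices of all data points within `radius` of any query row;
# one nn2 call per k-escalation round, so frontiers of thousands of points
# stay cheap
batched_radius <- function(data, query, radius) {
  n <- nrow(data)
  k <- min(n, 64L)
  hits <- integer()
  pending <- seq_len(nrow(query))
  repeat {
    res <- RANN::nn2(data, query[pending, , drop = FALSE], k = k,
                     searchtype = "radius", radius = radius * (1 + 1e-12), eps = 0)
    idx <- res$nn.idx
    saturated <- which(idx[, k] > 0)
    done <- if (length(saturated) > 0 && k < n) -saturated else seq_len(nrow(idx))
    got <- idx[done, , drop = FALSE]
    hits <- c(hits, got[got > 0])
    if (length(saturated) == 0 || k == n) break
    pending <- pending[saturated]
    k <- min(n, k * 4L)
  }
  unique(hits)
}

as_query_matrix <- function(query) {
  if (is.null(dim(query))) {
    stopifnot(length(query) == 3)
    matrix(as.double(query), 1, 3)
  } else {
    stopifnot(ncol(query) == 3)
    matrix(as.double(query), nrow(query), 3)
  }
}

#' Euclidean distance between two 3D points
#'
#' @param p1,p2 Length-3 numeric vectors.
#' @return The non-negative distance \eqn{\sqrt{\Delta x^2+\Delta y^2+\Delta z^2}}.
#' @examples
#' euclidean_distance(c(0, 0, 0), c(3, 4, 0)) # 5
#' @export
euclidean_distance <- function(p1, p2) {
  stopifnot(length(p1) == 3, length(p2) == 3, all(is.finite(p1)), all(is.finite(p2)))
  sqrt(sum((p1 - p2)^2))
}

# median nearest-neighbor spacing of a cloud; the basis for the default
# clustering and RANSAC distance thresholds
median_nn_spacing <- function(cloud) {
  n <- nrow(cloud)
  if (n < 2) return(NA_real_)
  res <- RANN::nn2(cloud_positions(cloud), k = 2)
  stats::median(res$nn.dists[, 2])
}
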