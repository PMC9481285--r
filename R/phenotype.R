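#' Metric scale calibration from a reference length
#'
#' A checkerboard of known square size (25 mm in the standard protocol) placed
#' in the scene gives the conversion ratio between model units and
#' millimetres: `k = l_real / l_virtual`.
#'
#' @param l_real Real-world reference length in mm (checkerboard square edge).
#' @param l_virtual The same length measured in the reconstructed model, in
#'   model units (e.g. picked in CloudCompare).
#' @return A `scale_calibration` list with fields `l_real`, `l_virtual`, `k`.
#' @examples
#' calibrate_scale(25, 5) # k = 5 mm per model unit
#' @export
calibrate_scale <- function(l_real = 25, l_virtual) {
  if (!is.finite(l_real) || l_real <= 0 || !is.finite(l_virtual) || l_virtual <= 0) {
    stop("reference lengths must be positive and finite", call. = FALSE)
  }
  structure(list(l_real = as.double(l_real), l_virtual = as.double(l_virtual),
                 k = l_real / l_virtual),
            class = "scale_calibration")
}

#' Scale a cloud to millimetres
#'
#' Multiplies all positions by the calibration factor `k` and updates the
#' cloud's `unit_scale`. Colors are untouched. Calling it on an
#' already-scaled cloud compounds the factors; the printed `unit_scale`
#' makes that visible.
#'
#' @param cloud A [point_cloud()].
#' @param cal A [calibrate_scale()] result, or a bare positive number `k`.
#' @return The scaled `point_cloud` with `unit_scale` multiplied by `k`.
#' @export
apply_scale <- function(cloud, cal) {
  k <- if (is.numeric(cal)) cal else cal$k
  if (!is.finite(k) || k <= 0) stop("scale factor must be positive", call. = FALSE)
  out <- tibble::as_tibble(cloud)
  out$x <- out$x * k
  out$y <- out$y * k
  out$z <- out$z * k
  new_point_cloud(out, unit_scale = unit_scale(cloud) * k)
}

#' Align the growth axis with +z
#'
#' Estimates the growth (stem) axis, rotates the cloud so the axis maps to
#' +z, and translates the minimum z to 0. The sign of the axis is
#' disambiguated by placing the half of the plant with the greater x-y
#' spread — the leafy canopy — at high z, so the stem base ends up at the
#' origin.
#'
#' The default `"stem"` estimator finds the axis by a coarse RANSAC line fit
#' (inlier tolerance 5% of the bounding-box diagonal) followed by two
#' trimmed total-least-squares refinements on the points nearest the axis.
#' On a leafy seedling the dominant principal component often runs along the
#' leaves rather than the stalk, so plain PCA (`method = "pca"`) is kept
#' only as a fallback for sparse or stem-less clouds.
#'
#' @param cloud A [point_cloud()] with at least 3 non-coincident points.
#' @param method `"stem"` (robust RANSAC axis, default) or `"pca"` (largest
#'   principal component).
#' @param seed Seed for the RANSAC axis estimate.
#' @return A list with elements `cloud` (the aligned `point_cloud`),
#'   `rotation` (3x3 matrix), and `translation` (length-3 vector); the
#'   transform maps input positions `p` to `p %*% t(rotation) + translation`.
#' @export
align_to_z <- function(cloud, method = c("stem", "pca"), seed = 1) {
  method <- match.arg(method)
  if (nrow(cloud) < 3) stop("need at least 3 points to align", call. = FALSE)
  pos <- cloud_positions(cloud)
  ctr <- colMeans(pos)
  centered <- sweep(pos, 2, ctr)
  if (all(abs(centered) < 1e-12)) stop("all points coincident; no axis", call. = FALSE)
  axis <- if (method == "pca") {
    eigen(crossprod(centered) / nrow(pos), symmetric = TRUE)$vectors[, 1]
  } else {
    growth_axis(pos, seed = seed)
  }
  rot <- rotation_to_z(axis)
  aligned <- centered %*% t(rot)
  if (canopy_is_down(aligned)) {
    # flip 180 degrees about x so the canopy half sits at +z
    flip <- diag(c(1, -1, -1))
    rot <- flip %*% rot
    aligned <- centered %*% t(rot)
  }
  shift <- c(0, 0, -min(aligned[, 3])) - as.vector(rot %*% ctr)
  out <- tibble::as_tibble(cloud)
  final <- sweep(pos %*% t(rot), 2, -shift)
  out$x <- final[, 1]; out$y <- final[, 2]; out$z <- final[, 3]
  list(cloud = new_point_cloud(out, unit_scale = unit_scale(cloud)),
       rotation = rot, translation = shift)
}

# robust growth-axis estimate: coarse RANSAC line (the stalk gathers the
# densest near-linear point band), then trimmed TLS refinement on the
# quarter of points nearest the axis
growth_axis <- function(pos, seed = 1) {
  diag_len <- sqrt(sum((apply(pos, 2, max) - apply(pos, 2, min))^2))
  fit <- withr::with_seed(seed,
                          axis_search(pos, tol = 0.025 * diag_len, n_iter = 300))
  anchor <- fit$anchor
  axis <- fit$direction
  # refine on the points inside an absolute distance band around the axis
  # (the band adapts to the stalk cross-section, not to a fixed quantile)
  for (round in 1:5) {
    d <- point_line_distance(pos, anchor, axis)
    core <- pos[d <= 1.3 * stats::quantile(d, 0.25), , drop = FALSE]
    if (nrow(core) < 3) break
    anchor <- colMeans(core)
    axis <- eigen(crossprod(sweep(core, 2, anchor)), symmetric = TRUE)$vectors[, 1]
  }
  axis
}

# fixed-budget RANSAC + local optimization for the densest line band; unlike
# the adaptive stem fit this never stops early, because on a whole plant the
# sample-pair success model underlying the adaptive bound does not hold (a
# pair on the stalk surface does not give the stalk axis)
axis_search <- function(pos, tol, n_iter = 300) {
  n <- nrow(pos)
  best <- list(count = -1L, anchor = NULL, direction = NULL)
  for (it in seq_len(n_iter)) {
    pick <- sample.int(n, 2)
    dir <- pos[pick[2], ] - pos[pick[1], ]
    len <- sqrt(sum(dir^2))
    if (len < 1e-12) next
    dir <- dir / len
    a <- pos[pick[1], ]
    d <- point_line_distance(pos, a, dir)
    count <- sum(d <= tol)
    # optimize any candidate in reach of the lead: a pair on the stalk
    # surface starts with a modest capture but snaps to the axis under LO
    if (count < 0.5 * best$count) next
    # widened-band TLS refits let the candidate snap to a thick structure's
    # axis; keep the largest capture
    repeat {
      grew <- FALSE
      for (band in c(2, 1)) {
        sub <- pos[d <= band * tol, , drop = FALSE]
        if (nrow(sub) < 2) next
        a2 <- colMeans(sub)
        v2 <- eigen(crossprod(sweep(sub, 2, a2)), symmetric = TRUE)$vectors[, 1]
        d2 <- point_line_distance(pos, a2, v2)
        if (sum(d2 <= tol) > count) {
          a <- a2; dir <- v2; d <- d2; count <- sum(d2 <= tol); grew <- TRUE
        }
      }
      if (!grew) break
    }
    if (count > best$count) best <- list(count = count, anchor = a, direction = dir)
  }
  best
}

# minimal rotation (Rodrigues) taking unit vector v to e_z
rotation_to_z <- function(v) {
  v <- v / sqrt(sum(v^2))
  ez <- c(0, 0, 1)
  c_ <- sum(v * ez)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1))) # 180 deg about x
  ax <- c(v[2] * ez[3] - v[3] * ez[2],
          v[3] * ez[1] - v[1] * ez[3],
          v[1] * ez[2] - v[2] * ez[1])
  s <- sqrt(sum(ax^2))
  ax <- ax / s
  K <- matrix(c(0, -ax[3], ax[2],
                ax[3], 0, -ax[1],
                -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

# TRUE when the lower z half has larger radial (x-y) spread than the upper,
# i.e. the leafy canopy currently points down
canopy_is_down <- function(aligned) {
  zmid <- stats::median(aligned[, 3])
  radial <- sqrt(aligned[, 1]^2 + aligned[, 2]^2)
  lower <- radial[aligned[, 3] <= zmid]
  upper <- radial[aligned[, 3] > zmid]
  if (length(upper) == 0 || length(lower) == 0) return(FALSE)
  mean(lower) > mean(upper)
}

#' Plant height of an aligned cloud
#'
#' The z extent `max(z) - min(z)`: distance from the soil-contact point to the
#' canopy top once the growth axis is aligned with z and the cloud scaled to
#' mm.
#'
#' @param cloud A non-empty, aligned, scaled [point_cloud()].
#' @return Height in the cloud's length units (mm when scaled).
#' @export
plant_height <- function(cloud) {
  if (nrow(cloud) == 0) stop("cannot measure the height of an empty cloud", call. = FALSE)
  max(cloud$z) - min(cloud$z)
}

#' RANSAC parameters for stem line fitting
#'
#' @param confidence Probability of sampling at least one outlier-free pair,
#'   default 0.99.
#' @param sample_size Minimal sample for a 3D line, 2 points.
#' @param inlier_distance Point-to-line distance below which a point supports
#'   a candidate (position units). `NULL` resolves at fit time to 1.5x the
#'   median nearest-neighbor spacing of the points being fitted.
#' @param max_iterations Hard cap on iterations, default 10000.
#' @return A `ransac_params` list.
#' @export
ransac_params <- function(confidence = 0.99, sample_size = 2,
                          inlier_distance = NULL, max_iterations = 10000) {
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)", call. = FALSE)
  if (sample_size < 2) stop("sample_size must be at least 2", call. = FALSE)
  if (!is.null(inlier_distance) && (!is.finite(inlier_distance) || inlier_distance <= 0)) {
    stop("inlier_distance must be positive", call. = FALSE)
  }
  structure(list(confidence = confidence, sample_size = as.integer(sample_size),
                 inlier_distance = inlier_distance,
                 max_iterations = as.integer(max_iterations)),
            class = "ransac_params")
}

#' Minimum RANSAC iteration count
#'
#' The lower bound on iterations needed to see one outlier-free minimal
#' sample with probability `confidence`, assuming each draw succeeds with
#' probability `1/sample_size`:
#' \eqn{M \ge \lceil \ln(1-P) / \ln(1-1/n) \rceil}. For the default
#' P = 0.99, n = 2 this is 7. The canonical adaptive bound replaces `1/n`
#' with `w^n` (w = inlier fraction); [fit_stem_line()] uses the adaptive
#' bound floored at this value.
#'
#' @param confidence Confidence P in (0, 1).
#' @param sample_size Minimal sample size n.
#' @return Integer iteration bound.
#' @export
ransac_min_iterations <- function(confidence = 0.99, sample_size = 2) {
  as.integer(ceiling(log(1 - confidence) / log(1 - 1 / sample_size)))
}

#' Fit the stem axis by RANSAC line fitting
#'
#' Repeatedly draws 2 distinct points, forms the line through them, and
#' counts points within `inlier_distance` of it. The iteration budget adapts
#' from the best inlier fraction seen (`M = ln(1-P)/ln(1-w^n)`), never below
#' the fixed bound of [ransac_min_iterations()] and never above the cap. The
#' best consensus set is refined by a total-least-squares line (principal
#' axis of the inliers), and the returned endpoints are the extreme inlier
#' projections onto that line.
#'
#' @param points An N x 3 position matrix, or a [point_cloud()] whose
#'   positions are used; N >= 2 distinct points.
#' @param params A [ransac_params()] object.
#' @param seed Integer seed making the fit reproducible.
#' @return A `stem_line` list: `anchor`, unit `direction`, integer
#'   `inlier_indices`, `endpoints` (2 x 3 matrix), `n_iterations`.
#' @export
fit_stem_line <- function(points, params = ransac_params(), seed = 1) {
  if (inherits(points, "point_cloud")) points <- cloud_positions(points)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) stop("need at least 2 points to fit a line", call. = FALSE)
  if (nrow(unique(points)) < 2) stop("all points coincident; line undefined", call. = FALSE)
  tol <- params$inlier_distance
  if (is.null(tol)) {
    spacing <- if (n >= 2) {
      stats::median(RANN::nn2(points, k = min(2, n))$nn.dists[, min(2, n)])
    } else NA_real_
    tol <- 1.5 * spacing
    if (!is.finite(tol) || tol <= 0) tol <- 1e-6
  }
  floor_iter <- ransac_min_iterations(params$confidence, params$sample_size)

  withr::with_seed(seed, {
    best_inliers <- integer()
    m_required <- params$max_iterations
    iter <- 0L
    while (iter < m_required || iter < floor_iter) {
      iter <- iter + 1L
      if (iter > params$max_iterations) break
      pick <- sample.int(n, 2)
      p0 <- points[pick[1], ]
      dir <- points[pick[2], ] - p0
      len <- sqrt(sum(dir^2))
      if (len < 1e-12) next
      dir <- dir / len
      d <- point_line_distance(points, p0, dir)
      inl <- which(d <= tol)
      if (length(inl) > length(best_inliers)) {
        # local optimization: refit by TLS on the consensus set (and on a
        # 2x-widened band, so a tilted sample line across a thick structure
        # such as the stalk surface can reach the structure's true axis),
        # recount at tol, and keep whichever capture is larger
        for (lo in 1:4) {
          if (length(inl) < 2) break
          grew <- FALSE
          for (cand_set in list(which(d <= 2 * tol), inl)) {
            sub <- points[cand_set, , drop = FALSE]
            a2 <- colMeans(sub)
            v2 <- eigen(crossprod(sweep(sub, 2, a2)), symmetric = TRUE)$vectors[, 1]
            d2 <- point_line_distance(points, a2, v2)
            inl2 <- which(d2 <= tol)
            if (length(inl2) > length(inl)) {
              inl <- inl2
              d <- d2
              grew <- TRUE
            }
          }
          if (!grew) break
        }
        best_inliers <- inl
        w <- length(inl) / n
        # adaptive standard bound, floored at the fixed minimum
        m_adapt <- if (w >= 1) 0 else {
          log(1 - params$confidence) / log(1 - w^params$sample_size)
        }
        m_required <- min(params$max_iterations,
                          max(floor_iter, ceiling(m_adapt)))
      }
    }
  })

  # least-squares refinement on the consensus set
  inl_pts <- points[best_inliers, , drop = FALSE]
  anchor <- colMeans(inl_pts)
  centered <- sweep(inl_pts, 2, anchor)
  direction <- eigen(crossprod(centered), symmetric = TRUE)$vectors[, 1]
  direction <- direction / sqrt(sum(direction^2))
  if (direction[3] < 0) direction <- -direction # point up by convention
  t_proj <- centered %*% direction
  endpoints <- rbind(anchor + min(t_proj) * direction,
                     anchor + max(t_proj) * direction)
  rownames(endpoints) <- c("base", "top")
  structure(list(anchor = anchor, direction = as.vector(direction),
                 inlier_indices = best_inliers, endpoints = endpoints,
                 inlier_distance = tol, n_iterations = iter),
            class = "stem_line")
}

point_line_distance <- function(points, anchor, direction) {
  rel <- sweep(as.matrix(points), 2, anchor)
  proj <- rel %*% direction
  sqrt(pmax(0, rowSums(rel^2) - as.vector(proj)^2))
}

#' @export
print.stem_line <- function(x, ...) {
  cat(sprintf(
    "<stem_line: %d inliers, direction (%.3f, %.3f, %.3f), length %.2f>\n",
    length(x$inlier_indices), x$direction[1], x$direction[2], x$direction[3],
    stem_height(x)))
  invisible(x)
}

#' Stem height from a fitted stem line
#'
#' The Euclidean distance between the two extreme inlier projections on the
#' RANSAC line — the stalk length from base to the topmost stem point.
#'
#' @param line A [fit_stem_line()] result.
#' @return Length in the cloud's units (mm when scaled).
#' @export
stem_height <- function(line) {
  if (length(line$inlier_indices) < 2) {
    stop("degenerate stem line: fewer than 2 inliers", call. = FALSE)
  }
  euclidean_distance(line$endpoints[1, ], line$endpoints[2, ])
}

#' Leaf measurements from picked extreme points
#'
#' Leaf length is the straight-line (chord) distance between the two
#' longitudinal extreme points; width is the distance between the two
#' transverse extreme points; relative leaf area is their product — a proxy
#' that ignores leaf curvature and lobing, adequate for the weakly curled
#' leaves of seedlings.
#'
#' @param tip_a,tip_b Length-3 points at the leaf base and apex (mm).
#' @param edge_a,edge_b Length-3 points at the widest transverse extent (mm).
#' @return A one-row tibble with columns `length`, `width`,
#'   `relative_area` (mm, mm, mm^2).
#' @export
measure_leaf <- function(tip_a, tip_b, edge_a, edge_b) {
  len <- euclidean_distance(tip_a, tip_b)
  wid <- euclidean_distance(edge_a, edge_b)
  tibble::tibble(length = len, width = wid, relative_area = len * wid)
}

#' Automatic leaf extreme-point picking
#'
#' An automated stand-in for interactive point selection: the tip pair is the
#' most distant pair of leaf points (the longitudinal chord), and the width
#' pair is the most distant pair along the direction orthogonal to the chord
#' within the leaf's best-fit plane. On a collinear leaf the width pair
#' degenerates to distance 0.
#'
#' @param leaf_points Integer indices of the leaf's points in `cloud`, or an
#'   N x 3 matrix of leaf positions (then `cloud` is ignored).
#' @param cloud The cloud the indices refer to.
#' @return A list with length-3 points `tip_a`, `tip_b`, `edge_a`, `edge_b`.
#' @export
auto_leaf_extremes <- function(leaf_points, cloud = NULL) {
  pts <- if (is.matrix(leaf_points)) leaf_points else {
    cloud_positions(cloud)[leaf_points, , drop = FALSE]
  }
  if (nrow(pts) < 4) stop("need at least 4 leaf points", call. = FALSE)
  # tip pair: diameter of the point set (exact pairwise scan)
  dm <- as.matrix(stats::dist(pts))
  far <- arrayInd(which.max(dm), dim(dm))
  tip_i <- sort(far[1, ])
  chord <- pts[tip_i[2], ] - pts[tip_i[1], ]
  chord <- chord / sqrt(sum(chord^2))
  # width direction: orthogonal to the chord, within the best-fit plane
  ctr <- colMeans(pts)
  centered <- sweep(pts, 2, ctr)
  normal <- eigen(crossprod(centered), symmetric = TRUE)$vectors[, 3]
  wdir <- c(chord[2] * normal[3] - chord[3] * normal[2],
            chord[3] * normal[1] - chord[1] * normal[3],
            chord[1] * normal[2] - chord[2] * normal[1])
  wlen <- sqrt(sum(wdir^2))
  if (wlen < 1e-12) {
    # collinear leaf: no transverse extent
    return(list(tip_a = pts[tip_i[1], ], tip_b = pts[tip_i[2], ],
                edge_a = pts[tip_i[1], ], edge_b = pts[tip_i[1], ]))
  }
  wdir <- wdir / wlen
  s <- centered %*% wdir
  list(tip_a = pts[tip_i[1], ], tip_b = pts[tip_i[2], ],
       edge_a = pts[which.min(s), ], edge_b = pts[which.max(s), ])
}
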