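#' Parameters of the synthetic maize-seedling generator
#'
#' Defaults describe a V3–V4 maize seedling as reconstructed by multi-view
#' photogrammetry: a vertical stalk with 2–8 alternately attached, gently
#' bowed ribbon leaves, surface-sampled at photogrammetric density, colored
#' by a green sampler guaranteed to pass the default [color_thresholds()].
#'
#' @param stem_length Stalk length in mm (default 90).
#' @param stem_radius Stalk radius in mm (default 5).
#' @param n_leaves Number of leaves, 2–8 (default 4).
#' @param leaf_length Per-leaf chord length in mm; a single value is recycled,
#'   `NULL` draws each from U(60, 140).
#' @param leaf_width Per-leaf maximal width in mm; `NULL` draws from U(10, 16).
#' @param leaf_curl Bow height as a fraction of the chord (default 0.12;
#'   0 gives flat, coplanar leaves).
#' @param point_density Surface sampling density in points per mm^2
#'   (default 2).
#' @param jitter_sd Isotropic Gaussian positional jitter in mm (default 0.12),
#'   mimicking reconstruction noise; 0 gives exact surfaces.
#' @param k_scale Millimetres per model unit of the emitted scene (default 1).
#'   The generator works in mm and divides positions by `k_scale`, so the
#'   scene arrives "unscaled" exactly as a photogrammetric model would.
#' @return A `plant_params` list.
#' @export
plant_params <- function(stem_length = 90, stem_radius = 5, n_leaves = 4,
                         leaf_length = NULL, leaf_width = NULL,
                         leaf_curl = 0.12, point_density = 2,
                         jitter_sd = 0.12, k_scale = 1) {
  if (stem_length <= 0 || stem_radius <= 0 || point_density <= 0 || k_scale <= 0) {
    stop("dimensions, density and k_scale must be positive", call. = FALSE)
  }
  if (n_leaves < 2 || n_leaves > 8) stop("n_leaves must be in 2..8", call. = FALSE)
  if (jitter_sd < 0 || leaf_curl < 0) stop("jitter_sd and leaf_curl must be >= 0", call. = FALSE)
  structure(list(stem_length = stem_length, stem_radius = stem_radius,
                 n_leaves = as.integer(n_leaves), leaf_length = leaf_length,
                 leaf_width = leaf_width, leaf_curl = leaf_curl,
                 point_density = point_density, jitter_sd = jitter_sd,
                 k_scale = k_scale),
            class = "plant_params")
}

# integer-green sampler rejection-constrained to pass the default thresholds
sample_green <- function(n, thresholds = color_thresholds()) {
  out <- matrix(NA_integer_, n, 3)
  need <- seq_len(n)
  while (length(need) > 0) {
    r <- sample(40:90, length(need), replace = TRUE)
    g <- sample(120:200, length(need), replace = TRUE)
    b <- sample(20:80, length(need), replace = TRUE)
    ok <- color_keep(r, g, b, thresholds)
    out[need[ok], ] <- cbind(r, g, b)[ok, , drop = FALSE]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic maize seedling with exact ground truth
#'
#' The stalk is a surface-sampled cylinder along +z from the origin; each
#' leaf is a quadratic-Bezier ribbon attached to the stalk at a distinct
#' height, with a parabolic width profile maximal at mid-leaf. The four
#' extreme points of every leaf (the two chord endpoints and the two widest
#' transverse edge points) are injected exactly and unjittered, so the
#' recorded tip and width pairs are true measurements, not approximations.
#'
#' @param params A [plant_params()] object.
#' @param seed Integer seed; the same seed reproduces the scene bit for bit.
#' @return A `maize_scene` list with elements `cloud` (a [point_cloud()] in
#'   model units) and `truth` (see Details).
#' @details `truth` holds: `height` (mm, `max z - min z` of the plant points
#'   by construction), `stem_endpoints` (2 x 3, mm), `stem_indices`,
#'   `leaves` (per leaf: point indices, exact tip/edge points in mm, chord
#'   length, width, relative area), `background_indices`, `noise_indices`,
#'   `edge_candidates` (leaf-boundary points eligible for white noise),
#'   `k_scale`, and `seed`.
#' @export
generate_plant <- function(params = plant_params(), seed = 1) {
  stopifnot(inherits(params, "plant_params"))
  withr::with_seed(seed, generate_plant_impl(params, seed))
}

generate_plant_impl <- function(params, seed) {
  p <- params
  spacing <- 1 / sqrt(p$point_density)

  # stalk: structured cylindrical grid, slight radial jitter
  nz <- max(4L, ceiling(p$stem_length / spacing))
  na <- max(8L, ceiling(2 * pi * p$stem_radius / spacing))
  zg <- seq(0, p$stem_length, length.out = nz)
  ag <- seq(0, 2 * pi, length.out = na + 1)[-(na + 1)]
  grid <- expand.grid(z = zg, a = ag)
  stem <- cbind(p$stem_radius * cos(grid$a), p$stem_radius * sin(grid$a), grid$z)

  # leaves: attachment heights stepped down from 0.95 of the stalk,
  # >= 15% of stem length apart (shrinks only when 7-8 leaves force it)
  n <- p$n_leaves
  step <- min(0.15, 0.8 / max(1, n - 1))
  attach_frac <- 0.95 - step * (seq_len(n) - 1)
  azimuth <- (seq_len(n) %% 2) * pi + stats::runif(n, -pi / 12, pi / 12)
  # upper (younger) leaves are the most erect, as on a real seedling; the
  # decreasing elevation down the stalk also keeps same-side leaves divergent
  elevation <- sort(stats::runif(n, 35, 55), decreasing = TRUE) * pi / 180
  chord <- if (is.null(p$leaf_length)) stats::runif(n, 60, 140) else rep_len(p$leaf_length, n)
  width <- if (is.null(p$leaf_width)) stats::runif(n, 10, 16) else rep_len(p$leaf_width, n)

  leaf_pts <- list(); leaf_edge <- list(); leaf_truth <- list()
  for (i in seq_len(n)) {
    u <- c(cos(azimuth[i]) * cos(elevation[i]),
           sin(azimuth[i]) * cos(elevation[i]),
           sin(elevation[i]))
    p0 <- c(p$stem_radius * cos(azimuth[i]), p$stem_radius * sin(azimuth[i]),
            attach_frac[i] * p$stem_length)
    p2 <- p0 + chord[i] * u
    # bow normal: in-plane vertical component orthogonal to the chord
    nb <- c(0, 0, 1) - sum(c(0, 0, 1) * u) * u
    nb <- nb / sqrt(sum(nb^2))
    p1 <- (p0 + p2) / 2 + p$leaf_curl * chord[i] * nb
    wdir <- c(u[2] * nb[3] - u[3] * nb[2],
              u[3] * nb[1] - u[1] * nb[3],
              u[1] * nb[2] - u[2] * nb[1])
    wdir <- wdir / sqrt(sum(wdir^2))

    nt <- max(10L, ceiling(chord[i] / spacing))
    tg <- seq(0, 1, length.out = nt)
    rows <- list(); edges <- list()
    for (t in tg) {
      bez <- (1 - t)^2 * p0 + 2 * t * (1 - t) * p1 + t^2 * p2
      half <- width[i] * 4 * t * (1 - t) / 2 # parabolic profile, max mid-leaf
      ns <- max(1L, ceiling(2 * half / spacing))
      s <- if (ns == 1) 0 else seq(-half, half, length.out = ns)
      rows[[length(rows) + 1]] <- sweep(outer(s, wdir), 2, bez, "+")
      edges[[length(edges) + 1]] <- if (ns == 1) TRUE else abs(s) >= 0.85 * half
    }
    pts <- do.call(rbind, rows)
    edge <- unlist(edges)
    # exact extreme points: chord endpoints and the two widest edge points
    mid <- 0.25 * p0 + 0.5 * p1 + 0.25 * p2
    edge_a <- mid - (width[i] / 2) * wdir
    edge_b <- mid + (width[i] / 2) * wdir
    exact <- rbind(p0, p2, edge_a, edge_b)
    leaf_pts[[i]] <- list(sampled = pts, exact = exact)
    leaf_edge[[i]] <- edge
    leaf_truth[[i]] <- list(tip_a = p0, tip_b = p2, edge_a = edge_a,
                            edge_b = edge_b, chord_length = chord[i],
                            width = width[i],
                            relative_area = chord[i] * width[i])
  }

  # assemble in mm, jitter sampled points only, then record indices
  jitter <- function(m) {
    if (p$jitter_sd == 0) m
    else m + matrix(stats::rnorm(length(m), 0, p$jitter_sd), nrow(m), 3)
  }
  blocks <- list(jitter(stem))
  stem_idx <- seq_len(nrow(stem))
  offset <- nrow(stem)
  edge_candidates <- integer()
  for (i in seq_len(n)) {
    sampled <- jitter(leaf_pts[[i]]$sampled)
    block <- rbind(sampled, leaf_pts[[i]]$exact)
    idx <- offset + seq_len(nrow(block))
    leaf_truth[[i]]$indices <- idx
    edge_candidates <- c(edge_candidates,
                         idx[seq_len(nrow(sampled))][leaf_edge[[i]]])
    blocks[[length(blocks) + 1]] <- block
    offset <- offset + nrow(block)
  }
  pos_mm <- do.call(rbind, blocks)
  colors <- sample_green(nrow(pos_mm))

  cloud <- point_cloud(
    x = pos_mm[, 1] / p$k_scale, y = pos_mm[, 2] / p$k_scale,
    z = pos_mm[, 3] / p$k_scale,
    r = colors[, 1], g = colors[, 2], b = colors[, 3]
  )
  truth <- list(
    height = max(pos_mm[, 3]) - min(pos_mm[, 3]),
    stem_endpoints = rbind(base = c(0, 0, 0), top = c(0, 0, p$stem_length)),
    stem_length = p$stem_length,
    stem_indices = stem_idx,
    leaves = leaf_truth,
    background_indices = integer(),
    noise_indices = integer(),
    edge_candidates = edge_candidates,
    k_scale = p$k_scale,
    seed = seed,
    params = p
  )
  structure(list(cloud = cloud, truth = truth), class = "maize_scene")
}

#' @export
print.maize_scene <- function(x, ...) {
  cat(sprintf(paste0(
    "<maize_scene: %d points (%d background, %d noise), %d leaves, ",
    "true height %.1f mm, k = %g mm/unit>\n"),
    nrow(x$cloud), length(x$truth$background_indices),
    length(x$truth$noise_indices), length(x$truth$leaves),
    x$truth$height, x$truth$k_scale))
  invisible(x)
}

#' Append non-plant background structures to a scene
#'
#' Adds the furniture a real recording contains: a horizontal table plane, a
#' pot (cylinder shell) below the stem base, and a planar checkerboard of
#' 25 mm squares lying on the table. All background colors fail the default
#' [color_thresholds()], and every structure is separated from the plant by
#' well more than the default clustering distance, so Euclidean clustering
#' isolates the seedling.
#'
#' @param scene A `maize_scene` from [generate_plant()].
#' @param gap Vertical clearance between the stem base and the pot rim, mm
#'   (default 8).
#' @param seed Integer seed for the background sampling.
#' @return The scene with background points appended and
#'   `truth$background_indices` filled; `truth$checker_edge_virtual` records
#'   the checkerboard square edge in model units (`25 / k_scale`).
#' @export
add_background <- function(scene, gap = 8, seed = scene$truth$seed + 1000L) {
  stopifnot(inherits(scene, "maize_scene"))
  withr::with_seed(seed, add_background_impl(scene, gap))
}

add_background_impl <- function(scene, gap) {
  p <- scene$truth$params
  # scenery is sampled coarser than the plant: it only has to cluster apart
  # and fail the color filter, not support measurement
  spacing <- max(1.5, 1 / sqrt(p$point_density))
  grid2 <- function(x, y) as.matrix(expand.grid(x = x, y = y))

  pot_h <- 40; pot_r <- 45
  pot_top <- -gap
  table_z <- pot_top - pot_h - gap

  # pot shell
  na <- ceiling(2 * pi * pot_r / spacing)
  zg <- seq(table_z + gap, pot_top, by = spacing)
  ag <- seq(0, 2 * pi, length.out = na + 1)[-(na + 1)]
  g <- expand.grid(z = zg, a = ag)
  pot <- cbind(pot_r * cos(g$a), pot_r * sin(g$a), g$z)
  pot_col <- cbind(sample(150:175, nrow(pot), TRUE),
                   sample(70:90, nrow(pot), TRUE),
                   sample(50:70, nrow(pot), TRUE)) # terracotta, r-dominant

  # table plane (coarser still: big surface)
  ts <- spacing * 2
  tbl <- grid2(seq(-120, 120, by = ts), seq(-120, 120, by = ts))
  tbl <- cbind(tbl, table_z)
  tbl_col <- cbind(sample(120:150, nrow(tbl), TRUE),
                   sample(95:115, nrow(tbl), TRUE),
                   sample(55:75, nrow(tbl), TRUE)) # wood brown, r > g

  # 4 x 4 checkerboard of 25 mm squares on the table, off to one side
  sq <- 25
  cb0 <- c(90, -50)
  cb <- grid2(seq(0, 4 * sq, by = spacing), seq(0, 4 * sq, by = spacing))
  sq_i <- (floor(cb[, 1] / sq) + floor(cb[, 2] / sq)) %% 2
  cb3 <- cbind(cb[, 1] + cb0[1], cb[, 2] + cb0[2], table_z + 0.5)
  dark <- sq_i == 0
  cb_col <- matrix(0L, nrow(cb3), 3)
  cb_col[dark, ] <- matrix(rep(sample(25:40, sum(dark), TRUE), 3), ncol = 3)
  cb_col[!dark, ] <- matrix(rep(sample(235:250, sum(!dark), TRUE), 3), ncol = 3)

  bg_mm <- rbind(pot, tbl, cb3)
  bg_col <- rbind(pot_col, tbl_col, cb_col)

  n0 <- nrow(scene$cloud)
  add <- tibble::tibble(
    x = bg_mm[, 1] / p$k_scale, y = bg_mm[, 2] / p$k_scale,
    z = bg_mm[, 3] / p$k_scale,
    r = as.integer(bg_col[, 1]), g = as.integer(bg_col[, 2]),
    b = as.integer(bg_col[, 3])
  )
  cloud <- new_point_cloud(dplyr::bind_rows(tibble::as_tibble(scene$cloud), add),
                           unit_scale = unit_scale(scene$cloud))
  scene$cloud <- cloud
  scene$truth$background_indices <- n0 + seq_len(nrow(add))
  scene$truth$checker_edge_virtual <- sq / p$k_scale
  scene
}

#' Inject white edge noise around the leaves
#'
#' Emulates the near-white speckle that photogrammetric reconstruction
#' scatters along leaf boundaries: `floor(fraction * N_plant)` points with
#' all channels in 230–255, displaced at most 2 mm from randomly chosen
#' leaf-boundary points.
#'
#' @param scene A `maize_scene`.
#' @param fraction Noise points as a fraction of the plant point count,
#'   in `[0, 1)`.
#' @param seed Integer seed.
#' @return The scene with noise appended and `truth$noise_indices` filled.
#' @export
add_edge_noise <- function(scene, fraction = 0.1, seed = scene$truth$seed + 2000L) {
  stopifnot(inherits(scene, "maize_scene"))
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)", call. = FALSE)
  if (fraction == 0) return(scene)
  withr::with_seed(seed, {
    p <- scene$truth$params
    n_plant <- length(scene$truth$stem_indices) +
      sum(lengths(lapply(scene$truth$leaves, `[[`, "indices")))
    n_noise <- floor(fraction * n_plant)
    anchors <- sample(scene$truth$edge_candidates, n_noise, replace = TRUE)
    base <- cloud_positions(scene$cloud)[anchors, , drop = FALSE] * p$k_scale
    # uniform displacement in a ball of radius 2 mm
    dir <- matrix(stats::rnorm(3 * n_noise), n_noise, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    rad <- 2 * stats::runif(n_noise)^(1 / 3)
    pos <- base + dir * rad
    col <- cbind(sample(230:255, n_noise, TRUE),
                 sample(230:255, n_noise, TRUE),
                 sample(230:255, n_noise, TRUE))
    n0 <- nrow(scene$cloud)
    add <- tibble::tibble(
      x = pos[, 1] / p$k_scale, y = pos[, 2] / p$k_scale, z = pos[, 3] / p$k_scale,
      r = as.integer(col[, 1]), g = as.integer(col[, 2]), b = as.integer(col[, 3])
    )
    scene$cloud <- new_point_cloud(
      dplyr::bind_rows(tibble::as_tibble(scene$cloud), add),
      unit_scale = unit_scale(scene$cloud))
    scene$truth$noise_indices <- n0 + seq_len(n_noise)
    scene
  })
}

#' All plant point indices of a scene
#'
#' @param scene A `maize_scene`.
#' @return Sorted integer indices of stem plus leaf points.
#' @export
plant_indices <- function(scene) {
  sort(c(scene$truth$stem_indices,
         unlist(lapply(scene$truth$leaves, `[[`, "indices"), use.names = FALSE)))
}
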