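#' Full-pipeline configuration
#'
#' Collects every stage parameter with its default; serializes to/from JSON
#' with [write_pipeline_config()] / [read_pipeline_config()]. Unknown keys in
#' a config file are rejected rather than ignored.
#'
#' @param cluster [clustering_params()].
#' @param thresholds [color_thresholds()].
#' @param voxel Voxel edge length in model units, or `NULL` to skip
#'   downsampling... default 1 model unit (1 mm at unit scale).
#' @param ransac [ransac_params()].
#' @param region [region_growing_params()].
#' @param scale_real Reference length in mm (checkerboard square, default 25).
#' @param scale_virtual The same length in model units; `NULL` means the
#'   cloud is already metric (`k = 1`).
#' @param seed Master seed governing RANSAC and any sampling.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cluster = clustering_params(),
                            thresholds = color_thresholds(),
                            voxel = 1,
                            ransac = ransac_params(),
                            region = region_growing_params(),
                            scale_real = 25,
                            scale_virtual = NULL,
                            seed = 1) {
  structure(list(cluster = cluster, thresholds = thresholds, voxel = voxel,
                 ransac = ransac, region = region, scale_real = scale_real,
                 scale_virtual = scale_virtual, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  plain <- lapply(unclass(config), function(x) {
    if (inherits(x, c("clustering_params", "color_thresholds", "ransac_params",
                      "region_growing_params"))) unclass(x) else x
  })
  # Inf does not survive JSON; encode as the string "Inf"
  if (is.infinite(plain$cluster$max_cluster_size)) plain$cluster$max_cluster_size <- "Inf"
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (identical(raw$cluster$max_cluster_size, "Inf")) raw$cluster$max_cluster_size <- Inf
  pipeline_config(
    cluster = do.call(clustering_params, as.list(raw$cluster)),
    thresholds = do.call(color_thresholds, as.list(raw$thresholds)),
    voxel = raw$voxel,
    ransac = do.call(ransac_params, as.list(raw$ransac)),
    region = do.call(region_growing_params, as.list(raw$region)),
    scale_real = raw$scale_real,
    scale_virtual = raw$scale_virtual,
    seed = raw$seed
  )
}

#' Run the full phenotyping pipeline on a scene
#'
#' Executes the processing chain on a raw colored scene: Euclidean
#' clustering, plant-cluster selection, color filtering, voxel downsampling,
#' metric scaling, growth-axis alignment, plant/stem measurement, and
#' region-growing stem/leaf segmentation with per-leaf measurements (extreme
#' points picked automatically unless supplied).
#'
#' @param scene A [point_cloud()], a `maize_scene`, or a file path readable
#'   by [read_cloud()].
#' @param config A [pipeline_config()].
#' @param leaf_picks Optional list of per-leaf manual picks, each a list with
#'   `tip_a`, `tip_b`, `edge_a`, `edge_b` (scaled mm coordinates); replaces
#'   automatic extreme-point picking.
#' @return A `pipeline_result` list: `phenotype` (one-row tibble: height,
#'   stem height, leaf count), `leaves` (per-leaf tibble), `segmentation`,
#'   `cloud` (the processed, aligned, scaled plant cloud), `stem_line`,
#'   `stage_counts` (tibble of point counts per stage), `config`.
#' @export
run_pipeline <- function(scene, config = pipeline_config(), leaf_picks = NULL) {
  cloud <- if (inherits(scene, "maize_scene")) scene$cloud
           else if (inherits(scene, "point_cloud")) scene
           else read_cloud(scene)
  if (nrow(cloud) == 0) stop("pipeline input stage: empty point cloud", call. = FALSE)
  counts <- list(raw = nrow(cloud))

  clusters <- euclidean_cluster(cloud, config$cluster)
  if (length(clusters) == 0) {
    stop("clustering stage: no cluster of at least ",
         config$cluster$min_cluster_size, " points", call. = FALSE)
  }
  plant_idx <- select_plant_cluster(clusters, cloud, config$thresholds)
  plant <- new_point_cloud(tibble::as_tibble(cloud)[plant_idx, , drop = FALSE],
                           unit_scale = unit_scale(cloud))
  counts$plant_cluster <- nrow(plant)

  plant <- color_filter(plant, config$thresholds)
  counts$color_filtered <- nrow(plant)
  if (nrow(plant) == 0) stop("color-filter stage: no vegetation points left", call. = FALSE)

  if (!is.null(config$voxel)) plant <- voxel_downsample(plant, voxel_params(config$voxel))
  counts$voxel_filtered <- nrow(plant)

  k <- if (is.null(config$scale_virtual)) 1 else {
    calibrate_scale(config$scale_real, config$scale_virtual)$k
  }
  if (k != 1) plant <- apply_scale(plant, k)

  aligned <- align_to_z(plant)
  plant <- aligned$cloud

  seg <- region_grow(plant, params = config$region)
  seg <- classify_regions(seg, plant, seed = config$seed)

  # stem candidates: the classified stem region when present, else points
  # below the lowest leaf region, else the whole plant
  stem_region <- which(seg$region_kind == "stem")
  stem_pts_idx <- if (length(stem_region) == 1) {
    which(seg$labels == stem_region - 1L)
  } else {
    leaf_regions <- which(seg$region_kind == "leaf")
    if (length(leaf_regions) > 0) {
      zmin_leaf <- min(plant$z[seg$labels %in% (leaf_regions - 1L)])
      idx <- which(plant$z < zmin_leaf)
      if (length(idx) >= 2) idx else seq_len(nrow(plant))
    } else {
      seq_len(nrow(plant))
    }
  }
  line <- fit_stem_line(cloud_positions(plant)[stem_pts_idx, , drop = FALSE],
                        config$ransac, seed = config$seed)
  line$inlier_indices <- stem_pts_idx[line$inlier_indices]

  leaf_regions <- which(seg$region_kind == "leaf")
  leaves <- purrr::map_dfr(seq_along(leaf_regions), function(j) {
    idx <- which(seg$labels == leaf_regions[j] - 1L)
    picks <- if (!is.null(leaf_picks) && j <= length(leaf_picks)) leaf_picks[[j]]
             else auto_leaf_extremes(idx, plant)
    dplyr::bind_cols(tibble::tibble(leaf = j, n_points = length(idx)),
                     measure_leaf(picks$tip_a, picks$tip_b,
                                  picks$edge_a, picks$edge_b))
  })

  phenotype <- tibble::tibble(
    plant_height = plant_height(plant),
    stem_height = stem_height(line),
    n_leaves = count_leaves(seg),
    n_points = nrow(plant),
    unit_scale = unit_scale(plant)
  )
  structure(list(
    phenotype = phenotype, leaves = leaves, segmentation = seg,
    cloud = plant, stem_line = line,
    stage_counts = tibble::tibble(stage = names(counts),
                                  n_points = unlist(counts, use.names = FALSE)),
    config = config
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  plant height %.1f mm | stem height %.1f mm | %d leaves\n",
              x$phenotype$plant_height, x$phenotype$stem_height,
              x$phenotype$n_leaves))
  cat(sprintf("  stage counts: %s\n",
              paste(sprintf("%s=%d", x$stage_counts$stage,
                            x$stage_counts$n_points), collapse = " -> ")))
  invisible(x)
}
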