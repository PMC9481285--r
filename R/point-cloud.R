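#' Build a colored point cloud
#'
#' A point cloud is a tibble with one row per point and columns `x`, `y`, `z`
#' (real coordinates) and `r`, `g`, `b` (integer colors in `[0, 255]`).
#' Coordinates are in dimensionless model units as reconstructed; after
#' [apply_scale()] they are in millimetres and the cloud's `unit_scale`
#' attribute records the mm-per-model-unit factor (1 = unscaled).
#'
#' @param x,y,z Numeric coordinate vectors of equal length. All values must be
#'   finite.
#' @param r,g,b Integer color channels in `[0, 255]`, same length as the
#'   coordinates. Fractional color values are rejected rather than rescaled:
#'   a cloud with colors in `[0, 1]` is ambiguous and must be converted by the
#'   caller.
#' @param unit_scale Millimetres per model unit (default 1, i.e. unscaled).
#'
#' @return A `point_cloud` tibble.
#' @examples
#' pc <- point_cloud(x = c(0, 1), y = c(0, 0), z = c(0, 2),
#'                   r = c(60, 60), g = c(150, 150), b = c(40, 40))
#' pc
#' @export
point_cloud <- function(x = double(), y = double(), z = double(),
                        r = integer(), g = integer(), b = integer(),
                        unit_scale = 1) {
  out <- tibble::tibble(
    x = as.double(x), y = as.double(y), z = as.double(z),
    r = r, g = g, b = b
  )
  new_point_cloud(out, unit_scale = unit_scale)
}

#' Coerce a data frame to a point cloud
#'
#' @param df A data frame with columns `x`, `y`, `z`, `r`, `g`, `b`.
#' @inheritParams point_cloud
#' @return A validated `point_cloud` tibble.
#' @export
as_point_cloud <- function(df, unit_scale = 1) {
  needed <- c("x", "y", "z", "r", "g", "b")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("missing point-cloud columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  new_point_cloud(tibble::as_tibble(df[needed]), unit_scale = unit_scale)
}

new_point_cloud <- function(df, unit_scale = 1) {
  validate_point_cloud(df)
  if (!is.numeric(unit_scale) || length(unit_scale) != 1 || !is.finite(unit_scale) ||
      unit_scale <= 0) {
    stop("unit_scale must be a single positive number", call. = FALSE)
  }
  df$r <- as.integer(df$r)
  df$g <- as.integer(df$g)
  df$b <- as.integer(df$b)
  attr(df, "unit_scale") <- as.double(unit_scale)
  class(df) <- c("point_cloud", class(tibble::tibble()))
  df
}

validate_point_cloud <- function(df) {
  for (ax in c("x", "y", "z")) {
    v <- df[[ax]]
    if (!is.numeric(v)) stop("coordinate column ", ax, " must be numeric", call. = FALSE)
    if (length(v) > 0 && any(!is.finite(v))) {
      stop("non-finite coordinate in column ", ax, call. = FALSE)
    }
  }
  for (ch in c("r", "g", "b")) {
    v <- df[[ch]]
    if (!is.numeric(v)) stop("color column ", ch, " must be numeric", call. = FALSE)
    if (length(v) > 0) {
      if (any(!is.finite(v)) || any(v != round(v))) {
        stop("color column ", ch, " must hold integers in [0, 255]; ",
             "fractional colors (e.g. [0,1] floats) are not rescaled", call. = FALSE)
      }
      if (any(v < 0 | v > 255)) {
        stop("color column ", ch, " out of [0, 255]", call. = FALSE)
      }
    }
  }
  invisible(df)
}

#' @export
print.point_cloud <- function(x, ...) {
  scale <- unit_scale(x)
  cat(sprintf("# A point cloud: %d points, unit_scale = %g mm/unit%s\n",
              nrow(x), scale, if (scale == 1) " (unscaled)" else ""))
  NextMethod()
}

#' Millimetres per model unit of a cloud
#'
#' @param cloud A `point_cloud`.
#' @return A single number; 1 means the cloud is unscaled model units.
#' @export
unit_scale <- function(cloud) {
  s <- attr(cloud, "unit_scale")
  if (is.null(s)) 1 else s
}

# N x 3 position matrix (no copy of colors)
cloud_positions <- function(cloud) {
  cbind(x = cloud$x, y = cloud$y, z = cloud$z)
}

cloud_colors <- function(cloud) {
  cbind(r = cloud$r, g = cloud$g, b = cloud$b)
}
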