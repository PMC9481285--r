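#' Read a colored point cloud from disk
#'
#' Supports ASCII PLY (`element vertex` with properties `x y z` and
#' `red green blue`, also accepted under the names `r g b` or
#' `diffuse_red/green/blue`) and whitespace-delimited XYZRGB text with rows
#' `x y z r g b`. Binary PLY is rejected with an explicit error; ASCII keeps
#' files diff-able and CloudCompare-compatible.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension: `.ply` vs anything else), `"ply"`, or
#'   `"xyzrgb"`.
#' @return A [point_cloud()] tibble with `unit_scale = 1`.
#' @seealso [write_cloud()]
#' @export
read_cloud <- function(path, format = c("auto", "ply", "xyzrgb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("point-cloud file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyzrgb"
  }
  switch(format,
    ply = read_ply_ascii(path),
    xyzrgb = read_xyzrgb(path)
  )
}

#' Write a colored point cloud to disk
#'
#' The written file round-trips through [read_cloud()]: colors exactly,
#' positions to the text precision used (`%.6f`).
#'
#' @param cloud A [point_cloud()].
#' @param path Output path; the parent directory must exist.
#' @param format `"auto"`, `"ply"` or `"xyzrgb"` (see [read_cloud()]).
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = c("auto", "ply", "xyzrgb")) {
  format <- match.arg(format)
  if (!dir.exists(dirname(path))) {
    stop("cannot write ", path, ": directory ", dirname(path), " does not exist",
         call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyzrgb"
  }
  body <- if (nrow(cloud) > 0) {
    sprintf("%.6f %.6f %.6f %d %d %d", cloud$x, cloud$y, cloud$z,
            cloud$r, cloud$g, cloud$b)
  } else {
    character()
  }
  lines <- if (format == "ply") {
    c("ply",
      "format ascii 1.0",
      "comment written by seedling3d",
      sprintf("element vertex %d", nrow(cloud)),
      "property float x", "property float y", "property float z",
      "property uchar red", "property uchar green", "property uchar blue",
      "end_header",
      body)
  } else {
    body
  }
  writeLines(lines, path)
  invisible(path)
}

read_xyzrgb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(point_cloud())
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  n_fields <- lengths(fields)
  bad <- which(n_fields != 6)
  if (length(bad) > 0) {
    stop("malformed XYZRGB row (expected 6 fields) at line ", bad[1], " of ", path,
         call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 6, byrow = TRUE)
  bad <- which(apply(m, 1, function(row) any(!is.finite(row))))
  if (length(bad) > 0) {
    stop("non-numeric value at line ", bad[1], " of ", path, call. = FALSE)
  }
  check_color_rows(m[, 4:6, drop = FALSE], path)
  point_cloud(x = m[, 1], y = m[, 2], z = m[, 3],
              r = as.integer(m[, 4]), g = as.integer(m[, 5]), b = as.integer(m[, 6]))
}

check_color_rows <- function(cols, path) {
  bad <- which(apply(cols, 1, function(row) {
    any(row != round(row)) || any(row < 0 | row > 255)
  }))
  if (length(bad) > 0) {
    stop("color value out of integer range [0, 255] at data row ", bad[1],
         " of ", path, call. = FALSE)
  }
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || trimws(lines[1]) != "ply") {
    stop("not a PLY file (missing 'ply' magic): ", path, call. = FALSE)
  }
  header_end <- match("end_header", trimws(lines))
  if (is.na(header_end)) stop("malformed PLY header (no end_header): ", path, call. = FALSE)
  header <- trimws(lines[seq_len(header_end)])

  fmt <- grep("^format ", header, value = TRUE)
  if (length(fmt) == 0) stop("malformed PLY header (no format line): ", path, call. = FALSE)
  if (!grepl("^format ascii", fmt[1])) {
    stop("binary PLY is not supported; convert to ASCII: ", path, call. = FALSE)
  }

  # walk the elements; only 'vertex' is parsed, its property order respected
  elem_lines <- grep("^element ", header)
  if (length(elem_lines) == 0) stop("PLY header declares no elements: ", path, call. = FALSE)
  elems <- do.call(rbind, lapply(elem_lines, function(i) {
    parts <- strsplit(header[i], "[[:space:]]+")[[1]]
    data.frame(line = i, name = parts[2], count = as.integer(parts[3]))
  }))
  vi <- which(elems$name == "vertex")
  if (length(vi) != 1) stop("PLY header must declare one vertex element: ", path, call. = FALSE)

  # properties belonging to the vertex element
  next_elem <- if (vi < nrow(elems)) elems$line[vi + 1] else header_end
  prop_idx <- grep("^property ", header)
  prop_idx <- prop_idx[prop_idx > elems$line[vi] & prop_idx < next_elem]
  props <- vapply(strsplit(header[prop_idx], "[[:space:]]+"),
                  function(p) p[length(p)], character(1))

  canonical <- c(
    x = "x", y = "y", z = "z",
    red = "r", green = "g", blue = "b",
    r = "r", g = "g", b = "b",
    diffuse_red = "r", diffuse_green = "g", diffuse_blue = "b"
  )
  mapped <- canonical[props]
  need <- c("x", "y", "z", "r", "g", "b")
  if (!all(need %in% mapped)) {
    stop("PLY vertex element lacks x/y/z and red/green/blue properties: ", path,
         call. = FALSE)
  }
  col_of <- vapply(need, function(f) which(mapped == f)[1], integer(1))

  n <- elems$count[vi]
  # vertex data follow the header; preceding elements would shift rows, but
  # vertex-first is universal in practice and enforced here
  if (vi != 1 && n > 0) {
    stop("PLY with vertex element not first is unsupported: ", path, call. = FALSE)
  }
  if (n == 0) return(point_cloud())
  data_lines <- lines[(header_end + 1):length(lines)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) < n) {
    stop("PLY declares ", n, " vertices but file holds ", length(data_lines),
         " data rows: ", path, call. = FALSE)
  }
  fields <- strsplit(trimws(data_lines[seq_len(n)]), "[[:space:]]+")
  n_fields <- lengths(fields)
  if (any(n_fields < length(props))) {
    stop("truncated PLY vertex row at data line ",
         which(n_fields < length(props))[1], ": ", path, call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(
    lapply(fields, function(f) f[seq_along(props)])
  ))), ncol = length(props), byrow = TRUE)
  if (any(!is.finite(m[, col_of]))) {
    stop("non-numeric vertex value in ", path, call. = FALSE)
  }
  check_color_rows(m[, col_of[4:6], drop = FALSE], path)
  point_cloud(
    x = m[, col_of[1]], y = m[, col_of[2]], z = m[, col_of[3]],
    r = as.integer(m[, col_of[4]]),
    g = as.integer(m[, col_of[5]]),
    b = as.integer(m[, col_of[6]])
  )
}
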