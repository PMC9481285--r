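#' Absolute and relative error of one measurement pair
#'
#' The absolute error is `|measured - reference|`; the relative error is that
#' as a percentage of the reference (the manual measurement is the reference,
#' the point-cloud value the measurement). Values are returned unrounded;
#' presentation rounding is applied by [format_error_table()].
#'
#' @param reference Manually measured "real" value; must be positive.
#' @param measured Point-cloud-derived value.
#' @return A one-row tibble with `absolute` and `relative_pct`.
#' @examples
#' error_row(64.00, 69.17) # 5.17 mm, 8.08 %
#' @export
error_row <- function(reference, measured) {
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    stop("reference values must be positive for relative error", call. = FALSE)
  }
  absolute <- abs(measured - reference)
  tibble::tibble(absolute = absolute,
                 relative_pct = 100 * absolute / reference)
}

#' Per-pair and per-trait error table
#'
#' Expands a table of measurement pairs with absolute and relative errors and
#' appends per-trait averages (arithmetic means of the per-pair entries),
#' mirroring the usual "Average error" row of phenotyping error analyses.
#'
#' @param pairs A data frame with columns `trait`, `reference`, `measured`
#'   (and optionally an id column, preserved).
#' @return A tibble of the input rows plus `absolute` and `relative_pct`
#'   columns and one `summary == "average"` row per trait; errors unrounded.
#' @export
error_table <- function(pairs) {
  if (nrow(pairs) == 0) stop("no measurement pairs supplied", call. = FALSE)
  needed <- c("trait", "reference", "measured")
  if (!all(needed %in% names(pairs))) {
    stop("pairs must have columns trait, reference, measured", call. = FALSE)
  }
  rows <- tibble::as_tibble(pairs) |>
    dplyr::mutate(error_row(.data$reference, .data$measured),
                  summary = "pair")
  avgs <- rows |>
    dplyr::summarise(
      reference = NA_real_, measured = NA_real_,
      absolute = mean(.data$absolute),
      relative_pct = mean(.data$relative_pct),
      summary = "average",
      .by = "trait"
    )
  dplyr::bind_rows(rows, avgs)
}

#' Round half away from zero
#'
#' Fixed-decimal presentation rounding in the convention of printed error
#' tables (2.345 -> 2.35), unlike base `round()`'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Presentation view of an error table
#'
#' @param tab An [error_table()] result.
#' @param digits Decimal places (default 2).
#' @return The table with `absolute` and `relative_pct` rounded half away
#'   from zero.
#' @export
format_error_table <- function(tab, digits = 2) {
  tab |>
    dplyr::mutate(absolute = round_half_away(.data$absolute, digits),
                  relative_pct = round_half_away(.data$relative_pct, digits))
}

#' Agreement statistics between manual and point-cloud measurements
#'
#' Ordinary least squares of the measured values on the reference values,
#' with \eqn{R^2 = 1 - SS_{res}/SS_{tot}}. RMSE is computed on the paired
#' differences, \eqn{\sqrt{\mathrm{mean}((measured - reference)^2)}}, so it
#' is in measurement units and directly comparable with the error table; the
#' regression-residual RMSE is also reported as `rmse_residual`.
#'
#' @param pairs A data frame with columns `reference` and `measured`
#'   (>= 3 rows); a `trait` column, if present, must be single-valued.
#' @return An `agreement_fit` object; see [tidy.agreement_fit()] and
#'   [glance.agreement_fit()].
#' @export
agreement_stats <- function(pairs) {
  if (nrow(pairs) < 3) stop("need at least 3 pairs", call. = FALSE)
  if ("trait" %in% names(pairs) && length(unique(pairs$trait)) > 1) {
    stop("agreement_stats expects a single trait; split first", call. = FALSE)
  }
  x <- pairs$reference
  y <- pairs$measured
  if (stats::var(x) == 0) stop("reference values have zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    rmse = sqrt(mean((y - x)^2)),
    rmse_residual = sqrt(mean(stats::residuals(fit)^2)),
    n = length(x),
    model = fit
  ), class = "agreement_fit")
}

#' @export
print.agreement_fit <- function(x, ...) {
  cat(sprintf(
    "<agreement_fit: n = %d, R^2 = %.3f, RMSE (paired) = %.2f, y = %.3f x + %.2f>\n",
    x$n, x$r_squared, x$rmse, x$slope, x$intercept))
  invisible(x)
}

#' Tidy an agreement fit
#'
#' @param x An [agreement_stats()] result.
#' @param ... Unused.
#' @return A two-row tibble of regression terms with estimates.
#' @export
tidy.agreement_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' One-row summary of an agreement fit
#'
#' @param x An [agreement_stats()] result.
#' @param ... Unused.
#' @return A one-row tibble with `r_squared`, `rmse`, `rmse_residual`,
#'   `slope`, `intercept`, `n`.
#' @export
glance.agreement_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, rmse = x$rmse,
                 rmse_residual = x$rmse_residual,
                 slope = x$slope, intercept = x$intercept, n = x$n)
}

#' The bundled manual-vs-cloud measurement table
#'
#' Fifteen maize seedlings measured both by hand and from their point-cloud
#' reconstructions: leaf length `L` (mm), leaf width `W` (mm), relative leaf
#' area `S` (mm^2) and plant height `H` (mm); the `0`-suffixed columns are
#' the manual references.
#'
#' @param long Return tidy long format (`plant`, `trait`, `reference`,
#'   `measured`) instead of the wide table (default `TRUE`).
#' @return A tibble.
#' @export
reference_measurements <- function(long = TRUE) {
  path <- system.file("extdata", "table2.csv", package = "seedling3d",
                      mustWork = TRUE)
  wide <- utils::read.csv(path, check.names = FALSE)
  wide <- tibble::as_tibble(wide)
  if (!long) return(wide)
  traits <- c(leaf_length = "L", leaf_width = "W",
              relative_area = "S", plant_height = "H")
  purrr::imap_dfr(traits, function(sym, trait) {
    tibble::tibble(plant = wide$plant, trait = trait,
                   reference = wide[[paste0(sym, "0")]],
                   measured = wide[[sym]])
  })
}
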