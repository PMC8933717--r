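#' Load seed ellipses from CSV
#'
#' Seed files are the headless replacement for clicking on cells in a GUI:
#' one row per cell with a rough centre and radii of an initial ellipse that
#' the active contour will refine. Columns: `cell_id`, `x`, `y`, `radius_x`
#' and optionally `radius_y` (defaults to `radius_x`, i.e. the initial
#' circular guess). Coordinates are 0-based pixels, `(x, y)` = (column, row),
#' origin top-left.
#'
#' @param path CSV file path.
#' @return A `data.frame` with columns `cell_id`, `x`, `y`, `radius_x`,
#'   `radius_y`, one row per seed.
#' @export
load_seeds <- function(path) {
  df <- utils::read.csv(path, strip.white = TRUE)
  need <- c("cell_id", "x", "y", "radius_x")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .stopf("seed file missing column(s): %s", paste(miss, collapse = ", "))
  if (!"radius_y" %in% names(df)) df$radius_y <- NA_real_
  df$radius_y <- ifelse(is.na(df$radius_y), df$radius_x, df$radius_y)
  if (anyDuplicated(df$cell_id))
    .stopf("duplicate cell_id in seed file: %s",
           paste(unique(df$cell_id[duplicated(df$cell_id)]), collapse = ", "))
  if (any(!is.finite(df$radius_x)) || any(!is.finite(df$radius_y)) ||
      any(df$radius_x <= 0) || any(df$radius_y <= 0))
    .stopf("seed radii must be positive")
  df[, c("cell_id", "x", "y", "radius_x", "radius_y")]
}

#' Load watershed click points from CSV
#'
#' Click files drive the threshold + watershed segmentation path: one row per
#' cell with the clicked point inside it. Columns: `cell_id`, `x`, `y`
#' (0-based pixel coordinates).
#'
#' @param path CSV file path.
#' @return A `data.frame` with columns `cell_id`, `x`, `y`.
#' @export
load_clicks <- function(path) {
  df <- utils::read.csv(path, strip.white = TRUE)
  miss <- setdiff(c("cell_id", "x", "y"), names(df))
  if (length(miss))
    .stopf("click file missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$cell_id)) .stopf("duplicate cell_id in click file")
  df[, c("cell_id", "x", "y")]
}

#' Write seed ellipses to CSV
#'
#' @param seeds Seed `data.frame` as returned by [load_seeds()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_seeds <- function(seeds, path) {
  utils::write.csv(seeds, path, row.names = FALSE)
  invisible(path)
}
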