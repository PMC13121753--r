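#' Construct and read junction tables
#'
#' A junction table lists overdrawn cell-cell junctions: ROI and junction
#' identifiers, either endpoint coordinates (micrometres) or a precomputed
#' acute angle to the ML axis, the mean staining intensity along the
#' junction, and the channel name. Angles must lie in [0, 90] degrees and
#' intensities must be finite and non-negative.
#'
#' @param df Data frame with columns `roi_id`, `junction_id`,
#'   `mean_intensity`, optionally `channel`, and either `angle_deg` or the
#'   endpoint columns `x1_um, y1_um, x2_um, y2_um`.
#' @return A `junction_table` data frame.
#' @export
junction_table <- function(df) {
  df <- as.data.frame(df)
  for (col in c("roi_id", "junction_id", "mean_intensity"))
    if (!col %in% names(df)) stop_format("missing column '%s'", col)
  has_angle <- "angle_deg" %in% names(df)
  has_ends <- all(c("x1_um", "y1_um", "x2_um", "y2_um") %in% names(df))
  if (!has_angle && !has_ends)
    stop_format("need either 'angle_deg' or endpoint columns x1_um..y2_um")
  df$roi_id <- as.character(df$roi_id)
  df$junction_id <- as.character(df$junction_id)
  df$mean_intensity <- as.numeric(df$mean_intensity)
  if (any(!is.finite(df$mean_intensity)) || any(df$mean_intensity < 0))
    stop_validation("'mean_intensity' must be finite and >= 0")
  if (has_angle) {
    df$angle_deg <- as.numeric(df$angle_deg)
    if (any(!is.finite(df$angle_deg)) ||
        any(df$angle_deg < 0 | df$angle_deg > 90))
      stop_validation("'angle_deg' must lie in [0, 90]")
  }
  if (!"channel" %in% names(df)) df$channel <- "junction"
  rownames(df) <- NULL
  class(df) <- c("junction_table", "data.frame")
  df
}

#' @rdname junction_table
#' @param path CSV path.
#' @export
read_junctions <- function(path) {
  if (!file.exists(path)) stop_format("junction file not found: %s", path)
  junction_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname junction_table
#' @param junctions A `junction_table` to write.
#' @export
write_junctions <- function(junctions, path) {
  out <- as.data.frame(junctions)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], formatC, digits = 17, format = "g")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Construct and read dorsoventral depth tables
#'
#' Transverse-section measurements: per cell, the distance to the dorsal
#' layer (`d_um`) and to the ventral layer (`v_um`), both micrometres. The
#' relative depth D/(D+V) x 100% is appended as `relative_depth_pct`
#' (0% = at the dorsal surface).
#'
#' @param df Data frame with columns `cell_id`, `d_um`, `v_um`, optionally
#'   `group` and `embryo_id`.
#' @return A `depth_table` data frame with `relative_depth_pct` added.
#' @export
depth_table <- function(df) {
  df <- as.data.frame(df)
  for (col in c("cell_id", "d_um", "v_um"))
    if (!col %in% names(df)) stop_format("missing column '%s'", col)
  df$cell_id <- as.character(df$cell_id)
  df$d_um <- as.numeric(df$d_um)
  df$v_um <- as.numeric(df$v_um)
  if (any(!is.finite(df$d_um)) || any(!is.finite(df$v_um)) ||
      any(df$d_um < 0) || any(df$v_um < 0))
    stop_validation("'d_um' and 'v_um' must be finite and >= 0")
  if (any(df$d_um + df$v_um <= 0))
    stop_validation("D + V must be > 0 for every cell")
  df$relative_depth_pct <- relative_depth(df$d_um, df$v_um)
  rownames(df) <- NULL
  class(df) <- c("depth_table", "data.frame")
  df
}

#' @rdname depth_table
#' @param path CSV path.
#' @export
read_depths <- function(path) {
  if (!file.exists(path)) stop_format("depth file not found: %s", path)
  depth_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read and write per-cell apical-area time series
#'
#' Long-format table: `cell_id`, `time_min`, `area_um2`, optional `group`.
#' Areas must be positive while the cell is present; a cell that ingresses
#' and disappears simply stops contributing rows.
#'
#' @param path CSV path.
#' @return A data frame sorted by cell and time.
#' @export
read_area_series <- function(path) {
  if (!file.exists(path)) stop_format("area series file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("cell_id", "time_min", "area_um2"))
    if (!col %in% names(df)) stop_format("missing column '%s'", col)
  df$cell_id <- as.character(df$cell_id)
  df <- df[order(df$cell_id, df$time_min), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_area_series
#' @param series Area-series data frame to write.
#' @export
write_area_series <- function(series, path) {
  out <- as.data.frame(series)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], formatC, digits = 17, format = "g")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
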