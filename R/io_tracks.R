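#' Construct and validate a track table
#'
#' A track table holds registered 3-D trajectories, one row per cell per
#' timepoint, keyed by `(embryo_id, track_id, time_min)`. It is the substrate
#' of all motion analytics. Tracks with fewer than two timepoints carry no
#' displacement information and are dropped with a warning.
#'
#' @param df Data frame with columns `embryo_id`, `track_id`, `time_min`,
#'   `x_um`, `y_um`, `z_um` and optionally `group`.
#' @param frame Optional [tissue_frame()] attached as the `"tissue_frame"`
#'   attribute.
#' @return A `track_table` (a data frame sorted by embryo, track, time).
#' @export
track_table <- function(df, frame = NULL) {
  req <- c("embryo_id", "track_id", "time_min", "x_um", "y_um", "z_um")
  for (col in req)
    if (!col %in% names(df)) stop_format("missing column '%s'", col)
  df <- as.data.frame(df)
  df$embryo_id <- as.character(df$embryo_id)
  df$track_id <- as.character(df$track_id)
  for (col in c("time_min", "x_um", "y_um", "z_um")) {
    df[[col]] <- as.numeric(df[[col]])
    if (anyNA(df[[col]]) || any(!is.finite(df[[col]])))
      stop_format("column '%s' contains non-finite values", col)
  }
  if (any(df$time_min < 0)) stop_validation("'time_min' must be >= 0")
  key <- paste(df$embryo_id, df$track_id, df$time_min, sep = "\r")
  if (anyDuplicated(key))
    stop_validation("duplicate (embryo_id, track_id, time_min) rows: %s",
                    paste(utils::head(unique(key[duplicated(key)]), 3L),
                          collapse = "; "))
  df <- df[order(df$embryo_id, df$track_id, df$time_min), , drop = FALSE]
  tid <- paste(df$embryo_id, df$track_id, sep = "\r")
  npts <- table(tid)
  short <- names(npts)[npts < 2L]
  if (length(short)) {
    warning(sprintf("dropped %d track(s) with < 2 timepoints", length(short)),
            call. = FALSE)
    df <- df[!tid %in% short, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("track_table", "data.frame")
  attr(df, "tissue_frame") <- frame
  df
}

#' Read a track table from CSV
#'
#' The expected dialect is the minimal schema any spot-tracking export can be
#' mapped onto: comma-separated, header required, UTF-8, columns
#' `embryo_id, track_id, time_min, x_um, y_um, z_um` and optionally `group`.
#' Coordinates are micrometres in the acquisition frame, time in minutes.
#'
#' @param path CSV file path.
#' @param frame Optional [tissue_frame()] stored on the result.
#' @return A validated `track_table`; single-timepoint tracks are dropped
#'   with a warning giving their count.
#' @seealso [write_tracks()]
#' @export
read_tracks <- function(path, frame = NULL) {
  if (!file.exists(path)) stop_format("track file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  track_table(df, frame = frame)
}

#' Write a track table to CSV
#'
#' Numeric fields are written with 17 significant digits so that
#' `read_tracks(write_tracks(x))` reproduces the numeric content exactly.
#'
#' @param tracks A `track_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  out <- as.data.frame(tracks)
  for (col in c("time_min", "x_um", "y_um", "z_um"))
    out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# split a track_table into per-track data frames (ordered by time)
split_tracks <- function(tracks) {
  split(as.data.frame(tracks),
        paste(tracks$embryo_id, tracks$track_id, sep = "\r"))
}
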