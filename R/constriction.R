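#' Normalize and align an apical-area series
#'
#' Divides a cell's apical-area series by its largest area and aligns time
#' so that 0 is the timepoint of maximal area (ties broken to the earliest
#' occurrence); negative aligned time is the preceding non-constriction
#' phase. The normalized series is 1 exactly at aligned time 0.
#'
#' @param time_min Sample times, minutes (strictly increasing).
#' @param area_um2 Areas, square micrometres (> 0).
#' @param cell_id Optional id carried through.
#' @return Data frame of class `"constriction_series"`: `cell_id`,
#'   `time_min`, `aligned_min`, `area_um2`, `norm_area`.
#' @export
normalize_align_series <- function(time_min, area_um2, cell_id = "cell") {
  if (length(time_min) != length(area_um2))
    stop_validation("time and area differ in length")
  if (length(time_min) < 3L)
    stop_validation("need >= 3 timepoints (got %d)", length(time_min))
  if (is.unsorted(time_min, strictly = TRUE))
    stop_validation("time must be strictly increasing")
  if (any(!is.finite(area_um2)) || any(area_um2 <= 0))
    stop_validation("areas must be positive")
  i_max <- which.max(area_um2)      # earliest maximum
  out <- data.frame(cell_id = cell_id, time_min = time_min,
                    aligned_min = time_min - time_min[i_max],
                    area_um2 = area_um2,
                    norm_area = area_um2 / area_um2[i_max],
                    stringsAsFactors = FALSE)
  class(out) <- c("constriction_series", "data.frame")
  out
}

#' Normalize and align every cell in a long area table
#'
#' @param series Long data frame `cell_id`, `time_min`, `area_um2`
#'   (optional `group` carried through).
#' @return Row-bound `constriction_series` for all cells with >= 3
#'   timepoints (others are dropped with a warning).
#' @export
normalize_align_all <- function(series) {
  parts <- split(series, series$cell_id)
  ok <- vapply(parts, nrow, integer(1)) >= 3L
  if (any(!ok))
    warning(sprintf("dropped %d cell(s) with < 3 timepoints", sum(!ok)),
            call. = FALSE)
  out <- do.call(rbind, lapply(parts[ok], function(g) {
    g <- g[order(g$time_min), ]
    r <- normalize_align_series(g$time_min, g$area_um2, g$cell_id[1L])
    if ("group" %in% names(g)) r$group <- g$group[1L]
    r
  }))
  rownames(out) <- NULL
  class(out) <- c("constriction_series", "data.frame")
  out
}

#' Aggregate aligned constriction series over cells
#'
#' Averages normalized area over all cells present at each aligned
#' timepoint; timepoints supported by fewer than `min_n` cells are
#' suppressed. By construction the mean equals 1 at aligned time 0.
#'
#' @param aligned A `constriction_series` (one or many cells), sampled on a
#'   common frame interval.
#' @param min_n Minimum cells per aligned timepoint (default 3).
#' @param by_group Aggregate separately per `group` column if present.
#' @return Data frame: (`group`,) `aligned_min`, `n`, `mean_norm_area`,
#'   `sem_norm_area`.
#' @export
aggregate_constriction <- function(aligned, min_n = 3, by_group = FALSE) {
  if (!nrow(aligned)) stop_validation("empty input")
  agg_one <- function(d, label = NULL) {
    parts <- split(d$norm_area, d$aligned_min)
    out <- data.frame(aligned_min = as.numeric(names(parts)),
                      n = lengths(parts),
                      mean_norm_area = vapply(parts, mean, numeric(1)),
                      sem_norm_area = vapply(parts, function(v)
                        if (length(v) > 1L) sem(v) else NA_real_, numeric(1)))
    if (!is.null(label)) out <- cbind(group = label, out,
                                      stringsAsFactors = FALSE)
    out[out$n >= min_n, , drop = FALSE]
  }
  out <- if (by_group && "group" %in% names(aligned)) {
    do.call(rbind, lapply(split(aligned, aligned$group),
                          function(d) agg_one(d, d$group[1L])))
  } else agg_one(aligned)
  out <- out[order(out$aligned_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect apical ingression from a normalized series
#'
#' Ingression is called at the first timepoint where the normalized area
#' drops below the threshold and never recovers to or above it (the
#' persistence rule guards against segmentation flicker), or at the first
#' timepoint after the cell's label disappears if it vanishes without
#' sampling a sub-threshold area. Returns `NA` for cells that never
#' ingress.
#'
#' @param series A single-cell `constriction_series`.
#' @param threshold Normalized-area threshold (default 0.1).
#' @param full_span_min Optional total observation span; a series ending
#'   before it is treated as a disappearing label.
#' @return Ingression time in minutes (original time base), or `NA`.
#' @export
detect_ingression <- function(series, threshold = 0.1,
                              full_span_min = NULL) {
  v <- series$norm_area
  t <- series$time_min
  below <- v < threshold
  if (any(below)) {
    # persistent: below from some index onward
    run_ok <- rev(cumprod(rev(below))) > 0
    if (any(run_ok)) return(t[which(run_ok)[1L]])
    return(NA_real_)
  }
  if (!is.null(full_span_min) && max(t) < full_span_min) {
    dt <- if (length(t) > 1L) stats::median(diff(t)) else NA_real_
    return(max(t) + if (is.na(dt)) 0 else dt)   # label disappeared
  }
  NA_real_
}

#' Paired first/last cortical intensities per cell
#'
#' Pairs each cell's cortical mean at the first and last measured frame and
#' reports the difference, ready for a paired comparison. Cells missing
#' either endpoint are excluded with a warning.
#'
#' @param first,last Named numeric vectors of cortical means (names = cell
#'   ids).
#' @return Data frame: `cell_id`, `start`, `end`, `change`.
#' @export
cortical_change <- function(first, last) {
  if (is.null(names(first)) || is.null(names(last)))
    stop_validation("first and last must be named by cell id")
  common <- intersect(names(first), names(last))
  missing_n <- length(union(names(first), names(last))) - length(common)
  if (missing_n)
    warning(sprintf("excluded %d cell(s) missing an endpoint", missing_n),
            call. = FALSE)
  data.frame(cell_id = common,
             start = unname(first[common]),
             end = unname(last[common]),
             change = unname(last[common] - first[common]),
             stringsAsFactors = FALSE)
}
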