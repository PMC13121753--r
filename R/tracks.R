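#' Register tracks to a moving landmark
#'
#' Subtracts a per-timepoint reference position (e.g. a somite landmark)
#' from every tracked position, so the landmark maps to the origin at all
#' times and embryo-scale drift is removed. Reference positions are linearly
#' interpolated between the timepoints they provide.
#'
#' @param tracks A `track_table`.
#' @param reference Data frame with columns `time_min`, `x_um`, `y_um`,
#'   `z_um` giving the landmark position over time.
#' @return A registered `track_table`.
#' @export
register_to_reference <- function(tracks, reference) {
  for (col in c("time_min", "x_um", "y_um", "z_um"))
    if (!col %in% names(reference)) stop_format("reference missing column '%s'", col)
  reference <- reference[order(reference$time_min), , drop = FALSE]
  tr <- range(tracks$time_min)
  rr <- range(reference$time_min)
  if (tr[1] < rr[1] || tr[2] > rr[2])
    stop_validation("track time %g min outside reference span [%g, %g]",
                    if (tr[1] < rr[1]) tr[1] else tr[2], rr[1], rr[2])
  for (col in c("x_um", "y_um", "z_um")) {
    ref_at <- if (nrow(reference) == 1L) {
      rep(reference[[col]], nrow(tracks))
    } else {
      stats::approx(reference$time_min, reference[[col]],
                    xout = tracks$time_min, rule = 1)$y
    }
    tracks[[col]] <- tracks[[col]] - ref_at
  }
  tracks
}

#' Subtract each track's starting location
#'
#' After origin subtraction every trajectory starts from (0, 0, 0); the
#' inter-timepoint step vectors are unchanged. Idempotent.
#'
#' @param tracks A `track_table`.
#' @return The origin-subtracted `track_table`.
#' @export
zero_origin <- function(tracks) {
  tid <- paste(tracks$embryo_id, tracks$track_id, sep = "\r")
  first <- !duplicated(tid)
  for (col in c("x_um", "y_um", "z_um")) {
    starts <- tracks[[col]][first]
    names(starts) <- tid[first]
    tracks[[col]] <- tracks[[col]] - starts[tid]
  }
  tracks
}

#' Default half-width from track starting positions
#'
#' The midline-to-edge half-width is taken as the 95th percentile of the
#' starting |ML - midline| distances, robust to stray lateral tracks.
#'
#' @param tracks A `track_table`.
#' @param midline_x Midline ML coordinate.
#' @param ml_axis Coordinate carrying the ML axis.
#' @param probs Quantile used (default 0.95).
#' @return Half-width in micrometres.
#' @export
estimate_half_width <- function(tracks, midline_x = 0, ml_axis = "x",
                                probs = 0.95) {
  tid <- paste(tracks$embryo_id, tracks$track_id, sep = "\r")
  x0 <- tracks[[paste0(ml_axis, "_um")]][!duplicated(tid)]
  unname(stats::quantile(abs(x0 - midline_x), probs = probs, type = 7))
}

#' Per-track displacement components
#'
#' Reduces each track to one displacement record: start position,
#' toward-midline displacement `|x_start - midline| - |x_end - midline|`
#' (positive when the endpoint is nearer the midline, well defined for
#' midline-crossing tracks), ventral displacement
#' `ventral_sign * (dv_end - dv_start)` (positive when net motion is
#' ventral, i.e. into deeper tissue), the net 3-D displacement magnitude,
#' and the region label of the starting position.
#'
#' @param tracks A `track_table` (registered).
#' @param frame A [tissue_frame()].
#' @return Data frame of class `displacement_records`, one row per track.
#' @export
displacement_components <- function(tracks, frame) {
  stopifnot(inherits(frame, "tissue_frame"))
  tid <- paste(tracks$embryo_id, tracks$track_id, sep = "\r")
  first <- !duplicated(tid)
  last <- !duplicated(tid, fromLast = TRUE)
  dur <- tracks$time_min[last] - tracks$time_min[first]
  keep <- dur > 0
  if (any(!keep))
    warning(sprintf("excluded %d zero-duration track(s)", sum(!keep)),
            call. = FALSE)
  ml <- tracks[[ml_col(frame)]]
  dv <- tracks[[dv_col(frame)]]
  x0 <- ml[first]; x1 <- ml[last]
  d0 <- abs(x0 - frame$midline_x)
  rec <- data.frame(
    embryo_id = tracks$embryo_id[first],
    track_id = tracks$track_id[first],
    start_x_um = tracks$x_um[first],
    start_y_um = tracks$y_um[first],
    start_z_um = tracks$z_um[first],
    start_ml_dist_um = d0,
    duration_min = dur,
    toward_midline_um = d0 - abs(x1 - frame$midline_x),
    ventral_um = frame$ventral_sign * (dv[last] - dv[first]),
    net_um = sqrt((tracks$x_um[last] - tracks$x_um[first])^2 +
                  (tracks$y_um[last] - tracks$y_um[first])^2 +
                  (tracks$z_um[last] - tracks$z_um[first])^2),
    stringsAsFactors = FALSE)
  if ("group" %in% names(tracks)) rec$group <- tracks$group[first]
  rec <- rec[keep, , drop = FALSE]
  rec$region <- classify_region(x0[keep], frame)
  rownames(rec) <- NULL
  class(rec) <- c("displacement_records", "data.frame")
  rec
}

#' Classify mediolateral region of a position
#'
#' Under the `"thirds"` scheme each side of the midline is divided into
#' three equal sections: medial is the innermost third (normalized distance
#' d < 1/3), lateral the outermost (d > 2/3), intermediate between. Under
#' `"fixed_band"`, medial means within `fixed_band_um` of the midline and
#' lateral within `fixed_band_um` of the lateral edge. Positions beyond the
#' half-width are clamped with a warning.
#'
#' @param x ML coordinates (micrometres), vectorized.
#' @param frame A [tissue_frame()].
#' @return Factor with levels medial, intermediate, lateral.
#' @export
classify_region <- function(x, frame) {
  stopifnot(inherits(frame, "tissue_frame"))
  d <- abs(x - frame$midline_x)
  if (any(d > frame$half_width_um)) {
    warning(sprintf("clamped %d position(s) beyond the half-width",
                    sum(d > frame$half_width_um)), call. = FALSE)
    d <- pmin(d, frame$half_width_um)
  }
  lab <- if (frame$region_scheme == "thirds") {
    dn <- d / frame$half_width_um
    ifelse(dn < 1 / 3, "medial", ifelse(dn > 2 / 3, "lateral", "intermediate"))
  } else {
    band <- frame$fixed_band_um
    ifelse(d <= band, "medial",
           ifelse(d >= frame$half_width_um - band, "lateral", "intermediate"))
  }
  factor(lab, levels = c("medial", "intermediate", "lateral"))
}

#' Displacement against normalized starting position
#'
#' Bins tracks by their normalized starting distance to the midline
#' (percent of the half-width, intervals (0, 100/n], ..., half-open at the
#' low edge) and reports mean +/- sem of the chosen displacement component
#' per bin, the decile convergence profile of the tissue.
#'
#' @param records Output of [displacement_components()].
#' @param frame A [tissue_frame()].
#' @param component `"toward_midline"` or `"ventral"`.
#' @param n_bins Number of equal start-distance bins (default 10).
#' @return Data frame with `bin_lo_pct`, `bin_hi_pct`, `n`, `mean_um`,
#'   `sem_um`; empty bins have `n = 0` and `NA` statistics.
#' @export
displacement_profile <- function(records, frame,
                                 component = c("toward_midline", "ventral"),
                                 n_bins = 10) {
  component <- match.arg(component)
  stopifnot(inherits(frame, "tissue_frame"))
  if (is.null(frame$half_width_um)) stop_validation("half_width_um missing")
  val <- records[[paste0(component, "_um")]]
  d <- records$start_ml_dist_um / frame$half_width_um
  idx <- pmin(pmax(ceiling(d * n_bins), 1L), n_bins)
  out <- data.frame(bin_lo_pct = (seq_len(n_bins) - 1L) * 100 / n_bins,
                    bin_hi_pct = seq_len(n_bins) * 100 / n_bins)
  out$n <- vapply(seq_len(n_bins), function(b) sum(idx == b), integer(1))
  out$mean_um <- vapply(seq_len(n_bins), function(b)
    if (out$n[b] > 0L) mean(val[idx == b]) else NA_real_, numeric(1))
  out$sem_um <- vapply(seq_len(n_bins), function(b)
    if (out$n[b] > 1L) sem(val[idx == b]) else NA_real_, numeric(1))
  out
}

#' Displacement-weighted polar directionality histogram
#'
#' Projects each origin-subtracted trajectory into a plane (in-plane XY or
#' transverse XZ), bins direction angles into sectors (default 20 degrees)
#' and weights each sector by its average trajectory displacement, so the
#' histogram reads as directionality weighted by how far cells actually
#' moved. Angles are degrees in [0, 360), 0 = +ML axis, counterclockwise;
#' bins are half-open `[lo, hi)`.
#'
#' In the default `"net"` mode each track contributes the angle of its net
#' displacement vector once; in `"step"` mode every inter-frame step
#' contributes. Zero-magnitude vectors carry no direction and are excluded
#' (their count is reported).
#'
#' @param tracks A `track_table`, origin-subtracted or not (only
#'   displacement differences enter).
#' @param plane `"XY"` (in-plane) or `"XZ"` (transverse).
#' @param config An [analysis_config()]; uses `polar_bin_deg` and
#'   `polar_mode`.
#' @return Data frame of class `polar_histogram` with `bin_lo_deg`,
#'   `bin_hi_deg`, `count`, `mean_magnitude_um`, `weight`; attributes
#'   `plane`, `mode`, `n_excluded`.
#' @export
polar_histogram <- function(tracks, plane = c("XY", "XZ"),
                            config = analysis_config()) {
  plane <- match.arg(plane)
  bw <- config$polar_bin_deg
  tid <- paste(tracks$embryo_id, tracks$track_id, sep = "\r")
  first <- !duplicated(tid)
  last <- !duplicated(tid, fromLast = TRUE)
  ycol <- if (plane == "XY") "y_um" else "z_um"
  if (config$polar_mode == "net") {
    dx <- tracks$x_um[last] - tracks$x_um[first]
    dy <- tracks[[ycol]][last] - tracks[[ycol]][first]
  } else {
    ord <- order(tid, tracks$time_min)
    x <- tracks$x_um[ord]; y <- tracks[[ycol]][ord]; id <- tid[ord]
    same <- id[-1] == id[-length(id)]
    dx <- diff(x)[same]; dy <- diff(y)[same]
  }
  mag <- sqrt(dx^2 + dy^2)
  zero <- mag == 0
  n_excluded <- sum(zero)
  dx <- dx[!zero]; dy <- dy[!zero]; mag <- mag[!zero]
  if (!length(mag)) stop_validation("no direction information: all vectors zero")
  ang <- (atan2(dy, dx) * 180 / pi) %% 360
  nb <- as.integer(360 / bw)
  idx <- pmin(floor(ang / bw), nb - 1L) + 1L
  out <- data.frame(bin_lo_deg = (seq_len(nb) - 1L) * bw,
                    bin_hi_deg = seq_len(nb) * bw)
  out$count <- vapply(seq_len(nb), function(b) sum(idx == b), integer(1))
  out$mean_magnitude_um <- vapply(seq_len(nb), function(b)
    if (out$count[b] > 0L) mean(mag[idx == b]) else 0, numeric(1))
  out$weight <- out$count * out$mean_magnitude_um
  attr(out, "plane") <- if (plane == "XY") "in-plane XY" else "transverse XZ"
  attr(out, "mode") <- config$polar_mode
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("polar_histogram", "data.frame")
  out
}

#' Paired mediolateral position histograms at two timepoints
#'
#' Histograms of |ML - midline| for two labeled position sets (e.g. track
#' starts at an early stage and endpoints at a late stage) over common bins,
#' ready for a distribution comparison.
#'
#' @param positions_a,positions_b Numeric vectors of ML coordinates.
#' @param bin_um Bin width in micrometres.
#' @param frame A [tissue_frame()].
#' @param labels Length-2 character vector naming the two timepoints.
#' @return Long data frame: `timepoint`, `bin_lo_um`, `bin_hi_um`, `count`.
#' @export
position_histogram <- function(positions_a, positions_b, bin_um = 20,
                               frame, labels = c("initial", "final")) {
  stopifnot(inherits(frame, "tissue_frame"))
  da <- abs(positions_a - frame$midline_x)
  db <- abs(positions_b - frame$midline_x)
  top <- max(da, db, frame$half_width_um)
  breaks <- seq(0, ceiling(top / bin_um) * bin_um, by = bin_um)
  count_in <- function(d) {
    idx <- pmin(floor(d / bin_um), length(breaks) - 2L) + 1L
    vapply(seq_len(length(breaks) - 1L), function(b) sum(idx == b), integer(1))
  }
  nb <- length(breaks) - 1L
  data.frame(timepoint = rep(labels, each = nb),
             bin_lo_um = rep(breaks[-length(breaks)], 2L),
             bin_hi_um = rep(breaks[-1L], 2L),
             count = c(count_in(da), count_in(db)),
             stringsAsFactors = FALSE)
}

#' Tissue width and length over time
#'
#' Width is the ML distance between the bilateral neural-plate borders at
#' node level; length the AP distance between the node (anterior border)
#' and the anterior tip of the primitive streak (posterior border).
#' Timepoints missing any landmark are skipped with a warning.
#'
#' @param node Data frame `time_min`, `ap_um` (node AP position).
#' @param borders Data frame `time_min`, `left_ml_um`, `right_ml_um`.
#' @param streak_tip Data frame `time_min`, `ap_um`.
#' @return Data frame `time_min`, `width_um`, `length_um` (both >= 0).
#' @export
tissue_dimensions <- function(node, borders, streak_tip) {
  for (col in c("time_min", "ap_um"))
    if (!col %in% names(node)) stop_format("node missing column '%s'", col)
  for (col in c("time_min", "left_ml_um", "right_ml_um"))
    if (!col %in% names(borders)) stop_format("borders missing column '%s'", col)
  for (col in c("time_min", "ap_um"))
    if (!col %in% names(streak_tip)) stop_format("streak_tip missing column '%s'", col)
  all_t <- sort(unique(c(node$time_min, borders$time_min, streak_tip$time_min)))
  common <- all_t[all_t %in% node$time_min & all_t %in% borders$time_min &
                  all_t %in% streak_tip$time_min]
  if (length(common) < length(all_t))
    warning(sprintf("skipped %d timepoint(s) missing a landmark",
                    length(all_t) - length(common)), call. = FALSE)
  ni <- match(common, node$time_min)
  bi <- match(common, borders$time_min)
  si <- match(common, streak_tip$time_min)
  data.frame(time_min = common,
             width_um = abs(borders$right_ml_um[bi] - borders$left_ml_um[bi]),
             length_um = abs(node$ap_um[ni] - streak_tip$ap_um[si]))
}
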