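#' Acute junction angle to the ML axis
#'
#' Angle in [0, 90] degrees between the junction chord (the straight
#' segment between its endpoints, even for curved junctions) and the
#' mediolateral axis. Invariant under reflection about either axis and
#' under swapping the endpoints.
#'
#' @param x1,y1,x2,y2 Endpoint coordinates, micrometres (vectorized).
#' @param frame Optional [tissue_frame()]; the ML axis defaults to x.
#' @return Angle(s) in degrees in [0, 90].
#' @export
junction_orientation <- function(x1, y1, x2, y2, frame = NULL) {
  dx <- x2 - x1; dy <- y2 - y1
  if (!is.null(frame) && frame$ml_axis == "y") { tmp <- dx; dx <- dy; dy <- tmp }
  if (any(dx == 0 & dy == 0))
    stop_validation("coincident junction endpoints")
  ang <- abs(atan2(dy, dx)) * 180 / pi
  ifelse(ang > 90, 180 - ang, ang)
}

#' Classify a junction as ML or AP
#'
#' A junction at an angle of less than `threshold` (default 45 degrees)
#' relative to the ML axis is an ML junction; above it, AP. Exactly at the
#' threshold the junction is classed AP (strict reading of "less than");
#' the convention is recorded in the `"tie_rule"` attribute.
#'
#' @param angle_deg Angle(s) in [0, 90].
#' @param threshold Classification threshold, degrees.
#' @return Factor with levels `ML`, `AP`.
#' @export
classify_junction <- function(angle_deg, threshold = 45) {
  if (any(angle_deg < 0 | angle_deg > 90))
    stop_validation("angles must lie in [0, 90]")
  out <- factor(ifelse(angle_deg < threshold, "ML", "AP"),
                levels = c("ML", "AP"))
  attr(out, "tie_rule") <- "angle == threshold -> AP"
  out
}

#' Planar-polarity intensity ratio per ROI
#'
#' Ratio of the mean ML-junction intensity to the mean AP-junction
#' intensity within each ROI. A ratio greater than one indicates enrichment
#' at ML junctions, less than one AP enrichment, and one no polarity.
#' ROIs missing either class have an undefined ratio (`NA`) and are
#' flagged.
#'
#' @param junctions A [junction_table()]. If `angle_deg` is absent it is
#'   computed from the endpoints.
#' @param threshold ML/AP angle threshold, degrees.
#' @param frame Optional [tissue_frame()] for the ML axis convention.
#' @return Data frame per ROI: `roi_id`, `n_ML`, `n_AP`, `mean_ML`,
#'   `mean_AP`, `ratio`, `defined`.
#' @export
polarity_ratio <- function(junctions, threshold = 45, frame = NULL) {
  stopifnot(inherits(junctions, "junction_table") ||
              is.data.frame(junctions))
  j <- as.data.frame(junctions)
  if (!"angle_deg" %in% names(j))
    j$angle_deg <- junction_orientation(j$x1_um, j$y1_um, j$x2_um, j$y2_um,
                                        frame)
  j$class <- classify_junction(j$angle_deg, threshold)
  out <- do.call(rbind, lapply(split(j, j$roi_id), function(g) {
    ml <- g$mean_intensity[g$class == "ML"]
    ap <- g$mean_intensity[g$class == "AP"]
    data.frame(roi_id = g$roi_id[1L],
               n_ML = length(ml), n_AP = length(ap),
               mean_ML = if (length(ml)) mean(ml) else NA_real_,
               mean_AP = if (length(ap)) mean(ap) else NA_real_,
               ratio = if (length(ml) && length(ap)) mean(ml) / mean(ap)
                       else NA_real_,
               defined = length(ml) > 0L && length(ap) > 0L,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (any(!out$defined))
    warning(sprintf("%d ROI(s) missing an ML or AP junction; ratio undefined",
                    sum(!out$defined)), call. = FALSE)
  out
}

#' Fraction of apically enriched cells per region
#'
#' Percentage of cells carrying a positive enrichment call in each region,
#' with counts. Regions with no cells are reported with `NA` and flagged.
#'
#' @param flags Logical vector of per-cell enrichment calls.
#' @param regions Factor/character vector of per-cell region labels.
#' @return Data frame: `region`, `n`, `n_flagged`, `percent`.
#' @export
apical_enrichment_fraction <- function(flags, regions) {
  if (length(flags) != length(regions))
    stop_validation("flags and regions differ in length")
  regions <- as.factor(regions)
  out <- data.frame(region = levels(regions),
                    n = as.integer(table(regions)))
  out$n_flagged <- as.integer(tapply(flags, regions, sum, default = 0L))
  out$percent <- ifelse(out$n > 0L, 100 * out$n_flagged / out$n, NA_real_)
  if (any(out$n == 0L))
    warning("empty region(s): percentage undefined", call. = FALSE)
  out
}
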