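#' Tissue coordinate frame
#'
#' Describes the coordinate conventions every spatial operation consults:
#' where the embryonic midline sits, how wide the tissue is from midline to
#' lateral edge, which coordinate axes are mediolateral (ML), anteroposterior
#' (AP) and dorsoventral (DV), which DV direction is ventral, and how the
#' tissue is partitioned into medial / intermediate / lateral regions.
#'
#' Two region schemes are supported: `"thirds"` divides each side of the
#' midline into three equal sections (medial = innermost third, lateral =
#' outermost third); `"fixed_band"` uses a fixed-width band at each edge
#' (medial = within `fixed_band_um` of the midline, lateral = within
#' `fixed_band_um` of the lateral edge).
#'
#' @param midline_x ML coordinate of the embryonic midline, micrometres.
#' @param half_width_um Midline-to-lateral-edge extent, micrometres (> 0).
#' @param ml_axis,ap_axis,dv_axis Which coordinate carries each tissue axis;
#'   one of `"x"`, `"y"`, `"z"`, all distinct.
#' @param ventral_sign `+1` if increasing DV coordinate is ventral, `-1`
#'   otherwise.
#' @param region_scheme `"thirds"` or `"fixed_band"`.
#' @param fixed_band_um Band width for the `"fixed_band"` scheme, micrometres;
#'   must not exceed `half_width_um`.
#' @return An object of class `"tissue_frame"`.
#' @examples
#' tissue_frame(half_width_um = 150)
#' tissue_frame(half_width_um = 150, region_scheme = "fixed_band")
#' @export
tissue_frame <- function(midline_x = 0, half_width_um,
                         ml_axis = "x", ap_axis = "y", dv_axis = "z",
                         ventral_sign = 1L,
                         region_scheme = c("thirds", "fixed_band"),
                         fixed_band_um = 100) {
  region_scheme <- match.arg(region_scheme)
  check_number(midline_x, "midline_x")
  check_number(half_width_um, "half_width_um", lower = 0, strict_lower = TRUE)
  axes <- c(ml_axis, ap_axis, dv_axis)
  if (!all(axes %in% c("x", "y", "z")) || anyDuplicated(axes))
    stop_validation("ml/ap/dv axes must be a permutation of x, y, z")
  if (!ventral_sign %in% c(-1, 1))
    stop_validation("'ventral_sign' must be +1 or -1")
  check_number(fixed_band_um, "fixed_band_um", lower = 0, strict_lower = TRUE)
  if (region_scheme == "fixed_band" && fixed_band_um > half_width_um)
    stop_validation("'fixed_band_um' (%g) exceeds 'half_width_um' (%g)",
                    fixed_band_um, half_width_um)
  structure(list(midline_x = midline_x, half_width_um = half_width_um,
                 ml_axis = ml_axis, ap_axis = ap_axis, dv_axis = dv_axis,
                 ventral_sign = as.integer(ventral_sign),
                 region_scheme = region_scheme,
                 fixed_band_um = fixed_band_um),
            class = "tissue_frame")
}

#' @export
print.tissue_frame <- function(x, ...) {
  cat("Tissue frame: midline at ", x$ml_axis, " = ", x$midline_x,
      " um, half-width ", x$half_width_um, " um\n",
      "  axes ML/AP/DV = ", x$ml_axis, "/", x$ap_axis, "/", x$dv_axis,
      ", ventral = ", if (x$ventral_sign > 0) "+" else "-", x$dv_axis, "\n",
      "  regions: ", x$region_scheme,
      if (x$region_scheme == "fixed_band")
        paste0(" (", x$fixed_band_um, " um band)") else "", "\n", sep = "")
  invisible(x)
}

# ML coordinate column name for a track-like data frame
ml_col <- function(frame) paste0(frame$ml_axis, "_um")
ap_col <- function(frame) paste0(frame$ap_axis, "_um")
dv_col <- function(frame) paste0(frame$dv_axis, "_um")

#' Analysis configuration
#'
#' Bundles the numeric conventions of the quantification pipeline. Defaults
#' follow the study conventions: 20 degree polar histogram bins, ten-bin
#' displacement profiles, apical cortex at 80% of the centroid-to-boundary
#' radius, nuclear positivity at background mean + 2 SD, the 45 degree
#' ML/AP junction threshold, ingression below 10% of maximal apical area,
#' and 10% relative-depth bins.
#'
#' @param polar_bin_deg Polar histogram bin width in degrees; must divide 360.
#' @param profile_bins Number of start-distance bins in displacement profiles.
#' @param cortex_radial_fraction Fraction of the per-angle centroid-to-boundary
#'   radius defining the apical cortex, in (0, 1).
#' @param classifier_k_sd Number of background SDs above the background mean
#'   for the nuclear positivity threshold.
#' @param junction_angle_threshold_deg Junctions at an angle below this
#'   (relative to the ML axis) are ML; above it AP.
#' @param ingression_area_fraction Normalized-area threshold below which a
#'   cell is considered ingressed.
#' @param depth_bin_pct Relative-depth histogram bin width, percent.
#' @param polar_mode `"net"` (one net-displacement vector per track, the
#'   default) or `"step"` (every inter-frame step contributes).
#' @param seed Optional integer seed recorded for simulation commands.
#' @return An object of class `"analysis_config"`.
#' @examples
#' analysis_config()
#' analysis_config(polar_bin_deg = 30)
#' @export
analysis_config <- function(polar_bin_deg = 20,
                            profile_bins = 10,
                            cortex_radial_fraction = 0.8,
                            classifier_k_sd = 2,
                            junction_angle_threshold_deg = 45,
                            ingression_area_fraction = 0.1,
                            depth_bin_pct = 10,
                            polar_mode = c("net", "step"),
                            seed = NULL) {
  polar_mode <- match.arg(polar_mode)
  check_number(polar_bin_deg, "polar_bin_deg", lower = 0, strict_lower = TRUE)
  if (360 %% polar_bin_deg != 0)
    stop_validation("'polar_bin_deg' (%g) must divide 360", polar_bin_deg)
  check_number(profile_bins, "profile_bins", lower = 1)
  check_number(cortex_radial_fraction, "cortex_radial_fraction",
               lower = 0, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  check_number(classifier_k_sd, "classifier_k_sd", lower = 0, strict_lower = TRUE)
  check_number(junction_angle_threshold_deg, "junction_angle_threshold_deg",
               lower = 0, upper = 90, strict_lower = TRUE, strict_upper = TRUE)
  check_number(ingression_area_fraction, "ingression_area_fraction",
               lower = 0, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  check_number(depth_bin_pct, "depth_bin_pct", lower = 0, upper = 100,
               strict_lower = TRUE)
  if (!is.null(seed)) check_number(seed, "seed")
  structure(list(polar_bin_deg = polar_bin_deg,
                 profile_bins = as.integer(profile_bins),
                 cortex_radial_fraction = cortex_radial_fraction,
                 classifier_k_sd = classifier_k_sd,
                 junction_angle_threshold_deg = junction_angle_threshold_deg,
                 ingression_area_fraction = ingression_area_fraction,
                 depth_bin_pct = depth_bin_pct,
                 polar_mode = polar_mode,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration:\n")
  for (k in setdiff(names(x), "seed"))
    cat(sprintf("  %-30s %s\n", k, format(x[[k]])))
  if (!is.null(x$seed)) cat(sprintf("  %-30s %d\n", "seed", x$seed))
  invisible(x)
}

#' Load an analysis configuration from YAML or JSON
#'
#' Absent keys take the [analysis_config()] defaults; unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file. An empty file yields
#'   the full default configuration.
#' @return An [analysis_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_format("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop_format("config root must be a mapping: %s", path)
  allowed <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown))
    stop_validation("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(analysis_config, vals)
}
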