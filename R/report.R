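# Pipeline commands: simulate -> analyze -> report. These are the
# programmatic surface behind the command-line wrapper; every command
# writes tidy CSV tables plus a JSON summary so reruns with the same seed
# are byte-identical.

write_csv_exact <- function(df, path) {
  out <- as.data.frame(df)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], formatC, digits = 17, format = "g")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Simulate a synthetic dataset to disk
#'
#' Runs one of the generators and writes its outputs plus
#' `ground_truth.json` under `out_dir`. Large ground-truth rasters (the
#' nuclear label image) are written as TIFF next to the JSON.
#'
#' @param what `"tracks"`, `"epithelium"`, `"constriction"` or
#'   `"sections"`.
#' @param out_dir Output directory (created).
#' @param seed Integer seed forwarded to the generator.
#' @param ... Overrides forwarded to the generator's parameter constructor.
#' @return Invisibly, the list of files written.
#' @export
run_simulate <- function(what = c("tracks", "epithelium", "constriction",
                                  "sections"),
                         out_dir, seed = 1L, ...) {
  what <- match.arg(what)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  truth_json <- NULL
  if (what == "tracks") {
    g <- gen_tracks(track_gen_params(seed = seed, ...))
    files["tracks"] <- write_tracks(g$tracks, file.path(out_dir, "tracks.csv"))
    truth_json <- list(kind = "tracks", per_track = g$truth$per_track,
                       params = unclass(g$truth$params),
                       frame = unclass(g$frame))
  } else if (what == "epithelium") {
    g <- gen_epithelium(epithelium_gen_params(seed = seed, ...))
    imgs <- write_image_pair(g$pair, out_dir)
    files[names(imgs)] <- imgs
    tiff::writeTIFF(g$truth$nuclear_labels / 65535,
                    file.path(out_dir, "nuclear_label.tif"),
                    bits.per.sample = 16L)
    files["nuclear_label"] <- file.path(out_dir, "nuclear_label.tif")
    files["junctions"] <- write_junctions(g$junctions,
                                          file.path(out_dir, "junctions.csv"))
    truth_json <- list(kind = "epithelium", cells = g$truth$cells,
                       junctions = g$truth$junctions,
                       n_cells = g$truth$n_cells,
                       params = unclass(g$truth$params))
  } else if (what == "constriction") {
    g <- gen_constriction_set(seed = seed, ...)
    files["areas"] <- write_area_series(g$series,
                                        file.path(out_dir, "areas.csv"))
    truth_json <- list(kind = "constriction", per_cell = g$truth$per_cell,
                       threshold_fraction = g$truth$threshold_fraction,
                       dt_min = g$truth$dt_min)
  } else {
    g <- gen_depth_sections(seed = seed, ...)
    files["depths"] <- write_csv_exact(as.data.frame(g$depths),
                                       file.path(out_dir, "depths.csv"))
    truth_json <- list(kind = "sections", per_cell = g$truth$per_cell,
                       weights = g$truth$weights)
  }
  files["ground_truth"] <- write_json_summary(truth_json,
                                              file.path(out_dir,
                                                        "ground_truth.json"))
  invisible(files)
}

#' Analyze a dataset directory
#'
#' Consumes the files a `simulate` run (or an equivalent export) produced
#' and writes result tables and a `summary.json` under `out_dir`.
#'
#' * `tracks`: displacement records, displacement profile, XY and XZ polar
#'   histograms, per-region means.
#' * `polarity`: per-ROI ML/AP intensity ratios from the junction table.
#' * `cortex`: per-cell cortical means over the 80%-radius mask plus
#'   automated enrichment calls.
#' * `positivity`: background statistics and nuclear positivity calls.
#' * `depth`: relative-depth histogram and third occupancy.
#' * `constriction`: normalized aligned series, aggregate curve and
#'   ingression calls.
#'
#' @param what Which analysis to run.
#' @param in_dir Directory holding the inputs.
#' @param out_dir Output directory (created).
#' @param frame Optional [tissue_frame()]; for track analysis the default
#'   half-width is estimated from starting positions
#'   ([estimate_half_width()]).
#' @param config An [analysis_config()].
#' @return Invisibly, the summary list.
#' @export
run_analyze <- function(what = c("tracks", "polarity", "cortex",
                                 "positivity", "depth", "constriction"),
                        in_dir, out_dir, frame = NULL,
                        config = analysis_config()) {
  what <- match.arg(what)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(analysis = what)
  if (what == "tracks") {
    tracks <- read_tracks(file.path(in_dir, "tracks.csv"))
    if (is.null(frame))
      frame <- tissue_frame(half_width_um = estimate_half_width(tracks))
    rec <- displacement_components(tracks, frame)
    prof <- displacement_profile(rec, frame, "toward_midline",
                                 n_bins = config$profile_bins)
    ph_xy <- polar_histogram(tracks, "XY", config)
    ph_xz <- polar_histogram(tracks, "XZ", config)
    write_csv_exact(rec, file.path(out_dir, "displacement_records.csv"))
    write_csv_exact(prof, file.path(out_dir, "profile.csv"))
    write_csv_exact(ph_xy, file.path(out_dir, "polar_histogram_xy.csv"))
    write_csv_exact(ph_xz, file.path(out_dir, "polar_histogram_xz.csv"))
    by_region <- summarize_groups(rec$toward_midline_um, rec$region)
    write_csv_exact(by_region, file.path(out_dir, "region_means.csv"))
    summary$n_tracks <- nrow(rec)
    summary$frame <- unclass(frame)
    summary$mean_toward_midline_um <- mean(rec$toward_midline_um)
    summary$region_means <- by_region
  } else if (what == "polarity") {
    j <- read_junctions(file.path(in_dir, "junctions.csv"))
    pr <- polarity_ratio(j, threshold = config$junction_angle_threshold_deg)
    write_csv_exact(pr, file.path(out_dir, "polarity_ratio.csv"))
    summary$n_junctions <- nrow(j)
    summary$rois <- pr
    summary$mean_ratio <- mean(pr$ratio[pr$defined])
  } else if (what == "cortex") {
    pair <- read_image_pair(file.path(in_dir, "label.tif"),
                            c(cortical = file.path(in_dir, "cortical.tif")),
                            pixel_size_um = 1)
    cells <- extract_cells(pair)
    cort <- vapply(cells, function(cl)
      cortical_mean_intensity(pair, "cortical",
                              cortex_mask(cl, pair,
                                          config$cortex_radial_fraction)),
      numeric(1))
    calls <- enrichment_call(cort)
    df <- data.frame(label = as.integer(names(cells)),
                     cortical_mean = unname(cort),
                     enriched = unname(calls))
    write_csv_exact(df, file.path(out_dir, "cortical_means.csv"))
    summary$n_cells <- nrow(df)
    summary$percent_enriched <- 100 * mean(df$enriched)
  } else if (what == "positivity") {
    pair <- read_image_pair(file.path(in_dir, "label.tif"),
                            c(nuclear = file.path(in_dir, "nuclear.tif")),
                            pixel_size_um = 1)
    nuc_lab <- tiff::readTIFF(file.path(in_dir, "nuclear_label.tif"),
                              as.is = TRUE)
    bg <- background_stats(pair, "nuclear", nuc_lab)
    nuc_pair <- image_pair(nuc_lab, pair$channels, pair$pixel_size_um)
    means <- cell_mean_intensity(nuc_pair, "nuclear")
    pos <- classify_positive(means, bg, k = config$classifier_k_sd)
    df <- data.frame(label = as.integer(names(means)),
                     nuclear_mean = unname(means), positive = unname(pos))
    write_csv_exact(df, file.path(out_dir, "positivity.csv"))
    summary$background <- list(mean = bg$mean, sd = bg$sd, n = bg$n)
    summary$n_nuclei <- nrow(df)
    summary$percent_positive <- 100 * mean(df$positive)
  } else if (what == "depth") {
    depths <- read_depths(file.path(in_dir, "depths.csv"))
    dh <- depth_histogram(depths$relative_depth_pct,
                          bin_pct = config$depth_bin_pct)
    thirds <- depth_third_fractions(depths$relative_depth_pct)
    write_csv_exact(dh, file.path(out_dir, "depth_histogram.csv"))
    summary$n_cells <- nrow(depths)
    summary$third_fractions <- as.list(thirds)
  } else {
    series <- read_area_series(file.path(in_dir, "areas.csv"))
    aligned <- normalize_align_all(series)
    agg <- aggregate_constriction(aligned,
                                  by_group = "group" %in% names(aligned))
    span <- max(series$time_min)
    ing <- vapply(split(aligned, aligned$cell_id), detect_ingression,
                  numeric(1), threshold = config$ingression_area_fraction,
                  full_span_min = span)
    ing_df <- data.frame(cell_id = names(ing), ingression_min = unname(ing),
                         stringsAsFactors = FALSE)
    write_csv_exact(aligned, file.path(out_dir, "aligned_series.csv"))
    write_csv_exact(agg, file.path(out_dir, "aggregate_constriction.csv"))
    write_csv_exact(ing_df, file.path(out_dir, "ingression_times.csv"))
    summary$n_cells <- length(ing)
    summary$n_ingressed <- sum(!is.na(ing))
  }
  write_json_summary(summary, file.path(out_dir, "summary.json"))
  invisible(summary)
}

#' Assemble a report bundle from analysis outputs
#'
#' Collects the summaries and result tables of one or more `analyze` runs
#' into a single directory: a merged `summary.json`, the result CSVs, and
#' simple figures (displacement profile, polar histograms, aggregate
#' constriction curve, depth histogram) for the sections whose tables are
#' present. Inputs that cannot be found are reported by name.
#'
#' @param analysis_dirs Named character vector of `analyze` output
#'   directories; names become report section names.
#' @param out_dir Report directory (created).
#' @param plots Draw PNG figures (default TRUE; tables are unaffected).
#' @return Invisibly, the merged summary list.
#' @export
build_report <- function(analysis_dirs, out_dir, plots = TRUE) {
  if (!length(analysis_dirs)) stop_validation("no analysis outputs given")
  if (is.null(names(analysis_dirs)))
    names(analysis_dirs) <- basename(analysis_dirs)
  missing <- analysis_dirs[!file.exists(file.path(analysis_dirs,
                                                  "summary.json"))]
  if (length(missing))
    stop_validation("missing analysis input(s): %s",
                    paste(names(missing), collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  merged <- list()
  for (nm in names(analysis_dirs)) {
    d <- analysis_dirs[[nm]]
    merged[[nm]] <- jsonlite::read_json(file.path(d, "summary.json"),
                                        simplifyVector = TRUE)
    for (f in list.files(d, pattern = "\\.csv$", full.names = TRUE))
      file.copy(f, file.path(out_dir, paste0(nm, "_", basename(f))),
                overwrite = TRUE)
  }
  write_json_summary(merged, file.path(out_dir, "summary.json"))
  if (plots) try(report_figures(out_dir), silent = TRUE)
  invisible(merged)
}

# Base-graphics figures for whichever tables the report contains.
report_figures <- function(out_dir) {
  draw <- function(file, expr) {
    grDevices::png(file.path(out_dir, file), width = 700, height = 500)
    on.exit(grDevices::dev.off())
    expr()
  }
  prof <- list.files(out_dir, pattern = "_profile\\.csv$", full.names = TRUE)
  if (length(prof)) {
    p <- utils::read.csv(prof[1L])
    draw("profile.png", function() {
      mid <- (p$bin_lo_pct + p$bin_hi_pct) / 2
      plot(mid, p$mean_um, type = "b", pch = 16,
           xlab = "start distance to midline (% half-width)",
           ylab = "toward-midline displacement (um)",
           main = "Convergence vs starting position")
      graphics::arrows(mid, p$mean_um - p$sem_um, mid, p$mean_um + p$sem_um,
                       angle = 90, code = 3, length = 0.03)
    })
  }
  for (ph in list.files(out_dir, pattern = "_polar_histogram_x[yz]\\.csv$",
                        full.names = TRUE)) {
    h <- utils::read.csv(ph)
    nm <- sub("\\.csv$", ".png", basename(ph))
    draw(nm, function() {
      theta <- (h$bin_lo_deg + h$bin_hi_deg) / 2 * pi / 180
      w <- h$weight / max(h$weight, 1e-12)
      plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1, axes = FALSE,
           xlab = "", ylab = "", main = basename(ph))
      graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE)
      graphics::segments(0, 0, w * cos(theta), w * sin(theta), lwd = 4)
    })
  }
  agg <- list.files(out_dir, pattern = "_aggregate_constriction\\.csv$",
                    full.names = TRUE)
  if (length(agg)) {
    a <- utils::read.csv(agg[1L])
    draw("constriction.png", function() {
      plot(a$aligned_min, a$mean_norm_area, type = "l",
           xlab = "aligned time (min)", ylab = "normalized apical area",
           main = "Apical constriction (aligned at maximal area)")
    })
  }
  dh <- list.files(out_dir, pattern = "_depth_histogram\\.csv$",
                   full.names = TRUE)
  if (length(dh)) {
    d <- utils::read.csv(dh[1L])
    draw("depth_histogram.png", function() {
      graphics::barplot(d$count, names.arg = paste0(d$bin_lo_pct, "-",
                                                    d$bin_hi_pct),
                        xlab = "relative depth (%)", ylab = "cells",
                        main = "Dorsoventral depth distribution")
    })
  }
  invisible(NULL)
}
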