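#' Generate synthetic apical-area time series
#'
#' Each cell holds a plateau at its maximal apical area for
#' `pre_phase_min` minutes (the non-constriction phase), after which
#' ingressing cells shrink linearly at `constriction_rate` (fraction of the
#' maximal area per minute) until the apical surface vanishes; the cell's
#' rows stop once its true area reaches zero, mirroring disappearance from
#' the dorsal surface. Non-ingressing cells stay on the plateau. Additive
#' Gaussian noise (clipped so areas stay positive) is applied on top.
#'
#' Ground truth records, per cell, whether it ingresses, its maximal area,
#' the constriction rate, and the first sampled timepoint at which the true
#' normalized area drops below `threshold_fraction`.
#'
#' @param n_cells Number of cells.
#' @param pre_phase_min Plateau duration before constriction starts, min.
#' @param constriction_rate Area loss per minute as a fraction of the
#'   maximal area (> 0 for ingressing cells).
#' @param ingressing_fraction Fraction of cells that constrict and ingress.
#' @param total_min Total observation span, minutes.
#' @param dt_min Frame interval, minutes.
#' @param max_area_range_um2 Range of per-cell maximal areas (uniform).
#' @param noise_sd Additive area noise SD, square micrometres.
#' @param threshold_fraction Normalized-area threshold recorded in the
#'   ground-truth ingression times (default 0.1).
#' @param seed Integer seed.
#' @return List with `series` (long data frame `cell_id`, `time_min`,
#'   `area_um2`, `group`) and `truth`.
#' @export
gen_constriction_set <- function(n_cells = 50, pre_phase_min = 60,
                                 constriction_rate = 1 / 60,
                                 ingressing_fraction = 0.5,
                                 total_min = 150, dt_min = 5,
                                 max_area_range_um2 = c(80, 120),
                                 noise_sd = 0, threshold_fraction = 0.1,
                                 seed = 1L) {
  check_number(n_cells, "n_cells", lower = 1)
  check_number(pre_phase_min, "pre_phase_min", lower = 0)
  check_number(ingressing_fraction, "ingressing_fraction", lower = 0, upper = 1)
  if (ingressing_fraction > 0)
    check_number(constriction_rate, "constriction_rate",
                 lower = 0, strict_lower = TRUE)
  check_number(dt_min, "dt_min", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(threshold_fraction, "threshold_fraction", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  set.seed(seed)
  times <- seq(0, total_min, by = dt_min)
  n_ing <- round(ingressing_fraction * n_cells)
  ingressing <- seq_len(n_cells) %in% sample(n_cells, n_ing)
  a_max <- stats::runif(n_cells, max_area_range_um2[1], max_area_range_um2[2])
  ids <- sprintf("c%03d", seq_len(n_cells))
  rows <- vector("list", n_cells)
  t_ing <- rep(NA_real_, n_cells)
  for (i in seq_len(n_cells)) {
    frac <- rep(1, length(times))
    if (ingressing[i]) {
      post <- pmax(times - pre_phase_min, 0)
      frac <- pmax(1 - constriction_rate * post, 0)
    }
    a_true <- a_max[i] * frac
    keep <- a_true > 0
    if (ingressing[i]) {
      below <- which(frac < threshold_fraction)
      if (length(below)) t_ing[i] <- times[below[1L]]
    }
    a <- a_true[keep]
    if (noise_sd > 0)
      a <- pmax(a + stats::rnorm(sum(keep), 0, noise_sd), 1e-6)
    rows[[i]] <- data.frame(cell_id = ids[i], time_min = times[keep],
                            area_um2 = a,
                            group = if (ingressing[i]) "ingressing" else "resident",
                            stringsAsFactors = FALSE)
  }
  series <- do.call(rbind, rows)
  rownames(series) <- NULL
  list(series = series,
       truth = list(per_cell = data.frame(
                      cell_id = ids, ingressing = ingressing,
                      max_area_um2 = a_max,
                      constriction_rate = ifelse(ingressing, constriction_rate, 0),
                      constriction_start_min = ifelse(ingressing, pre_phase_min, NA),
                      true_ingression_min = t_ing,
                      stringsAsFactors = FALSE),
                    threshold_fraction = threshold_fraction,
                    dt_min = dt_min))
}

#' Generate synthetic dorsoventral depth sections
#'
#' Draws per-cell dorsal (D) and ventral (V) distances such that the
#' relative depth D/(D+V) x 100% follows a requested mixture over the
#' dorsal, middle and ventral thirds of the tissue (uniform within the
#' chosen third); tissue thickness D+V varies uniformly over
#' `thickness_range_um`.
#'
#' @param n_cells Number of cells.
#' @param weights Length-3 non-negative mixture weights over
#'   dorsal/middle/ventral thirds; must sum to 1.
#' @param thickness_range_um Range of total D+V thickness, micrometres.
#' @param seed Integer seed.
#' @return List with `depths` (a [depth_table()]) and `truth` (per-cell true
#'   third and relative depth, plus the weights).
#' @export
gen_depth_sections <- function(n_cells = 200, weights = c(1, 1, 1) / 3,
                               thickness_range_um = c(40, 60), seed = 1L) {
  check_number(n_cells, "n_cells", lower = 1)
  if (length(weights) != 3L || any(!is.finite(weights)) || any(weights < 0))
    stop_validation("'weights' must be three non-negative numbers")
  if (abs(sum(weights) - 1) > 1e-8)
    stop_validation("'weights' must sum to 1 (got %g)", sum(weights))
  set.seed(seed)
  third <- sample.int(3L, n_cells, replace = TRUE, prob = weights)
  lo <- (third - 1) * 100 / 3
  depth_pct <- lo + stats::runif(n_cells) * 100 / 3
  total <- stats::runif(n_cells, thickness_range_um[1], thickness_range_um[2])
  d <- depth_pct / 100 * total
  ids <- sprintf("s%04d", seq_len(n_cells))
  depths <- depth_table(data.frame(cell_id = ids, d_um = d, v_um = total - d,
                                   embryo_id = "sim1",
                                   stringsAsFactors = FALSE))
  list(depths = depths,
       truth = list(per_cell = data.frame(cell_id = ids, third = third,
                                          depth_pct = depth_pct,
                                          stringsAsFactors = FALSE),
                    weights = weights))
}
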