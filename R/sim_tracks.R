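#' Parameters for synthetic trajectory generation
#'
#' Defaults emulate the study conditions for junctional-zone convergence:
#' a 150 um half-width, 3 h of imaging, a linear mediolateral convergence
#' gradient (per-cell toward-midline speed `v_conv * d`, with `d` the
#' normalized starting distance to the midline, so mean convergent
#' displacement over uniform starts is `v_conv * duration / 2` = 16.2 um),
#' a ventral drift restricted to the medial band (0.035 um/min over 180 min
#' = 6.3 um of medial ventral displacement), and per-step isotropic
#' Gaussian noise.
#'
#' @param n_tracks Number of cells to simulate.
#' @param duration_min Total imaging duration, minutes.
#' @param dt_min Frame interval, minutes (> 0).
#' @param half_width_um Midline-to-edge half-width, micrometres.
#' @param ap_extent_um AP extent over which starts are placed.
#' @param v_conv_um_min Convergence gradient scale: a cell starting at
#'   normalized distance d drifts toward the midline at `v_conv * d` um/min.
#' @param v_ing_um_min Ventral drift speed, applied at steps where the cell
#'   currently sits within the medial band.
#' @param medial_band_um Half-width of the medial band gating ventral drift.
#' @param diffusion_sigma_um Per-step isotropic Gaussian noise SD.
#' @param seed Integer seed.
#' @return A validated parameter list of class `"track_gen_params"`.
#' @export
track_gen_params <- function(n_tracks = 500, duration_min = 180, dt_min = 10,
                             half_width_um = 150, ap_extent_um = 300,
                             v_conv_um_min = 0.18, v_ing_um_min = 0.035,
                             medial_band_um = 50, diffusion_sigma_um = 1,
                             seed = 1L) {
  check_number(n_tracks, "n_tracks", lower = 1)
  check_number(duration_min, "duration_min", lower = 0, strict_lower = TRUE)
  check_number(dt_min, "dt_min", lower = 0, strict_lower = TRUE)
  check_number(half_width_um, "half_width_um", lower = 0, strict_lower = TRUE)
  check_number(ap_extent_um, "ap_extent_um", lower = 0, strict_lower = TRUE)
  check_number(v_conv_um_min, "v_conv_um_min", lower = 0)
  check_number(v_ing_um_min, "v_ing_um_min", lower = 0)
  check_number(medial_band_um, "medial_band_um", lower = 0,
               upper = half_width_um)
  check_number(diffusion_sigma_um, "diffusion_sigma_um", lower = 0)
  structure(list(n_tracks = as.integer(n_tracks), duration_min = duration_min,
                 dt_min = dt_min, half_width_um = half_width_um,
                 ap_extent_um = ap_extent_um, v_conv_um_min = v_conv_um_min,
                 v_ing_um_min = v_ing_um_min, medial_band_um = medial_band_um,
                 diffusion_sigma_um = diffusion_sigma_um,
                 seed = as.integer(seed)),
            class = "track_gen_params")
}

#' Generate synthetic cell trajectories with known ground truth
#'
#' Starting positions are uniform over `[-half_width, half_width]` in ML and
#' over the AP extent, with z = 0 at the dorsal surface. Each step adds the
#' deterministic drift (toward-midline convergence at the per-cell speed,
#' plus ventral drift while the cell sits inside the medial band) and
#' isotropic Gaussian noise. The canonical frame is used: x = ML (midline at
#' 0), y = AP, z = DV with ventral positive.
#'
#' The ground truth records, per track, the starting position, the per-cell
#' convergence speed and its drift integral `v * duration`, and the
#' exactly-integrated ventral drift actually applied (the ventral gate
#' depends on the realized path, so it is accumulated during simulation) —
#' enough to predict every downstream displacement estimator without
#' re-simulation.
#'
#' @param params A [track_gen_params()].
#' @return List with elements `tracks` (a `track_table`), `truth` (per-track
#'   data frame plus the parameters), and `frame` (the matching
#'   [tissue_frame()]).
#' @export
gen_tracks <- function(params = track_gen_params()) {
  stopifnot(inherits(params, "track_gen_params"))
  set.seed(params$seed)
  n <- params$n_tracks
  n_steps <- floor(params$duration_min / params$dt_min)
  times <- seq(0, by = params$dt_min, length.out = n_steps + 1L)
  x0 <- stats::runif(n, -params$half_width_um, params$half_width_um)
  y0 <- stats::runif(n, 0, params$ap_extent_um)
  d0 <- abs(x0) / params$half_width_um
  v_conv <- params$v_conv_um_min * d0
  X <- matrix(NA_real_, n, n_steps + 1L)
  Y <- matrix(NA_real_, n, n_steps + 1L)
  Z <- matrix(NA_real_, n, n_steps + 1L)
  X[, 1L] <- x0; Y[, 1L] <- y0; Z[, 1L] <- 0
  ventral_applied <- numeric(n)
  dt <- params$dt_min
  sig <- params$diffusion_sigma_um
  for (s in seq_len(n_steps)) {
    x <- X[, s]
    medial_now <- abs(x) < params$medial_band_um
    dz_drift <- ifelse(medial_now, params$v_ing_um_min * dt, 0)
    ventral_applied <- ventral_applied + dz_drift
    X[, s + 1L] <- x - sign(x) * v_conv * dt + stats::rnorm(n, 0, sig)
    Y[, s + 1L] <- Y[, s] + stats::rnorm(n, 0, sig)
    Z[, s + 1L] <- Z[, s] + dz_drift + stats::rnorm(n, 0, sig)
  }
  ids <- sprintf("t%04d", seq_len(n))
  tracks <- track_table(data.frame(
    embryo_id = "sim1",
    track_id = rep(ids, each = n_steps + 1L),
    time_min = rep(times, times = n),
    x_um = as.vector(t(X)), y_um = as.vector(t(Y)), z_um = as.vector(t(Z)),
    stringsAsFactors = FALSE))
  frame <- tissue_frame(midline_x = 0, half_width_um = params$half_width_um,
                        ventral_sign = 1L)
  truth <- list(
    per_track = data.frame(
      embryo_id = "sim1", track_id = ids,
      x0_um = x0, y0_um = y0, d0_norm = d0,
      conv_speed_um_min = v_conv,
      conv_drift_um = v_conv * n_steps * dt,
      ventral_drift_um = ventral_applied,
      stringsAsFactors = FALSE),
    params = params)
  list(tracks = tracks, truth = truth, frame = frame)
}
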