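#' Parameters for synthetic epithelium generation
#'
#' The synthetic epithelium is a Voronoi-like tessellation grown from
#' jittered grid points, giving convex-ish cells on which the polar
#' cortex transform is well posed. Three channels are painted on top of it:
#'
#' * `junction`: shared cell boundaries, with ML-oriented junctions painted
#'   at `ml_polarity_factor` times the AP intensity (planar polarity);
#' * `cortical`: an interior patch (inside the 80% cortex) added for a
#'   chosen fraction of cells (apical enrichment);
#' * `nuclear`: Gaussian background plus a positive offset, in background-SD
#'   units, on the nuclei of a known positive subset.
#'
#' All channels are quantized to integer grey levels (as a camera would),
#' so written rasters round-trip bit-exactly.
#'
#' @param n_cells Approximate number of cells; realized as an nx-by-ny
#'   jittered grid and reported exactly in the ground truth.
#' @param cell_diameter_px Grid spacing, i.e. mean cell diameter in pixels.
#' @param jitter_frac Seed jitter as a fraction of the spacing, in
#'   [0, 0.45] (the bound keeps nearest-seed assignment exact under a
#'   3 x 3 grid-neighbourhood search).
#' @param pixel_size_um Pixel size, micrometres.
#' @param junction_base Painted intensity of AP junctions (grey levels).
#' @param ml_polarity_factor f >= 1; ML junctions are painted at
#'   `f * junction_base`.
#' @param junction_min_px Junctions rasterized to fewer pixels than this are
#'   not recorded in the junction table.
#' @param cortical_fraction Fraction of cells receiving a cortical patch.
#' @param cortical_offset Added grey levels inside the patch.
#' @param patch_radius_frac Patch radius as a fraction of the cell radius
#'   (default 0.4, safely inside the 80% cortex).
#' @param nuclear_bg_mean,nuclear_bg_sd Nuclear-channel background mean and
#'   SD (grey levels).
#' @param positive_fraction Fraction of nuclei that are truly positive.
#' @param positive_offset_sd Positive offset in units of the background SD.
#' @param nucleus_radius_px Nucleus disk radius, pixels.
#' @param noise_sd Additive Gaussian noise SD on the junction and cortical
#'   channels (clipped at 0).
#' @param seed Integer seed.
#' @return A validated parameter list of class `"epithelium_gen_params"`.
#' @export
epithelium_gen_params <- function(n_cells = 100, cell_diameter_px = 16,
                                  jitter_frac = 0.35, pixel_size_um = 0.5,
                                  junction_base = 1000,
                                  ml_polarity_factor = 1,
                                  junction_min_px = 4,
                                  cortical_fraction = 0,
                                  cortical_offset = 2000,
                                  patch_radius_frac = 0.4,
                                  nuclear_bg_mean = 500, nuclear_bg_sd = 50,
                                  positive_fraction = 0,
                                  positive_offset_sd = 5,
                                  nucleus_radius_px = 3,
                                  noise_sd = 0, seed = 1L) {
  check_number(n_cells, "n_cells", lower = 4)
  check_number(cell_diameter_px, "cell_diameter_px", lower = 6)
  check_number(jitter_frac, "jitter_frac", lower = 0, upper = 0.45)
  check_number(pixel_size_um, "pixel_size_um", lower = 0, strict_lower = TRUE)
  check_number(junction_base, "junction_base", lower = 0, strict_lower = TRUE)
  check_number(ml_polarity_factor, "ml_polarity_factor", lower = 1)
  check_number(cortical_fraction, "cortical_fraction", lower = 0, upper = 1)
  check_number(cortical_offset, "cortical_offset", lower = 0)
  check_number(patch_radius_frac, "patch_radius_frac", lower = 0, upper = 0.8)
  check_number(nuclear_bg_mean, "nuclear_bg_mean", lower = 0)
  check_number(nuclear_bg_sd, "nuclear_bg_sd", lower = 0)
  check_number(positive_fraction, "positive_fraction", lower = 0, upper = 1)
  check_number(positive_offset_sd, "positive_offset_sd", lower = 0)
  check_number(nucleus_radius_px, "nucleus_radius_px", lower = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(as.list(environment()), class = "epithelium_gen_params")
}

# exact nearest-seed label assignment via 3x3 grid-neighbourhood search;
# valid because jitter_frac <= 0.45 bounds any seed's offset from its grid
# cell center by less than half a spacing
voronoi_labels <- function(sx, sy, grid_ix, grid_iy, nx, ny, W, H, spacing) {
  px <- rep(seq_len(W), times = H)     # x = column
  py <- rep(seq_len(H), each = W)      # y = row
  gx <- pmin(pmax(ceiling(px / spacing), 1L), nx)
  gy <- pmin(pmax(ceiling(py / spacing), 1L), ny)
  seed_at <- matrix(NA_integer_, nx, ny)
  seed_at[cbind(grid_ix, grid_iy)] <- seq_along(sx)
  best_d <- rep(Inf, length(px))
  best_l <- integer(length(px))
  for (ox in -1:1) for (oy in -1:1) {
    cx <- gx + ox; cy <- gy + oy
    ok <- cx >= 1L & cx <= nx & cy >= 1L & cy <= ny
    lab <- rep(NA_integer_, length(px))
    lab[ok] <- seed_at[cbind(cx[ok], cy[ok])]
    has <- !is.na(lab)
    d <- rep(Inf, length(px))
    d[has] <- (px[has] - sx[lab[has]])^2 + (py[has] - sy[lab[has]])^2
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_l[upd] <- lab[upd]
  }
  matrix(best_l, nrow = H, ncol = W, byrow = TRUE)   # [row=y, col=x]
}

#' Generate a synthetic epithelium with known ground truth
#'
#' Builds the label image, paints the junction, cortical and nuclear
#' channels as described in [epithelium_gen_params()], and returns the
#' junction table (every painted junction with its true angle and class)
#' plus full ground truth: per-cell cortical and positive flags, the
#' nuclear label raster, and per-junction painted values.
#'
#' Junction orientation is the principal axis of the junction's rasterized
#' pixels, folded to an acute angle against the ML (x) axis; a junction is
#' ML when that angle is below 45 degrees. Pixels shared by several
#' junctions (vertex pixels) are painted with the maximum class value and
#' excluded from per-junction means, so at zero noise the recorded mean of
#' an ML junction is exactly `f * junction_base`.
#'
#' @param params An [epithelium_gen_params()].
#' @return List with `pair` (an [image_pair()] with channels `junction`,
#'   `cortical`, `nuclear`), `junctions` (a [junction_table()]), and
#'   `truth`.
#' @export
gen_epithelium <- function(params = epithelium_gen_params()) {
  stopifnot(inherits(params, "epithelium_gen_params"))
  set.seed(params$seed)
  spacing <- params$cell_diameter_px
  nx <- max(2L, round(sqrt(params$n_cells)))
  ny <- max(2L, ceiling(params$n_cells / nx))
  W <- as.integer(nx * spacing); H <- as.integer(ny * spacing)
  if (W < 2 * spacing || H < 2 * spacing)
    stop_validation("cell diameter incompatible with image size")
  k <- nx * ny
  grid_ix <- rep(seq_len(nx), times = ny)
  grid_iy <- rep(seq_len(ny), each = nx)
  j <- params$jitter_frac * spacing
  sx <- (grid_ix - 0.5) * spacing + stats::runif(k, -j, j)
  sy <- (grid_iy - 0.5) * spacing + stats::runif(k, -j, j)
  lab <- voronoi_labels(sx, sy, grid_ix, grid_iy, nx, ny, W, H, spacing)

  # shared boundaries: pixel pairs whose 4-neighbour labels differ
  right_diff <- lab[, -W] != lab[, -1L]
  down_diff <- lab[-H, ] != lab[-1L, ]
  idx_l <- which(cbind(right_diff, FALSE))          # left pixel of a V edge
  idx_u <- which(rbind(down_diff, FALSE))           # upper pixel of an H edge
  pix_a <- c(idx_l, idx_u)
  pix_b <- c(idx_l + H, idx_u + 1L)                 # right / lower neighbour
  la <- lab[pix_a]; lb <- lab[pix_b]
  key <- paste(pmin(la, lb), pmax(la, lb), sep = "_")
  jpix <- unique(data.frame(pix = c(pix_a, pix_b), key = c(key, key),
                            stringsAsFactors = FALSE))
  # vertex pixels: claimed by more than one junction
  claims <- table(jpix$pix)
  shared <- as.integer(names(claims)[claims > 1L])
  by_j <- split(jpix$pix, jpix$key)
  by_j <- by_j[lengths(by_j) >= params$junction_min_px]

  jx <- function(p) ((p - 1L) %/% H) + 1L           # column = x
  jy <- function(p) ((p - 1L) %% H) + 1L            # row = y
  jstat <- lapply(names(by_j), function(kk) {
    p <- by_j[[kk]]
    x <- jx(p); y <- jy(p)
    cx <- mean(x); cy <- mean(y)
    cv <- cbind(x - cx, y - cy)
    ev <- eigen(crossprod(cv) / length(x), symmetric = TRUE)
    proj <- cv %*% ev$vectors[, 1L]
    e1 <- which.min(proj); e2 <- which.max(proj)
    # the recorded angle is the endpoint-chord angle, the same quantity
    # junction_orientation() computes, so both analysis routes agree
    ang <- abs(atan2(y[e2] - y[e1], x[e2] - x[e1])) * 180 / pi
    if (ang > 90) ang <- 180 - ang
    list(key = kk, pix = p, angle = ang,
         x1 = x[e1], y1 = y[e1], x2 = x[e2], y2 = y[e2])
  })

  junction_ch <- matrix(0, H, W)
  paint_val <- numeric(length(jstat))
  mean_int <- numeric(length(jstat))
  noise_ch <- if (params$noise_sd > 0)
    matrix(stats::rnorm(H * W, 0, params$noise_sd), H, W) else NULL
  for (i in seq_along(jstat)) {
    js <- jstat[[i]]
    val <- params$junction_base *
      if (js$angle < 45) params$ml_polarity_factor else 1
    paint_val[i] <- val
    junction_ch[js$pix] <- pmax(junction_ch[js$pix], val)
  }
  if (!is.null(noise_ch)) junction_ch <- pmax(junction_ch + noise_ch, 0)
  junction_ch <- round(pmin(junction_ch, 65535))
  for (i in seq_along(jstat)) {
    own <- setdiff(jstat[[i]]$pix, shared)
    if (!length(own)) own <- jstat[[i]]$pix
    mean_int[i] <- mean(junction_ch[own])
  }

  # per-cell centroids from the label raster
  pix_all <- which(lab > 0L)
  cx_cell <- tapply(jx(pix_all), lab[pix_all], mean)
  cy_cell <- tapply(jy(pix_all), lab[pix_all], mean)
  labels <- as.integer(names(cx_cell))

  cortical_ch <- matrix(0, H, W)
  n_cort <- round(params$cortical_fraction * k)
  cortical_cells <- sort(sample(labels, n_cort))
  pr <- params$patch_radius_frac * spacing / 2       # fraction of cell radius
  X <- matrix(rep(seq_len(W), each = H), H, W)
  Y <- matrix(rep(seq_len(H), times = W), H, W)
  for (cl in cortical_cells) {
    sel <- lab == cl & (X - cx_cell[as.character(cl)])^2 +
      (Y - cy_cell[as.character(cl)])^2 <= pr^2
    cortical_ch[sel] <- cortical_ch[sel] + params$cortical_offset
  }
  if (params$noise_sd > 0)
    cortical_ch <- pmax(cortical_ch +
                          matrix(stats::rnorm(H * W, 0, params$noise_sd), H, W), 0)
  cortical_ch <- round(pmin(cortical_ch, 65535))

  nuclear_lab <- matrix(0L, H, W)
  for (cl in labels) {
    sel <- (X - round(cx_cell[as.character(cl)]))^2 +
      (Y - round(cy_cell[as.character(cl)]))^2 <= params$nucleus_radius_px^2
    nuclear_lab[sel] <- cl
  }
  n_pos <- round(params$positive_fraction * k)
  positive_cells <- sort(sample(labels, n_pos))
  nuclear_ch <- matrix(stats::rnorm(H * W, params$nuclear_bg_mean,
                                    params$nuclear_bg_sd), H, W)
  off <- params$positive_offset_sd * params$nuclear_bg_sd
  nuclear_ch[nuclear_lab %in% positive_cells] <-
    nuclear_ch[nuclear_lab %in% positive_cells] + off
  nuclear_ch <- round(pmin(pmax(nuclear_ch, 0), 65535))

  pair <- image_pair(lab, list(junction = junction_ch,
                               cortical = cortical_ch,
                               nuclear = nuclear_ch),
                     pixel_size_um = params$pixel_size_um)
  ps <- params$pixel_size_um
  jt <- junction_table(data.frame(
    roi_id = "roi1",
    junction_id = vapply(jstat, `[[`, character(1), "key"),
    x1_um = vapply(jstat, `[[`, numeric(1), "x1") * ps,
    y1_um = vapply(jstat, `[[`, numeric(1), "y1") * ps,
    x2_um = vapply(jstat, `[[`, numeric(1), "x2") * ps,
    y2_um = vapply(jstat, `[[`, numeric(1), "y2") * ps,
    angle_deg = vapply(jstat, `[[`, numeric(1), "angle"),
    mean_intensity = mean_int,
    channel = "junction",
    stringsAsFactors = FALSE))
  truth <- list(
    cells = data.frame(label = labels,
                       centroid_x_px = as.numeric(cx_cell),
                       centroid_y_px = as.numeric(cy_cell),
                       cortical = labels %in% cortical_cells,
                       positive = labels %in% positive_cells),
    junctions = data.frame(junction_id = vapply(jstat, `[[`, character(1), "key"),
                           angle_deg = vapply(jstat, `[[`, numeric(1), "angle"),
                           class = ifelse(vapply(jstat, `[[`, numeric(1),
                                                 "angle") < 45, "ML", "AP"),
                           painted_value = paint_val,
                           stringsAsFactors = FALSE),
    nuclear_labels = nuclear_lab,
    n_cells = k,
    params = params)
  list(pair = pair, junctions = jt, truth = truth)
}
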