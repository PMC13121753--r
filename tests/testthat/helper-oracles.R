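# Independent brute-force oracles. Each recomputes a quantity by the most
# literal route available (per-element loops, direct formulas) so the
# vectorized implementations are checked against code that shares nothing
# with them.

# net-vector polar histogram: explicit loop over tracks
brute_polar_hist <- function(tracks, bin_deg, ycol = "y_um") {
  ids <- unique(paste(tracks$embryo_id, tracks$track_id))
  nb <- 360 / bin_deg
  count <- integer(nb); sums <- numeric(nb); excluded <- 0L
  for (id in ids) {
    g <- tracks[paste(tracks$embryo_id, tracks$track_id) == id, ]
    g <- g[order(g$time_min), ]
    dx <- g$x_um[nrow(g)] - g$x_um[1]
    dy <- g[[ycol]][nrow(g)] - g[[ycol]][1]
    m <- sqrt(dx^2 + dy^2)
    if (m == 0) { excluded <- excluded + 1L; next }
    ang <- atan2(dy, dx) * 180 / pi
    if (ang < 0) ang <- ang + 360
    b <- floor(ang / bin_deg) + 1
    if (b > nb) b <- nb
    count[b] <- count[b] + 1L
    sums[b] <- sums[b] + m
  }
  mean_mag <- ifelse(count > 0, sums / count, 0)
  list(count = count, mean_magnitude = mean_mag,
       weight = count * mean_mag, excluded = excluded)
}

# per-label channel means by per-pixel accumulation
brute_label_means <- function(lab, ch) {
  sums <- list(); counts <- list()
  for (i in seq_len(nrow(lab))) for (j in seq_len(ncol(lab))) {
    l <- lab[i, j]
    if (l > 0) {
      key <- as.character(l)
      sums[[key]] <- (sums[[key]] %||% 0) + ch[i, j]
      counts[[key]] <- (counts[[key]] %||% 0) + 1
    }
  }
  keys <- names(sums)[order(as.integer(names(sums)))]
  out <- vapply(keys, function(k) sums[[k]] / counts[[k]], numeric(1))
  names(out) <- keys
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# background mean / population SD by per-pixel accumulation
brute_background <- function(ch, nuclab) {
  vals <- c()
  for (i in seq_len(nrow(ch))) for (j in seq_len(ncol(ch)))
    if (nuclab[i, j] == 0) vals <- c(vals, ch[i, j])
  m <- sum(vals) / length(vals)
  list(mean = m, sd = sqrt(sum((vals - m)^2) / length(vals)),
       n = length(vals))
}

# two-sample KS statistic as the max ECDF gap at every data point
brute_ks_stat <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  gap <- 0
  for (p in pts) {
    fa <- sum(a <= p) / length(a)
    fb <- sum(b <= p) / length(b)
    gap <- max(gap, abs(fa - fb))
  }
  gap
}

# Welch t statistic and two-sided p from the textbook formulas
brute_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t, p = 2 * pt(-abs(t), df))
}

brute_paired_t <- function(a, b) {
  d <- a - b
  t <- mean(d) / (sd(d) / sqrt(length(d)))
  list(statistic = t, p = 2 * pt(-abs(t), length(d) - 1))
}

# independently written even-odd point-in-polygon (loop form)
oracle_point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly); inside <- FALSE
  jj <- n
  for (ii in seq_len(n)) {
    xi <- poly[ii, 1]; yi <- poly[ii, 2]
    xj <- poly[jj, 1]; yj <- poly[jj, 2]
    if ((yi > y) != (yj > y) &&
        x < (xj - xi) * (y - yi) / (yj - yi) + xi) inside <- !inside
    jj <- ii
  }
  inside
}

# cortex oracle: pixel centers inside the boundary polygon scaled by
# `frac` about the centroid (valid for star-shaped cells)
oracle_cortex_pixels <- function(cell, pair, frac) {
  lab <- pair$label_image; ps <- pair$pixel_size_um; H <- nrow(lab)
  pix <- which(lab == cell$label)
  cx <- cell$centroid_um[["x"]]; cy <- cell$centroid_um[["y"]]
  sp <- cbind(cx + frac * (cell$boundary_um[, 1] - cx),
              cy + frac * (cell$boundary_um[, 2] - cy))
  keep <- vapply(pix, function(p) {
    x <- (((p - 1) %/% H) + 1) * ps
    y <- (((p - 1) %% H) + 1) * ps
    (x == cx && y == cy) || oracle_point_in_polygon(x, y, sp)
  }, logical(1))
  pix[keep]
}

# a cell_shape built directly from a polygon (rasterized pixel set,
# pixel-mean centroid, the polygon itself as boundary)
cell_from_polygon <- function(poly, size, label = 1L) {
  lab <- rasterize_polygon(poly, size, label)
  if (sum(lab > 0) == 0) return(NULL)
  pix <- which(lab == label)
  H <- nrow(lab)
  x <- ((pix - 1) %/% H) + 1
  y <- ((pix - 1) %% H) + 1
  cell <- structure(list(label = label, n_pixels = length(pix),
                         area_um2 = length(pix),
                         centroid_um = c(x = mean(x), y = mean(y)),
                         boundary_um = poly),
                    class = "cell_shape")
  list(cell = cell, pair = make_pair(lab))
}

# random convex polygon (convex hull of random points), centered near c0
random_convex_polygon <- function(n_pts = 12, radius = 10, c0 = c(16, 16)) {
  x <- c0[1] + runif(n_pts, -radius, radius)
  y <- c0[2] + runif(n_pts, -radius, radius)
  h <- chull(x, y)
  cbind(x[h], y[h])
}

# rasterize a polygon into a label image of the given size
rasterize_polygon <- function(poly, size, label = 1L) {
  lab <- matrix(0L, size, size)
  for (i in seq_len(size)) for (j in seq_len(size)) {
    # row i = y, col j = x
    if (oracle_point_in_polygon(j, i, poly)) lab[i, j] <- label
  }
  lab
}

make_pair <- function(lab, ch = NULL, ps = 1) {
  if (is.null(ch)) ch <- matrix(0, nrow(lab), ncol(lab))
  image_pair(lab, list(ch = ch), pixel_size_um = ps)
}

# minimal track table builder for hand-crafted cases
tt <- function(..., embryo = "e1") {
  pts <- list(...)
  df <- do.call(rbind, lapply(seq_along(pts), function(i) {
    p <- pts[[i]]
    data.frame(embryo_id = embryo, track_id = sprintf("t%02d", i),
               time_min = p[, 1], x_um = p[, 2], y_um = p[, 3],
               z_um = p[, 4], stringsAsFactors = FALSE)
  }))
  track_table(df)
}
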