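#' Extract per-cell shapes from a label image
#'
#' One shape per label: pixel count area, pixel-mean centroid, and the
#' boundary polygon traced as the outer contour. Contour pixel centers are
#' pushed half a pixel radially outward so the polygon approximates the
#' true object boundary rather than the centers of the outermost pixels
#' (the distinction matters for the cortex area ratio at small radii).
#' Labels with fewer than 4 pixels carry no usable geometry and are skipped
#' with a warning.
#'
#' @param pair An [image_pair()].
#' @return A list of class `"cell_shapes"`; each element has `label`,
#'   `area_um2`, `centroid_um` (x, y), `boundary_um` (n x 2 matrix) and
#'   `n_pixels`.
#' @export
extract_cells <- function(pair) {
  stopifnot(inherits(pair, "image_pair"))
  lab <- pair$label_image
  ps <- pair$pixel_size_um
  labels <- sort(setdiff(unique(as.vector(lab)), 0L))
  counts <- tabulate(lab[lab > 0L], nbins = max(labels))
  small <- labels[counts[labels] < 4L]
  if (length(small)) {
    warning(sprintf("skipped %d label(s) with < 4 pixels", length(small)),
            call. = FALSE)
    labels <- setdiff(labels, small)
  }
  contours <- EBImage::ocontour(lab)
  H <- nrow(lab)
  shapes <- lapply(labels, function(l) {
    pix <- which(lab == l)
    x <- ((pix - 1L) %/% H) + 1L
    y <- ((pix - 1L) %% H) + 1L
    cx <- mean(x); cy <- mean(y)
    oc <- contours[[as.character(l)]]
    if (is.null(oc)) oc <- contours[[l]]
    # ocontour reports (dim1, dim2) = (row, col) 0-based -> (y, x)
    by <- oc[, 1L] + 1; bx <- oc[, 2L] + 1
    r <- sqrt((bx - cx)^2 + (by - cy)^2)
    scale <- ifelse(r > 0, (r + 0.5) / r, 1)
    poly <- cbind((cx + (bx - cx) * scale) * ps,
                  (cy + (by - cy) * scale) * ps)
    structure(list(label = l,
                   n_pixels = length(pix),
                   area_um2 = length(pix) * ps^2,
                   centroid_um = c(x = cx * ps, y = cy * ps),
                   boundary_um = poly),
              class = "cell_shape")
  })
  names(shapes) <- as.character(labels)
  class(shapes) <- "cell_shapes"
  shapes
}

#' @export
print.cell_shapes <- function(x, ...) {
  cat(sprintf("%d cell shapes; mean area %.1f um^2\n", length(x),
              mean(vapply(x, `[[`, numeric(1), "area_um2"))))
  invisible(x)
}

#' Per-cell mean channel intensity
#'
#' Mean of an intensity channel over each label's pixel set; background
#' (label 0) is excluded. This is the per-cell expression readout used for
#' stainings measured on segmented projections.
#'
#' @param pair An [image_pair()].
#' @param channel Channel name.
#' @param labels Optional integer vector restricting which labels to score.
#' @return Named numeric vector of means, names = label ids.
#' @export
cell_mean_intensity <- function(pair, channel, labels = NULL) {
  stopifnot(inherits(pair, "image_pair"))
  if (!channel %in% names(pair$channels))
    stop_format("no channel '%s' (have: %s)", channel,
                paste(names(pair$channels), collapse = ", "))
  lab <- pair$label_image
  ch <- pair$channels[[channel]]
  sel <- lab > 0L
  means <- tapply(ch[sel], lab[sel], mean)
  out <- as.numeric(means)
  names(out) <- names(means)
  if (!is.null(labels)) out <- out[as.character(labels)]
  out
}

#' Normalize per-cell intensities by a reference channel
#'
#' Elementwise target / reference over matching cell ids, e.g. junctional
#' protein intensity normalized by a tight-junction (ZO-1) reference to
#' remove staining-depth variation. Cells whose reference is non-positive
#' cannot be normalized; they are excluded with a warning and listed in the
#' `"excluded"` attribute.
#'
#' @param target,reference Named numeric vectors over the same cell ids.
#' @return Named numeric vector of normalized intensities.
#' @export
normalize_by_reference <- function(target, reference) {
  if (is.null(names(target)) || is.null(names(reference)))
    stop_validation("target and reference must be named by cell id")
  common <- intersect(names(target), names(reference))
  if (!setequal(names(target), names(reference)))
    warning(sprintf("restricting to %d shared cell id(s)", length(common)),
            call. = FALSE)
  t <- target[common]; r <- reference[common]
  bad <- !is.finite(r) | r <= 0
  if (any(bad))
    warning(sprintf("excluded %d cell(s) with non-positive reference",
                    sum(bad)), call. = FALSE)
  out <- t[!bad] / r[!bad]
  attr(out, "excluded") <- common[bad]
  out
}

#' Polar-coordinate apical cortex mask
#'
#' Transforms the cell boundary into polar coordinates about the centroid
#' and keeps the pixels within `radial_fraction` (default 80%) of the
#' per-angle centroid-to-boundary radius: a pixel at angle theta and
#' distance r belongs to the cortex iff `r <= radial_fraction * R(theta)`,
#' where `R(theta)` is the first boundary crossing along the ray at theta,
#' linearly interpolated between boundary samples (i.e. the exact
#' ray-polyline intersection). This separates the apical cortex from the
#' junctional band at the cell boundary. For non-star-shaped cells the
#' first crossing under-covers distal lobes; the transform presumes
#' convex-ish cells. If the centroid falls outside the polygon (extreme
#' concavity) the most interior boundary-distant pixel is used as pole,
#' with a message.
#'
#' @param cell A `cell_shape` from [extract_cells()].
#' @param pair The [image_pair()] the cell came from.
#' @param radial_fraction Fraction of the per-angle radius kept, in (0, 1).
#' @return Object of class `"cortex_mask"`: `label`, `pixels` (linear
#'   indices into the rasters), `radial_fraction`.
#' @export
cortex_mask <- function(cell, pair, radial_fraction = 0.8) {
  stopifnot(inherits(cell, "cell_shape"), inherits(pair, "image_pair"))
  check_number(radial_fraction, "radial_fraction", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  poly <- cell$boundary_um
  if (nrow(poly) < 3L) stop_validation("degenerate boundary polygon")
  lab <- pair$label_image
  ps <- pair$pixel_size_um
  H <- nrow(lab)
  pix <- which(lab == cell$label)
  px <- (((pix - 1L) %/% H) + 1L) * ps
  py <- (((pix - 1L) %% H) + 1L) * ps
  cx <- cell$centroid_um[["x"]]; cy <- cell$centroid_um[["y"]]
  if (!points_in_polygon(cx, cy, poly)) {
    message(sprintf("label %d: centroid outside boundary; using interior pole",
                    cell$label))
    # pole: cell pixel with the largest clearance from the boundary
    clear <- vapply(seq_along(px), function(i)
      min(sqrt((poly[, 1] - px[i])^2 + (poly[, 2] - py[i])^2)), numeric(1))
    inside <- points_in_polygon(px, py, poly)
    cand <- if (any(inside)) which(inside) else seq_along(px)
    best <- cand[which.max(clear[cand])]
    cx <- px[best]; cy <- py[best]
  }
  dx <- px - cx; dy <- py - cy
  r <- sqrt(dx^2 + dy^2)
  keep <- rep(TRUE, length(pix))
  nz <- r > 0
  if (any(nz)) {
    R <- ray_polygon_first_crossing(cx, cy, dx[nz] / r[nz], dy[nz] / r[nz],
                                    poly)
    keep[nz] <- r[nz] <= radial_fraction * R
  }
  structure(list(label = cell$label, pixels = pix[keep],
                 radial_fraction = radial_fraction),
            class = "cortex_mask")
}

#' Mean channel intensity over a cortex mask
#'
#' @param pair An [image_pair()].
#' @param channel Channel name.
#' @param cortex A [cortex_mask()].
#' @return Mean intensity over the cortex pixels.
#' @export
cortical_mean_intensity <- function(pair, channel, cortex) {
  stopifnot(inherits(cortex, "cortex_mask"))
  if (!channel %in% names(pair$channels))
    stop_format("no channel '%s'", channel)
  if (!length(cortex$pixels)) stop_validation("empty cortex mask")
  mean(pair$channels[[channel]][cortex$pixels])
}

#' Automated apical-enrichment call from cortical scores
#'
#' Flags a cell as apically enriched when its cortical mean exceeds the
#' population median by more than `k` median absolute deviations, an
#' explicit surrogate for the by-eye scoring of apical accumulation.
#'
#' @param cortical_means Named numeric vector of per-cell cortical means.
#' @param k MAD multiplier (default 3).
#' @return Named logical vector.
#' @export
enrichment_call <- function(cortical_means, k = 3) {
  med <- stats::median(cortical_means)
  madv <- stats::mad(cortical_means)
  cortical_means > med + k * madv
}
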