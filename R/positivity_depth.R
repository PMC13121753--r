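#' Background intensity statistics outside nuclei
#'
#' Mean and population SD of a channel over all pixels outside every
#' nucleus, the reference distribution for the positivity threshold. No
#' dilation margin is applied around nuclei by default.
#'
#' @param pair An [image_pair()].
#' @param channel Channel name.
#' @param nuclear_labels Integer matrix of nuclear labels (0 = background),
#'   same shape as the channel.
#' @param dilate_px Optional margin: nuclei grown by this many pixels
#'   (chessboard metric) before taking the complement.
#' @return Object of class `"background_stats"`: `mean`, `sd`
#'   (population), `n`, `channel`.
#' @export
background_stats <- function(pair, channel, nuclear_labels, dilate_px = 0) {
  stopifnot(inherits(pair, "image_pair"))
  if (!channel %in% names(pair$channels))
    stop_format("no channel '%s'", channel)
  ch <- pair$channels[[channel]]
  if (!identical(dim(nuclear_labels), dim(ch)))
    stop_validation("nuclear label shape (%s) does not match channel (%s)",
                    paste(dim(nuclear_labels), collapse = "x"),
                    paste(dim(ch), collapse = "x"))
  fg <- nuclear_labels > 0L
  if (dilate_px > 0) {
    kern <- EBImage::makeBrush(2L * as.integer(dilate_px) + 1L,
                               shape = "box")
    fg <- EBImage::dilate(fg * 1, kern) > 0
  }
  bg <- ch[!fg]
  if (length(bg) < 100L)
    stop_validation("only %d background pixels (need >= 100)", length(bg))
  m <- mean(bg)
  structure(list(mean = m,
                 sd = sqrt(mean((bg - m)^2)),   # population SD
                 n = length(bg), channel = channel),
            class = "background_stats")
}

#' @export
print.background_stats <- function(x, ...) {
  cat(sprintf("Background ('%s'): mean %.3f, SD %.3f over %d pixels\n",
              x$channel, x$mean, x$sd, x$n))
  invisible(x)
}

#' Background-referenced nuclear positivity
#'
#' A nucleus is positive iff its mean intensity exceeds the background mean
#' by more than `k` background standard deviations (strictly greater:
#' a nucleus exactly at the threshold is negative). Monotone in intensity
#' and anti-monotone in `k`.
#'
#' @param nuclear_means Named numeric vector of per-nucleus mean
#'   intensities.
#' @param bg A [background_stats()] object (or a list with `mean`, `sd`).
#' @param k Number of SDs (default 2).
#' @return Named logical vector.
#' @export
classify_positive <- function(nuclear_means, bg, k = 2) {
  check_number(k, "k", lower = 0, strict_lower = TRUE)
  nuclear_means > bg$mean + k * bg$sd
}

#' Positive-cell percentage per region
#'
#' Percentage of positive cells per region, optionally restricted to a
#' marked subpopulation (e.g. only successfully electroporated cells).
#'
#' @param positive Logical vector of per-cell positivity calls.
#' @param regions Per-cell region labels.
#' @param restrict_to Optional logical vector; only cells where it is
#'   `TRUE` enter the denominator.
#' @return Data frame: `region`, `n`, `n_positive`, `percent` (`NA` and a
#'   warning where the restricted population is empty).
#' @export
positive_fraction_by_region <- function(positive, regions,
                                        restrict_to = NULL) {
  if (!is.null(restrict_to)) {
    positive <- positive[restrict_to]
    regions <- regions[restrict_to]
  }
  regions <- as.factor(regions)
  out <- data.frame(region = levels(regions),
                    n = as.integer(table(regions)))
  out$n_positive <- as.integer(tapply(positive, regions, sum, default = 0L))
  out$percent <- ifelse(out$n > 0L, 100 * out$n_positive / out$n, NA_real_)
  if (any(out$n == 0L))
    warning("empty restricted population in some region(s)", call. = FALSE)
  out
}

#' Relative dorsoventral depth
#'
#' `D/(D+V) x 100`: the position of a cell along the dorsoventral axis as a
#' percentage, 0% at the dorsal surface, 100% at the ventral layer.
#' Satisfies `relative_depth(D, V) + relative_depth(V, D) = 100`.
#'
#' @param d_um Distance to the dorsal layer, micrometres (>= 0).
#' @param v_um Distance to the ventral layer, micrometres (>= 0).
#' @return Percent in [0, 100], vectorized.
#' @export
relative_depth <- function(d_um, v_um) {
  if (any(d_um < 0 | v_um < 0)) stop_validation("D and V must be >= 0")
  if (any(d_um + v_um <= 0)) stop_validation("D + V must be > 0")
  d_um / (d_um + v_um) * 100
}

#' Relative-depth histogram and frequency ratio
#'
#' Bins relative depths every `bin_pct` percent (half-open bins, the last
#' closed at 100). With a reference sample, also reports the per-bin ratio
#' of relative frequencies (group / reference), undefined where the
#' reference bin is empty.
#'
#' @param depths_pct Relative depths in [0, 100].
#' @param bin_pct Bin width, percent (default 10).
#' @param reference_pct Optional reference-group depths.
#' @return Data frame: `bin_lo_pct`, `bin_hi_pct`, `count`, `rel_freq`, and
#'   with a reference also `ref_count`, `ref_rel_freq`, `freq_ratio`.
#' @export
depth_histogram <- function(depths_pct, bin_pct = 10, reference_pct = NULL) {
  if (any(depths_pct < 0 | depths_pct > 100))
    stop_validation("depths must lie in [0, 100]")
  nb <- ceiling(100 / bin_pct)
  bin_of <- function(d) pmin(floor(d / bin_pct), nb - 1L) + 1L
  counts <- tabulate(bin_of(depths_pct), nbins = nb)
  out <- data.frame(bin_lo_pct = (seq_len(nb) - 1L) * bin_pct,
                    bin_hi_pct = pmin(seq_len(nb) * bin_pct, 100),
                    count = counts,
                    rel_freq = counts / sum(counts))
  if (!is.null(reference_pct)) {
    if (any(reference_pct < 0 | reference_pct > 100))
      stop_validation("reference depths must lie in [0, 100]")
    rc <- tabulate(bin_of(reference_pct), nbins = nb)
    out$ref_count <- rc
    out$ref_rel_freq <- rc / sum(rc)
    out$freq_ratio <- ifelse(out$ref_rel_freq > 0,
                             out$rel_freq / out$ref_rel_freq, NA_real_)
  }
  out
}

#' Occupancy of the dorsal, middle and ventral thirds
#'
#' Fractions of cells with relative depth in [0, 100/3), [100/3, 200/3) and
#' [200/3, 100]; the fractions sum to 1.
#'
#' @param depths_pct Relative depths in [0, 100].
#' @return Named numeric vector `dorsal`, `middle`, `ventral`.
#' @export
depth_third_fractions <- function(depths_pct) {
  if (!length(depths_pct)) stop_validation("empty input")
  if (any(depths_pct < 0 | depths_pct > 100))
    stop_validation("depths must lie in [0, 100]")
  idx <- pmin(floor(depths_pct / (100 / 3)), 2) + 1
  f <- tabulate(idx, nbins = 3L) / length(depths_pct)
  c(dorsal = f[1L], middle = f[2L], ventral = f[3L])
}
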