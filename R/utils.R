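# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard error of the mean
#'
#' Sample standard deviation (n - 1 denominator) divided by the square root
#' of n, the convention used throughout for mean +/- sem reporting.
#'
#' @param x Numeric vector; `NA`s are dropped.
#' @return A single number; `NA` if fewer than two observations remain.
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

stop_format <- function(...) {
  stop(structure(class = c("jz_format_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

stop_validation <- function(...) {
  stop(structure(class = c("jz_validation_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation("'%s' must be a single finite number", name)
  if (x < lower || (strict_lower && x <= lower))
    stop_validation("'%s' must be %s %s (got %s)", name,
                    if (strict_lower) ">" else ">=", format(lower), format(x))
  if (x > upper || (strict_upper && x >= upper))
    stop_validation("'%s' must be %s %s (got %s)", name,
                    if (strict_upper) "<" else "<=", format(upper), format(x))
  invisible(x)
}

# Even-odd rule point-in-polygon, vectorized over query points.
# Polygon rows are (x, y) vertices in order; closure is implicit.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1L]; ys <- poly[, 2L]
  xe <- xs[c(2:n, 1L)]; ye <- ys[c(2:n, 1L)]
  inside <- logical(length(px))
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ye[i] > py))
    if (any(crosses)) {
      xint <- xs[i] + (py[crosses] - ys[i]) / (ye[i] - ys[i]) * (xe[i] - xs[i])
      flip <- px[crosses] < xint
      idx <- which(crosses)[flip]
      inside[idx] <- !inside[idx]
    }
  }
  inside
}

# First positive crossing distance of rays from a common origin with a
# polygon outline. `ux`, `uy` are unit direction components per ray.
# Returns the distance to the nearest boundary crossing (Inf if none),
# i.e. R(theta) with linear interpolation between boundary samples.
ray_polygon_first_crossing <- function(ox, oy, ux, uy, poly) {
  n <- nrow(poly)
  xs <- poly[, 1L] - ox; ys <- poly[, 2L] - oy
  xe <- xs[c(2:n, 1L)]; ye <- ys[c(2:n, 1L)]
  best <- rep(Inf, length(ux))
  for (i in seq_len(n)) {
    dx <- xe[i] - xs[i]; dy <- ye[i] - ys[i]
    den <- ux * dy - uy * dx
    ok <- abs(den) > 1e-12
    t <- (xs[i] * dy - ys[i] * dx) / den        # distance along ray
    s <- (xs[i] * uy - ys[i] * ux) / den        # position along segment
    hit <- ok & t > 0 & s >= 0 & s <= 1
    best[hit] <- pmin(best[hit], t[hit])
  }
  best
}
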