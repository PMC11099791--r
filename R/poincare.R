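# Poincare-plot cluster quantification and tachogram preparation.

#' Poincaré point set
#'
#' Pairs each RR interval with its successor: `x = RR_i`, `y = RR_{i+1}`.
#'
#' @param series An [rr_series()] or numeric vector of intervals (ms).
#' @return `data.frame(x, y)` with `length(intervals) - 1` rows.
#' @export
poincare_points <- function(series) {
  v <- if (inherits(series, "rr_series")) series$intervals else as.numeric(series)
  n <- length(v)
  if (n < 2L) return(data.frame(x = numeric(0), y = numeric(0)))
  data.frame(x = v[-n], y = v[-1])
}

#' Points on the line of identity
#'
#' Subsets a Poincaré point set to the band `|y - x| <= band_halfwidth`
#' around the line of identity, where linear beat-to-beat heart-rate change
#' lives.
#'
#' @param points `data.frame(x, y)` from [poincare_points()].
#' @param band_halfwidth Half-width of the band in ms (> 0).
#' @return The subset of `points` inside the band.
#' @export
loi_band <- function(points, band_halfwidth = 40) {
  stopifnot(band_halfwidth > 0)
  points[abs(points$y - points$x) <= band_halfwidth, , drop = FALSE]
}

#' Quantify Poincaré cluster geometry
#'
#' Computes the four cluster measurements: shortest and longest interval on
#' the line of identity (LOI), their range, and the shortest horizontal
#' deviation (minimum `y` of the off-LOI arm). "Cluster" is operationalised
#' by a density filter: points are binned (20 ms default) along `x` for the
#' LOI and along `y` for the deviation arm, and only dense bins count, so
#' isolated strays and faint smears do not stretch the measurements.
#'
#' The default boundary rule is *modal-relative*: a bin belongs to the
#' cluster if it holds at least `min_density` (5%) of the points in the
#' most occupied bin of its own arm. This mirrors a visual cluster
#' judgement, which responds to density relative to the bright core of the
#' plot rather than to the raw point count — a band carrying 0.1% of a
#' quarter-million intervals is invisible next to a core bin ten thousand
#' strong. Set `density_reference = "total"` for an absolute rule
#' (fraction of all points).
#'
#' @param points `data.frame(x, y)` from [poincare_points()].
#' @param band_halfwidth LOI band half-width in ms.
#' @param bin_width Density bin width in ms.
#' @param min_density Minimum bin occupancy: a fraction (of the modal bin,
#'   or of the total point count, per `density_reference`) if < 1,
#'   otherwise an absolute count.
#' @param density_reference `"modal"` (default) or `"total"`.
#' @return Object of class `cluster_metrics`: list with `shortest_loi`,
#'   `longest_loi`, `range_loi`, `shortest_horizontal_deviation` (all ms;
#'   the deviation is `NA` if no off-LOI bin is dense enough).
#' @export
cluster_metrics <- function(points, band_halfwidth = 40, bin_width = 20,
                            min_density = 0.05,
                            density_reference = c("modal", "total")) {
  density_reference <- match.arg(density_reference)
  n <- nrow(points)
  if (n == 0L) stop("no identifiable line-of-identity cluster", call. = FALSE)
  on <- abs(points$y - points$x) <= band_halfwidth

  dense_x <- dense_members(points$x[on], bin_width, min_density,
                           density_reference, n)
  if (!length(dense_x)) {
    stop("no identifiable line-of-identity cluster", call. = FALSE)
  }
  dense_y <- dense_members(points$y[!on], bin_width, min_density,
                           density_reference, n)

  structure(
    list(shortest_loi = min(dense_x),
         longest_loi = max(dense_x),
         range_loi = max(dense_x) - min(dense_x),
         shortest_horizontal_deviation =
           if (length(dense_y)) min(dense_y) else NA_real_),
    class = "cluster_metrics")
}

# values belonging to bins passing the density rule
dense_members <- function(x, bin_width, min_density, density_reference, n_total) {
  if (!length(x)) return(numeric(0))
  b <- floor(x / bin_width)
  tab <- table(b)
  thr <- if (min_density >= 1) {
    min_density
  } else if (density_reference == "modal") {
    max(1, min_density * max(tab))
  } else {
    max(1, ceiling(min_density * n_total))
  }
  keep <- names(tab)[tab >= thr]
  x[as.character(b) %in% keep]
}

#' @export
print.cluster_metrics <- function(x, ...) {
  cat(sprintf(paste0("<cluster_metrics> LOI %.0f-%.0f ms (range %.0f), ",
                     "shortest horizontal deviation %s ms\n"),
              x$shortest_loi, x$longest_loi, x$range_loi,
              if (is.na(x$shortest_horizontal_deviation)) "NA"
              else sprintf("%.0f", x$shortest_horizontal_deviation)))
  invisible(x)
}

#' Tachogram data
#'
#' Each interval against its cumulative elapsed time (end-of-interval
#' timestamps), ready for plotting interval bands over a recording.
#'
#' @param series An [rr_series()] or numeric vector of intervals.
#' @return `data.frame(time_ms, rr)` in recording order.
#' @export
tachogram_data <- function(series) {
  v <- if (inherits(series, "rr_series")) series$intervals else as.numeric(series)
  data.frame(time_ms = cumsum(v), rr = v)
}

#' Count distinct interval bands
#'
#' Estimates how many distinct horizontal bands a tachogram shows (the
#' hallmark of exit block is intervals clustering near integer multiples of
#' a base cycle) by counting prominent modes of a kernel density estimate
#' of the interval distribution.
#'
#' @param series An [rr_series()] or numeric vector of intervals.
#' @param bw Kernel bandwidth in ms.
#' @param min_height Mode prominence threshold, as a fraction of the
#'   tallest mode.
#' @return Integer count of modes.
#' @export
count_interval_bands <- function(series, bw = 30, min_height = 0.05) {
  v <- if (inherits(series, "rr_series")) series$intervals else as.numeric(series)
  if (length(v) < 10L) stop("too few intervals for band counting", call. = FALSE)
  d <- stats::density(v, bw = bw, n = 1024)
  y <- d$y
  peaks <- which(y > c(-Inf, y[-length(y)]) & y >= c(y[-1], -Inf) &
                   y >= min_height * max(y))
  length(peaks)
}

#' Exit-block ratio of an interval
#'
#' Nearest integer multiple of the base (prevailing shortest) cycle length
#' that a long conducted interval represents; used to read block ratios off
#' an electrocardiogram or Poincaré plot.
#'
#' @param interval_ms Observed conducted interval (ms).
#' @param base_ms Base cycle length (ms).
#' @return Integer ratio(s), `round(interval / base)`.
#' @examples
#' block_ratio(2633, 660)  # 4: a 4:1 exit block
#' @export
block_ratio <- function(interval_ms, base_ms) {
  round(interval_ms / base_ms)
}

#' Convert an interval to instantaneous heart rate
#'
#' @param interval_ms Interval in ms.
#' @return Heart rate in bpm (`60000 / interval`).
#' @export
interval_to_bpm <- function(interval_ms) 60000 / interval_ms
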