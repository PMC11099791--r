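# Heart-rate, sinus-pause and corrected-RMSSD variables, plus automatic
# stable/sleep-hour window selection.

#' Rate-corrected RMSSD
#'
#' Root-mean-square of successive RR differences divided by the mean RR
#' interval. Division by the prevailing interval is the standard heart-rate
#' correction for short-term variability indices; the resulting ratio is
#' dimensionless (conventionally still reported under an "ms" column
#' heading in Holter summaries).
#'
#' @param series An [rr_series()] or numeric vector of intervals (ms).
#' @return Non-negative ratio; 0 iff all successive differences are 0.
#' @examples
#' crmssd(c(800, 400, 800, 400))  # 400 / 600
#' @export
crmssd <- function(series) {
  v <- if (inherits(series, "rr_series")) series$intervals else as.numeric(series)
  if (length(v) < 2L) {
    stop("crmssd requires at least 2 intervals", call. = FALSE)
  }
  sqrt(mean(diff(v)^2)) / mean(v)
}

#' Heart-rate and pause metrics for a recording
#'
#' Computes the standard Holter summary variables from a sinus-only
#' interval series: average heart rate and RR interval, minimum heart rate,
#' minutes spent below 50 bpm, pause counts above 2/3/4 s, longest pause
#' and rate-corrected RMSSD.
#'
#' Pauses are intervals *strictly* exceeding each threshold; count pauses on
#' a series already passed through [merge_nonsinus()] so escape beats do not
#' split true sinus pauses. Minimum heart rate is `60000 / max mean RR` over
#' a trailing 60-s sliding window (an instantaneous minimum would simply
#' equal the longest pause). Time below 50 bpm is the number of whole
#' elapsed minutes whose mean RR exceeds 1200 ms.
#'
#' @param series Non-empty [rr_series()].
#' @param pause_thresholds Pause thresholds in seconds (default 2, 3, 4).
#' @return Object of class `hr_metrics`: a named list with fields
#'   `avg_hr` (bpm), `avg_rr` (ms), `min_hr` (bpm), `time_below_50` (min),
#'   `n_pauses_gt2`, `n_pauses_gt3`, `n_pauses_gt4`, `longest_pause` (s),
#'   `crmssd`, `n_intervals`.
#' @export
basic_metrics <- function(series, pause_thresholds = c(2, 3, 4)) {
  v <- if (inherits(series, "rr_series")) series$intervals else as.numeric(series)
  if (length(v) == 0L) stop("empty series", call. = FALSE)
  avg_rr <- mean(v)
  out <- list(
    avg_hr = 60000 / avg_rr,
    avg_rr = avg_rr,
    min_hr = 60000 / max(rolling_mean_rr(v, 60000)),
    time_below_50 = minutes_below(v, bpm = 50),
    longest_pause = max(v) / 1000,
    crmssd = if (length(v) >= 2L) crmssd(v) else NA_real_,
    n_intervals = length(v)
  )
  counts <- vapply(pause_thresholds, function(thr) sum(v > thr * 1000), 0)
  names(counts) <- sprintf("n_pauses_gt%g", pause_thresholds)
  out <- c(out, as.list(counts))
  structure(out[c("avg_hr", "avg_rr", "min_hr", "time_below_50",
                  names(counts), "longest_pause", "crmssd", "n_intervals")],
            class = "hr_metrics")
}

#' @export
print.hr_metrics <- function(x, ...) {
  cat("<hr_metrics>\n")
  for (nm in setdiff(names(x), "n_intervals")) {
    cat(sprintf("  %-18s %s\n", nm, format(x[[nm]], digits = 4)))
  }
  cat(sprintf("  %-18s %d\n", "n_intervals", x$n_intervals))
  invisible(x)
}

# mean RR over a trailing 60-s window ending at each beat (ms); short
# leading windows use whatever has elapsed
rolling_mean_rr <- function(v, window_ms = 60000) {
  e <- cumsum(v)
  lo <- findInterval(e - window_ms, e)  # beats fully before the window
  csum <- c(0, e)
  (e - csum[lo + 1L]) / (seq_along(v) - lo)
}

# whole elapsed minutes whose mean RR implies HR < bpm
minutes_below <- function(v, bpm = 50) {
  e <- cumsum(v)
  bucket <- floor((e - v / 2) / 60000)  # minute containing interval midpoint
  mean_rr <- tapply(v, bucket, mean)
  sum(mean_rr > 60000 / bpm)
}

span_hour_sequence <- function(start_hour, end_hour) {
  # clock hours from start_hour up to (not including) end_hour, wrapping
  if (start_hour < end_hour) return(start_hour:(end_hour - 1))
  c(start_hour:23, if (end_hour > 0) 0:(end_hour - 1))
}

#' Select the stable/sleep-hour window
#'
#' Scans contiguous whole-clock-hour windows of 1 to 6 hours inside the
#' 2200-0700 search span and scores each by rank of low mean heart rate
#' plus rank of high pause (>2 s) count, penalising windows whose
#' hour-to-hour mean-RR coefficient of variation exceeds the stability
#' threshold. Ties resolve to the earlier start, then the longer duration.
#'
#' @param series [rr_series()] with a clock anchor, covering at least one
#'   hour of the search span.
#' @param start_hour,end_hour Clock hours bounding the search span
#'   (default 22 to 7, crossing midnight).
#' @param min_hours,max_hours Window duration bounds in whole hours.
#' @param pause_threshold_s Pause threshold used in the score (s).
#' @param cv_threshold Stability threshold on the hourly mean-RR CV.
#' @return Object of class `sleep_window`: list with `start_hour`,
#'   `duration` (h), `hours` (clock hours covered), `start_clock`,
#'   `end_clock` (seconds since midnight), `score`, and the candidate
#'   table as attribute `"candidates"`.
#' @export
select_sleep_window <- function(series, start_hour = 22, end_hour = 7,
                                min_hours = 1, max_hours = 6,
                                pause_threshold_s = 2, cv_threshold = 0.5) {
  if (is.null(series$start_clock)) {
    stop("series has no clock anchor", call. = FALSE)
  }
  v <- series$intervals
  clock <- (series$start_clock + cumsum(v) / 1000) %% 86400
  hour <- floor(clock / 3600)
  span <- span_hour_sequence(start_hour, end_hour)
  cover_s <- vapply(span, function(h) sum(v[hour == h]) / 1000, 0)
  eligible <- cover_s >= 1800  # at least half the hour recorded
  if (!any(eligible)) {
    stop("series does not cover the sleep search span", call. = FALSE)
  }
  hr_mean_rr <- vapply(span, function(h) mean(v[hour == h]), 0)
  hr_n <- vapply(span, function(h) sum(hour == h), 0)
  hr_pauses <- vapply(span, function(h) {
    sum(v[hour == h] > pause_threshold_s * 1000)
  }, 0)

  cand <- list()
  for (s in seq_along(span)) {
    for (d in min_hours:max_hours) {
      idx <- s:(s + d - 1)
      if (max(idx) > length(span) || !all(eligible[idx])) next
      mean_rr <- sum(hr_mean_rr[idx] * hr_n[idx]) / sum(hr_n[idx])
      cv <- if (d == 1) 0 else stats::sd(hr_mean_rr[idx]) / mean(hr_mean_rr[idx])
      cand[[length(cand) + 1L]] <- data.frame(
        pos = s, start_hour = span[s], duration = d,
        mean_rr = mean_rr, pauses = sum(hr_pauses[idx]), cv = cv)
    }
  }
  if (!length(cand)) stop("no candidate sleep window", call. = FALSE)
  cand <- do.call(rbind, cand)
  penalty <- ifelse(cand$cv > cv_threshold, 2 * nrow(cand), 0)
  cand$score <- rank(cand$mean_rr) + rank(cand$pauses) - penalty
  best <- order(-cand$score, cand$pos, -cand$duration)[1]
  w <- cand[best, ]
  hours <- span[w$pos:(w$pos + w$duration - 1)]
  structure(
    list(start_hour = w$start_hour, duration = w$duration, hours = hours,
         start_clock = w$start_hour * 3600,
         end_clock = ((w$start_hour + w$duration) %% 24) * 3600,
         score = w$score),
    class = "sleep_window", candidates = cand)
}

#' @export
print.sleep_window <- function(x, ...) {
  cat(sprintf("<sleep_window> %02d:00-%02d:00 (%d h), score %.1f\n",
              x$start_hour, (x$start_hour + x$duration) %% 24,
              x$duration, x$score))
  invisible(x)
}

#' Slice a recording by clock hours
#'
#' Extracts the intervals whose terminating beat falls inside the given
#' clock hours (e.g. a selected sleep window), preserving order.
#'
#' @param series [rr_series()] with a clock anchor.
#' @param window A `sleep_window`, or a vector of clock hours.
#' @return [rr_series()] anchored at the first retained beat.
#' @export
clock_slice <- function(series, window) {
  hours <- if (inherits(window, "sleep_window")) window$hours else as.numeric(window)
  if (is.null(series$start_clock)) {
    stop("series has no clock anchor", call. = FALSE)
  }
  v <- series$intervals
  clock <- (series$start_clock + cumsum(v) / 1000) %% 86400
  keep <- floor(clock / 3600) %in% hours
  if (!any(keep)) stop("no intervals inside the window", call. = FALSE)
  first <- which(keep)[1]
  anchor <- if (first == 1) series$start_clock else clock[first - 1]
  rr_series(v[keep], start_clock = anchor,
            beat_flags = series$beat_flags[keep], label = series$label)
}

#' Sleep-window metrics
#'
#' Convenience wrapper: selects the stable/sleep window, slices the series
#' to it, and reports [basic_metrics()] plus `time_below_50` normalised to
#' minutes per hour (the unit used when summarising sleep hours).
#'
#' @inheritParams select_sleep_window
#' @return List with `window` and `metrics`; the metrics gain a
#'   `time_below_50_per_hour` field.
#' @export
sleep_metrics <- function(series, ...) {
  w <- select_sleep_window(series, ...)
  sub <- clock_slice(series, w)
  m <- basic_metrics(sub)
  m$time_below_50_per_hour <- m$time_below_50 / w$duration
  list(window = w, metrics = m)
}
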