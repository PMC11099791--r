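# Domain types and file I/O for beat-to-beat RR-interval series.

#' Diagnosis classes
#'
#' The three rhythm diagnoses recognised throughout the package, in the
#' fixed order used for tie-breaking and confusion matrices: balanced
#' autonomic modulation, high-parasympathetic/low-sympathetic modulation,
#' and sinus node dysfunction.
#'
#' @return Character vector `c("BALANCED", "HPLSM", "SND")`.
#' @export
diagnosis_levels <- function() c("BALANCED", "HPLSM", "SND")

#' Construct an RR-interval series
#'
#' An `rr_series` holds an ordered sequence of sinus beat-to-beat intervals
#' in milliseconds, with an optional time-of-day anchor, optional per-beat
#' sinus annotations, and an optional recording-level diagnosis label.
#'
#' Beat flags annotate the beat that *terminates* each interval, so
#' `beat_flags[i]` refers to the beat between interval `i` and interval
#' `i + 1`; the recording is taken to begin at a sinus beat.
#'
#' @param intervals Numeric vector of intervals in ms; all finite and > 0.
#' @param start_clock Optional time-of-day anchor for the first beat, either
#'   seconds since midnight or a string `"HH:MM:SS"` / `"HH:MM:SS.mmm"`.
#' @param beat_flags Optional per-interval annotation: character
#'   (`"sinus"`/`"non-sinus"`) or logical (`TRUE` = sinus).
#' @param label Optional diagnosis, one of [diagnosis_levels()].
#' @return An object of class `rr_series`.
#' @examples
#' rr_series(c(660, 660, 2640), start_clock = "22:00:00", label = "SND")
#' @export
rr_series <- function(intervals, start_clock = NULL, beat_flags = NULL,
                      label = NULL) {
  intervals <- as.numeric(intervals)
  if (any(!is.finite(intervals))) {
    stop("all intervals must be finite", call. = FALSE)
  }
  if (any(intervals <= 0)) {
    stop("all intervals must be > 0 ms", call. = FALSE)
  }
  if (!is.null(start_clock)) {
    if (is.character(start_clock)) start_clock <- parse_clock(start_clock)
    stopifnot(is.numeric(start_clock), length(start_clock) == 1L,
              start_clock >= 0, start_clock < 86400)
  }
  if (!is.null(beat_flags)) {
    if (is.logical(beat_flags)) {
      beat_flags <- ifelse(beat_flags, "sinus", "non-sinus")
    }
    if (length(beat_flags) != length(intervals)) {
      stop("beat_flags must have one entry per interval", call. = FALSE)
    }
    if (!all(beat_flags %in% c("sinus", "non-sinus"))) {
      stop("beat_flags must be 'sinus' or 'non-sinus'", call. = FALSE)
    }
  }
  if (!is.null(label)) {
    label <- match.arg(label, diagnosis_levels())
  }
  structure(
    list(intervals = intervals, start_clock = start_clock,
         beat_flags = beat_flags, label = label),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  n <- length(x$intervals)
  cat(sprintf("<rr_series> %d intervals, %.1f min elapsed", n,
              sum(x$intervals) / 60000))
  if (!is.null(x$label)) cat(sprintf(", label %s", x$label))
  if (!is.null(x$start_clock)) {
    cat(sprintf(", starts %s", format_clock(x$start_clock)))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' Parse and format clock times
#'
#' `parse_clock()` converts `"HH:MM:SS"` or `"HH:MM:SS.mmm"` (24-hour clock)
#' to seconds since midnight; `format_clock()` is the inverse.
#'
#' @param x Character vector of clock strings, or numeric seconds.
#' @return Numeric seconds since midnight, or character clock strings.
#' @export
parse_clock <- function(x) {
  m <- regmatches(x, regexec("^\\s*(\\d{1,2}):(\\d{2}):(\\d{2}(?:\\.\\d+)?)\\s*$", x))
  vapply(seq_along(x), function(i) {
    p <- m[[i]]
    if (length(p) != 4L) {
      stop(sprintf("cannot parse clock time '%s'", x[i]), call. = FALSE)
    }
    as.numeric(p[2]) * 3600 + as.numeric(p[3]) * 60 + as.numeric(p[4])
  }, numeric(1))
}

#' @rdname parse_clock
#' @export
format_clock <- function(x) {
  x <- x %% 86400
  h <- floor(x / 3600)
  mn <- floor((x - h * 3600) / 60)
  s <- x - h * 3600 - mn * 60
  ms <- round((s - floor(s)) * 1000)
  s <- floor(s)
  # carry rounding overflow upward
  carry <- ms >= 1000
  ms[carry] <- 0
  s[carry] <- s[carry] + 1
  sprintf("%02d:%02d:%02d.%03d", as.integer(h), as.integer(mn),
          as.integer(s), as.integer(ms))
}

#' Read an RR-interval file
#'
#' Reads a beat-interval export in one of two text dialects. `plain` is one
#' interval (ms) per line, with an optional trailing `*` marking the
#' terminating beat of that interval as non-sinus. `csv` is two columns,
#' `clock-time,interval_ms` (header optional); the first clock time anchors
#' the series.
#'
#' @param source Path to a file, or a string containing the file text.
#' @param dialect `"plain"` or `"csv"`.
#' @return An [rr_series()]; blank lines are skipped.
#' @examples
#' read_rr_file("660\n660\n", dialect = "plain")
#' @export
read_rr_file <- function(source, dialect = c("plain", "csv")) {
  dialect <- match.arg(dialect)
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- strsplit(paste(source, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  keep <- which(!grepl("^\\s*$", lines))
  if (dialect == "plain") {
    raw <- trimws(lines[keep])
    flagged <- grepl("\\*$", raw)
    val_txt <- trimws(sub("\\*$", "", raw))
    vals <- suppressWarnings(as.numeric(val_txt))
    bad <- which(is.na(vals))
    if (length(bad)) {
      stop(sprintf("parse error at line %d: '%s'", keep[bad[1]],
                   lines[keep[bad[1]]]), call. = FALSE)
    }
    neg <- which(vals <= 0)
    if (length(neg)) {
      stop(sprintf("invalid interval at line %d: %s ms (must be > 0)",
                   keep[neg[1]], val_txt[neg[1]]), call. = FALSE)
    }
    flags <- if (any(flagged)) ifelse(flagged, "non-sinus", "sinus") else NULL
    rr_series(vals, beat_flags = flags)
  } else {
    raw <- lines[keep]
    fields <- strsplit(raw, ",", fixed = TRUE)
    bad_shape <- which(lengths(fields) < 2L)
    if (length(bad_shape)) {
      stop(sprintf("parse error at line %d: expected 'time,interval_ms'",
                   keep[bad_shape[1]]), call. = FALSE)
    }
    # optional header: first field of the first row is not a clock time
    start_row <- 1L
    if (length(fields) &&
        !grepl("^\\s*\\d{1,2}:\\d{2}:\\d{2}", fields[[1]][1])) {
      start_row <- 2L
    }
    if (start_row > length(fields)) {
      stop("csv source contains no data rows", call. = FALSE)
    }
    rows <- start_row:length(fields)
    vals <- suppressWarnings(as.numeric(trimws(vapply(fields[rows], `[`, "", 2))))
    bad <- which(is.na(vals))
    if (length(bad)) {
      stop(sprintf("parse error at line %d: '%s'", keep[rows[bad[1]]],
                   raw[rows[bad[1]]]), call. = FALSE)
    }
    neg <- which(vals <= 0)
    if (length(neg)) {
      stop(sprintf("invalid interval at line %d: %s ms (must be > 0)",
                   keep[rows[neg[1]]], vals[neg[1]]), call. = FALSE)
    }
    start_clock <- parse_clock(trimws(fields[[rows[1]]][1]))
    rr_series(vals, start_clock = start_clock)
  }
}

fmt_ms <- function(v) {
  # integers written as integers; fractional values at full precision
  ifelse(v == round(v), sprintf("%.0f", v), sprintf("%.17g", v))
}

#' Write an RR-interval series
#'
#' Inverse of [read_rr_file()]. Whole-millisecond intervals are written as
#' integers; fractional intervals keep full precision so a read/write/read
#' round trip is exact. In the `csv` dialect the clock column is the
#' time-of-day of the beat *starting* each interval, derived from the
#' series anchor (midnight crossings wrap), so the first row carries the
#' anchor itself.
#'
#' @param series An [rr_series()].
#' @param path Output file path.
#' @param dialect `"plain"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_rr_file <- function(series, path, dialect = c("plain", "csv")) {
  dialect <- match.arg(dialect)
  v <- series$intervals
  if (dialect == "plain") {
    txt <- fmt_ms(v)
    if (!is.null(series$beat_flags)) {
      txt <- paste0(txt, ifelse(series$beat_flags == "non-sinus", "*", ""))
    }
  } else {
    start <- if (is.null(series$start_clock)) 0 else series$start_clock
    clock <- (start + c(0, cumsum(v)[-length(v)]) / 1000) %% 86400
    txt <- paste(format_clock(clock), fmt_ms(v), sep = ",")
  }
  writeLines(txt, path)
  invisible(path)
}

#' Merge escape-beat-bounded intervals into true sinus pauses
#'
#' When escape (non-sinus) beats interrupt a sinus pause, the intervals they
#' bound are summed into the single sinus-to-sinus interval spanning them,
#' recovering the true pause duration. Total elapsed time is conserved,
#' except that a run ending the recording (last beat non-sinus) has no
#' closing sinus beat and is dropped with a warning.
#'
#' @param series An [rr_series()] with `beat_flags` present (a series
#'   without flags is returned unchanged: all beats sinus).
#' @return An [rr_series()] whose beats are all sinus.
#' @examples
#' s <- rr_series(c(500, 800, 700), beat_flags = c(FALSE, TRUE, TRUE))
#' merge_nonsinus(s)$intervals  # 1300 700
#' @export
merge_nonsinus <- function(series) {
  flags <- series$beat_flags
  if (is.null(flags) || all(flags == "sinus")) {
    series$beat_flags <- rep("sinus", length(series$intervals))
    return(series)
  }
  v <- series$intervals
  n <- length(v)
  sinus <- flags == "sinus"
  # interval i starts a new sinus-to-sinus group iff the beat before it
  # (the one ending interval i - 1) was sinus
  grp <- cumsum(c(TRUE, sinus[-n]))
  merged <- as.numeric(tapply(v, grp, sum))
  if (!sinus[n]) {
    warning("recording ends on a non-sinus beat; dropping unpaired trailing interval(s)",
            call. = FALSE)
    merged <- merged[-length(merged)]
  }
  rr_series(merged, start_clock = series$start_clock,
            beat_flags = rep("sinus", length(merged)), label = series$label)
}

#' Extract rolling interval triples
#'
#' Returns all overlapping windows of three consecutive intervals, the unit
#' of classification for both the density grid and the neural network. For
#' `n` intervals there are `max(n - 2, 0)` triples; interior interval `i`
#' appears in triples `i - 2`, `i - 1` and `i`.
#'
#' @param series An [rr_series()], or a numeric vector of intervals.
#' @return Numeric matrix with columns `rr1`, `rr2`, `rr3`.
#' @examples
#' extract_triples(rr_series(c(600, 620, 640, 660)))
#' @export
extract_triples <- function(series) {
  v <- if (inherits(series, "rr_series")) series$intervals else as.numeric(series)
  if (length(v) < 3L) {
    m <- matrix(numeric(0), nrow = 0, ncol = 3)
  } else {
    m <- stats::embed(v, 3)[, 3:1, drop = FALSE]
  }
  colnames(m) <- c("rr1", "rr2", "rr3")
  m
}
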