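# Reading, writing, resampling and gap-flagging of continuous annotation traces.
#
# Two plain-text dialects are supported:
#   simple_csv: header "time_s,value"
#   pagan_csv:  header "participant,stimulus,timestamp_ms,value"
# Event logs are changes-only: the logger records a row when the value changes,
# so a long silence between two equal values is a valid constant hold, while a
# long silence bridging two *different* values is a data lapse.

#' Construct a raw event log
#'
#' An event log is the changes-only record produced by a continuous annotation
#' interface: a sequence of (time, value) rows with strictly increasing
#' timestamps and values bounded by the annotation scale.
#'
#' @param events data.frame with numeric columns `time_s` and `value`.
#' @param annotator_id,stimulus_id opaque identifier strings.
#' @param v_min,v_max bounds of the annotation scale (default -100, 100).
#' @return An object of class `event_log`.
#' @export
event_log <- function(events, annotator_id = "a1", stimulus_id = "s1",
                      v_min = -100, v_max = 100) {
  stopifnot(is.data.frame(events), all(c("time_s", "value") %in% names(events)))
  events <- events[, c("time_s", "value")]
  if (nrow(events) == 0) stop("event log must contain at least one event")
  if (anyNA(events$time_s) || anyNA(events$value))
    stop("event log contains missing time or value fields")
  if (any(diff(events$time_s) <= 0))
    stop("event timestamps must be strictly increasing")
  if (any(events$value < v_min - 1e-9) || any(events$value > v_max + 1e-9))
    stop(sprintf("event values outside scale bounds [%g, %g]", v_min, v_max))
  structure(
    list(annotator_id = as.character(annotator_id),
         stimulus_id = as.character(stimulus_id),
         events = events, v_min = v_min, v_max = v_max),
    class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> annotator %s, stimulus %s: %d events over [%g, %g] s\n",
              x$annotator_id, x$stimulus_id, nrow(x$events),
              x$events$time_s[1], x$events$time_s[nrow(x$events)]))
  invisible(x)
}

#' Read an event log from disk
#'
#' @param path file path of a CSV event log.
#' @param dialect `"simple_csv"` (header `time_s,value`) or `"pagan_csv"`
#'   (header `participant,stimulus,timestamp_ms,value`; timestamps converted
#'   from milliseconds to seconds).
#' @param v_min,v_max annotation scale bounds used for range validation.
#' @return An [event_log] with events in file order (which must be strictly
#'   increasing in time); changes-only logs are preserved verbatim, no fill.
#' @export
load_event_log <- function(path, dialect = c("simple_csv", "pagan_csv"),
                           v_min = -100, v_max = 100) {
  dialect <- match.arg(dialect)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (dialect == "simple_csv") {
    need <- c("time_s", "value")
    if (!all(need %in% names(raw)))
      stop(sprintf("'%s' is not a simple_csv event log (expected header time_s,value)", path))
    times <- suppressWarnings(as.numeric(raw$time_s))
    values <- suppressWarnings(as.numeric(raw$value))
    annotator <- "a1"; stimulus <- "s1"
  } else {
    need <- c("participant", "stimulus", "timestamp_ms", "value")
    if (!all(need %in% names(raw)))
      stop(sprintf("'%s' is not a pagan_csv event log (expected header %s)",
                   path, paste(need, collapse = ",")))
    times <- suppressWarnings(as.numeric(raw$timestamp_ms)) / 1000
    values <- suppressWarnings(as.numeric(raw$value))
    if (length(unique(raw$participant)) > 1 || length(unique(raw$stimulus)) > 1)
      stop(sprintf("'%s' mixes multiple participants or stimuli in one log", path))
    annotator <- as.character(raw$participant[1])
    stimulus <- as.character(raw$stimulus[1])
  }
  bad <- which(is.na(times) | is.na(values))
  if (length(bad))
    stop(sprintf("malformed row at line %d of '%s'", bad[1] + 1L, path))
  if (any(diff(times) <= 0)) {
    i <- which(diff(times) <= 0)[1]
    stop(sprintf("non-increasing timestamp at line %d of '%s'", i + 2L, path))
  }
  rng <- which(values < v_min - 1e-9 | values > v_max + 1e-9)
  if (length(rng))
    stop(sprintf("value out of range [%g, %g] at line %d of '%s'",
                 v_min, v_max, rng[1] + 1L, path))
  event_log(data.frame(time_s = times, value = values),
            annotator_id = annotator, stimulus_id = stimulus,
            v_min = v_min, v_max = v_max)
}

#' Write an event log to disk
#'
#' @param log an [event_log].
#' @param path output file path.
#' @param dialect output dialect, see [load_event_log()].
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path, dialect = c("simple_csv", "pagan_csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(log, "event_log"))
  if (dialect == "simple_csv") {
    out <- data.frame(time_s = log$events$time_s, value = log$events$value)
  } else {
    out <- data.frame(participant = log$annotator_id,
                      stimulus = log$stimulus_id,
                      timestamp_ms = log$events$time_s * 1000,
                      value = log$events$value)
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an annotation on a uniform time grid
#'
#' @param values numeric samples; `NA` marks missing data.
#' @param rate_hz sampling rate in Hz; the sampling period `delta = 1/rate_hz`
#'   is the step used for all differencing operations.
#' @param annotator_id,stimulus_id opaque identifier strings.
#' @param t0 time of the first sample in seconds.
#' @return An object of class `annotation`.
#' @export
annotation <- function(values, rate_hz = 1, annotator_id = "a1",
                       stimulus_id = "s1", t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("annotation needs at least 2 samples")
  stopifnot(rate_hz > 0)
  structure(
    list(annotator_id = as.character(annotator_id),
         stimulus_id = as.character(stimulus_id),
         rate_hz = rate_hz, delta = 1 / rate_hz, t0 = t0, values = values),
    class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("<annotation> annotator %s, stimulus %s: %d samples at %g Hz (%d missing)\n",
              x$annotator_id, x$stimulus_id, length(x$values), x$rate_hz,
              sum(is.na(x$values))))
  invisible(x)
}

#' Sample times of an annotation
#' @param x an [annotation].
#' @return numeric vector of sample times in seconds.
#' @export
annotation_times <- function(x) {
  stopifnot(inherits(x, "annotation"))
  x$t0 + (seq_along(x$values) - 1) * x$delta
}

#' Resample an event log onto a uniform grid
#'
#' Linear interpolation onto the grid `t0, t0 + delta, ...` starting at the
#' first event. Because the logger records only value changes, a gap between
#' two events with *equal* values is a valid constant hold. A gap between
#' events with *different* values and a duration exceeding `max_gap_s` is a
#' data lapse: grid points strictly inside it are flagged missing (`NA`).
#' Grid points at or after the last event hold its value.
#'
#' @param log an [event_log] with at least 2 events.
#' @param rate_hz target sampling rate (default 1 Hz).
#' @param max_gap_s maximum trusted duration for a value-changing gap; longer
#'   unequal-endpoint gaps are flagged. Default (`NULL`) is two sampling
#'   periods, `2 / rate_hz`.
#' @return An [annotation].
#' @export
resample <- function(log, rate_hz = 1, max_gap_s = NULL) {
  stopifnot(inherits(log, "event_log"), rate_hz > 0)
  ev <- log$events
  if (nrow(ev) < 2) stop("degenerate input: resample needs at least 2 events")
  if (is.null(max_gap_s)) max_gap_s <- 2 / rate_hz
  delta <- 1 / rate_hz
  t0 <- ev$time_s[1]
  t_end <- ev$time_s[nrow(ev)]
  n <- floor((t_end - t0) * rate_hz + 1e-9) + 1L
  grid <- t0 + (seq_len(n) - 1) * delta
  vals <- approx(ev$time_s, ev$value, xout = grid, rule = 2)$y
  # lapse rule: unequal endpoint values over a gap longer than max_gap_s
  gap_len <- diff(ev$time_s)
  changed <- abs(diff(ev$value)) > 0
  lapse <- which(changed & gap_len > max_gap_s + 1e-9)
  for (i in lapse) {
    inside <- grid > ev$time_s[i] + 1e-9 & grid < ev$time_s[i + 1] - 1e-9
    vals[inside] <- NA_real_
  }
  annotation(vals, rate_hz = rate_hz, annotator_id = log$annotator_id,
             stimulus_id = log$stimulus_id, t0 = t0)
}

#' Write an annotation as CSV
#'
#' Output header is `time_s,value`; missing samples are written as empty
#' fields.
#'
#' @param x an [annotation].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(x, path) {
  stopifnot(inherits(x, "annotation"))
  df <- data.frame(time_s = annotation_times(x), value = x$values)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read an annotation CSV written by [write_annotation()]
#'
#' @param path file path; header must be `time_s,value`.
#' @param annotator_id,stimulus_id identifiers to attach.
#' @return An [annotation]; the rate is inferred from the time column.
#' @export
read_annotation <- function(path, annotator_id = "a1", stimulus_id = "s1") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "value") %in% names(df)))
    stop(sprintf("'%s' is not an annotation CSV (expected header time_s,value)", path))
  tt <- as.numeric(df$time_s)
  dt <- diff(tt)
  if (length(dt) == 0 || any(abs(dt - dt[1]) > 1e-6))
    stop(sprintf("'%s' does not lie on a uniform time grid", path))
  annotation(as.numeric(df$value), rate_hz = 1 / dt[1],
             annotator_id = annotator_id, stimulus_id = stimulus_id, t0 = tt[1])
}
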