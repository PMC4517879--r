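#' Scorer annotation: one scorer's pass over one record
#'
#' An annotation is an ordered list of scored segments, each carrying the
#' assigned pattern, half-open record-time interval `[start_s, end_s)`, and
#' the wall-clock timestamp (seconds since session start) at which the score
#' was committed. Events must not overlap in record time and must lie within
#' the record.
#'
#' @param events Data frame with columns `start_s`, `end_s`, `pattern`,
#'   `wallclock_s` and optionally `comment`.
#' @param record_length_s Record duration in seconds.
#' @param scorer_id,iteration Provenance tags.
#' @return An object of class `rip_annotation`.
#' @export
rip_annotation <- function(events, record_length_s, scorer_id = "scorer",
                           iteration = 1L) {
  stopifnot(is.data.frame(events))
  need <- c("start_s", "end_s", "pattern", "wallclock_s")
  if (!all(need %in% names(events))) {
    stop("events must have columns start_s, end_s, pattern, wallclock_s",
         call. = FALSE)
  }
  if (!"comment" %in% names(events)) events$comment <- rep("", nrow(events))
  assert_patterns(events$pattern)
  if (nrow(events) > 0L) {
    if (any(events$end_s <= events$start_s)) {
      stop("every event must satisfy end_s > start_s", call. = FALSE)
    }
    if (any(events$start_s < 0) || any(events$end_s > record_length_s + 1e-9)) {
      stop("events must lie within [0, record_length_s]", call. = FALSE)
    }
    o <- order(events$start_s)
    events <- events[o, , drop = FALSE]
    if (nrow(events) > 1L &&
        any(events$start_s[-1] < events$end_s[-nrow(events)] - 1e-9)) {
      stop("events must not overlap in record time", call. = FALSE)
    }
  }
  rownames(events) <- NULL
  structure(list(events = events, record_length_s = record_length_s,
                 scorer_id = scorer_id, iteration = iteration),
            class = "rip_annotation")
}

#' @export
print.rip_annotation <- function(x, ...) {
  cat(sprintf("<rip_annotation> %s iter %s: %d events over %.1f s\n",
              x$scorer_id, x$iteration, nrow(x$events), x$record_length_s))
  invisible(x)
}

#' Expand an annotation to a per-sample label vector
#'
#' Sample `i` (1-based) covers record time `[(i-1)/fs, i/fs)`; an event's
#' half-open interval `[start_s, end_s)` therefore claims exactly the
#' samples whose left edge falls inside it, so abutting events share no
#' sample. Unscored samples are `"NONE"`.
#'
#' @param annotation A [rip_annotation()].
#' @param sample_rate Samples per second.
#' @return Character vector of length `round(record_length_s * sample_rate)`.
#' @export
expand_labels <- function(annotation, sample_rate = 50) {
  stopifnot(inherits(annotation, "rip_annotation"))
  n <- round(annotation$record_length_s * sample_rate)
  labels <- rep(rip_none(), n)
  ev <- annotation$events
  for (i in seq_len(nrow(ev))) {
    i1 <- floor(ev$start_s[i] * sample_rate + 1e-9) + 1L
    i2 <- floor(ev$end_s[i] * sample_rate + 1e-9)
    if (i2 >= i1) labels[i1:min(i2, n)] <- ev$pattern[i]
  }
  labels
}

#' Convert a ground-truth track to an annotation
#'
#' Utility inverse of [expand_labels()]: turns the segment table of a
#' [ground_truth()] into an annotation with synthetic wall-clock timestamps.
#'
#' @param truth A [ground_truth()].
#' @param seconds_per_event Wall-clock cost assigned per event.
#' @param scorer_id,iteration Provenance tags.
#' @return A [rip_annotation()] (runs labeled `NONE` are left unscored).
#' @export
truth_as_annotation <- function(truth, seconds_per_event = 5,
                                scorer_id = "truth", iteration = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  fs <- truth$sample_rate
  st <- truth$segments
  st <- st[st$pattern != rip_none(), , drop = FALSE]
  ev <- data.frame(
    start_s = (st$start - 1L) / fs,
    end_s = (st$end - 1L) / fs,
    pattern = st$pattern,
    wallclock_s = seq_len(nrow(st)) * seconds_per_event,
    comment = ""
  )
  rip_annotation(ev, record_length_s = length(truth$labels) / fs,
                 scorer_id = scorer_id, iteration = iteration)
}

# wallclock cost per event: difference from the previous event's timestamp,
# NA for the first event; differences over the threshold are interruptions
event_costs <- function(annotation, max_gap_s = 120) {
  wc <- annotation$events$wallclock_s
  d <- c(NA_real_, diff(wc))
  d[!is.na(d) & d > max_gap_s] <- NA_real_
  d
}

#' Overall scoring rate
#'
#' The time spent scoring is the sum of wall-clock differences between
#' consecutive scores; differences greater than `max_gap_s` (default 2 min)
#' are excluded as likely interruptions. The rate is hours of data scored
#' per hour of scoring time.
#'
#' @param annotation A [rip_annotation()] with at least 2 events.
#' @param max_gap_s Gap-exclusion threshold in seconds (inclusive: a
#'   difference of exactly `max_gap_s` is kept).
#' @return Scoring rate (data-hours per scoring-hour).
#' @export
scoring_rate <- function(annotation, max_gap_s = 120) {
  stopifnot(inherits(annotation, "rip_annotation"))
  if (nrow(annotation$events) < 2L) {
    stop("undefined-rate: need at least 2 scored events", call. = FALSE)
  }
  d <- event_costs(annotation, max_gap_s)
  scoring_s <- sum(d, na.rm = TRUE)
  if (scoring_s <= 0) {
    stop("undefined-rate: zero scoring time", call. = FALSE)
  }
  annotation$record_length_s / scoring_s
}

#' Pattern-specific scoring rate
#'
#' Ratio of the total record-time length of segments assigned to `pattern`
#' to the wall-clock time attributed to scoring them. Each event's cost is
#' the difference from the previous event's timestamp (the first event has
#' no attributable cost); differences over `max_gap_s` are excluded.
#'
#' @inheritParams scoring_rate
#' @param pattern One of [rip_patterns()].
#' @return Scoring rate (data-hours per scoring-hour) for that pattern.
#' @export
pattern_scoring_rate <- function(annotation, pattern, max_gap_s = 120) {
  stopifnot(inherits(annotation, "rip_annotation"))
  assert_patterns(pattern)
  ev <- annotation$events
  d <- event_costs(annotation, max_gap_s)
  sel <- ev$pattern == pattern
  if (!any(sel)) {
    stop(sprintf("undefined-rate: no events assigned to %s", pattern),
         call. = FALSE)
  }
  usable <- sel & !is.na(d)
  if (!any(usable)) {
    stop(sprintf("undefined-rate: no usable timing for %s events", pattern),
         call. = FALSE)
  }
  # numerator: total length of ALL events of the pattern (as for the overall
  # rate, where the full record length is divided by the usable time)
  data_s <- sum(ev$end_s[sel] - ev$start_s[sel])
  data_s / sum(d[usable])
}

#' Read and write annotation files
#'
#' Annotation files are CSV with mandatory header
#' `start_s,end_s,pattern,wallclock_s,comment`. Reading validates strictly
#' (pattern codes, ordering, overlap, bounds) and reports the offending line.
#'
#' @param annotation A [rip_annotation()].
#' @param path File path.
#' @param record_length_s Record length; defaults to the last event end on
#'   read.
#' @param scorer_id,iteration Provenance tags on read.
#' @return `read_annotation()` returns a [rip_annotation()];
#'   `write_annotation()` returns its input invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "rip_annotation"))
  utils::write.csv(annotation$events[, c("start_s", "end_s", "pattern",
                                         "wallclock_s", "comment")],
                   path, row.names = FALSE)
  invisible(annotation)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path, record_length_s = NULL,
                            scorer_id = "scorer", iteration = 1L) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop(sprintf(
                   "cannot parse annotation file %s: %s", path,
                   conditionMessage(e)), call. = FALSE))
  need <- c("start_s", "end_s", "pattern", "wallclock_s")
  if (!all(need %in% names(df))) {
    stop("annotation file must have header start_s,end_s,pattern,wallclock_s",
         call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    if (!is.finite(df$start_s[i]) || !is.finite(df$end_s[i]) ||
        df$end_s[i] <= df$start_s[i]) {
      stop(sprintf("malformed event at line %d of %s", i + 1L, path),
           call. = FALSE)
    }
    if (!df$pattern[i] %in% rip_patterns()) {
      stop(sprintf("invalid pattern '%s' at line %d of %s",
                   df$pattern[i], i + 1L, path), call. = FALSE)
    }
  }
  if (is.null(record_length_s)) record_length_s <- max(df$end_s, 0)
  rip_annotation(df, record_length_s, scorer_id, iteration)
}
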