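#' Multi-channel RIP record container
#'
#' A fixed-rate container for respiratory inductive plethysmography signals.
#' Ribcage (`rcg`) and abdomen (`abd`) channels are mandatory;
#' photoplethysmography (`ppg`) and oxygen saturation (`sat`) are optional
#' and play no role in pattern scoring.
#'
#' @param rcg,abd Numeric vectors of equal length: ribcage and abdomen band
#'   signals in arbitrary units.
#' @param sample_rate Sampling rate in samples per second (default 50).
#' @param ppg,sat Optional numeric channels, same length as `rcg`.
#' @param t0 Record start time in seconds (epoch-agnostic offset).
#' @return An object of class `rip_record`.
#' @examples
#' r <- rip_record(sin(seq(0, 10, by = 0.02)), cos(seq(0, 10, by = 0.02)))
#' r
#' @export
rip_record <- function(rcg, abd, sample_rate = 50, ppg = NULL, sat = NULL,
                       t0 = 0) {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("sample_rate must be a positive scalar", call. = FALSE)
  }
  n <- length(rcg)
  if (n < 1L) stop("record must contain at least one sample", call. = FALSE)
  for (ch in list(abd = abd, ppg = ppg, sat = sat)) {
    if (!is.null(ch) && length(ch) != n) {
      stop("all channels must have identical length", call. = FALSE)
    }
  }
  structure(
    list(rcg = as.numeric(rcg), abd = as.numeric(abd),
         ppg = if (!is.null(ppg)) as.numeric(ppg),
         sat = if (!is.null(sat)) as.numeric(sat),
         sample_rate = sample_rate, t0 = t0),
    class = "rip_record"
  )
}

#' @export
length.rip_record <- function(x) length(x$rcg)

#' Record duration in seconds
#' @param record A `rip_record`.
#' @return Duration in seconds.
#' @export
record_duration <- function(record) {
  stopifnot(inherits(record, "rip_record"))
  length(record$rcg) / record$sample_rate
}

#' @export
print.rip_record <- function(x, ...) {
  chans <- c("rcg", "abd", if (!is.null(x$ppg)) "ppg", if (!is.null(x$sat)) "sat")
  cat(sprintf("<rip_record> %d samples @ %g Hz (%.1f s), channels: %s\n",
              length(x$rcg), x$sample_rate, record_duration(x),
              paste(chans, collapse = ", ")))
  invisible(x)
}

#' Labeled two-channel signal excerpt
#'
#' The currency of training, evaluation and quality control: a ribcage/abdomen
#' excerpt whose respiratory pattern is known.
#'
#' @param rcg,abd Numeric vectors of equal positive length.
#' @param pattern One of the six codes from [rip_patterns()].
#' @param sample_rate Samples per second.
#' @param source_id Opaque provenance tag (default: generated).
#' @param meta Optional named list of generator metadata.
#' @return An object of class `labeled_segment`.
#' @export
labeled_segment <- function(rcg, abd, pattern, sample_rate = 50,
                            source_id = NULL, meta = list()) {
  if (length(rcg) < 1L || length(rcg) != length(abd)) {
    stop("rcg and abd must have equal, positive length", call. = FALSE)
  }
  assert_patterns(pattern)
  if (length(pattern) != 1L) stop("pattern must be a single code", call. = FALSE)
  if (is.null(source_id)) {
    source_id <- sprintf("%s-%08x", tolower(pattern),
                         as.integer(sum(cumsum(abs(rcg))) %% 0xFFFFFFF))
  }
  structure(
    list(rcg = as.numeric(rcg), abd = as.numeric(abd),
         pattern = pattern, sample_rate = sample_rate,
         source_id = as.character(source_id), meta = meta),
    class = "labeled_segment"
  )
}

#' @export
length.labeled_segment <- function(x) length(x$rcg)

#' @export
print.labeled_segment <- function(x, ...) {
  cat(sprintf("<labeled_segment> %s, %d samples @ %g Hz (%.2f s) [%s]\n",
              x$pattern, length(x$rcg), x$sample_rate,
              length(x$rcg) / x$sample_rate, x$source_id))
  invisible(x)
}

#' Library of labeled segments
#'
#' @param segments List of [labeled_segment()] objects.
#' @return An object of class `segment_library` with a `counts_by_pattern`
#'   table consistent with its contents.
#' @export
segment_library <- function(segments) {
  if (!is.list(segments) ||
      !all(vapply(segments, inherits, logical(1), "labeled_segment"))) {
    stop("segments must be a list of labeled_segment objects", call. = FALSE)
  }
  pats <- vapply(segments, `[[`, character(1), "pattern")
  counts <- table(factor(pats, levels = rip_patterns()))
  structure(
    list(segments = segments,
         counts_by_pattern = stats::setNames(as.integer(counts), names(counts))),
    class = "segment_library"
  )
}

#' @export
length.segment_library <- function(x) length(x$segments)

#' @export
print.segment_library <- function(x, ...) {
  cat(sprintf("<segment_library> %d segments\n", length(x$segments)))
  print(x$counts_by_pattern)
  invisible(x)
}

#' Read and write RIP signal files
#'
#' Signal files are delimited text with header `time_s,rcg,abd,ppg,sat`, one
#' row per sample; absent optional channels are written as empty columns.
#'
#' @param record A `rip_record`.
#' @param path File path.
#' @return `write_signals()` returns `record` invisibly; `read_signals()`
#'   returns a `rip_record`.
#' @export
write_signals <- function(record, path) {
  stopifnot(inherits(record, "rip_record"))
  n <- length(record$rcg)
  df <- data.frame(
    time_s = record$t0 + (seq_len(n) - 1L) / record$sample_rate,
    rcg = record$rcg, abd = record$abd,
    ppg = if (is.null(record$ppg)) rep("", n) else record$ppg,
    sat = if (is.null(record$sat)) rep("", n) else record$sat
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(record)
}

#' @rdname write_signals
#' @export
read_signals <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "rcg", "abd")
  if (!all(need %in% names(df))) {
    stop("signal file must have columns time_s, rcg, abd", call. = FALSE)
  }
  if (nrow(df) < 2L) stop("signal file must contain >= 2 samples", call. = FALSE)
  fs <- 1 / stats::median(diff(df$time_s))
  opt <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (is.null(df[[col]]) || all(is.na(v))) NULL else v
  }
  rip_record(df$rcg, df$abd, sample_rate = fs,
             ppg = opt("ppg"), sat = opt("sat"), t0 = df$time_s[1])
}

# deterministic seed derivation for sub-streams; keeps results < 2^31
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647
}
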