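#' Cross-fade transition weights
#'
#' Weights for the overlap concatenation of two signal segments: over a
#' transition window of `n_t` samples the outgoing segment is attenuated by
#' the complementary weight `1 - ramp` while the incoming segment is
#' amplified by `ramp`, so the two always sum to the blended signal with
#' unit total gain. The default ramp is a half-period raised cosine,
#' `0.5 - 0.5 * cos(pi * k / (n_t - 1))`: sigmoid-shaped and exactly 0 and 1
#' at the window edges, which guarantees bit-exact output outside the
#' window. A logistic ramp (rescaled to hit 0/1 exactly) is available via
#' `shape = "logistic"`.
#'
#' @param n_t Transition-window length in samples (>= 0).
#' @param shape `"cosine"` (default) or `"logistic"`.
#' @return An object of class `crossfade_spec` with fields `n_t` and `ramp`
#'   (non-decreasing, in `[0, 1]`, endpoints exactly 0 and 1 for
#'   `n_t >= 2`).
#' @examples
#' crossfade_weights(4)$ramp
#' @export
crossfade_weights <- function(n_t, shape = c("cosine", "logistic")) {
  shape <- match.arg(shape)
  if (!is.numeric(n_t) || length(n_t) != 1L || n_t < 0 || n_t != round(n_t)) {
    stop("n_t must be a non-negative integer", call. = FALSE)
  }
  n_t <- as.integer(n_t)
  ramp <- if (n_t == 0L) {
    numeric(0)
  } else if (n_t == 1L) {
    1  # degenerate single-sample window: taken from the incoming segment
  } else if (shape == "cosine") {
    k <- 0:(n_t - 1L)
    0.5 - 0.5 * cos(pi * k / (n_t - 1L))
  } else {
    k <- seq(-6, 6, length.out = n_t)
    f <- 1 / (1 + exp(-k))
    (f - f[1]) / (f[n_t] - f[1])
  }
  structure(list(n_t = n_t, ramp = ramp), class = "crossfade_spec")
}

as_crossfade <- function(spec) {
  if (inherits(spec, "crossfade_spec")) spec else crossfade_weights(spec)
}

#' Concatenate two two-channel segments with a cross-fade
#'
#' Aligns the last `n_t` samples of `a` with the first `n_t` samples of `b`
#' and blends them with complementary sigmoid weights, yielding a smooth
#' transition without the sharp transients of naive abutment. Output length
#' is `length(a) + length(b) - n_t`; samples before the window equal `a`
#' exactly, samples after equal `b` exactly.
#'
#' @param a,b Objects with `rcg` and `abd` channels ([labeled_segment()] or
#'   [rip_record()]) or plain lists with those fields.
#' @param spec A [crossfade_weights()] object or an `n_t` integer.
#' @return List with blended `rcg` and `abd` channels.
#' @export
concat_pair <- function(a, b, spec = crossfade_weights(50)) {
  spec <- as_crossfade(spec)
  n_t <- spec$n_t
  la <- length(a$rcg); lb <- length(b$rcg)
  if (la < n_t || lb < n_t) {
    stop("segments must be at least n_t samples long", call. = FALSE)
  }
  blend <- function(xa, xb) {
    if (n_t == 0L) return(c(xa, xb))
    head_a <- xa[seq_len(la - n_t)]
    win <- (1 - spec$ramp) * xa[(la - n_t + 1L):la] +
      spec$ramp * xb[seq_len(n_t)]
    tail_b <- if (lb > n_t) xb[(n_t + 1L):lb] else numeric(0)
    c(head_a, win, tail_b)
  }
  list(rcg = blend(a$rcg, b$rcg), abd = blend(a$abd, b$abd))
}

#' Concatenate labeled segments into a record with ground truth
#'
#' Folds a list of labeled segments into one continuous record via pairwise
#' cross-fades and builds the per-sample ground-truth label track. Record
#' length is the sum of segment lengths minus `(k - 1) * n_t` for `k`
#' segments. Inside each transition window the label is split at the window
#' midpoint: the first half keeps the preceding segment's pattern, the
#' second half takes the following segment's.
#'
#' @param segments Non-empty list of [labeled_segment()] objects sharing a
#'   sample rate.
#' @param spec A [crossfade_weights()] object or an `n_t` integer.
#' @return List with elements `record` ([rip_record()]) and `truth`
#'   (`ground_truth` object, see [ground_truth()]).
#' @export
concat_segments <- function(segments, spec = crossfade_weights(50)) {
  spec <- as_crossfade(spec)
  if (!is.list(segments) || length(segments) == 0L) {
    stop("segments must be a non-empty list", call. = FALSE)
  }
  lens <- vapply(segments, function(s) length(s$rcg), integer(1))
  if (any(lens < spec$n_t)) {
    stop("every segment must be at least n_t samples long", call. = FALSE)
  }
  fs <- segments[[1]]$sample_rate
  n_t <- spec$n_t
  k <- length(segments)

  sig <- segments[[1]][c("rcg", "abd")]
  if (k > 1L) {
    for (i in 2:k) sig <- concat_pair(sig, segments[[i]], spec)
  }
  total <- sum(lens) - (k - 1L) * n_t

  # nominal (untrimmed) extent of each segment in the output, 1-based,
  # half-open [start, end); consecutive extents overlap by n_t samples
  starts <- integer(k); ends <- integer(k)
  pos <- 0L
  for (i in seq_len(k)) {
    starts[i] <- pos + 1L
    ends[i] <- pos + lens[i] + 1L   # one past last sample
    pos <- pos + lens[i] - n_t
  }
  # label boundaries: midpoint of each transition window
  bounds <- integer(k + 1L)
  bounds[1] <- 1L
  bounds[k + 1L] <- total + 1L
  if (k > 1L) {
    for (i in 2:k) {
      win_start <- starts[i]               # first sample of window i-1 -> i
      bounds[i] <- win_start + n_t %/% 2L
    }
  }
  seg_tab <- data.frame(
    start = bounds[seq_len(k)],
    end = bounds[2:(k + 1L)],
    pattern = vapply(segments, `[[`, character(1), "pattern"),
    source_id = vapply(segments, `[[`, character(1), "source_id"),
    nominal_start = starts,
    nominal_end = ends,
    stringsAsFactors = FALSE
  )
  truth <- ground_truth(seg_tab, n_samples = total, sample_rate = fs)
  list(record = rip_record(sig$rcg, sig$abd, sample_rate = fs), truth = truth)
}

#' Ground-truth label track
#'
#' Pairs a per-sample pattern label vector with the segment table that
#' generated it. The segment table tiles the record without gaps or
#' overlaps using half-open `[start, end)` sample intervals (1-based).
#'
#' @param segment_table Data frame with columns `start`, `end`, `pattern`,
#'   `source_id` (and optionally the untrimmed `nominal_start`/`nominal_end`
#'   extents).
#' @param n_samples Record length in samples.
#' @param sample_rate Samples per second.
#' @return An object of class `ground_truth` with fields `labels` (length
#'   `n_samples`), `segments`, `sample_rate`.
#' @export
ground_truth <- function(segment_table, n_samples, sample_rate = 50) {
  st <- segment_table
  if (nrow(st) > 0L) {
    if (st$start[1] != 1L || st$end[nrow(st)] != n_samples + 1L ||
        (nrow(st) > 1L && any(st$start[-1] != st$end[-nrow(st)]))) {
      stop("segment_table must tile the record without gaps or overlaps",
           call. = FALSE)
    }
    assert_patterns(st$pattern, allow_none = TRUE)
  }
  labels <- rep(rip_none(), n_samples)
  for (i in seq_len(nrow(st))) {
    if (st$end[i] > st$start[i]) {
      labels[st$start[i]:(st$end[i] - 1L)] <- st$pattern[i]
    }
  }
  structure(list(labels = labels, segments = st, sample_rate = sample_rate),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d samples, %d segments @ %g Hz\n",
              length(x$labels), nrow(x$segments), x$sample_rate))
  print(table(factor(x$labels, levels = c(rip_patterns(), rip_none()))))
  invisible(x)
}

#' Read and write label tracks in run-length form
#'
#' Label-track files are CSV with columns `start_s,end_s,pattern` using
#' half-open second intervals and pattern codes
#' SYB/ASB/SIH/PAU/MVT/UNK/NONE.
#'
#' @param truth A `ground_truth` object.
#' @param path File path.
#' @param sample_rate Samples per second used to reconstruct sample indices
#'   on read.
#' @return `read_track()` returns a `ground_truth`; `write_track()` returns
#'   `truth` invisibly.
#' @export
write_track <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  fs <- truth$sample_rate
  df <- data.frame(start_s = (truth$segments$start - 1L) / fs,
                   end_s = (truth$segments$end - 1L) / fs,
                   pattern = truth$segments$pattern)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(truth)
}

#' @rdname write_track
#' @export
read_track <- function(path, sample_rate = 50) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "pattern")
  if (!all(need %in% names(df))) {
    stop("track file must have columns start_s, end_s, pattern", call. = FALSE)
  }
  assert_patterns(df$pattern, allow_none = TRUE)
  st <- data.frame(start = as.integer(round(df$start_s * sample_rate)) + 1L,
                   end = as.integer(round(df$end_s * sample_rate)) + 1L,
                   pattern = df$pattern,
                   source_id = sprintf("row-%d", seq_len(nrow(df))),
                   stringsAsFactors = FALSE)
  ground_truth(st, n_samples = st$end[nrow(st)] - 1L,
               sample_rate = sample_rate)
}
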