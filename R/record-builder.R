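#' Default per-pattern segment counts for quality-control insertion
#'
#' The canonical quality-control insertion scheme selects 152 segments
#' (about 1,000 s of data) with every pattern approximately equally
#' represented: 25 SYB, 26 ASB, 27 SIH, 22 PAU, 27 MVT and 25 UNK.
#'
#' @return Named integer vector over the six patterns.
#' @export
qc_default_counts <- function() {
  c(SYB = 25L, ASB = 26L, SIH = 27L, PAU = 22L, MVT = 27L, UNK = 25L)
}

# turn a generator function or a segment_library into a draw(pattern) closure
make_source <- function(source, params = synth_params(),
                        duration_range = c(10, 40)) {
  if (is.function(source)) return(source)
  if (inherits(source, "segment_library")) {
    pats <- vapply(source$segments, `[[`, character(1), "pattern")
    return(function(pattern) {
      idx <- which(pats == pattern)
      if (length(idx) == 0L) {
        stop(sprintf("library has no %s segments", pattern), call. = FALSE)
      }
      source$segments[[if (length(idx) == 1L) idx else sample(idx, 1L)]]
    })
  }
  if (is.null(source)) {
    return(function(pattern) {
      lo <- duration_range[1]
      # sigh and pause generators have pattern-specific minimum durations
      if (pattern == "SIH") lo <- max(lo, min_sigh_duration(params) + 0.2)
      if (pattern == "PAU") lo <- max(lo, 2.2 / params$breath_rate + 1)
      d <- stats::runif(1, min(lo, duration_range[2]), duration_range[2])
      synth_segment(pattern, max(d, lo), params, seed = NULL)
    })
  }
  stop("source must be NULL, a function(pattern), or a segment_library",
       call. = FALSE)
}

seg_patterns <- function(segments) {
  vapply(segments, `[[`, character(1), "pattern")
}

#' Randomly reorder segments avoiding adjacent equal patterns
#'
#' Applies a seeded random permutation followed by the push-to-end repair:
#' whenever two contiguous segments share a pattern, the second is pushed to
#' the end of the list. The repair is bounded to three full passes; any
#' residual conflicts are then resolved by greedy re-insertion, and if a
#' conflict-free arrangement still cannot be found (e.g. all segments share
#' one pattern) the current arrangement is returned with a warning.
#'
#' @param segments Non-empty list of [labeled_segment()] objects.
#' @param seed Integer seed for the permutation; `NULL` uses the ambient RNG.
#' @return Reordered list of segments.
#' @export
reorder_no_adjacent <- function(segments, seed = NULL) {
  if (!is.list(segments) || length(segments) == 0L) {
    stop("segments must be a non-empty list", call. = FALSE)
  }
  with_opt_seed(seed, {
    lst <- segments[sample.int(length(segments))]
    k <- length(lst)
    for (pass in 1:3) {
      j <- 2L; moves <- 0L
      while (j <= k && moves <= k) {
        if (seg_patterns(lst)[j] == seg_patterns(lst)[j - 1L]) {
          lst <- c(lst[-j], lst[j]); moves <- moves + 1L
        } else j <- j + 1L
      }
      pats <- seg_patterns(lst)
      if (!any(pats[-1] == pats[-k])) return(lst)
    }
    # greedy re-insertion of residual tail conflicts
    repeat {
      pats <- seg_patterns(lst)
      con <- which(pats[-1] == pats[-k]) + 1L
      if (length(con) == 0L) return(lst)
      i <- con[1]
      p <- pats[i]
      moved <- FALSE
      for (pos in 0:(k - 1L)) {    # insert after position pos (0 = front)
        if (pos == i - 1L || pos == i) next
        rest <- seg_patterns(lst[-i])
        left <- if (pos >= 1L) rest[pos] else NA_character_
        right <- if (pos < k - 1L) rest[pos + 1L] else NA_character_
        if (!identical(left, p) && !identical(right, p)) {
          lst <- append(lst[-i], lst[i], after = pos)
          moved <- TRUE
          break
        }
      }
      if (!moved) {
        warning("no conflict-free ordering exists; adjacent equal patterns remain")
        return(lst)
      }
    }
  })
}

accumulate_segments <- function(draw, total_s, patterns = rip_patterns()) {
  segs <- list()
  acc <- 0
  i <- 0L
  while (acc <= total_s) {
    pat <- patterns[(i %% length(patterns)) + 1L]
    s <- draw(pat)
    segs[[length(segs) + 1L]] <- s
    acc <- acc + length(s$rcg) / s$sample_rate
    i <- i + 1L
  }
  segs
}

#' Build a training-mode record
#'
#' Simulates segments of each pattern category in rotation until more than
#' `accumulate_s` (default 1.5 h) of data is stored, randomly reorders the
#' list with the adjacent-equal-pattern repair, truncates it to the shortest
#' prefix whose total length reaches `target_s` (default 1 h), and
#' concatenates the prefix into a continuous record with its ground-truth
#' track. The result contains every pattern category and no two adjacent
#' ground-truth segments share a pattern.
#'
#' @param source `NULL` (synthesize with `params`), a `function(pattern)`
#'   returning a [labeled_segment()], or a [segment_library()].
#' @param spec Cross-fade spec or `n_t` (default 50 samples = 1 s at 50 Hz).
#' @param seed Integer seed.
#' @param target_s Record length target in seconds (default 3600).
#' @param accumulate_s Accumulation threshold in seconds (default 5400).
#' @param params [synth_params()] used when `source` is `NULL`.
#' @param duration_range Segment duration range in seconds for synthesis.
#' @return List with `record` ([rip_record()]) and `truth`
#'   ([ground_truth()]).
#' @export
build_training_record <- function(source = NULL, spec = crossfade_weights(50),
                                  seed = NULL, target_s = 3600,
                                  accumulate_s = 5400,
                                  params = synth_params(),
                                  duration_range = c(10, 40)) {
  spec <- as_crossfade(spec)
  with_opt_seed(seed, {
    draw <- make_source(source, params, duration_range)
    segs <- accumulate_segments(draw, accumulate_s)
    for (try in 1:10) {
      ord <- reorder_no_adjacent(segs, seed = NULL)
      lens_s <- vapply(ord, function(s) length(s$rcg) / s$sample_rate,
                       numeric(1))
      # shortest prefix whose concatenated length (transition overlaps
      # deducted) reaches the target, so the record is at least target_s
      fs <- segs[[1]]$sample_rate
      concat_s <- cumsum(lens_s) - (seq_along(lens_s) - 1L) * spec$n_t / fs
      n_keep <- which(concat_s >= target_s)[1]
      if (is.na(n_keep)) n_keep <- length(ord)
      kept <- ord[seq_len(n_keep)]
      if (setequal(unique(seg_patterns(kept)), rip_patterns())) {
        return(concat_segments(kept, spec))
      }
    }
    stop("could not build a truncated list containing all six patterns",
         call. = FALSE)
  })
}

#' Build an evaluation-mode record with duplicated halves
#'
#' Simulates unique segments totalling at least `half_s` (default 30 min),
#' duplicates the list, independently reorders each copy with the
#' adjacent-pattern repair, joins the two halves and concatenates them. Each
#' unique segment therefore appears exactly once in each half, in a
#' different random order, enabling consistency scoring; the pairing links
#' the two copies sample-for-sample.
#'
#' @inheritParams build_training_record
#' @param half_s Target length of each half in seconds (default 1800).
#' @return List with `record`, `truth`, and `pairing` (a data frame with one
#'   row per unique segment: `source_id`, `pattern`, and the half-open
#'   nominal sample extents `first_start`, `first_end`, `second_start`,
#'   `second_end`; both copies have equal extent lengths).
#' @export
build_evaluation_record <- function(source = NULL,
                                    spec = crossfade_weights(50),
                                    seed = NULL, half_s = 1800,
                                    params = synth_params(),
                                    duration_range = c(10, 40)) {
  spec <- as_crossfade(spec)
  with_opt_seed(seed, {
    draw <- make_source(source, params, duration_range)
    uniq <- accumulate_segments(draw, half_s)
    # distinct per-copy source ids, shared stem for pairing
    for (i in seq_along(uniq)) uniq[[i]]$source_id <- sprintf("seg-%03d", i)
    copy1 <- reorder_no_adjacent(uniq, seed = NULL)
    ids1 <- vapply(copy1, `[[`, character(1), "source_id")
    for (try in 1:10) {
      copy2 <- reorder_no_adjacent(uniq, seed = NULL)
      ids2 <- vapply(copy2, `[[`, character(1), "source_id")
      if (!identical(ids1, ids2)) break
    }
    # avoid an adjacent-equal clash across the join where possible
    join_p <- seg_patterns(copy1)[length(copy1)]
    if (seg_patterns(copy2)[1] == join_p) {
      alt <- which(seg_patterns(copy2) != join_p &
                     c(TRUE, seg_patterns(copy2)[-length(copy2)] !=
                         seg_patterns(copy2)[1]))[1]
      if (!is.na(alt)) {
        copy2 <- c(copy2[alt], copy2[-alt])
      }
    }
    out <- concat_segments(c(copy1, copy2), spec)
    segs <- out$truth$segments
    k <- length(uniq)
    first <- segs[seq_len(k), ]
    second <- segs[(k + 1L):(2L * k), ]
    second <- second[match(first$source_id, second$source_id), ]
    # align the two copies on the intersection of their labeled cores
    # relative to the segment content (copies are identical content, so the
    # shared core has equal length and identical ground truth in both)
    rel_start <- pmax(first$start - first$nominal_start,
                      second$start - second$nominal_start)
    rel_end <- pmin(first$end - first$nominal_start,
                    second$end - second$nominal_start)
    pairing <- data.frame(
      source_id = first$source_id,
      pattern = first$pattern,
      first_start = first$nominal_start + rel_start,
      first_end = first$nominal_start + rel_end,
      second_start = second$nominal_start + rel_start,
      second_end = second$nominal_start + rel_end,
      stringsAsFactors = FALSE
    )
    c(out, list(pairing = pairing))
  })
}

#' Select quality-control segments from a library
#'
#' Uniform random selection without replacement of the requested number of
#' segments per pattern (default: the canonical 152-segment scheme of
#' [qc_default_counts()]).
#'
#' @param library A [segment_library()].
#' @param counts_by_pattern Named integer vector (names among
#'   [rip_patterns()]).
#' @param seed Integer seed.
#' @return List of [labeled_segment()] objects, grouped by pattern.
#' @export
select_qc_segments <- function(library, counts_by_pattern = qc_default_counts(),
                               seed = NULL) {
  stopifnot(inherits(library, "segment_library"))
  assert_patterns(names(counts_by_pattern))
  pats <- vapply(library$segments, `[[`, character(1), "pattern")
  with_opt_seed(seed, {
    picked <- list()
    for (p in names(counts_by_pattern)) {
      want <- counts_by_pattern[[p]]
      if (want == 0L) next
      avail <- which(pats == p)
      if (length(avail) < want) {
        stop(sprintf("library has %d %s segments but %d requested",
                     length(avail), p, want), call. = FALSE)
      }
      take <- if (length(avail) == 1L) avail else sample(avail, want)
      picked <- c(picked, library$segments[take])
    }
    picked
  })
}

# --- run-aware concatenation --------------------------------------------
# pieces: list of list(rcg, abd, runs = data.frame(start, end, pattern,
# source_id)) where runs tile the piece with half-open 1-based sample
# intervals. Blends junctions like concat_segments and returns the combined
# record, run table (junction boundaries moved to window midpoints) and the
# nominal output extent of every piece.
concat_with_runs <- function(pieces, spec, sample_rate) {
  spec <- as_crossfade(spec)
  n_t <- spec$n_t
  k <- length(pieces)
  lens <- vapply(pieces, function(p) length(p$rcg), integer(1))
  if (any(lens < max(n_t, 1L))) {
    stop("every piece must be at least n_t samples long", call. = FALSE)
  }
  total <- sum(lens) - (k - 1L) * n_t
  offs <- cumsum(c(0L, lens[-k] - n_t))          # piece i starts at offs[i]+1
  # preallocated assembly: write each piece at its extent, blending the
  # first n_t samples with the tail of the previous piece already in place
  assemble <- function(chan) {
    out <- numeric(total)
    for (i in seq_len(k)) {
      x <- pieces[[i]][[chan]]
      idx <- (offs[i] + 1L):(offs[i] + lens[i])
      if (i > 1L && n_t > 0L) {
        w <- seq_len(n_t)
        x[w] <- (1 - spec$ramp) * out[idx[w]] + spec$ramp * x[w]
      }
      out[idx] <- x
    }
    out
  }
  sig <- list(rcg = assemble("rcg"), abd = assemble("abd"))

  run_list <- vector("list", k)
  for (i in seq_len(k)) {
    r <- pieces[[i]]$runs
    r$start <- r$start + offs[i]
    r$end <- r$end + offs[i]
    run_list[[i]] <- r
  }
  # move junction boundaries to the transition-window midpoint
  if (k > 1L && n_t > 0L) {
    for (i in 2:k) {
      mid <- offs[i] + 1L + n_t %/% 2L           # boundary sample index
      rl <- run_list[[i - 1L]]
      rl$end[nrow(rl)] <- mid
      run_list[[i - 1L]] <- rl
      rr <- run_list[[i]]
      rr$start[1] <- mid
      run_list[[i]] <- rr
    }
  }
  runs <- do.call(rbind, run_list)
  # merge adjacent runs with equal pattern and source (cosmetic)
  truth <- ground_truth(runs, n_samples = total, sample_rate = sample_rate)
  extents <- data.frame(start = offs + 1L, end = offs + lens + 1L)
  list(record = rip_record(sig$rcg, sig$abd, sample_rate = sample_rate),
       truth = truth, piece_extents = extents)
}

single_run <- function(n, pattern, source_id) {
  data.frame(start = 1L, end = n + 1L, pattern = pattern,
             source_id = source_id, stringsAsFactors = FALSE)
}

# split a run table at cut (boundary after sample `cut`) into left/right
split_runs <- function(runs, cut) {
  left <- runs[runs$start <= cut, , drop = FALSE]
  left$end[nrow(left)] <- cut + 1L
  right <- runs[runs$end > cut + 1L, , drop = FALSE]
  right$start[1] <- cut + 1L
  right$start <- right$start - cut
  right$end <- right$end - cut
  list(left = left, right = right)
}

# one insertion pass: draws cut points uniformly in region (sample indices,
# in current-record coordinates), each inside an unscored (NONE) stretch and
# clear of other cuts, then splices the shuffled segments in.
insert_pass <- function(record, truth, segments, region, spec, pass_id,
                        min_gap = 0L, max_tries = 20000L) {
  n_t <- spec$n_t
  fs <- record$sample_rate
  n <- length(record$rcg)
  k <- length(segments)
  labels <- truth$labels
  gap <- max(2L * n_t, min_gap, 1L)
  lo <- max(region[1], n_t + 1L)
  hi <- min(region[2], n - n_t - 1L)
  if (hi - lo < k * gap) {
    stop("insertion region too small for requested segments", call. = FALSE)
  }
  cuts <- integer(0)
  tries <- 0L
  while (length(cuts) < k) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place all insertions after bounded retries",
           call. = FALSE)
    }
    c0 <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    win <- max(1L, c0 - n_t):min(n, c0 + n_t)
    if (any(labels[win] != rip_none())) next
    if (length(cuts) > 0L && min(abs(cuts - c0)) < gap) next
    cuts <- c(cuts, c0)
  }
  cuts <- sort(cuts)
  order_ids <- sample.int(k)
  segs <- segments[order_ids]

  pieces <- list()
  runs <- truth$segments
  prev <- 0L
  host_sig <- record
  rest_runs <- runs
  rest_rcg <- record$rcg
  rest_abd <- record$abd
  seg_piece_idx <- integer(k)
  for (i in seq_len(k)) {
    cut_rel <- cuts[i] - prev
    sp <- split_runs(rest_runs, cut_rel)
    pieces[[length(pieces) + 1L]] <- list(
      rcg = rest_rcg[seq_len(cut_rel)], abd = rest_abd[seq_len(cut_rel)],
      runs = sp$left)
    s <- segs[[i]]
    seg_piece_idx[i] <- length(pieces) + 1L
    pieces[[length(pieces) + 1L]] <- list(
      rcg = s$rcg, abd = s$abd,
      runs = single_run(length(s$rcg), s$pattern, s$source_id))
    rest_rcg <- rest_rcg[(cut_rel + 1L):length(rest_rcg)]
    rest_abd <- rest_abd[(cut_rel + 1L):length(rest_abd)]
    rest_runs <- sp$right
    prev <- cuts[i]
  }
  pieces[[length(pieces) + 1L]] <- list(rcg = rest_rcg, abd = rest_abd,
                                        runs = rest_runs)
  out <- concat_with_runs(pieces, spec, fs)
  ext <- out$piece_extents[seg_piece_idx, , drop = FALSE]
  plan <- data.frame(
    pass = pass_id,
    position_s = (ext$start - 1L) / fs,
    source_id = vapply(segs, `[[`, character(1), "source_id"),
    pattern = vapply(segs, `[[`, character(1), "pattern"),
    length_s = vapply(segs, function(s) length(s$rcg) / fs, numeric(1)),
    nominal_start = ext$start, nominal_end = ext$end,
    stringsAsFactors = FALSE
  )
  list(record = out$record, truth = out$truth, plan = plan)
}

#' Insert quality-control segments into a long record
#'
#' Implements the quality-control pre-processing scheme: the selected
#' "true-pattern" segments are randomly ordered and inserted into the first
#' insertion region of the record at uniformly drawn times (pass 1), then
#' independently re-ordered and inserted into the last region (pass 2).
#' Each insertion splits the host record at the drawn time and splices the
#' segment in with two cross-fade transition windows, so the output length is
#' the input length plus `2 * sum(lengths) - 4 * k * n_t` for `k` segments
#' per pass. Draw times that would fall inside a previously inserted span
#' are rejected and re-drawn (bounded).
#'
#' @param record Host [rip_record()] (e.g. a long validation recording).
#' @param qc_segments List of [labeled_segment()]s, e.g. from
#'   [select_qc_segments()].
#' @param region_1,region_2 Two-element numeric vectors `c(start_s, end_s)`
#'   bounding the two insertion regions; defaults are the first and last
#'   3 hours of the final record.
#' @param spec Cross-fade spec or `n_t`.
#' @param seed Integer seed.
#' @param min_gap_s Minimum spacing between insertion times in seconds.
#' @return List with `record` (the grown [rip_record()]), `plan` (data frame
#'   `pass, position_s, source_id, pattern, length_s` plus nominal sample
#'   extents), and `truth` (a [ground_truth()] over the output record whose
#'   labels are `NONE` on host samples and the segment pattern on inserted
#'   spans).
#' @export
insert_qc_segments <- function(record, qc_segments,
                               region_1 = NULL, region_2 = NULL,
                               spec = crossfade_weights(50), seed = NULL,
                               min_gap_s = 0) {
  stopifnot(inherits(record, "rip_record"))
  spec <- as_crossfade(spec)
  fs <- record$sample_rate
  n <- length(record$rcg)
  k <- length(qc_segments)
  seg_len <- vapply(qc_segments, function(s) length(s$rcg), integer(1))
  growth <- sum(seg_len) - 2L * k * spec$n_t       # per pass, in samples
  region_samp <- function(region) {
    as.integer(round(region * fs))
  }
  with_opt_seed(seed, {
    # pass 1: spans must end inside the first region of the FINAL record;
    # pass-2 insertions happen later in the record and do not shift them
    r1 <- if (is.null(region_1)) c(0, 3 * 3600) else region_1
    r1s <- region_samp(r1)
    r1s[2] <- min(r1s[2] - growth - max(seg_len), n)
    truth0 <- ground_truth(
      data.frame(start = 1L, end = n + 1L, pattern = rip_none(),
                 source_id = "host", stringsAsFactors = FALSE),
      n_samples = n, sample_rate = fs)
    p1 <- insert_pass(record, truth0, qc_segments, r1s, spec, 1L,
                      min_gap = as.integer(round(min_gap_s * fs)))
    n1 <- length(p1$record$rcg)
    # pass 2: drawn in the grown record; shift the region start by twice the
    # pass growth so every final span sits inside the stated region of the
    # final record regardless of how much growth lands before it
    r2 <- if (is.null(region_2)) c(n1 / fs - 3 * 3600, n1 / fs) else region_2
    r2s <- region_samp(r2)
    r2s[1] <- max(r2s[1] + 2L * growth, 1L)
    r2s[2] <- min(r2s[2], n1)
    p2 <- insert_pass(p1$record, p1$truth, qc_segments, r2s, spec, 2L,
                      min_gap = as.integer(round(min_gap_s * fs)))
    # pass-1 nominal extents are unchanged by pass-2 insertions (disjoint
    # regions), so the recorded plan remains valid in final coordinates
    plan <- rbind(p1$plan, p2$plan)
    attr(plan, "n_t") <- spec$n_t
    list(record = p2$record, plan = plan, truth = p2$truth)
  })
}

#' Pair the two quality-control passes for consistency scoring
#'
#' Builds a pairing table (same shape as the evaluation-record pairing)
#' linking each segment's pass-1 and pass-2 inserted copies by source id.
#'
#' @param plan The `plan` component returned by [insert_qc_segments()].
#' @param n_t Transition-window length used at insertion time (default: read
#'   from the plan's `"n_t"` attribute).
#' @return Data frame with `source_id`, `pattern`, `first_start`,
#'   `first_end`, `second_start`, `second_end`: the sample extents of the
#'   labeled core of each copy (the inserted span minus the half transition
#'   windows absorbed by the cross-fades), equal length for the two copies.
#' @export
qc_pairing <- function(plan, n_t = attr(plan, "n_t")) {
  if (is.null(n_t)) n_t <- 0L
  h <- n_t %/% 2L
  p1 <- plan[plan$pass == 1L, ]
  p2 <- plan[plan$pass == 2L, ]
  m <- match(p1$source_id, p2$source_id)
  data.frame(source_id = p1$source_id, pattern = p1$pattern,
             first_start = p1$nominal_start + h,
             first_end = p1$nominal_end - n_t + h,
             second_start = p2$nominal_start[m] + h,
             second_end = p2$nominal_end[m] - n_t + h,
             stringsAsFactors = FALSE)
}

#' Training-session termination rule
#'
#' A training session terminates once the trainee has correctly scored
#' `quota` segments of every pattern consecutively: in the current unbroken
#' suffix of correct scores, each of the six patterns must have accumulated
#' at least `quota` correct assignments. Any scoring error resets all
#' per-pattern counters.
#'
#' @param history Data frame with columns `pattern` (codes from
#'   [rip_patterns()]) and `correct` (logical), ordered by event time.
#' @param quota Required consecutive correct count per pattern (default 5).
#' @param record_exhausted Set `TRUE` if the record ran out, which also ends
#'   the session.
#' @return Logical: is the session complete? The per-pattern counters of the
#'   current correct suffix are attached as attribute `"counters"`.
#' @export
training_complete <- function(history, quota = 5L, record_exhausted = FALSE) {
  stopifnot(is.data.frame(history),
            all(c("pattern", "correct") %in% names(history)))
  assert_patterns(history$pattern)
  counters <- stats::setNames(integer(6), rip_patterns())
  done <- FALSE
  for (i in seq_len(nrow(history))) {
    if (isTRUE(history$correct[i])) {
      p <- history$pattern[i]
      counters[p] <- counters[p] + 1L
      if (all(counters >= quota)) { done <- TRUE; break }
    } else {
      counters[] <- 0L
    }
  }
  structure(done || isTRUE(record_exhausted), counters = counters)
}
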