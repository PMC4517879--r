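mk_seg <- function(pattern, n = 120L) {
  labeled_segment(rep(0, n), rep(0, n), pattern,
                  source_id = sprintf("%s-%d", pattern, sample.int(1e6, 1)))
}

test_that("reorder separates duplicate patterns whenever possible", {
  withr::with_seed(1, {
    for (trial in 1:20) {
      segs <- list(mk_seg("SYB"), mk_seg("SYB"), mk_seg("PAU"))
      out <- reorder_no_adjacent(segs, seed = trial)
      pats <- vapply(out, `[[`, character(1), "pattern")
      expect_false(any(pats[-1] == pats[-3]))
    }
  })
})

test_that("reorder warns and returns when no conflict-free ordering exists", {
  segs <- withr::with_seed(1, list(mk_seg("SYB"), mk_seg("SYB")))
  expect_warning(out <- reorder_no_adjacent(segs, seed = 1),
                 "no conflict-free")
  expect_length(out, 2)
})

test_that("reorder is deterministic given a seed", {
  segs <- withr::with_seed(2, lapply(sample(rip_patterns(), 12, TRUE), mk_seg))
  a <- reorder_no_adjacent(segs, seed = 5)
  b <- reorder_no_adjacent(segs, seed = 5)
  expect_identical(vapply(a, `[[`, character(1), "source_id"),
                   vapply(b, `[[`, character(1), "source_id"))
})

test_that("training records respect truncation, coverage and adjacency", {
  tr <- build_training_record(seed = 11, target_s = 300, accumulate_s = 450,
                              duration_range = c(8, 20))
  dur <- record_duration(tr$record)
  expect_gte(dur, 300)       # at least the target duration
  expect_lt(dur, 300 + 20)   # less than one extra longest segment
  pats <- tr$truth$segments$pattern
  expect_setequal(unique(pats), rip_patterns())
  expect_false(any(pats[-1] == pats[-length(pats)]))
})

test_that("evaluation records duplicate every segment across halves", {
  ev <- build_evaluation_record(seed = 12, half_s = 240,
                                duration_range = c(8, 20))
  k <- nrow(ev$pairing)
  st <- ev$truth$segments
  expect_equal(nrow(st), 2L * k)
  expect_true(all(table(st$source_id) == 2))
  h1 <- st$pattern[seq_len(k)]
  h2 <- st$pattern[(k + 1L):(2L * k)]
  expect_identical(sort(h1), sort(h2))        # identical half histograms
  expect_false(identical(st$source_id[seq_len(k)],
                         st$source_id[(k + 1L):(2L * k)]))  # orders differ
  # paired copies have equal aligned lengths
  expect_equal(ev$pairing$first_end - ev$pairing$first_start,
               ev$pairing$second_end - ev$pairing$second_start)
})

test_that("a perfect scorer is perfectly consistent and accurate on an evaluation record", {
  ev <- build_evaluation_record(seed = 31, half_s = 240,
                                duration_range = c(8, 20))
  ann <- simulate_scorer(ev$truth, scorer_profile(), seed = 3)
  lab <- expand_labels(ann, 50)
  expect_equal(consistency_kappa(lab, ev$pairing)$kappa, 1)
  expect_equal(accuracy_kappa(lab, ev$truth$labels)$kappa, 1)
})

test_that("QC selection draws the requested per-pattern counts without replacement", {
  lib <- make_test_library()
  qc <- select_qc_segments(lib, seed = 3)
  expect_length(qc, 152)
  pats <- vapply(qc, `[[`, character(1), "pattern")
  got <- as.integer(table(factor(pats, rip_patterns())))
  expect_equal(got, unname(qc_default_counts()[rip_patterns()]))
  ids <- vapply(qc, `[[`, character(1), "source_id")
  expect_false(any(duplicated(ids)))
  expect_length(select_qc_segments(lib, stats::setNames(rep(0L, 6),
                                                        rip_patterns())), 0)
  expect_error(select_qc_segments(lib, c(SIH = 1000L)), "SIH")
})

test_that("QC insertion with no transition window grows the record by exactly 2L", {
  lib <- make_test_library(n_per_pattern = 3L)
  qc <- select_qc_segments(lib, stats::setNames(rep(2L, 6), rip_patterns()),
                           seed = 1)
  host <- synth_breathing(600, seed = 2)
  rec <- rip_record(host$rcg, host$abd)
  ins <- insert_qc_segments(rec, qc, region_1 = c(0, 250),
                            region_2 = c(350, 600),
                            spec = crossfade_weights(0), seed = 4)
  total_l <- sum(vapply(qc, length, integer(1)))
  expect_length(ins$record$rcg, length(rec$rcg) + 2L * total_l)
  # with n_t = 0, removing the inserted spans restores the host bit-exactly
  keep <- ins$truth$labels == rip_none()
  expect_identical(ins$record$rcg[keep], rec$rcg)
  expect_identical(ins$record$abd[keep], rec$abd)
})

test_that("QC insertion places each pass in its region with one copy per segment", {
  lib <- make_test_library(n_per_pattern = 5L)
  qc <- select_qc_segments(lib, stats::setNames(rep(3L, 6), rip_patterns()),
                           seed = 5)
  host <- synth_breathing(900, seed = 6)
  ins <- insert_qc_segments(rip_record(host$rcg, host$abd), qc,
                            region_1 = c(0, 350), region_2 = c(550, 900),
                            seed = 7)
  plan <- ins$plan
  expect_equal(sum(plan$pass == 1L), 18L)
  expect_equal(sum(plan$pass == 2L), 18L)
  expect_true(all(table(plan$source_id) == 2))
  p1 <- plan[plan$pass == 1L, ]
  p2 <- plan[plan$pass == 2L, ]
  dur <- record_duration(ins$record)
  expect_true(all(p1$position_s + p1$length_s <= 350))
  expect_true(all(p2$position_s >= dur - 350))
  # round trip: a perfect scorer on the QC truth scores kappa = 1
  ann <- simulate_scorer(ins$truth, scorer_profile(), seed = 8)
  lab <- expand_labels(ann, 50)
  expect_equal(accuracy_kappa(lab, ins$truth$labels)$kappa, 1)
  expect_equal(consistency_kappa(lab, qc_pairing(plan))$kappa, 1)
})

test_that("insertion positions are reproducible and uniform-ish over the region", {
  lib <- make_test_library(n_per_pattern = 3L)
  qc <- select_qc_segments(lib, stats::setNames(rep(1L, 6), rip_patterns()),
                           seed = 2)
  host <- synth_breathing(600, seed = 3)
  rec <- rip_record(host$rcg, host$abd)
  a <- insert_qc_segments(rec, qc, region_1 = c(0, 250),
                          region_2 = c(350, 600), seed = 11)
  b <- insert_qc_segments(rec, qc, region_1 = c(0, 250),
                          region_2 = c(350, 600), seed = 11)
  expect_identical(a$plan$position_s, b$plan$position_s)
  expect_identical(a$record$rcg, b$record$rcg)
  # uniformity sanity: pooled pass-1 positions over many seeds spread over
  # the region rather than clustering (chi-square over 4 bins)
  pos <- unlist(lapply(1:25, function(s) {
    ins <- insert_qc_segments(rec, qc, region_1 = c(0, 250),
                              region_2 = c(350, 600), seed = s)
    ins$plan$position_s[ins$plan$pass == 1L]
  }))
  counts <- table(cut(pos, breaks = seq(0, 250, length.out = 5)))
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 1e-4)
})

test_that("the training quota rule matches a reference state machine", {
  h <- data.frame(pattern = rep(rip_patterns(), each = 5), correct = TRUE)
  expect_true(training_complete(h))
  h2 <- data.frame(pattern = c(rep(rip_patterns(), each = 5)[-30], "SYB"),
                   correct = TRUE)  # only 4 UNK
  expect_false(training_complete(h2))
  h3 <- rbind(h, h)
  h3$correct[29] <- FALSE  # error resets all counters
  expect_true(training_complete(h3))       # second block completes it
  expect_false(training_complete(h3[1:35, ]))
  withr::with_seed(17, {
    for (trial in 1:50) {
      n <- sample(20:80, 1)
      hist <- data.frame(pattern = sample(rip_patterns(), n, TRUE),
                         correct = stats::runif(n) < 0.9)
      expect_equal(as.logical(training_complete(hist)),
                   oracle_training_done(hist))
    }
  })
})
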