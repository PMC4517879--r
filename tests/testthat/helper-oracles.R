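# Independent brute-force oracles, written before the implementations they
# check and kept deliberately literal (explicit loops, pairwise counting).

# Fleiss' kappa via pairwise rater agreement: P_i is the fraction of ordered
# rater pairs that agree on sample i.
oracle_fleiss <- function(mat, categories = ripkit::rip_patterns()) {
  n <- nrow(mat); m <- ncol(mat)
  p_i <- numeric(n)
  for (i in seq_len(n)) {
    agree <- 0L
    for (r in seq_len(m)) {
      for (s in seq_len(m)) {
        if (r != s && mat[i, r] == mat[i, s]) agree <- agree + 1L
      }
    }
    p_i[i] <- agree / (m * (m - 1L))
  }
  p_bar <- mean(p_i)
  p_k <- vapply(categories, function(k) sum(mat == k), numeric(1)) / (n * m)
  p_e <- sum(p_k^2)
  if (1 - p_e < .Machine$double.eps) return(1)
  (p_bar - p_e) / (1 - p_e)
}

rand_label_matrix <- function(n, m, categories = ripkit::rip_patterns()) {
  matrix(sample(categories, n * m, replace = TRUE), nrow = n)
}

# reference state machine for the consecutive-correct training quota,
# independent of training_complete()
oracle_training_done <- function(history, quota = 5L) {
  counts <- stats::setNames(integer(6), ripkit::rip_patterns())
  for (i in seq_len(nrow(history))) {
    if (history$correct[i]) {
      p <- history$pattern[i]
      counts[p] <- counts[p] + 1L
      if (all(counts >= quota)) return(TRUE)
    } else {
      counts[seq_along(counts)] <- 0L
    }
  }
  FALSE
}

# small synthetic segment library deep enough for the canonical QC counts
make_test_library <- function(n_per_pattern = 30L, seed = 99L,
                              params = ripkit::synth_params()) {
  withr::with_seed(seed, {
    segs <- list()
    for (p in ripkit::rip_patterns()) {
      lo <- if (p == "SIH") ripkit::min_sigh_duration(params) + 0.2 else 4
      for (i in seq_len(n_per_pattern)) {
        s <- ripkit::synth_segment(p, stats::runif(1, lo, 9), params,
                                   seed = NULL)
        s$source_id <- sprintf("%s-%03d", tolower(p), i)
        segs[[length(segs) + 1L]] <- s
      }
    }
    ripkit::segment_library(segs)
  })
}
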