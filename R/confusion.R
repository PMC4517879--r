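#' Consensus labels across scoring iterations
#'
#' A sample is assigned the consensus pattern it received in an absolute
#' majority of the scoring iterations — at least `floor(m / 2) + 1` of `m`
#' iterations (4 or more of 6 in the canonical design) — and `"NONE"`
#' otherwise. Unscored (`"NONE"`) votes count toward `m` but can never win.
#'
#' @param iteration_labels List of `m >= 2` equal-length label vectors.
#' @param majority Required vote count; default `floor(m / 2) + 1`.
#' @return Character consensus vector (patterns or `"NONE"`).
#' @export
consensus_labels <- function(iteration_labels, majority = NULL) {
  m <- length(iteration_labels)
  if (m < 2L) stop("need at least 2 iterations", call. = FALSE)
  n <- length(iteration_labels[[1]])
  if (any(vapply(iteration_labels, length, integer(1)) != n)) {
    stop("iteration label vectors must have equal length", call. = FALSE)
  }
  if (is.null(majority)) majority <- m %/% 2L + 1L
  mat <- do.call(cbind, lapply(iteration_labels, as.character))
  counts <- vapply(rip_patterns(), function(p) rowSums(mat == p), numeric(n))
  if (n == 1L) counts <- matrix(counts, nrow = 1L,
                                dimnames = list(NULL, rip_patterns()))
  best <- max.col(counts, ties.method = "first")
  top <- counts[cbind(seq_len(n), best)]
  out <- rep(rip_none(), n)
  win <- top >= majority
  out[win] <- rip_patterns()[best[win]]
  out
}

#' Conditional-probability confusion matrix against consensus
#'
#' For each consensus pattern `i`, the `N_i` sample-by-iteration ratings of
#' consensus-`i` samples are tallied: `N_ij` is the number of times those
#' samples were scored as pattern `j`, and `P_ij = N_ij / N_i` estimates the
#' conditional probability that a sample with consensus pattern `i` is
#' scored as `j`. Samples without a consensus pattern are excluded, as are
#' individual unscored (`"NONE"`) ratings. Rows with no consensus samples
#' are reported as undefined (`NaN`).
#'
#' @param consensus Consensus label vector (see [consensus_labels()]).
#' @param iteration_labels List of label vectors from the scoring
#'   iteration(s) under evaluation (one per iteration; a single scorer's two
#'   iterations, or all six for the group matrix).
#' @param bootstrap Number of bootstrap resamples for per-cell standard
#'   deviations (0 = skip).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `rip_confusion`: list with `p` (6 x 6 row-
#'   stochastic matrix), `n_i` (ratings counted per consensus row), `n_ij`
#'   (count matrix), and `sd` (per-cell bootstrap SD or `NULL`).
#' @export
confusion_probs <- function(consensus, iteration_labels, bootstrap = 0,
                            seed = NULL) {
  if (!is.list(iteration_labels)) iteration_labels <- list(iteration_labels)
  n <- length(consensus)
  if (any(vapply(iteration_labels, length, integer(1)) != n)) {
    stop("iteration labels must match the consensus length", call. = FALSE)
  }
  if (all(consensus == rip_none())) {
    stop("empty-analysis: no samples have a consensus pattern", call. = FALSE)
  }
  pats <- rip_patterns()
  mat <- do.call(cbind, lapply(iteration_labels, as.character))
  tally <- function(keep) {
    n_ij <- matrix(0, 6, 6, dimnames = list(pats, pats))
    for (i in seq_along(pats)) {
      rows <- keep & consensus == pats[i]
      if (!any(rows)) next
      sub <- mat[rows, , drop = FALSE]
      for (j in seq_along(pats)) n_ij[i, j] <- sum(sub == pats[j])
    }
    n_ij
  }
  n_ij <- tally(rep(TRUE, n))
  n_i <- rowSums(n_ij)
  p <- n_ij / ifelse(n_i > 0, n_i, NA)
  sd <- NULL
  if (bootstrap >= 2) {
    idx_pool <- which(consensus != rip_none())
    sd <- with_opt_seed(seed, {
      acc <- array(NA_real_, dim = c(6, 6, bootstrap))
      for (b in seq_len(bootstrap)) {
        take <- sample(idx_pool, length(idx_pool), replace = TRUE)
        cb <- consensus[take]
        mb <- mat[take, , drop = FALSE]
        nb <- matrix(0, 6, 6)
        for (i in seq_along(pats)) {
          rows <- cb == pats[i]
          if (!any(rows)) next
          sub <- mb[rows, , drop = FALSE]
          for (j in seq_along(pats)) nb[i, j] <- sum(sub == pats[j])
        }
        ni_b <- rowSums(nb)
        acc[, , b] <- nb / ifelse(ni_b > 0, ni_b, NA)
      }
      out <- apply(acc, c(1, 2), stats::sd, na.rm = TRUE)
      dimnames(out) <- list(pats, pats)
      out
    })
  }
  structure(list(p = p, n_i = n_i, n_ij = n_ij, sd = sd),
            class = "rip_confusion")
}

#' @export
print.rip_confusion <- function(x, digits = 3, ...) {
  cat("<rip_confusion> P[consensus i scored as j]\n")
  print(round(x$p, digits))
  invisible(x)
}

#' Confusion matrices after excluding short scored segments
#'
#' Recomputes the confusion matrix after excluding, for each threshold,
#' the samples that belong to scored segments shorter than that threshold.
#' Threshold 0 reproduces the unfiltered matrix exactly.
#'
#' @param consensus Consensus label vector.
#' @param annotations List of [rip_annotation()] objects, one per scoring
#'   iteration (the segment structure drives the exclusion).
#' @param thresholds_s Numeric vector of length thresholds in seconds
#'   (default `0:20`).
#' @param sample_rate Samples per second.
#' @return Named list mapping each threshold to a `rip_confusion`.
#' @export
confusion_by_length <- function(consensus, annotations, thresholds_s = 0:20,
                                sample_rate = 50) {
  if (any(thresholds_s < 0)) stop("thresholds must be >= 0", call. = FALSE)
  if (!is.list(annotations) || !all(vapply(annotations, inherits, logical(1),
                                           "rip_annotation"))) {
    stop("annotations must be a list of rip_annotation objects", call. = FALSE)
  }
  out <- lapply(thresholds_s, function(th) {
    iters <- lapply(annotations, function(ann) {
      keep <- ann$events[ann$events$end_s - ann$events$start_s >= th, ,
                         drop = FALSE]
      ann2 <- rip_annotation(keep, ann$record_length_s,
                             ann$scorer_id, ann$iteration)
      expand_labels(ann2, sample_rate)
    })
    lens <- vapply(iters, length, integer(1))
    if (any(lens != length(consensus))) {
      stop("annotation records must match the consensus length", call. = FALSE)
    }
    if (all(vapply(iters, function(v) all(v == rip_none()), logical(1)))) {
      stop("empty-analysis: all scored segments shorter than threshold",
           call. = FALSE)
    }
    confusion_probs(consensus, iters)
  })
  names(out) <- as.character(thresholds_s)
  out
}

#' Write a confusion matrix report
#'
#' Writes the 6 x 6 conditional-probability matrix with row/column headers
#' and a companion counts file (`<path>` and `<path base>_counts.csv`).
#'
#' @param cm A `rip_confusion`.
#' @param path Output CSV path for the probability matrix.
#' @return `cm`, invisibly.
#' @export
write_confusion <- function(cm, path) {
  stopifnot(inherits(cm, "rip_confusion"))
  utils::write.csv(as.data.frame(cm$p), path, row.names = TRUE)
  counts_path <- sub("(\\.csv)?$", "_counts.csv", path)
  utils::write.csv(as.data.frame(cm$n_ij), counts_path, row.names = TRUE)
  invisible(cm)
}
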