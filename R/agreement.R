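#' Fleiss' kappa for sample-wise multi-rater agreement
#'
#' Chance-corrected agreement between `m >= 2` raters classifying `n`
#' samples into nominal categories, generalizing Cohen's kappa to multiple
#' raters. With `n_ik` raters assigning sample `i` to category `k`:
#' per-sample agreement `P_i = (sum_k n_ik^2 - m) / (m (m - 1))`, observed
#' agreement `Pbar = mean(P_i)`, chance agreement `Pe = sum_k p_k^2` from
#' pooled category proportions `p_k`, and
#' `kappa = (Pbar - Pe) / (1 - Pe)`. In the degenerate case where every
#' rating is one category (`Pe = 1`, `Pbar = 1`) the function returns 1 with
#' attribute `degenerate = TRUE`.
#'
#' @param labels An `n x m` character matrix (samples x raters) of category
#'   codes; every cell must be a scoreable category (exclude unscored rows
#'   upstream, e.g. via [accuracy_kappa()]).
#' @param categories Category alphabet (default [rip_patterns()]).
#' @return Kappa in `[-1, 1]`.
#' @examples
#' m <- cbind(c("SYB", "PAU", "MVT"), c("SYB", "PAU", "MVT"))
#' fleiss_kappa(m)  # 1
#' @export
fleiss_kappa <- function(labels, categories = rip_patterns()) {
  labels <- as.matrix(labels)
  n <- nrow(labels); m <- ncol(labels)
  if (m < 2L) stop("need at least 2 raters", call. = FALSE)
  if (n < 1L) stop("need at least 1 sample", call. = FALSE)
  bad <- setdiff(unique(as.vector(labels)), categories)
  if (length(bad) > 0L) {
    stop(sprintf("labels outside the category alphabet: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  # n x K count matrix
  counts <- vapply(categories, function(k) {
    rowSums(labels == k)
  }, numeric(n))
  if (n == 1L) counts <- matrix(counts, nrow = 1L)
  p_i <- (rowSums(counts^2) - m) / (m * (m - 1))
  p_bar <- mean(p_i)
  p_k <- colSums(counts) / (n * m)
  p_e <- sum(p_k^2)
  if (1 - p_e < .Machine$double.eps) {
    return(structure(1, degenerate = TRUE))
  }
  (p_bar - p_e) / (1 - p_e)
}

#' Agreement result container
#'
#' @param kappa Kappa value in `[-1, 1]`.
#' @param sd Bootstrap standard deviation (`NA` when not computed).
#' @param n_samples Number of samples entering the comparison.
#' @return An object of class `agreement_result` with fields `kappa`, `sd`,
#'   `n_samples` and `band` (see [kappa_band()]).
#' @export
agreement_result <- function(kappa, sd = NA_real_, n_samples = NA_integer_) {
  structure(list(kappa = as.numeric(kappa), sd = sd,
                 n_samples = n_samples, band = kappa_band(as.numeric(kappa))),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("kappa = %.4f%s (%s), n = %s\n", x$kappa,
              if (is.finite(x$sd)) sprintf(" +/- %.4f", x$sd) else "",
              x$band, format(x$n_samples, big.mark = ",")))
  invisible(x)
}

# rows where every column is a scored category
scored_rows <- function(mat) {
  rowSums(mat == rip_none()) == 0L
}

two_rater_result <- function(a, b, bootstrap = 0, seed = NULL,
                             categories = rip_patterns()) {
  if (length(a) != length(b)) stop("label vectors must have equal length",
                                   call. = FALSE)
  mat <- cbind(as.character(a), as.character(b))
  mat <- mat[scored_rows(mat), , drop = FALSE]
  if (nrow(mat) == 0L) {
    stop("undefined-agreement: no samples scored by both parties",
         call. = FALSE)
  }
  k <- fleiss_kappa(mat, categories)
  sd <- if (bootstrap >= 2) {
    bootstrap_sd(mat, function(m) fleiss_kappa(m, categories),
                 n_resamples = bootstrap, seed = seed)
  } else NA_real_
  agreement_result(k, sd, nrow(mat))
}

#' Accuracy: agreement between assigned labels and the actual pattern
#'
#' Sample-wise kappa between a scorer's label vector and the ground-truth
#' label vector, restricted to samples where both are scored (neither is
#' `"NONE"`).
#'
#' @param assigned,truth Equal-length character label vectors.
#' @param bootstrap Number of bootstrap resamples for the standard
#'   deviation (0 = skip; the conventional choice is 100).
#' @param seed Integer seed for the bootstrap.
#' @return An [agreement_result()].
#' @export
accuracy_kappa <- function(assigned, truth, bootstrap = 0, seed = NULL) {
  two_rater_result(assigned, truth, bootstrap, seed)
}

#' Consistency: agreement between the two copies of each segment
#'
#' In an evaluation record every unique segment appears once in each half;
#' consistency is the sample-wise kappa between the labels a scorer assigned
#' to the first and second copies, aligned positionally (the copies are
#' identical content of equal length).
#'
#' @param labels Per-sample label vector for the whole record (e.g. from
#'   [expand_labels()]).
#' @param pairing Pairing data frame from [build_evaluation_record()] or
#'   [qc_pairing()].
#' @inheritParams accuracy_kappa
#' @return An [agreement_result()].
#' @export
consistency_kappa <- function(labels, pairing, bootstrap = 0, seed = NULL) {
  need <- c("first_start", "first_end", "second_start", "second_end")
  if (!all(need %in% names(pairing))) {
    stop("pairing must carry first/second sample extents", call. = FALSE)
  }
  n <- length(labels)
  if (max(pairing$first_end, pairing$second_end) - 1L > n) {
    stop("pairing extents exceed the label vector", call. = FALSE)
  }
  first <- character(0); second <- character(0)
  for (i in seq_len(nrow(pairing))) {
    l1 <- pairing$first_end[i] - pairing$first_start[i]
    l2 <- pairing$second_end[i] - pairing$second_start[i]
    len <- min(l1, l2)
    if (len <= 0L) next
    first <- c(first, labels[pairing$first_start[i] + 0:(len - 1L)])
    second <- c(second, labels[pairing$second_start[i] + 0:(len - 1L)])
  }
  two_rater_result(first, second, bootstrap, seed)
}

#' Intra-scorer repeatability: same scorer, two iterations
#'
#' Overall kappa between the label vectors a scorer produced on the same
#' data in two independent instances, plus per-pattern kappas computed by
#' one-vs-rest binarization (each pattern against all others pooled, then a
#' two-category kappa).
#'
#' @param iter1,iter2 Equal-length label vectors.
#' @inheritParams accuracy_kappa
#' @return List with `overall` ([agreement_result()]) and `per_pattern`
#'   (named list of [agreement_result()] or `NA` where the pattern is absent
#'   from both iterations).
#' @export
intra_scorer_kappa <- function(iter1, iter2, bootstrap = 0, seed = NULL) {
  overall <- two_rater_result(iter1, iter2, bootstrap, seed)
  per <- lapply(rip_patterns(), function(p) {
    mat <- cbind(as.character(iter1), as.character(iter2))
    mat <- mat[scored_rows(mat), , drop = FALSE]
    if (!any(mat == p)) return(NA)
    bin <- ifelse(mat == p, p, "OTHER")
    k <- fleiss_kappa(bin, categories = c(p, "OTHER"))
    sd <- if (bootstrap >= 2) {
      bootstrap_sd(bin, function(m) fleiss_kappa(m, categories = c(p, "OTHER")),
                   n_resamples = bootstrap, seed = seed)
    } else NA_real_
    agreement_result(k, sd, nrow(mat))
  })
  names(per) <- rip_patterns()
  list(overall = overall, per_pattern = per)
}

#' Inter-scorer repeatability over all iteration combinations
#'
#' Enumerates the Cartesian product of one iteration per scorer (for 3
#' scorers with 2 iterations each: 8 combinations), computes the multi-rater
#' kappa for each combination over samples scored by all parties, and
#' reports the mean and standard deviation across combinations.
#'
#' @param iterations Named list: one element per scorer, each a list of
#'   per-iteration label vectors (all of equal length).
#' @return List with `mean`, `sd`, `n_combinations`, `per_combination`
#'   (numeric vector), and `band` of the mean.
#' @export
inter_scorer_kappa <- function(iterations) {
  if (!is.list(iterations) || length(iterations) < 2L) {
    stop("need at least 2 scorers", call. = FALSE)
  }
  n_iter <- vapply(iterations, length, integer(1))
  if (any(n_iter < 1L)) stop("every scorer needs >= 1 iteration",
                             call. = FALSE)
  combos <- expand.grid(lapply(n_iter, seq_len))
  kappas <- apply(combos, 1L, function(ix) {
    mat <- do.call(cbind, Map(function(sc, i) as.character(sc[[i]]),
                              iterations, as.integer(ix)))
    mat <- mat[scored_rows(mat), , drop = FALSE]
    if (nrow(mat) == 0L) {
      stop("undefined-agreement: no samples scored by all scorers",
           call. = FALSE)
    }
    fleiss_kappa(mat)
  })
  list(mean = mean(kappas),
       sd = if (length(kappas) > 1L) stats::sd(kappas) else 0,
       n_combinations = nrow(combos),
       per_combination = as.numeric(kappas),
       band = kappa_band(mean(kappas)))
}

#' Bootstrap standard deviation of an agreement statistic
#'
#' Resamples the rows (samples) of a label matrix with replacement,
#' recomputes the statistic on each resample, and returns the standard
#' deviation across resamples. Resamples on which the statistic is
#' undefined are redrawn (bounded), after which the error propagates.
#'
#' @param labels An `n x m` label matrix.
#' @param statistic Function of a label matrix returning a scalar
#'   (default [fleiss_kappa()]).
#' @param n_resamples Number of bootstrap resamples (default 100).
#' @param seed Integer seed.
#' @return Standard deviation of the statistic across resamples.
#' @export
bootstrap_sd <- function(labels, statistic = fleiss_kappa,
                         n_resamples = 100, seed = NULL) {
  labels <- as.matrix(labels)
  if (n_resamples < 2L) stop("n_resamples must be >= 2", call. = FALSE)
  n <- nrow(labels)
  with_opt_seed(seed, {
    vals <- numeric(n_resamples)
    for (b in seq_len(n_resamples)) {
      v <- NULL
      for (try in 1:10) {
        idx <- sample.int(n, n, replace = TRUE)
        v <- tryCatch(statistic(labels[idx, , drop = FALSE]),
                      error = function(e) NULL)
        if (!is.null(v)) break
      }
      if (is.null(v)) {
        stop("statistic undefined on repeated bootstrap resamples",
             call. = FALSE)
      }
      vals[b] <- v
    }
    stats::sd(vals)
  })
}
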