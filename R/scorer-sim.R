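#' Simulated scorer profile
#'
#' Describes a synthetic human scorer for closed-loop testing of the
#' evaluation statistics: a 6 x 6 row-stochastic confusion matrix mapping
#' each true pattern to the probability of each assigned pattern, Gaussian
#' jitter applied to segment boundaries (modeling edge-placement
#' disagreement separately from category confusion), and a wall-clock rate
#' model giving the mean and spread of seconds spent per scored segment.
#'
#' @param confusion 6 x 6 row-stochastic numeric matrix (rows and columns in
#'   [rip_patterns()] order); default identity (a perfect scorer).
#' @param boundary_jitter_sd Boundary jitter standard deviation in seconds.
#' @param rate_mean,rate_sd Wall-clock seconds per scored segment.
#' @return An object of class `scorer_profile`.
#' @export
scorer_profile <- function(confusion = diag(6), boundary_jitter_sd = 0,
                           rate_mean = 4, rate_sd = 1) {
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(6L, 6L))) {
    stop("confusion must be a 6 x 6 matrix", call. = FALSE)
  }
  if (any(confusion < 0) || any(abs(rowSums(confusion) - 1) > 1e-9)) {
    stop("confusion rows must be non-negative and sum to 1", call. = FALSE)
  }
  if (boundary_jitter_sd < 0) stop("jitter must be >= 0", call. = FALSE)
  if (rate_mean <= 0) stop("rate_mean must be > 0", call. = FALSE)
  dimnames(confusion) <- list(rip_patterns(), rip_patterns())
  structure(list(confusion = confusion,
                 boundary_jitter_sd = boundary_jitter_sd,
                 rate_mean = rate_mean, rate_sd = rate_sd),
            class = "scorer_profile")
}

#' Symmetric confusion channel
#'
#' Convenience constructor: correct with probability `p_correct`, the
#' remainder spread evenly over the 5 other patterns.
#'
#' @param p_correct Diagonal probability in `[0, 1]`.
#' @return 6 x 6 row-stochastic matrix.
#' @export
symmetric_confusion <- function(p_correct) {
  stopifnot(p_correct >= 0, p_correct <= 1)
  m <- matrix((1 - p_correct) / 5, 6, 6,
              dimnames = list(rip_patterns(), rip_patterns()))
  diag(m) <- p_correct
  m
}

#' Simulate a scorer's pass over a ground-truth track
#'
#' Walks the truth segment table in record order: each segment boundary is
#' perturbed by Gaussian jitter (clamped to preserve ordering; segments
#' collapsing below one sample are dropped with a warning), each segment's
#' assigned pattern is drawn from the confusion row of its true pattern, and
#' wall-clock timestamps accumulate from the rate model. Runs whose truth is
#' `"NONE"` (unscored host data in quality-control records) receive a
#' uniform random pattern, since a scorer must score all data but those
#' samples never enter truth-restricted comparisons.
#'
#' @param truth A [ground_truth()] tiling a record.
#' @param profile A [scorer_profile()].
#' @param seed Integer seed; fixed seed gives byte-identical annotations.
#' @param scorer_id,iteration Provenance tags.
#' @return A [rip_annotation()] covering the record.
#' @export
simulate_scorer <- function(truth, profile, seed = NULL,
                            scorer_id = "sim", iteration = 1L) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(profile, "scorer_profile"))
  fs <- truth$sample_rate
  st <- truth$segments
  k <- nrow(st)
  rec_len <- length(truth$labels) / fs
  with_opt_seed(seed, {
    bounds <- c(st$start - 1L, st$end[k] - 1L) / fs  # k + 1 boundaries, seconds
    if (profile$boundary_jitter_sd > 0 && k > 1L) {
      mid <- 2:k
      bounds[mid] <- bounds[mid] +
        stats::rnorm(k - 1L, 0, profile$boundary_jitter_sd)
      bounds[1] <- 0
      bounds[k + 1L] <- rec_len
      for (i in 2:(k + 1L)) {   # clamp to preserve ordering
        bounds[i] <- min(max(bounds[i], bounds[i - 1L]), rec_len)
      }
    }
    pats <- rip_patterns()
    dropped <- 0L
    rows <- vector("list", k)
    wc <- 0
    for (i in seq_len(k)) {
      s0 <- bounds[i]; s1 <- bounds[i + 1L]
      if (s1 - s0 < 1 / fs) { dropped <- dropped + 1L; next }
      truep <- st$pattern[i]
      lab <- if (truep == rip_none()) {
        sample(pats, 1L)
      } else {
        sample(pats, 1L, prob = profile$confusion[truep, ])
      }
      wc <- wc + max(0.1, stats::rnorm(1, profile$rate_mean, profile$rate_sd))
      rows[[i]] <- data.frame(start_s = s0, end_s = s1, pattern = lab,
                              wallclock_s = wc, comment = "")
    }
    if (dropped > 0L) {
      warning(sprintf("%d segment(s) collapsed below one sample and were dropped",
                      dropped))
    }
    ev <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    rip_annotation(ev, record_length_s = rec_len,
                   scorer_id = scorer_id, iteration = iteration)
  })
}

flatten_agreement <- function(x) {
  if (inherits(x, "agreement_result")) {
    list(kappa = x$kappa, sd = x$sd, n = x$n_samples, band = x$band)
  } else x
}

#' Run a closed-loop validation experiment
#'
#' End-to-end pipeline mirroring the scorer-validation design: synthesize a
#' segment library and host records, insert two passes of quality-control
#' segments, have each simulated scorer analyze every record in two (or
#' more) independent blinded iterations, and compute the full battery of
#' evaluation statistics: per-scorer accuracy, consistency and scoring
#' rates, intra-scorer repeatability, inter-scorer repeatability over all
#' iteration combinations, and consensus-based confusion matrices per
#' scorer and for the group.
#'
#' @param config Named list (or path to a YAML file) with any of:
#'   `seed` (integer, default 1), `n_records` (default 1),
#'   `record_duration_s` (host length, default 23400 = 6.5 h),
#'   `qc_counts` (named vector, default [qc_default_counts()]),
#'   `qc_duration_range` (seconds, default `c(4, 9)`),
#'   `n_iterations` (default 2), `n_t` (transition samples, default 50),
#'   `region_1`, `region_2` (insertion regions, default first/last 3 h),
#'   `scorers` (named list of [scorer_profile()] objects; default three
#'   profiles of graded quality), `params` ([synth_params()]).
#' @param out Optional path: write the report as JSON.
#' @return Nested report list (also serializable with
#'   [jsonlite::write_json()]).
#' @export
run_validation_experiment <- function(config = list(), out = NULL) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or YAML path", call. = FALSE)
  cfg <- utils::modifyList(list(
    seed = 1L, n_records = 1L, record_duration_s = 6.5 * 3600,
    qc_counts = qc_default_counts(), qc_duration_range = c(4, 9),
    n_iterations = 2L, n_t = 50L, region_1 = NULL, region_2 = NULL,
    scorers = NULL, params = synth_params()
  ), config)
  if (is.null(cfg$scorers)) {
    cfg$scorers <- list(
      SC1 = scorer_profile(symmetric_confusion(0.95), boundary_jitter_sd = 0.2),
      SC2 = scorer_profile(symmetric_confusion(0.90), boundary_jitter_sd = 0.3),
      SC3 = scorer_profile(symmetric_confusion(0.85), boundary_jitter_sd = 0.4)
    )
  }
  for (nm in names(cfg$scorers)) {
    if (!inherits(cfg$scorers[[nm]], "scorer_profile")) {
      stop(sprintf("config field scorers$%s is not a scorer_profile", nm),
           call. = FALSE)
    }
  }
  if (cfg$n_records < 1L) stop("config field n_records must be >= 1",
                               call. = FALSE)
  spec <- crossfade_weights(cfg$n_t)
  fs <- cfg$params$sample_rate
  seed <- as.integer(cfg$seed)

  # segment library deep enough for the requested QC counts
  lib <- withr::with_seed(derive_seed(seed, 1), {
    segs <- list()
    for (p in rip_patterns()) {
      need <- cfg$qc_counts[[p]] + 5L
      lo <- cfg$qc_duration_range[1]
      hi <- cfg$qc_duration_range[2]
      if (p == "SIH") lo <- max(lo, min_sigh_duration(cfg$params) + 0.2)
      if (p == "PAU") lo <- max(lo, 2.2 / cfg$params$breath_rate + 1)
      lo <- min(lo, hi)
      for (i in seq_len(need)) {
        d <- stats::runif(1, lo, hi)
        s <- synth_segment(p, d, cfg$params, seed = NULL)
        s$source_id <- sprintf("%s-%03d", tolower(p), i)
        segs[[length(segs) + 1L]] <- s
      }
    }
    segment_library(segs)
  })
  qc <- select_qc_segments(lib, cfg$qc_counts, seed = derive_seed(seed, 2))

  scorer_names <- names(cfg$scorers)
  iters <- seq_len(cfg$n_iterations)
  # per scorer x iteration: concatenated label vectors across records
  lab <- lapply(scorer_names, function(s) lapply(iters, function(i) character(0)))
  names(lab) <- scorer_names
  truth_all <- character(0)
  pair_all <- NULL
  rates <- stats::setNames(vector("list", length(scorer_names)), scorer_names)
  offset <- 0L

  for (r in seq_len(cfg$n_records)) {
    host <- synth_breathing(cfg$record_duration_s, cfg$params,
                            seed = derive_seed(seed, 100 + r))
    host_rec <- rip_record(host$rcg, host$abd, sample_rate = fs)
    ins <- insert_qc_segments(host_rec, qc, region_1 = cfg$region_1,
                              region_2 = cfg$region_2, spec = spec,
                              seed = derive_seed(seed, 200 + r))
    truth_all <- c(truth_all, ins$truth$labels)
    # what the scorer actually sees: the host record is synchronous
    # breathing, so its full-record truth labels host runs SYB while the
    # QC-restricted truth (NONE on host) drives accuracy/consistency
    sim_runs <- ins$truth$segments
    sim_runs$pattern[sim_runs$pattern == rip_none()] <- "SYB"
    sim_truth <- ground_truth(sim_runs, length(ins$truth$labels), fs)
    pr <- qc_pairing(ins$plan)
    pr[, c("first_start", "first_end", "second_start", "second_end")] <-
      pr[, c("first_start", "first_end", "second_start", "second_end")] + offset
    pair_all <- rbind(pair_all, pr)
    for (s in scorer_names) {
      for (i in iters) {
        ann <- simulate_scorer(sim_truth, cfg$scorers[[s]],
                               seed = derive_seed(seed, 1000 * i + 10 * r +
                                                    match(s, scorer_names)),
                               scorer_id = s, iteration = i)
        lab[[s]][[i]] <- c(lab[[s]][[i]], expand_labels(ann, fs))
        if (i == 1L) {
          rates[[s]] <- c(rates[[s]], scoring_rate(ann))
        }
      }
    }
    offset <- offset + length(ins$truth$labels)
  }

  per_scorer <- lapply(scorer_names, function(s) {
    acc <- lapply(iters, function(i) accuracy_kappa(lab[[s]][[i]], truth_all))
    con <- lapply(iters, function(i) consistency_kappa(lab[[s]][[i]], pair_all))
    intra <- if (cfg$n_iterations >= 2L) {
      intra_scorer_kappa(lab[[s]][[1]], lab[[s]][[2]])
    } else NULL
    list(
      accuracy = lapply(acc, flatten_agreement),
      consistency = lapply(con, flatten_agreement),
      scoring_rate_mean = mean(unlist(rates[[s]])),
      intra_scorer = if (!is.null(intra)) {
        list(overall = flatten_agreement(intra$overall),
             per_pattern = lapply(intra$per_pattern, function(p) {
               if (identical(p, NA)) NULL else flatten_agreement(p)
             }))
      }
    )
  })
  names(per_scorer) <- scorer_names

  inter <- inter_scorer_kappa(lapply(lab, function(x) x))

  all_iters <- unlist(lab, recursive = FALSE)
  cons <- consensus_labels(all_iters)
  group_cm <- confusion_probs(cons, all_iters)
  scorer_cm <- lapply(scorer_names, function(s) {
    cm <- confusion_probs(cons, lab[[s]])
    list(p = cm$p, n_i = cm$n_i)
  })
  names(scorer_cm) <- scorer_names

  report <- list(
    design = list(n_records = cfg$n_records,
                  record_duration_s = cfg$record_duration_s,
                  qc_segments_per_pass = sum(cfg$qc_counts),
                  n_scorers = length(scorer_names),
                  n_iterations = cfg$n_iterations, seed = seed),
    per_scorer = per_scorer,
    inter_scorer = inter[c("mean", "sd", "n_combinations", "band")],
    consensus_proportion = mean(cons != rip_none()),
    group_confusion = list(p = group_cm$p, n_i = group_cm$n_i),
    per_scorer_confusion = scorer_cm
  )
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  report
}
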