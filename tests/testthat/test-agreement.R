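test_that("kappa is 1 under perfect agreement on varied samples", {
  m <- cbind(c("SYB", "PAU", "MVT", "UNK"), c("SYB", "PAU", "MVT", "UNK"))
  expect_equal(fleiss_kappa(m), 1)
})

test_that("kappa matches the hand-evaluated formula on a frozen fixture", {
  mat <- rbind(c("SYB", "SYB", "SYB"),
               c("PAU", "PAU", "UNK"),
               c("MVT", "MVT", "MVT"),
               c("SYB", "ASB", "SYB"),
               c("UNK", "UNK", "UNK"),
               c("PAU", "MVT", "PAU"))
  expect_equal(fleiss_kappa(mat), 0.568, tolerance = 1e-12)
  expect_equal(oracle_fleiss(mat), 0.568, tolerance = 1e-12)
})

test_that("kappa equals the brute-force oracle on random fixtures", {
  withr::with_seed(101, {
    for (trial in 1:300) {
      n <- sample(1:20, 1)
      m <- sample(2:4, 1)
      mat <- rand_label_matrix(n, m)
      expect_equal(as.numeric(fleiss_kappa(mat)), oracle_fleiss(mat),
                   tolerance = 1e-12)
    }
  })
})

test_that("kappa is invariant under row and column permutations", {
  withr::with_seed(7, {
    mat <- rand_label_matrix(50, 4)
    k0 <- fleiss_kappa(mat)
    expect_equal(fleiss_kappa(mat[sample(50), ]), k0, tolerance = 1e-12)
    expect_equal(fleiss_kappa(mat[, sample(4)]), k0, tolerance = 1e-12)
  })
})

test_that("independent uniform raters approach zero kappa", {
  withr::with_seed(11, {
    mat <- rand_label_matrix(20000, 2)
    expect_lt(abs(fleiss_kappa(mat)), 0.025)
  })
})

test_that("a single repeated category is degenerate with kappa 1", {
  mat <- matrix("SYB", 5, 3)
  k <- fleiss_kappa(mat)
  expect_equal(as.numeric(k), 1)
  expect_true(isTRUE(attr(k, "degenerate")))
})

test_that("accuracy kappa equals the two-rater oracle and excludes NONE", {
  withr::with_seed(21, {
    truth <- sample(rip_patterns(), 2000, TRUE)
    assigned <- truth
    flip <- truth == "PAU" & stats::runif(2000) < 0.4
    assigned[flip] <- "UNK"
    r <- accuracy_kappa(assigned, truth)
    expect_equal(r$kappa, oracle_fleiss(cbind(assigned, truth)),
                 tolerance = 1e-12)
    # NONE samples on either side are dropped before comparison
    assigned2 <- assigned
    assigned2[1:100] <- rip_none()
    r2 <- accuracy_kappa(assigned2, truth)
    expect_equal(r2$n_samples, 1900)
    expect_equal(r2$kappa,
                 oracle_fleiss(cbind(assigned[101:2000], truth[101:2000])),
                 tolerance = 1e-12)
  })
  expect_error(accuracy_kappa(c("SYB", "NONE"), c("NONE", "SYB")),
               "undefined-agreement")
})

test_that("consistency through a symmetric error channel matches the closed form", {
  withr::with_seed(31, {
    n <- 30000
    c_ok <- 0.9
    truth <- sample(rip_patterns(), n, TRUE)
    noisy <- function() {
      x <- truth
      bad <- stats::runif(n) >= c_ok
      x[bad] <- vapply(truth[bad], function(tp) {
        sample(setdiff(rip_patterns(), tp), 1)
      }, character(1))
      x
    }
    labels <- c(noisy(), noisy())
    pairing <- data.frame(source_id = "s", pattern = "SYB",
                          first_start = 1L, first_end = n + 1L,
                          second_start = n + 1L, second_end = 2L * n + 1L)
    k <- consistency_kappa(labels, pairing)$kappa
    # agreement prob: both correct or both the same wrong category
    p_agree <- c_ok^2 + (1 - c_ok)^2 / 5
    k_expected <- (p_agree - 1 / 6) / (1 - 1 / 6)
    expect_equal(k, k_expected, tolerance = 0.03)
  })
})

test_that("intra-scorer kappa reports overall and one-vs-rest per-pattern values", {
  withr::with_seed(41, {
    a <- sample(c("SYB", "PAU", "MVT"), 1500, TRUE)
    r <- intra_scorer_kappa(a, a)
    expect_equal(r$overall$kappa, 1)
    for (p in c("SYB", "PAU", "MVT")) {
      expect_equal(r$per_pattern[[p]]$kappa, 1)
    }
    expect_true(identical(r$per_pattern$SIH, NA))  # absent pattern
    # binarized kappa equals the 2-category oracle on the binarized vectors
    b <- sample(c("SYB", "PAU", "MVT"), 1500, TRUE)
    r2 <- intra_scorer_kappa(a, b)
    bin <- ifelse(cbind(a, b) == "PAU", "PAU", "OTHER")
    expect_equal(r2$per_pattern$PAU$kappa,
                 oracle_fleiss(bin, categories = c("PAU", "OTHER")),
                 tolerance = 1e-12)
  })
})

test_that("inter-scorer kappa enumerates the full iteration product", {
  withr::with_seed(51, {
    v <- sample(rip_patterns(), 500, TRUE)
    iters <- list(A = list(v, v), B = list(v, v), C = list(v, v))
    r <- inter_scorer_kappa(iters)
    expect_equal(r$n_combinations, 8L)
    expect_equal(r$mean, 1)
    expect_equal(r$sd, 0)
    r2 <- inter_scorer_kappa(list(A = list(v), B = list(v)))
    expect_equal(r2$n_combinations, 1L)
    expect_equal(r2$sd, 0)
  })
  expect_error(inter_scorer_kappa(list(list())), "2 scorers")
})

test_that("bootstrap SD is zero under perfect agreement and reproducible", {
  mat <- cbind(rep(rip_patterns(), 10), rep(rip_patterns(), 10))
  expect_equal(bootstrap_sd(mat, n_resamples = 50, seed = 1), 0)
  withr::with_seed(61, {
    noisy <- rand_label_matrix(500, 2)
    s1 <- bootstrap_sd(noisy, n_resamples = 100, seed = 9)
    s2 <- bootstrap_sd(noisy, n_resamples = 100, seed = 9)
    expect_identical(s1, s2)
    expect_gt(s1, 0)
  })
})

test_that("bootstrap SD agrees with a replicate-simulation estimate within factor 2", {
  withr::with_seed(71, {
    gen <- function() {
      truth <- sample(rip_patterns(), 1500, TRUE)
      noisy <- ifelse(stats::runif(1500) < 0.8, truth,
                      sample(rip_patterns(), 1500, TRUE))
      cbind(noisy, truth)
    }
    boot <- bootstrap_sd(gen(), n_resamples = 100, seed = 3)
    sim <- stats::sd(vapply(1:60, function(i) fleiss_kappa(gen()), numeric(1)))
    expect_gt(boot, sim / 2)
    expect_lt(boot, sim * 2)
  })
})

test_that("kappa bands classify the printed boundaries exactly", {
  expect_equal(kappa_band(-0.1), "poor")
  expect_equal(kappa_band(0), "slight")
  expect_equal(kappa_band(0.2), "slight")
  expect_equal(kappa_band(0.21), "fair")
  expect_equal(kappa_band(0.4), "fair")
  expect_equal(kappa_band(0.6), "moderate")
  expect_equal(kappa_band(0.8), "substantial")
  expect_equal(kappa_band(0.81), "almost perfect")
  expect_equal(kappa_band(1), "almost perfect")
  expect_error(kappa_band(1.2), "\\[-1, 1\\]")
})
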