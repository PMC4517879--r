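test_that("zero-phase breathing is samplewise proportional and scored SYB", {
  s <- synth_breathing(30, synth_params(phase_deg = 0, noise_sd = 0), seed = 1)
  expect_equal(s$pattern, "SYB")
  expect_equal(s$rcg, s$abd)
})

test_that("antiphase breathing is anti-correlated and scored ASB", {
  s <- synth_breathing(30, synth_params(phase_deg = 180, noise_sd = 0), seed = 1)
  expect_equal(s$pattern, "ASB")
  expect_equal(stats::cor(s$rcg, s$abd), -1, tolerance = 1e-12)
})

test_that("the 90-degree boundary is assigned to ASB", {
  expect_equal(synth_breathing(20, synth_params(phase_deg = 89.9),
                               seed = 1)$pattern, "SYB")
  expect_equal(synth_breathing(20, synth_params(phase_deg = 90),
                               seed = 1)$pattern, "ASB")
  expect_equal(synth_breathing(20, synth_params(phase_deg = 271),
                               seed = 1)$pattern, "SYB")  # folds to 89
})

test_that("measure_phase recovers analytic and generated phases", {
  t <- seq(0, 20, by = 0.02)
  expect_equal(measure_phase(sin(pi * t), sin(pi * t), 50), 0,
               tolerance = 0.5)
  expect_equal(measure_phase(sin(pi * t), sin(pi * t - pi / 2), 50), 90,
               tolerance = 2)
  for (ph in c(45, 120)) {
    s <- synth_breathing(40, synth_params(phase_deg = ph, amplitude_cv = 0.05,
                                          rate_cv = 0.05), seed = ph)
    expect_equal(measure_phase(s$rcg, s$abd, 50), ph, tolerance = 10)
  }
})

test_that("measure_phase rejects aperiodic signals", {
  m <- synth_mvt(30, seed = 3)
  expect_error(measure_phase(m$rcg, m$abd, 50), "aperiodic")
})

test_that("measure_breaths is analytic on a pure sinusoid and empty on flat", {
  t <- seq(0, 20, by = 0.02)
  b <- measure_breaths(2 * sin(2 * pi * 0.5 * t), 50)
  expect_gt(nrow(b), 5)
  expect_equal(mean(b$amplitude), 4, tolerance = 0.05)   # peak-to-trough 2A
  expect_equal(mean(b$duration_s), 2, tolerance = 0.05)  # period T
  expect_equal(nrow(measure_breaths(rep(1, 200), 50)), 0L)
})

test_that("sigh segments satisfy the 2x amplitude and duration rule in both channels", {
  for (seed in 1:50) {
    s <- synth_sigh(40, seed = seed)
    expect_equal(s$pattern, "SIH")
    for (chan in c("rcg", "abd")) {
      b <- measure_breaths(s[[chan]], s$sample_rate)
      mx <- which.max(b$amplitude)
      expect_gte(b$amplitude[mx] / mean(b$amplitude[-mx]), 2)
      expect_gte(b$duration_s[mx] / mean(b$duration_s[-mx]), 2)
    }
  }
})

test_that("an exactly-2x sigh yields a ratio of 2 without noise or jitter", {
  p <- synth_params(noise_sd = 0, amplitude_cv = 0, rate_cv = 0, phase_deg = 0)
  s <- synth_sigh(40, p, amp_gain = 2, dur_gain = 2, seed = 1)
  b <- measure_breaths(s$rcg, 50)
  mx <- which.max(b$amplitude)
  expect_equal(b$amplitude[mx] / mean(b$amplitude[-mx]), 2, tolerance = 0.02)
})

test_that("pause segments keep both channels under 10% of the preceding breath", {
  # band-limit to the respiratory band before measuring excursions, as the
  # scoring rule concerns breathing movements, not the broadband noise floor
  smooth <- function(x) {
    y <- as.numeric(stats::filter(x, rep(1 / 15, 15), sides = 2))
    y[is.na(y)] <- x[is.na(y)]  # keep edges
    y
  }
  for (seed in 1:50) {
    s <- synth_pause(30, pause_s = 3, seed = seed)
    expect_equal(s$pattern, "PAU")
    # trim the smoothing half-width so boundary samples mixed with the
    # preceding/following breaths do not enter the excursion
    win <- (s$meta$pause_samples[1] + 8L):(s$meta$pause_samples[2] - 8L)
    for (chan in c("rcg", "abd")) {
      xs <- smooth(s[[chan]])
      b <- measure_breaths(xs[seq_len(s$meta$pause_samples[1] - 1L)],
                           s$sample_rate)
      ref <- b$amplitude[nrow(b)]
      exc <- max(xs[win], na.rm = TRUE) - min(xs[win], na.rm = TRUE)
      expect_lt(exc / ref, 0.10)
    }
  }
})

test_that("a 2-second pause at 50 Hz spans exactly 100 samples", {
  s <- synth_pause(30, pause_s = 2.0, seed = 5)
  expect_equal(diff(s$meta$pause_samples) + 1L, 100L)
})

test_that("a zero-gain pause flatlines at baseline with only the noise floor", {
  p <- synth_params(noise_sd = 0.01)
  s <- synth_pause(30, pause_s = 3, params = p, pause_gain = 0, seed = 2)
  win <- s$meta$pause_samples[1]:s$meta$pause_samples[2]
  expect_lt(max(s$rcg[win]) - min(s$rcg[win]), 8 * p$noise_sd)
})

test_that("movement artifact is dominated by sub-breathing-band power", {
  for (seed in 1:50) {
    m <- synth_mvt(30, seed = seed)
    expect_equal(m$pattern, "MVT")
    expect_gt(low_freq_ratio(m$rcg, 50), 1)
    expect_gt(low_freq_ratio(m$abd, 50), 1)
  }
  # breathing, by contrast, concentrates power at the breathing frequency
  s <- synth_breathing(30, seed = 1)
  expect_lt(low_freq_ratio(s$rcg, 50), 1)
})

test_that("discordant unknown segments disagree across channels", {
  for (seed in 1:10) {
    u <- synth_unk(30, mode = "discordant", seed = seed)
    expect_equal(u$pattern, "UNK")
    expect_gt(low_freq_ratio(u$rcg, 50), 1)   # movement-like ribcage
    expect_lt(low_freq_ratio(u$abd, 50), 1)   # breathing abdomen
  }
})

test_that("flat-line unknown without noise has one constant channel", {
  u <- synth_unk(30, synth_params(noise_sd = 0), mode = "flatline", seed = 1)
  expect_equal(stats::sd(u$rcg), 0)
  expect_gt(stats::sd(u$abd), 0)
})

test_that("generators are deterministic given a seed", {
  for (pat in rip_patterns()) {
    a <- synth_segment(pat, 20, seed = 7)
    b <- synth_segment(pat, 20, seed = 7)
    expect_identical(a$rcg, b$rcg)
    expect_identical(a$abd, b$abd)
    expect_equal(a$pattern, pat)
  }
})

test_that("generator preconditions reject too-short durations", {
  expect_error(synth_breathing(1, synth_params()), "breath cycles")
  expect_error(synth_pause(5, pause_s = 4), "pause_s")
  expect_error(synth_mvt(1), ">= 2 s")
})
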