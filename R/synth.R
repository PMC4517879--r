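#' Parameters for synthetic RIP pattern generation
#'
#' Breathing is synthesized breath-by-breath as a quasi-sinusoid: each breath
#' draws its period and peak-to-trough amplitude from log-normal
#' distributions around the nominal rate and amplitude (coefficients of
#' variation `rate_cv`, `amplitude_cv`), the abdomen channel lags the ribcage
#' by `phase_deg`, and additive Gaussian sensor noise of standard deviation
#' `noise_sd` is superimposed. Defaults emulate quiet infant breathing:
#' 45 breaths/min (0.75 Hz), unit amplitude, a small thoraco-abdominal phase
#' lag, and 5% breath-to-breath variability.
#'
#' @param breath_rate Nominal breathing frequency in Hz.
#' @param breath_amplitude Nominal peak-to-trough excursion, arbitrary units.
#' @param phase_deg Ribcage-abdomen phase difference in degrees, `[0, 360)`.
#' @param amplitude_cv,rate_cv Breath-to-breath coefficients of variation.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param sample_rate Samples per second.
#' @param seed Default integer seed for generators using these parameters.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(breath_rate = 0.75, breath_amplitude = 1,
                         phase_deg = 20, amplitude_cv = 0.05, rate_cv = 0.05,
                         noise_sd = 0.02, sample_rate = 50, seed = NULL) {
  if (breath_rate <= 0) stop("breath_rate must be > 0", call. = FALSE)
  if (phase_deg < 0 || phase_deg >= 360) {
    stop("phase_deg must lie in [0, 360)", call. = FALSE)
  }
  if (amplitude_cv < 0 || rate_cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(breath_rate = breath_rate, breath_amplitude = breath_amplitude,
         phase_deg = phase_deg, amplitude_cv = amplitude_cv,
         rate_cv = rate_cv, noise_sd = noise_sd,
         sample_rate = sample_rate, seed = seed),
    class = "synth_params"
  )
}

# run expr under a fixed seed when one is supplied, else in the ambient RNG
with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# log-normal multiplier with unit median and coefficient of variation cv
ln_jitter <- function(k, cv) {
  if (cv <= 0) return(rep(1, k))
  exp(stats::rnorm(k, 0, sqrt(log(1 + cv^2))))
}

# phase folded to [0, 180] degrees
fold_phase <- function(phase_deg) {
  p <- phase_deg %% 360
  if (p > 180) p <- 360 - p
  p
}

# Core breath-by-breath waveform engine. Returns per-channel samples for a
# piecewise-linear phase built from per-breath periods/amplitudes; inspiration
# starts at each breath onset (trough), so waveform is -cos(2*pi*frac).
# periods, amps: per-breath vectors; t: sample times from 0.
breath_wave <- function(t, periods, amps, phase_frac = 0) {
  onsets <- c(0, cumsum(periods))
  k <- findInterval(t, onsets, rightmost.closed = FALSE)
  k[k < 1L] <- 1L
  k[k > length(periods)] <- length(periods)
  frac <- (t - onsets[k]) / periods[k]
  amps[k] / 2 * (-cos(2 * pi * (frac - phase_frac)))
}

# draw enough breaths to cover duration_s with margin
draw_breaths <- function(duration_s, params) {
  t_breath <- 1 / params$breath_rate
  k <- ceiling(duration_s / t_breath * (1 + 6 * params$rate_cv)) + 4L
  periods <- t_breath * ln_jitter(k, params$rate_cv)
  amps <- params$breath_amplitude * ln_jitter(k, params$amplitude_cv)
  list(periods = periods, amps = amps)
}

#' Synthesize a quasi-sinusoidal breathing segment
#'
#' Generates synchronous (`SYB`) or asynchronous (`ASB`) breathing depending
#' on the requested ribcage-abdomen phase: folded to `[0, 180]` degrees, a
#' phase below 90 is scored synchronous and 90 or more asynchronous.
#'
#' @param duration_s Segment duration in seconds; must fit at least two
#'   breath cycles at `params$breath_rate`.
#' @param params A [synth_params()] object.
#' @param seed Integer seed; overrides `params$seed` when given.
#' @return A [labeled_segment()] with pattern `SYB` or `ASB`.
#' @examples
#' seg <- synth_breathing(30, synth_params(phase_deg = 0, noise_sd = 0), seed = 1)
#' seg$pattern
#' @export
synth_breathing <- function(duration_s, params = synth_params(),
                            seed = params$seed) {
  check_min_cycles(duration_s, params, 2)
  fs <- params$sample_rate
  n <- round(duration_s * fs)
  with_opt_seed(seed, {
    br <- draw_breaths(duration_s, params)
    t <- (seq_len(n) - 1L) / fs
    delta <- params$phase_deg / 360
    rcg <- breath_wave(t, br$periods, br$amps) +
      stats::rnorm(n, 0, params$noise_sd)
    abd <- breath_wave(t, br$periods, br$amps, phase_frac = delta) +
      stats::rnorm(n, 0, params$noise_sd)
    pat <- if (fold_phase(params$phase_deg) < 90) "SYB" else "ASB"
    labeled_segment(rcg, abd, pat, sample_rate = fs,
                    meta = list(phase_deg = params$phase_deg))
  })
}

check_min_cycles <- function(duration_s, params, n_cycles) {
  if (!is.numeric(duration_s) || duration_s <= 0 ||
      duration_s * params$breath_rate < n_cycles) {
    stop(sprintf("duration_s must allow >= %g breath cycles at %g Hz",
                 n_cycles, params$breath_rate), call. = FALSE)
  }
}

#' Synthesize a sigh segment
#'
#' Embeds a single sigh breath into baseline breathing: the sigh has
#' `amp_gain` times the amplitude and `dur_gain` times the duration of the
#' surrounding mean breath, in both channels. Gains default above the scoring
#' threshold of 2 so that jitter and noise cannot drag the realized ratio
#' under it.
#'
#' @inheritParams synth_breathing
#' @param amp_gain,dur_gain Sigh amplitude and duration multipliers (>= 2
#'   for a scoreable sigh).
#' @return A [labeled_segment()] with pattern `SIH`; `meta$sigh_onset_s` and
#'   `meta$sigh_end_s` delimit the sigh breath.
#' @export
synth_sigh <- function(duration_s, params = synth_params(),
                       amp_gain = 2.3, dur_gain = 2.3, seed = params$seed) {
  check_min_cycles(duration_s, params, 3 + dur_gain)
  fs <- params$sample_rate
  n <- round(duration_s * fs)
  with_opt_seed(seed, {
    br <- draw_breaths(duration_s, params)
    # sigh breath = the one whose onset is nearest the segment midpoint
    onsets <- c(0, cumsum(br$periods))
    m <- which.min(abs(onsets[seq_along(br$periods)] - duration_s / 2))
    m <- max(2L, min(m, length(br$periods) - 2L))
    # gains apply to the nominal (epoch-average) breath, not the jittered
    # draw, so the realized ratio sits at the requested multiple
    br$periods[m] <- dur_gain / params$breath_rate
    br$amps[m] <- amp_gain * params$breath_amplitude
    onsets <- c(0, cumsum(br$periods))
    t <- (seq_len(n) - 1L) / fs
    delta <- params$phase_deg / 360
    rcg <- breath_wave(t, br$periods, br$amps) +
      stats::rnorm(n, 0, params$noise_sd)
    abd <- breath_wave(t, br$periods, br$amps, phase_frac = delta) +
      stats::rnorm(n, 0, params$noise_sd)
    labeled_segment(rcg, abd, "SIH", sample_rate = fs,
                    meta = list(sigh_onset_s = onsets[m],
                                sigh_end_s = onsets[m + 1L],
                                amp_gain = amp_gain, dur_gain = dur_gain))
  })
}

#' Synthesize a respiratory pause segment
#'
#' Breathing is interrupted by a contiguous window of `pause_s` seconds in
#' which both channels' peak-to-trough excursion is `pause_gain` times the
#' preceding breath's (default 5%, under the 10% scoring threshold), after
#' which breathing resumes. The pause begins and ends at a start of
#' inspiration. Respiratory pauses are scoreable regardless of duration.
#'
#' @inheritParams synth_breathing
#' @param pause_s Pause duration in seconds; must satisfy
#'   `0 < pause_s < duration_s - 2` breath periods.
#' @param pause_gain Residual excursion during the pause as a fraction of the
#'   preceding breath amplitude (< 0.10 for a scoreable pause).
#' @return A [labeled_segment()] with pattern `PAU`; `meta$pause_start_s`,
#'   `meta$pause_end_s` and `meta$pause_samples` delimit the pause window.
#' @export
synth_pause <- function(duration_s, pause_s, params = synth_params(),
                        pause_gain = 0.05, seed = params$seed) {
  t_breath <- 1 / params$breath_rate
  if (!is.numeric(pause_s) || pause_s <= 0 ||
      pause_s >= duration_s - 2 * t_breath) {
    stop("pause_s must satisfy 0 < pause_s < duration_s - 2 breath periods",
         call. = FALSE)
  }
  fs <- params$sample_rate
  n <- round(duration_s * fs)
  with_opt_seed(seed, {
    pre <- draw_breaths(duration_s, params)
    onsets <- c(0, cumsum(pre$periods))
    # pause starts at the inspiration onset nearest the centre of the
    # breathing time available around the pause
    target <- (duration_s - pause_s) / 2
    j <- which.min(abs(onsets - target))
    j <- max(2L, j)
    pause_start <- onsets[j]
    i1 <- floor(pause_start * fs + 1e-9) + 1L   # first pause sample
    np <- round(pause_s * fs)                    # pause length in samples
    i2 <- i1 + np - 1L
    t <- (seq_len(n) - 1L) / fs
    delta <- params$phase_deg / 360
    a_prev <- pre$amps[j - 1L]

    mk_channel <- function(phase_frac) {
      x <- numeric(n)
      pre_idx <- seq_len(i1 - 1L)
      x[pre_idx] <- breath_wave(t[pre_idx], pre$periods[seq_len(j - 1L)],
                                pre$amps[seq_len(j - 1L)], phase_frac)
      pau_idx <- i1:i2
      # the band signal holds near the end-expiratory (trough) level during
      # a pause, with a small residual oscillation; this keeps the waveform
      # continuous at the pause onset (which is a start of inspiration)
      x[pau_idx] <- -a_prev / 2 + pause_gain * a_prev / 2 *
        (1 - cos(2 * pi * ((t[pau_idx] - pause_start) / t_breath - phase_frac)))
      if (i2 < n) {
        post_idx <- (i2 + 1L):n
        post <- draw_breaths(duration_s, params)
        pause_end <- i2 / fs
        x[post_idx] <- breath_wave(t[post_idx] - pause_end,
                                   post$periods, post$amps, phase_frac)
      }
      x + stats::rnorm(n, 0, params$noise_sd)
    }
    rcg <- mk_channel(0)
    abd <- mk_channel(delta)
    labeled_segment(rcg, abd, "PAU", sample_rate = fs,
                    meta = list(pause_start_s = pause_start,
                                pause_end_s = pause_start + pause_s,
                                pause_samples = c(i1, i2),
                                pause_gain = pause_gain))
  })
}

#' Synthesize a movement-artifact segment
#'
#' Both channels are dominated by irregular, non-sinusoidal, low-frequency
#' motion: a Gaussian random walk low-pass filtered below the breathing band
#' (Butterworth, default cutoff 0.4 Hz) and scaled to breathing-comparable
#' amplitude.
#'
#' @inheritParams synth_breathing
#' @param cutoff_hz Low-pass cutoff of the motion band in Hz.
#' @return A [labeled_segment()] with pattern `MVT`.
#' @export
synth_mvt <- function(duration_s, params = synth_params(), cutoff_hz = 0.4,
                      seed = params$seed) {
  if (!is.numeric(duration_s) || duration_s < 2) {
    stop("duration_s must be >= 2 s", call. = FALSE)
  }
  fs <- params$sample_rate
  n <- round(duration_s * fs)
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  with_opt_seed(seed, {
    mk <- function() {
      w <- cumsum(stats::rnorm(n))
      x <- signal::filtfilt(bf, w - mean(w))
      x <- x / max(stats::sd(x), .Machine$double.eps) * params$breath_amplitude
      x + stats::rnorm(n, 0, params$noise_sd)
    }
    labeled_segment(mk(), mk(), "MVT", sample_rate = fs,
                    meta = list(cutoff_hz = cutoff_hz))
  })
}

#' Synthesize an unknown-pattern segment
#'
#' The unknown category covers signals matching no other pattern. Two motifs
#' are provided: `"discordant"`, where the ribcage shows movement-artifact
#' motion while the abdomen breathes quasi-sinusoidally (the two channels
#' disagree), and `"flatline"`, a technical fault where the ribcage is flat
#' (optionally with step artifacts from connector loss) while the abdomen
#' breathes.
#'
#' @inheritParams synth_breathing
#' @param mode `"discordant"` or `"flatline"`.
#' @param n_steps Number of step artifacts in flatline mode.
#' @param step_amplitude Step height in arbitrary units.
#' @return A [labeled_segment()] with pattern `UNK`.
#' @export
synth_unk <- function(duration_s, params = synth_params(),
                      mode = c("discordant", "flatline"),
                      n_steps = 0, step_amplitude = 1, seed = params$seed) {
  mode <- match.arg(mode)
  check_min_cycles(duration_s, params, 2)
  fs <- params$sample_rate
  n <- round(duration_s * fs)
  with_opt_seed(seed, {
    breath <- synth_breathing(duration_s, params, seed = NULL)
    if (mode == "discordant") {
      mvt <- synth_mvt(duration_s, params, seed = NULL)
      rcg <- mvt$rcg
    } else {
      rcg <- rep(0, n)
      if (n_steps > 0) {
        at <- sort(sample.int(n - 1L, n_steps))
        for (i in at) {
          rcg[(i + 1L):n] <- rcg[(i + 1L):n] +
            step_amplitude * sample(c(-1, 1), 1)
        }
      }
      rcg <- rcg + stats::rnorm(n, 0, params$noise_sd)
    }
    labeled_segment(rcg, breath$abd, "UNK", sample_rate = fs,
                    meta = list(mode = mode))
  })
}

#' Synthesize a segment of a requested pattern
#'
#' Dispatcher over the pattern-specific generators, used by record builders
#' and the command line. Synchronous/asynchronous breathing are produced by
#' overriding `params$phase_deg` with a draw from the corresponding phase
#' range (SYB: 0-70 degrees; ASB: 110-250 degrees, folded).
#'
#' @param pattern One of [rip_patterns()].
#' @inheritParams synth_breathing
#' @param ... Passed to the pattern-specific generator.
#' @return A [labeled_segment()].
#' @export
synth_segment <- function(pattern, duration_s, params = synth_params(),
                          seed = params$seed, ...) {
  assert_patterns(pattern)
  with_opt_seed(seed, {
    switch(pattern,
      SYB = {
        p <- params; p$phase_deg <- stats::runif(1, 0, 70)
        synth_breathing(duration_s, p, seed = NULL)
      },
      ASB = {
        p <- params; p$phase_deg <- stats::runif(1, 110, 250)
        synth_breathing(duration_s, p, seed = NULL)
      },
      SIH = synth_sigh(duration_s, params, seed = NULL, ...),
      PAU = {
        avail <- duration_s - 2.2 / params$breath_rate
        if (avail <= 0.5) {
          stop("duration_s too short for a pause segment", call. = FALSE)
        }
        synth_pause(duration_s,
                    pause_s = stats::runif(1, min(1, 0.4 * avail),
                                           min(10, 0.8 * avail)),
                    params, seed = NULL, ...)
      },
      MVT = synth_mvt(duration_s, params, seed = NULL, ...),
      UNK = synth_unk(duration_s, params, seed = NULL,
                      mode = sample(c("discordant", "flatline"), 1), ...)
    )
  })
}

#' Shortest duration that can host a sigh segment
#'
#' A sigh needs the sigh breath plus surrounding baseline breaths, i.e.
#' `3 + dur_gain` breath cycles at the nominal rate.
#'
#' @inheritParams synth_sigh
#' @return Duration in seconds.
#' @export
min_sigh_duration <- function(params = synth_params(), dur_gain = 2.3) {
  (3 + dur_gain) / params$breath_rate
}

#' Measure the ribcage-abdomen phase of a breathing segment
#'
#' Estimates the phase magnitude between the two channels at the dominant
#' respiratory frequency from the cross-spectrum, folded to `[0, 180]`
#' degrees. During breathing the ribcage-versus-abdomen Lissajous ellipse
#' tilts right below 90 degrees and left above.
#'
#' @param rcg,abd Numeric vectors of equal length covering at least two
#'   breath cycles.
#' @param sample_rate Samples per second.
#' @return Phase in degrees, in `[0, 180]`.
#' @export
measure_phase <- function(rcg, abd, sample_rate) {
  if (length(rcg) != length(abd)) {
    stop("rcg and abd must have equal length", call. = FALSE)
  }
  n <- length(rcg)
  if (n < 8L) stop("series too short for phase estimation", call. = FALSE)
  x <- rcg - mean(rcg)
  y <- abd - mean(abd)
  if (!is_periodic(x) && !is_periodic(y)) {
    stop("signals-aperiodic: no dominant respiratory periodicity",
         call. = FALSE)
  }
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
  fx <- stats::fft(x * w)
  fy <- stats::fft(y * w)
  half <- 2:floor(n / 2)
  pow <- Mod(fx[half])^2 + Mod(fy[half])^2
  pk <- which.max(pow)
  bins <- pk + (-2:2)
  bins <- bins[bins >= 1 & bins <= length(half)]
  cross <- sum(fx[half][bins] * Conj(fy[half][bins]))
  fold_phase(Arg(cross) * 180 / pi)
}

# periodicity gate: normalized autocorrelation has a secondary peak >= 0.3
is_periodic <- function(x, min_peak = 0.3) {
  n <- length(x)
  a <- stats::acf(x, lag.max = min(n - 2L, 2000L), plot = FALSE,
                  demean = TRUE)$acf[, 1, 1]
  # first zero crossing, then look for a local max beyond it
  zc <- which(a < 0)[1]
  if (is.na(zc) || zc >= length(a) - 1L) return(FALSE)
  tail_a <- a[(zc + 1L):length(a)]
  max(tail_a) >= min_peak
}

#' Detect breaths and measure their amplitude and duration
#'
#' Segments a respiratory channel into breaths: inspiration onsets are the
#' troughs preceding each rising crossing of the centered signal (with
#' hysteresis against noise), breath duration is onset-to-onset, and breath
#' amplitude is the peak-to-trough excursion within the breath.
#'
#' @param x Numeric respiratory signal.
#' @param sample_rate Samples per second.
#' @return A data frame with one row per detected breath and columns
#'   `onset_s`, `duration_s`, `amplitude`. Zero rows when no breaths are
#'   detected (e.g. a flat signal).
#' @export
measure_breaths <- function(x, sample_rate) {
  empty <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      amplitude = numeric(0))
  n <- length(x)
  if (n < 4L) return(empty)
  xc <- x - stats::median(x)
  rng <- max(xc) - min(xc)
  if (rng <= .Machine$double.eps) return(empty)
  h <- 0.2 * rng / 2
  # hysteresis state machine: record an upward event each time the signal
  # rises above +h after having been below -h
  below <- xc < -h
  above <- xc > h
  state <- 0L  # 1 after being below -h
  ups <- integer(0)
  for (i in seq_len(n)) {
    if (below[i]) state <- 1L
    else if (above[i] && state == 1L) { ups <- c(ups, i); state <- 0L }
  }
  if (length(ups) < 2L) return(empty)
  # inspiration onset = trough between consecutive upward events
  onsets <- integer(length(ups) - 1L)
  for (k in seq_len(length(ups) - 1L)) {
    seg <- ups[k]:ups[k + 1L]
    onsets[k] <- seg[which.min(xc[seg])]
  }
  # prepend the trough before the first upward event
  first_tr <- which.min(xc[1:ups[1]])
  onsets <- unique(c(first_tr, onsets))
  if (length(onsets) < 2L) return(empty)
  res <- lapply(seq_len(length(onsets) - 1L), function(k) {
    idx <- onsets[k]:(onsets[k + 1L] - 1L)
    data.frame(onset_s = (onsets[k] - 1L) / sample_rate,
               duration_s = length(idx) / sample_rate,
               amplitude = max(x[idx]) - min(x[idx]))
  })
  do.call(rbind, res)
}

#' Spectral dominance of sub-breathing-band motion
#'
#' Ratio of periodogram power below `cutoff_hz` to power in a narrow band
#' around the nominal breathing frequency; above 1 the segment is dominated
#' by low-frequency (movement-like) content. Used as the oracle for the
#' movement-artifact and discordant-unknown generators.
#'
#' @param x Numeric signal.
#' @param sample_rate Samples per second.
#' @param breath_rate Nominal breathing frequency in Hz.
#' @param cutoff_hz Upper edge of the motion band in Hz.
#' @return Positive scalar power ratio.
#' @export
low_freq_ratio <- function(x, sample_rate, breath_rate = 0.75,
                           cutoff_hz = 0.4) {
  n <- length(x)
  xc <- x - mean(x)
  sp <- Mod(stats::fft(xc))^2
  freqs <- (seq_len(n) - 1L) / n * sample_rate
  half <- 2:floor(n / 2)
  f <- freqs[half]; p <- sp[half]
  low <- sum(p[f < cutoff_hz])
  band <- p[f >= breath_rate * 0.8 & f <= breath_rate * 1.2]
  if (length(band) == 0L || sum(band) == 0) return(Inf)
  low / sum(band)
}
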