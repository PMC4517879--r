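---
title: "Simulating and evaluating manual scoring of infant RIP signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and evaluating manual scoring of infant RIP signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripkit)
```

## The problem

Respiratory inductive plethysmography (RIP) measures infant breathing with
two elastic bands, one around the ribcage (RCG) and one around the abdomen
(ABD). Scoring such recordings by hand — assigning every sample to one of
six mutually exclusive patterns (SYB, ASB, SIH, PAU, MVT, UNK) — is the
reference analysis for studies of postoperative apnea, but it is only as
good as the scorers are repeatable. `ripkit` implements the computational
core of a scorer training and monitoring workflow: synthetic records with
known ground truth, smooth segment concatenation, quality-control
insertion, simulated scorers, and the full battery of agreement statistics.

Everything in the package is driven by explicit integer seeds, and every
generator is paired with a measurement oracle so that the scoring rule each
pattern must satisfy can be verified on the generated signal itself.

## Signal model

Breathing is synthesized breath by breath. Each breath $k$ draws a period
$T_k$ and a peak-to-trough amplitude $A_k$ from log-normal distributions
around the nominal rate and amplitude with coefficients of variation
`rate_cv` and `amplitude_cv`; the waveform within a breath is
$-\cos$ of the accumulated phase, so every breath starts at its trough
(start of inspiration) and the per-breath amplitude steps occur where the
signal is continuous. The abdomen channel lags the ribcage by a constant
phase `phase_deg`; additive Gaussian noise of standard deviation `noise_sd`
models the sensor floor.

Defaults are chosen for quiet infant breathing and are deliberately plain:
45 breaths/min (0.75 Hz), unit amplitude, a 20° thoraco-abdominal lag, 5%
breath-to-breath variability, noise at 2% of amplitude, and 50 Hz sampling.
The breathing-rate and amplitude distributions of real infant data are not
prescribed anywhere in the scoring rules, so these are parameters, not
constants; all scoring rules in the package are *ratio* rules (10% of the
preceding breath, 2× the epoch average, phase relative to 90°) and are
insensitive to the absolute scale.

Pattern-specific constructions:

- **SYB/ASB** — the phase, folded to $[0, 180]°$, decides the label; the
  90° boundary goes to ASB because the asynchrony rule is "90° or more".
  The generic `synth_segment()` dispatcher draws SYB phases from 0–70° and
  ASB from 110–250° so that labels remain unambiguous under the ±10°
  accuracy of the cross-spectral phase oracle.
- **SIH** — one breath receives `amp_gain` (default 2.3) times the nominal
  amplitude and `dur_gain` times the nominal duration. The gains apply to
  the *nominal* breath rather than the jittered draw so the realized ratio
  against the epoch mean sits at the requested multiple; defaults slightly
  above 2 keep the measured ratio above the scoring threshold in the
  presence of jitter and noise.
- **PAU** — the pause starts and ends at a start of inspiration, and the
  signal holds near the end-expiratory (trough) level with a residual
  oscillation of `pause_gain` (default 5%) of the preceding breath's
  excursion. Holding the trough keeps the waveform continuous at the pause
  onset; a zero-centered residual would produce a step the size of half a
  breath. Pauses are scoreable regardless of duration.
- **MVT** — a Gaussian random walk low-pass filtered below the breathing
  band (4th-order Butterworth, cutoff 0.4 Hz) and rescaled to
  breathing-comparable amplitude: chaotic, non-sinusoidal, low-frequency.
- **UNK** — either discordant channels (movement-like RCG over a breathing
  ABD) or a technical-fault flat-line with optional step artifacts.

The oracles: `measure_phase()` gates on autocorrelation periodicity and
then reads the phase of the power-weighted cross-spectrum around the
dominant respiratory bin; `measure_breaths()` segments a channel into
breaths at the troughs preceding hysteresis-protected rising crossings and
reports peak-to-trough amplitudes and onset-to-onset durations;
`low_freq_ratio()` compares periodogram power below 0.4 Hz to the power in
a ±20% band around the breathing frequency.

## Concatenation

Segments are joined over a transition window of $N_T$ samples: the
outgoing segment is multiplied by a decaying sigmoid, the incoming by the
complementary rising sigmoid, and the two are summed. The ramp is a
half-period raised cosine, $0.5 - 0.5\cos(\pi k/(N_T-1))$, which is
sigmoid-shaped and hits 0 and 1 *exactly* at the window edges — that
guarantees bit-exact equality with the inputs outside the window, which the
tests rely on. A logistic ramp (rescaled to exact endpoints) is available
behind `shape = "logistic"`. The default $N_T$ is 50 samples (1 s at
50 Hz): long enough to suppress splice transients, shorter than any
scoreable segment it must preserve. A window of one sample cannot satisfy
both endpoint constraints; it is defined to take the incoming sample.

Inside a transition window, ground-truth labels are split at the window
midpoint — the first half keeps the outgoing segment's pattern, the second
half takes the incoming segment's. Only segment boundaries are stored by
the scoring workflow, so some convention is required; the midpoint is the
symmetric choice. Consequences ripple into consistency scoring: the two
copies of a segment in an evaluation record are aligned on the intersection
of their labeled cores (the content minus the half-windows absorbed by the
cross-fades), which is what makes a perfect scorer's consistency exactly 1.

## Records

**Training records** accumulate segments of each pattern in rotation until
1.5 h of material exists, shuffle them, repair adjacent equal patterns by
pushing the second segment to the end, and keep the shortest prefix whose
*concatenated* length (transition overlaps deducted) reaches 1 h — so the
record is always at least an hour and less than one segment longer. The
push-to-end repair is not guaranteed to converge (consider all segments
sharing a pattern), so it is bounded at three passes followed by a greedy
re-insertion step; if conflicts still remain a warning is raised and the
minimal-conflict arrangement returned. Segment durations are drawn
uniformly from 10–40 s by default, with pattern-specific floors where a
generator needs room (a sigh needs `3 + dur_gain` breath cycles).

**Evaluation records** simulate 30 min of unique segments, duplicate the
list, reorder each copy independently (re-drawing if the two orders
coincide), and concatenate both halves. Every unique segment appears
exactly once per half; the returned pairing table carries the aligned
sample extents of the two copies for consistency scoring.

**Quality-control insertion** selects 152 library segments — 25 SYB,
26 ASB, 27 SIH, 22 PAU, 27 MVT, 25 UNK, about 1000 s of signal — and
splices them into a long host record twice: once at uniformly drawn times
in the first 3 h, once (independently re-ordered) in the last 3 h. Each
insertion splits the host at the drawn time and applies two cross-fades,
so the record grows by $2\sum \ell_i - 4kN_T$ samples. Draws that would
land inside a previous insertion or within $2N_T$ of another cut are
rejected and re-drawn (bounded), keeping every inserted span attributable
to exactly one truth label; insertion regions are pre-shrunk by the pass
growth so that the spans land inside the stated regions of the *final*
record. A configurable minimum spacing (default 0, beyond the $2N_T$
needed for well-formed cross-fades) is available.

**Training termination**: a session ends when, in the current unbroken run
of correct scores, every one of the six patterns has accumulated five
correct assignments; any error resets all six counters (the strict reading
of "consecutively").

## Agreement statistics

Fleiss' kappa is computed sample-wise from the category counts per sample;
the implementation is checked in the test suite against an independently
written brute-force transcription of the published formula (pairwise rater
agreement) to $10^{-12}$ over a thousand random fixtures, and against the
two-rater chance limit ($\kappa \to 0$ for independent uniform raters).
When pooled proportions are degenerate ($\bar P_e = 1$, all ratings one
category) the statistic is returned as 1 with a `degenerate` attribute.

Conventions worth stating explicitly:

- Samples labeled `NONE` (unscored / no consensus) by any party to a
  comparison are excluded from that comparison.
- Per-pattern kappas are computed by one-vs-rest binarization followed by a
  two-category kappa. The per-pattern decomposition is not uniquely
  defined in the multi-category setting; one-vs-rest is the standard
  choice and is flagged here because other conventions exist.
- Inter-scorer repeatability enumerates the Cartesian product of one
  iteration per scorer (8 combinations for 3 scorers × 2 iterations) and
  reports the mean ± SD of the per-combination kappas.
- Bootstrap SDs resample *samples* (rows) with replacement, 100 resamples
  by default. Label tracks are strongly autocorrelated, so these SDs
  describe sampling noise under an i.i.d. approximation and are best read
  comparatively.
- The interpretation bands use closed upper bounds: 0.8 is "substantial",
  0.81 "almost perfect".
- Pattern-specific scoring rates attribute each event's wall-clock cost to
  the gap from the previous event's timestamp (the first event has none);
  gaps over 2 min are excluded as interruptions, with the threshold
  inclusive. The attribution of a burst's first event is a convention the
  timestamp data cannot resolve; the previous-gap rule is used throughout
  and noted here.

Consensus labels require an absolute majority — $\lfloor m/2\rfloor + 1$
of $m$ iterations, i.e. at least 4 of 6 in the canonical design — and the
confusion matrix rows are conditional probabilities
$P_{ij} = N_{ij}/N_i$ over sample-by-iteration ratings of consensus-$i$
samples. Per-scorer matrices count that scorer's iterations over the
consensus samples ($N_i$ is twice the consensus-sample count for two
iterations); the group matrix pools all iterations. By default the
consensus includes the scorer under evaluation, matching a design where
the consensus is fixed once from all six iterations; passing a consensus
computed from any subset of iterations is equally supported since
`confusion_probs()` takes the consensus vector as data.

## Scorer simulation

A `scorer_profile` is a 6×6 row-stochastic confusion channel, a boundary
jitter SD in seconds, and a wall-clock seconds-per-segment model. The
simulator walks the truth segment table, jitters the internal boundaries
(clamped to preserve ordering; segments collapsing below one sample are
dropped with a warning), draws each label from the channel row of the true
pattern, and accumulates timestamps. Jitter is applied to edges *before*
label assignment because edge placement and category confusion are
distinct human error modes, and edge error is the dominant one on
pattern-dense records.

`run_validation_experiment()` wires everything together: a synthesized
segment library, a long synchronous-breathing host record per replicate,
two-pass QC insertion, two blinded iterations per scorer, then accuracy,
consistency, rates, intra-/inter-scorer kappas, consensus and confusion.
Accuracy and consistency are computed against the inserted QC truth only
(the host is unscored reference data), while repeatability and confusion
use the whole record, where the simulated scorer sees the host's true
breathing content. One emergent behavior deserves a note: because the host
is overwhelmingly SYB, pooled category proportions are highly skewed,
chance agreement is large, and whole-record kappas are much lower than the
raw percent agreement — the well-known prevalence sensitivity of
chance-corrected statistics, visible here by construction.

## What the synthetic data does and does not show

The generators realize the *defining* features of each pattern — phase
relationships, amplitude/duration ratios, spectral content — plus
log-normal breath-to-breath variability and additive noise. They do not
model baseline drift, cardiogenic oscillations, behavioral-state
transitions, RIP calibration change, or the breath-shape irregularity of
real infants. Green tests therefore demonstrate that the *machinery* —
splicing, record assembly, bookkeeping, statistics — is correct and that
the generators satisfy their own scoring rules; they say nothing about how
human scorers perform on real data, and the package deliberately makes no
such claim. Scale choices in the test suite (e.g. 5-minute training
records in unit tests, a single 6.5 h host record in the end-to-end
script) are the package's own, sized to exercise every code path at full
structural fidelity — the canonical 152-segment scheme always runs at its
real size.

## Numerical details

- Sample indices are 1-based inside R with half-open `[start, end)`
  intervals everywhere (sample $i$ covers time $[(i-1)/f_s,\, i/f_s)$), so
  a `[0, 2)` s event at 50 Hz is exactly 100 samples and abutting events
  share none.
- All stochastic functions accept a `seed`; `NULL` uses the ambient RNG.
  Derived sub-seeds stay below $2^{31}$.
- `fleiss_kappa()` treats $1 - \bar P_e <$ machine epsilon as degenerate.
- Bootstrap resamples on which a statistic is undefined are redrawn up to
  ten times before the error propagates.
- Cross-fade ramps are exact at their endpoints by construction; the
  complementary pair sums to 1 at every sample, so constant signals are
  invariant under splicing.
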