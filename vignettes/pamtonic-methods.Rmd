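---
title: "Tonic auriculomotor EMG under dichotic listening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tonic auriculomotor EMG under dichotic listening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamtonic)
```

## The scientific problem

The posterior auricular muscle (PAM) is a vestigial pinna-orienting muscle
whose surface EMG carries two separable signatures of hearing: a stereotyped
short-latency (5–30 ms) sound-evoked reflex, and a sustained *tonic*
activity level. During lateralized selective listening, tonic PAM activity
is elevated on the attended side. `pamtonic` implements, and stress-tests on
synthetic data with known ground truth, a complete analysis chain for
detecting this tonic lateralization in a dichotic oddball paradigm: brief
tone bursts stream into one ear, brief rising-frequency chirps into the
other, attention is cued to one ear per trial, and the listener reports
attenuated deviants in the attended stream.

Because no raw recordings of this paradigm are publicly available, the
package treats the *synthetic study* as a first-class object: every analysis
is exercised against simulations whose attention gain, tonic decay and
reflex amplitudes are known exactly, and the acceptance surface is parameter
recovery, not reproduction of any particular empirical table.

## Stimulus model

* **Tone burst** — 50 ms of an 800 Hz sinusoid; the first and last 12 ms are
  weighted by the rising/falling halves of a 24 ms Hanning window. Epoch
  time-zero is the end of the rise time (12 ms), where the burst first
  reaches full amplitude.
* **Chirp** — a 14.9 ms unwindowed sweep whose instantaneous frequency rises
  exponentially in time from 100 Hz to 9,800 Hz
  (`f(t) = 100 * 98^(t/14.9 ms)`), approximating a cochlear-delay-
  compensating chirp by its duration and endpoints; the cochlear-mechanics
  derivation of the original waveform is intentionally out of scope. Because
  the reflex-triggering high-frequency energy arrives at the sweep's end,
  time-zero is the chirp *offset* (14.9 ms).
* **Sequences** — 600 events, each assigned to an ear independently with
  probability 1/2; onset-to-onset inter-stimulus intervals uniform on
  250–400 ms. Onset-to-onset is the reading consistent with the printed mean
  sequence duration of about 3.26 min (599 × 325 ms ≈ 3.25 min);
  offset-to-onset would overshoot by roughly 10%. Within each ear, deviants
  (identical waveforms attenuated by 15 dB) recur with inter-deviant gaps —
  counting the deviant — drawn uniformly from the integers 3–20; the first
  deviant's position is drawn from the same distribution. A uniform gap on
  [3, 20] implies a deviant probability near 8.7%, slightly below the
  nominal 9.4%; the gap range, not the probability, is treated as the
  primitive, and the generator exposes it as a parameter rather than tuning
  it.

Event count (600) rather than sequence duration is held fixed; only a
per-ear average of 300 is prescribed, and a fixed event count is the
simplest generator consistent with it.

## Generative EMG model

For each PAM, `simulate_trial()` draws a latent source

> sigma(t) = `background_rms` × (1 + a·1[attended == side]) × exp(−t/tau)

multiplying band-limited (20–500 Hz) Gaussian noise, where `a` is the
ipsilateral attention gain and `tau` the tonic decay constant. Attention
acts *multiplicatively*: the downstream z-scoring is affine-invariant, so
additive vs multiplicative modulation is not identified by the analyses, and
the multiplicative form keeps amplitudes positive. The exponential decay
form is likewise a modeling choice — only "a general decline over the trial"
is established empirically.

Every acoustic event evokes a biphasic reflex: a difference-of-Gaussians
pulse strictly confined to 5–30 ms after time-zero, positive peak at 12 ms,
scaled by (i) a per-kind amplitude (`reflex_amp`; tone bursts default to 0,
reflecting stimuli whose slow 12 ms rise fails to trigger reflexes reliably,
while chirps default to the background RMS — subthreshold in single trials,
as real PAM reflexes are, and clearly resolved after averaging hundreds of
epochs; a much stronger default would let reflex energy inflate the ongoing
envelope on the chirp side, which the analysis premise excludes), (ii) an
ipsilateral/contralateral drive pair (1.0/0.6 — the laterality of the reflex
drive is not established, so it is configurable), (iii) a lognormal
per-event factor with CV 0.3, and (iv) a 0.5 scale for the 15 dB-attenuated
deviants.

Each muscle's source splits onto its two unipolar electrodes with opposite
half-amplitude polarity, plus a shared common-mode noise floor (cancelled
exactly by the bipolar derivation), 50/100/150 Hz line components with a 20%
inter-electrode gain imbalance (so a differential line residual survives and
the comb filter has real work to do), and sporadic high-amplitude artifact
bursts (Poisson, default 0.02/s per electrode) injected into single
electrodes. Between participants, baseline RMS and reflex amplitude vary
lognormally (CV 0.3 each) around the population values — the order of
magnitude of real inter-individual PAM variability is known only
qualitatively, so these are modeling choices, stated once and not revisited.

The native simulation rate defaults to 9,600 Hz so the resampling stage of
the preprocessing chain is genuinely exercised.

## Conditioning chain

Per muscle: bipolar derivation (`ch1 − ch2`), decimation to 4,800 Hz behind
a Blackman windowed-sinc anti-alias low-pass (≥ 60 dB alias rejection),
a notching IIR comb at 50 Hz and every harmonic up to Nyquist (Q = 35,
−3 dB width 50/35 Hz), and a 20–1,000 Hz linear-phase FIR band-pass of order
4,800 (Hamming windowed-sinc; any linear-phase design meeting the stopband
contracts would do). Comb and band-pass are applied forward and backward,
i.e. with the magnitude-squared response and exactly zero phase; edges are
reflection-padded by three filter lengths so start-up transients fall
outside the region that any analysis later reads (the first seconds of each
trial are always trimmed). In the pipeline the two zero-phase responses are
fused into a single cached frequency-domain multiplication; a test asserts
the fused path equals the sequential operators.

Numerical conventions worth stating: windows are half-open — baseline
[−250, 0) ms, post-stimulus [0, 250) ms, pre-stimulus [−100, 0) ms — except
the reflex search range 5–30 ms, which is inclusive; epochs at 4,800 Hz are
exactly 9,600 samples; the comb requires the sampling rate to be an integer
multiple of 50 Hz so notches align with harmonics.

## Epoch screening, reliability and normalization

Chirp-locked epochs (±1 s, linearly detrended over the full epoch — the fit
window is not prescribed, and the full epoch matches the stated order of
operations — then baseline-corrected by the [−250, 0) ms mean) are screened
by their SNR, `10·log10(var[0,250) / var[−250,0))`. The retention mean and
SD are computed once over *all* epochs of the 2 × 2 × 2 design (both PAMs),
separately for standards and deviants; an epoch survives iff it lies within
3 SD. Representative-epoch selection then takes, per cell, the `n_per_cell`
retained epochs with SNR closest to the overall mean SNR (ties broken by
presentation order); `n_per_cell` is the minimum retained count across cells
*and* certified participants, derived by the study-level orchestration pass
because it is data-dependent. The overall mean used for ranking is
recomputed over retained epochs — whether the original procedure reused the
pre-rejection mean is ambiguous, and recomputation is the more internally
consistent reading.

Reliability certification correlates odd- vs even-indexed epoch averages
(1-based presentation order; unequal counts allowed) within 5–30 ms, per
standard-stimulus cell; a participant passes with r ≥ 0.4 in at least 6 of
the 8 pooled cells, which automatically forces at least 2 of 4 per muscle —
the pooled 6-of-8 rule is the single operative criterion.

Reflex normalization (per muscle and participant) averages the selected
epochs per cell of the standard and deviant 2 × 2 designs, takes the maximum
absolute amplitude of the eight averages within 5–30 ms as the factor, and
divides every epoch by it — a single common divisor, so every within-muscle
contrast is preserved exactly.

## Tonic analyses

**Ongoing (primary).** A centered 1 s moving-RMS envelope of each
conditioned signal is trimmed to a region of interest starting 5 s after
the first stimulus onset and lasting 180 s, cut into five 36 s segments,
and reduced to segment means. Per muscle and participant, all 100 values
(20 trials × 5 segments — the pooled reading of the procedure) are pooled;
values strictly outside the 2.5th–97.5th percentiles (linear-interpolation
percentiles, R type 7; boundary values retained) are removed; the remainder
is z-scored with the sample SD; and cell means are formed over the
2 (PAM) × 2 (stimulus type at that side) × 2 (attended side) × 5 (segment)
design, five trials per cell. Statistics retain segments 1 and 5 as a
two-level time factor and run one fully within-subject 2 × 2 × 2
repeated-measures ANOVA per stimulus type (PAM location × listening
condition × time), every effect tested against its own effect-by-subject
interaction with df (1, N−1); partial eta-squared is
SS_effect/(SS_effect + SS_error). No multiple-testing correction is applied
and p-values come from the exact F/t distributions (α = 0.05, strict
inequality).

**Time-locked (secondary).** A 10 ms moving-RMS envelope — short enough to
keep the reflex localized — is epoched at chirp offsets (±100 ms), keeping
exactly the trials whose non-rectified counterparts were selected. Per
muscle, epochs are collapsed over chirp side and averaged per attended side
× chirp class; the four averages are jointly z-normalized by the mean and SD
of their concatenated [−100, 0) ms samples (one shared affine map per
muscle — normalizing per muscle first is forced by the stated per-muscle
2 × 2 normalization, then toward/away pooling follows). No subtractive
baseline correction is applied at this stage. The per-participant
toward-minus-away pre-stimulus means feed two-tailed paired t-tests. Because
the smallest ISI (250 ms) exceeds the pre-window plus reflex span, and the
centered 10 ms envelope window smears at most 5 ms, a reflex at +5 ms or
later cannot reach the [−100, 0) ms window through the envelope; the
zero-phase band-pass does spread a few percent of reflex energy
symmetrically into the last ~15 ms of the baseline (band-limitation
ringing), an effect that is visible at the reduced test band (250 Hz edge),
negligible at the full 1,000 Hz band, and cancelled in the paired
reflex-independence comparison either way.

## Problem sizes used for simulation studies

The replicate parameter-recovery runs use a one-third-scale configuration
chosen once (`scaled_study_config()`): 200-event sequences (≈ 65 s trials),
a 60 s region of interest starting 5/3 s after the first onset in five 12 s
segments, native rate 1,200 Hz, analysis rate 600 Hz, 20–250 Hz band of
order 600 — the same chain topology and all screening rules unchanged. At
these sizes one 17-participant study takes well under a minute, so 20
replicate studies plus the type-I simulation (2,000 table-level null draws)
complete on a single CPU in minutes while leaving every stage of the
pipeline — including decimation, comb alignment and the reliability gate —
genuinely exercised. The full-rate filter contracts are verified separately
at 9,600 → 4,800 Hz. `run_study()` holds per-participant epoch sets in
memory and is sized for these reduced configurations; a full-scale
(9,600 Hz, 600-event, 31-participant) run would want a disk-backed epoch
store, which is out of scope.

## What the synthetic data do and do not establish

The generator reproduces the *statistical structure the analyses assume*:
multiplicative ipsilateral gain, monotone tonic decay, stimulus-locked
biphasic reflexes with trial-to-trial variability, line contamination,
common-mode pickup and sporadic artifacts. It does not model motor-unit
physiology, electrode geometry, skin impedance, inter-muscle crosstalk, or
non-stationarities beyond the exponential decay. Passing recovery tests
therefore shows the pipeline is correct and well-calibrated *under its own
assumptions* — e.g. that the type-I error of the listening-condition test is
nominal when the gain is zero, and that the pre-stimulus contrast is
insensitive to reflex amplitude — not that real recordings satisfy those
assumptions.

## Known limitations and open choices

* The deviant-probability wording (9.4% vs the ~8.7% implied by a uniform
  [3, 20] gap) is resolved in favor of the gap range; both are exposed as
  parameters.
* Whether outlier removal pools across stimulus-type trials is read
  literally as "all 100 values per muscle"; the alternative (per stimulus
  type) differs only in degenerate cases.
* The percentile method (type 7) and the strict-exterior removal rule are
  stated choices; no percentile convention is prescribed by the procedure
  itself.
* Interaction terms involving time are *expected* to be non-null under the
  generative model (a multiplicative gain on a decaying baseline yields a
  condition × time interaction after z-scoring), so recovery checks assert
  only the main effects and the absence of a spurious PAM-location effect.
* The ten stimulus sequences are shared across participants, as in the
  actual design. Any chance asymmetry between the tone-left and tone-right
  sequence groups (e.g. in total chirp count) therefore repeats identically
  for every participant and cannot be averaged away; it stays harmless only
  while per-stimulus energy contributions to the 1 s envelope are small,
  which is one reason the default reflex amplitude sits at the single-trial
  noise floor.
* Behavioral scoring implements the greedy earliest-first one-to-one
  matching of presses to targets within 50–1,500 ms; trial breaks and
  impedance control have no computational analogue and are not modeled.
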