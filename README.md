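# pamtonic

Analysis pipeline for **tonic posterior auricular muscle (PAM) EMG during
dichotic selective listening**, built as an R package plus a sequence of
analysis drivers, with a synthetic-data generator as a first-class, tested
component.

## The problem

The PAM, a vestigial pinna-orienting muscle behind each ear, shows two
separable EMG signatures of hearing: a short-latency (5–30 ms) sound-evoked
reflex and a sustained *tonic* activity level. When a listener attends to
sounds in one ear, tonic PAM activity rises on that side. Detecting this
lateralization in a dichotic oddball paradigm (800 Hz tone bursts in one
ear, 100→9,800 Hz exponential-sweep chirps in the other, attention cued to
one ear per ~3.3 min trial) requires a long chain of signal processing —
bipolar derivation, resampling, 50 Hz comb + 20–1,000 Hz zero-phase
band-pass, chirp-locked epoching with SNR screening, split-half reliability
gating, reflex-based normalization — before the two tonic analyses:

1. **Ongoing activity:** 1 s moving-RMS envelopes over a 180 s region of
   interest, five 36 s segment means, 2.5/97.5 percentile outlier removal,
   within-muscle z-scoring, and per stimulus type a fully within-subject
   2×2×2 repeated-measures ANOVA (PAM location × listening condition ×
   time), each effect tested against its own subject interaction,
   F(1, N−1), with partial eta-squared SS_eff/(SS_eff + SS_err).
2. **Time-locked activity:** 10 ms moving-RMS envelopes epoched at chirp
   offsets (±100 ms), per-muscle baseline (−100–0 ms) z-normalization, and
   paired t-tests on the toward-vs-away pre-stimulus means — an attention
   readout constructed to be independent of the reflex.

Because no raw recordings of this paradigm are deposited anywhere, the
package ships a generative model with known ground truth (multiplicative
ipsilateral attention gain `a`, exponential tonic decay `tau`, biphasic
5–30 ms reflex templates, line noise, common-mode pickup, artifact bursts)
and validates the pipeline by parameter recovery on replicate simulated
studies.

## Worked example

```r
library(pamtonic)

# a reduced-size simulated study: 3 participants, one-third-scale trials
cfg <- scaled_study_config(n_participants = 3, master_seed = 7)
res <- run_study(cfg)

res$reliability$passed
#> [1] TRUE TRUE TRUE

subset(res$anova$chirp, effect %in% c("pam", "condition", "time"))
#>      effect df1 df2        F        p    pes
#> 1       pam   1   2 1.33e-01 7.50e-01 0.0625
#> 2 condition   1   2 1.92e+04 5.20e-05 0.9999
#> 3      time   1   2 3.24e+04 3.08e-05 0.9999
```

With the default attention gain `a = 0.3` and decay `tau = 150 s`, the
listening-condition and time main effects are overwhelming while the
PAM-location effect stays at chance — the qualitative pattern the method is
designed to detect. Running `analysis/03_preprocess_certify.R` then
`analysis/04_tonic_ongoing.R` (8 participants, master seed 20260925)
prints:

```
participants certified: 8 of 8
2x2x2 repeated-measures ANOVAs (df 1, 7):
 stim_side   effect        F        p       pes  signif
 tone_burst  pam       1.03e+00  3.44e-01  0.128
 tone_burst  condition 6.00e+04  5.00e-15  1.000  **
 tone_burst  time      7.86e+05  6.13e-19  1.000  **
 chirp       pam       1.41e+00  2.73e-01  0.168
 chirp       condition 3.07e+04  5.20e-14  1.000  **
 chirp       time      4.04e+04  2.00e-14  1.000  **
 ...
mean z (attend toward PAM side): 0.806 / away: -0.786
mean z first segment: 1.015 / last segment: -0.92
```

and `analysis/05_tonic_timelocked.R`:

```
pre-stimulus toward/away contrasts (within-subject t-tests):
  standard t(7) = 113.45, p = 1.09e-12
  deviant  t(7) = 98.54, p = 2.92e-12
```

The interpretation: the tonic z-amplitude is higher when attention is
directed toward a muscle's side and declines from the first to the last
trial segment, in both the ongoing-envelope and the pre-stimulus
time-locked readouts, with no left/right muscle asymmetry.

## The analysis drivers

| script | what it does |
|---|---|
| `analysis/01_stimuli.R` | builds both stimulus waveforms, renders an example dichotic sequence (WAV + event CSV), summarizes generator design quantities over 1,000 sequences |
| `analysis/02_simulate_study.R` | draws a study's ground truth (parameters, schedule), exports an example recording (CSV + JSON sidecar) |
| `analysis/03_preprocess_certify.R` | full per-participant pipeline through SNR screening and split-half reliability; writes the reliability table |
| `analysis/04_tonic_ongoing.R` | ongoing-activity tonic analysis, tidy tonic table, RM-ANOVA tables, time-resolved figure |
| `analysis/05_tonic_timelocked.R` | time-locked tonic analysis, normalized waveform export, paired t contrasts |

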