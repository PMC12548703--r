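#' Generative model parameters for one participant's PAM EMG
#'
#' Parameters of the two-muscle surface-EMG generative model. Each posterior
#' auricular muscle (PAM) produces a latent band-limited Gaussian source whose
#' instantaneous standard deviation is
#' `sigma(t) = background_rms * (1 + attention_gain * [attended == side]) * exp(-t / decay_tau_s)`,
#' i.e. attention multiplicatively boosts the ipsilateral tonic level and the
#' tonic level decays exponentially over the listening trial. Each acoustic
#' event additionally evokes a short-latency biphasic reflex confined to the
#' 5-30 ms post-time-zero window, scaled by a lognormal per-trial factor and
#' by an ipsilateral/contralateral drive gain. The source is split onto two
#' unipolar electrodes with opposite half-amplitude polarity plus a shared
#' common-mode noise floor; 50 Hz power-line contamination (with harmonics) is
#' added with a small inter-electrode gain imbalance so a differential
#' residual survives the bipolar derivation, and occasional high-amplitude
#' artifact bursts are injected into single electrodes.
#'
#' Amplitudes are in arbitrary microvolt-like units; only ratios matter
#' downstream because the analyses z-score within muscle and participant.
#'
#' @param background_rms Baseline tonic RMS per PAM.
#' @param attention_gain Dimensionless ipsilateral tonic gain `a >= 0`.
#' @param decay_tau_s Exponential tonic decay constant in seconds.
#' @param reflex_amp Named vector, peak reflex amplitude per stimulus kind
#'   (`tone_burst`, `chirp`). The default gives tone bursts no reflex,
#'   mirroring stimuli whose slow rise fails to trigger the reflex, and sets
#'   the chirp reflex at the background RMS: subthreshold in single trials
#'   (reflexes become well-defined only after averaging hundreds of epochs)
#'   so reflex energy does not dominate the ongoing tonic envelope.
#' @param reflex_peak_ms Reflex peak latency after time-zero (within 5-30 ms).
#' @param reflex_trial_cv Coefficient of variation of the lognormal per-event
#'   reflex amplitude factor.
#' @param reflex_contra_gain Drive gain for stimuli contralateral to the PAM
#'   (ipsilateral gain is 1).
#' @param deviant_reflex_scale Reflex scale for the 15 dB attenuated deviants.
#' @param line_amp Amplitude of the 50 Hz component on each electrode
#'   (harmonics at 100/150 Hz enter at 1/2 and 1/4 of this amplitude).
#' @param line_imbalance Fractional gain imbalance of the line pickup between
#'   the two electrodes of a pair.
#' @param cm_rms RMS of the shared common-mode noise per electrode pair.
#' @param artifact_rate_hz Expected artifact bursts per second per electrode.
#' @param artifact_amp Peak amplitude of artifact bursts.
#' @param noise_band_hz Passband of the latent EMG source in Hz.
#' @param rate Simulation sampling rate in samples/s (study default 9600).
#' @param seed Integer seed.
#' @return An `emg_model_params` list.
#' @export
emg_model_params <- function(background_rms = 10,
                             attention_gain = 0.3,
                             decay_tau_s = 150,
                             reflex_amp = c(tone_burst = 0, chirp = 10),
                             reflex_peak_ms = 12,
                             reflex_trial_cv = 0.3,
                             reflex_contra_gain = 0.6,
                             deviant_reflex_scale = 0.5,
                             line_amp = 20,
                             line_imbalance = 0.2,
                             cm_rms = 10,
                             artifact_rate_hz = 0.02,
                             artifact_amp = 300,
                             noise_band_hz = c(20, 500),
                             rate = 9600,
                             seed = 1L) {
  stopifnot(background_rms >= 0, attention_gain >= 0, decay_tau_s > 0,
            all(reflex_amp >= 0), reflex_peak_ms > 0, reflex_peak_ms < 100,
            all(c("tone_burst", "chirp") %in% names(reflex_amp)),
            noise_band_hz[2] < rate / 2)
  structure(as.list(environment()), class = "emg_model_params")
}

# Band-limited unit-RMS Gaussian noise, synthesized in the frequency domain
# with raised-cosine (5 Hz) band edges. Drawing an independent complex
# Gaussian spectrum and inverse-transforming yields two independent real
# band-limited series (real and imaginary part), so one FFT provides a pair.
band_limited_noise_pair <- function(n, rate, band, trans_hz = 5) {
  nf <- stats::nextn(n, c(2, 3, 5))
  f <- seq(0, rate, length.out = nf + 1)[seq_len(nf)]
  f <- pmin(f, rate - f)
  mask <- rep(0, nf)
  mask[f >= band[1] & f <= band[2]] <- 1
  lo <- f >= band[1] - trans_hz & f < band[1]
  hi <- f > band[2] & f <= band[2] + trans_hz
  mask[lo] <- 0.5 * (1 - cos(pi * (f[lo] - band[1] + trans_hz) / trans_hz))
  mask[hi] <- 0.5 * (1 + cos(pi * (f[hi] - band[2]) / trans_hz))
  idx <- which(mask > 0)
  spec <- complex(real = rep(0, nf), imaginary = rep(0, nf))
  spec[idx] <- mask[idx] * complex(real = stats::rnorm(length(idx)),
                                   imaginary = stats::rnorm(length(idx)))
  y <- stats::fft(spec, inverse = TRUE)[seq_len(n)]
  a <- Re(y); b <- Im(y)
  list(a / stats::sd(a), b / stats::sd(b))
}

band_limited_noise <- function(n, rate, band, trans_hz = 5) {
  band_limited_noise_pair(n, rate, band, trans_hz)[[1]]
}

#' Biphasic PAM reflex template
#'
#' Difference-of-Gaussians pulse confined to the 5-30 ms post-time-zero
#' window, shifted so its positive peak falls exactly at `peak_ms` and
#' tapered to zero at the window edges. Peak amplitude 1.
#'
#' @param rate Sampling rate in samples/s.
#' @param peak_ms Desired positive-peak latency in ms (default 12).
#' @return A list with `samples` and `offset_samples`, the sample lag of the
#'   template start relative to the time-zero sample (the template spans
#'   5-30 ms post time-zero).
#' @export
reflex_template <- function(rate, peak_ms = 12) {
  t0 <- 0.005; t1 <- 0.030
  tt <- seq(t0, t1, by = 1 / rate)
  shape <- function(tc) {
    exp(-((tt - tc)^2) / (2 * 0.0025^2)) -
      0.8 * exp(-((tt - tc - 0.006)^2) / (2 * 0.0035^2))
  }
  raw <- shape(peak_ms / 1000)
  # re-center so the realized argmax sits at peak_ms despite the trough pull
  shift <- peak_ms / 1000 - tt[which.max(raw)]
  w <- shape(peak_ms / 1000 + shift)
  # taper to zero at window edges so no energy leaks outside [5, 30] ms
  edge <- pmin(1, pmin(tt - t0, t1 - tt) / 0.003)
  w <- w * 0.5 * (1 - cos(pi * pmin(edge, 1)))
  w <- w / max(abs(w))
  list(samples = w, offset_samples = round(t0 * rate))
}

#' Simulate one dichotic listening trial of two-PAM EMG
#'
#' Runs the generative model of [emg_model_params()] for one stimulus
#' sequence and attended side, producing a five-channel unipolar recording
#' (two electrodes per PAM plus a trigger channel carrying unit impulses at
#' event onsets).
#'
#' @param params An [emg_model_params()] object.
#' @param seq A `dichotic_sequence` from [generate_sequence()].
#' @param attended `"left"` or `"right"`.
#' @param seed Optional integer overriding `params$seed`.
#' @return A `pam_recording`: list with `channels` (n x 5 matrix with columns
#'   `pam_left_1`, `pam_left_2`, `pam_right_1`, `pam_right_2`, `trigger`),
#'   `rate`, `events` (the event log with 1-based `onset_sample`), and
#'   `attended`.
#' @export
simulate_trial <- function(params, seq, attended, seed = params$seed) {
  stopifnot(inherits(params, "emg_model_params"),
            attended %in% c("left", "right"))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rate <- params$rate
  dur <- sequence_duration_s(seq) + 1.2   # tail for the 1 s post-stimulus epochs
  n <- ceiling(dur * rate)
  t <- (seq_len(n) - 1) / rate
  tmpl <- reflex_template(rate, params$reflex_peak_ms)
  onset_sample <- round(seq$onset_s * rate) + 1L
  tz_sample <- round((seq$onset_s + timezero_offset_s(seq$kind)) * rate) + 1L

  channels <- matrix(0, n, 5, dimnames = list(NULL, c(
    "pam_left_1", "pam_left_2", "pam_right_1", "pam_right_2", "trigger")))
  line_wave <- params$line_amp * (
    sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi)) +
      0.5 * sin(2 * pi * 100 * t + stats::runif(1, 0, 2 * pi)) +
      0.25 * sin(2 * pi * 150 * t + stats::runif(1, 0, 2 * pi)))
  cv <- params$reflex_trial_cv
  sdlog <- sqrt(log(1 + cv^2))

  src_noise <- band_limited_noise_pair(n, rate, params$noise_band_hz)
  cm_noise <- if (params$cm_rms > 0) {
    band_limited_noise_pair(n, rate, params$noise_band_hz)
  }
  names(src_noise) <- c("left", "right")
  for (side in c("left", "right")) {
    gain <- 1 + params$attention_gain * (attended == side)
    sigma <- params$background_rms * gain * exp(-t / params$decay_tau_s)
    src <- src_noise[[side]] * sigma
    # event-locked reflexes from both ears, ipsi/contra weighted
    amp <- unname(params$reflex_amp[seq$kind]) *
      ifelse(seq$ear == side, 1, params$reflex_contra_gain) *
      ifelse(seq$is_deviant, params$deviant_reflex_scale, 1) *
      stats::rlnorm(nrow(seq), -sdlog^2 / 2, sdlog)
    for (i in which(amp > 0)) {
      i0 <- tz_sample[i] + tmpl$offset_samples
      span <- i0:(i0 + length(tmpl$samples) - 1L)
      ok <- span >= 1 & span <= n
      src[span[ok]] <- src[span[ok]] + amp[i] * tmpl$samples[ok]
    }
    cm <- if (params$cm_rms > 0) {
      cm_noise[[match(side, c("left", "right"))]] * params$cm_rms
    } else 0
    ch1 <- src / 2 + cm + line_wave * (1 + params$line_imbalance)
    ch2 <- -src / 2 + cm + line_wave * (1 - params$line_imbalance)
    # sporadic high-amplitude bursts, independent per electrode
    for (k in 1:2) {
      n_art <- stats::rpois(1, params$artifact_rate_hz * dur)
      x <- if (k == 1) ch1 else ch2
      if (n_art > 0) {
        for (a in seq_len(n_art)) {
          a0 <- sample.int(n, 1)
          len <- round(stats::runif(1, 0.05, 0.2) * rate)
          span <- a0:min(n, a0 + len - 1L)
          tau <- seq_along(span) / rate
          x[span] <- x[span] + params$artifact_amp *
            sin(2 * pi * 8 * tau) * exp(-tau / 0.05)
        }
      }
      channels[, paste0("pam_", side, "_", k)] <- x
    }
  }
  channels[onset_sample, "trigger"] <- 1
  ev <- as.data.frame(seq)
  ev$onset_sample <- onset_sample
  ev$timezero_sample <- tz_sample
  structure(list(channels = channels, rate = rate, events = ev,
                 attended = attended),
            class = "pam_recording")
}

#' Participant-level parameter sampler
#'
#' Returns a sampler function drawing per-participant [emg_model_params()]
#' around a base parameter set: baseline RMS and the chirp reflex amplitude
#' vary lognormally across participants (each with the given CV) to emulate
#' the well-known between-individual variability of PAM amplitude; the
#' structural parameters (attention gain, decay constant) are shared.
#'
#' @param base An [emg_model_params()] used as the population center.
#' @param rms_cv,reflex_cv Between-participant coefficients of variation.
#' @return `function(participant_id)` -> `emg_model_params` (the caller is
#'   responsible for seeding the RNG before invoking it).
#' @export
default_params_sampler <- function(base = emg_model_params(),
                                   rms_cv = 0.3, reflex_cv = 0.3) {
  force(base)
  function(participant_id) {
    p <- base
    s1 <- sqrt(log(1 + rms_cv^2))
    s2 <- sqrt(log(1 + reflex_cv^2))
    p$background_rms <- base$background_rms * stats::rlnorm(1, -s1^2 / 2, s1)
    p$reflex_amp <- base$reflex_amp * stats::rlnorm(1, -s2^2 / 2, s2)
    names(p$reflex_amp) <- names(base$reflex_amp)
    p
  }
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(master, participant = 0L, trial = 0L) {
  as.integer((as.numeric(master) * 7919 + participant * 104729 +
                trial * 1299709) %% 2147483647)
}

#' Simulate the ground truth of a multi-participant dichotic study
#'
#' Lays out the study design — ten distinct stimulus sequences with the
#' tone-burst ear balanced (five tone-left, five tone-right), each presented
#' once under attend-left and once under attend-right, i.e. 20 listening
#' trials per participant and five trials per combination of stimulus type,
#' stimulus side and attended side — and draws per-participant generative
#' parameters via the sampler. Everything is reproducible from `master_seed`.
#'
#' Recordings themselves are simulated lazily with [simulate_trial()] (see
#' [trial_recording()]); set `eager = TRUE` to also return the full list of
#' recordings (only sensible for small configurations).
#'
#' @param n_participants Number of participants (>= 2).
#' @param params_sampler A function `participant_id -> emg_model_params`,
#'   e.g. [default_params_sampler()].
#' @param master_seed Integer master seed.
#' @param n_events Events per sequence (default 600).
#' @param eager If `TRUE`, return `recordings`: a list (participants) of
#'   lists (trials) of `pam_recording`s.
#' @return A `study_ground_truth`: list with `participants` (per-participant
#'   `emg_model_params`), `schedule` (data.frame: `trial`, `seq_id`,
#'   `tone_ear`, `attended`, `seq_seed`), `sequences` (the ten
#'   `dichotic_sequence`s), `master_seed`, `n_participants`, and optionally
#'   `recordings`.
#' @export
simulate_study <- function(n_participants, params_sampler = default_params_sampler(),
                           master_seed = 1L, n_events = 600, eager = FALSE) {
  stopifnot(n_participants >= 2)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  tone_ear <- rep(c("left", "right"), each = 5)
  seq_seed <- vapply(1:10, function(j) derive_seed(master_seed, 0L, j),
                     integer(1))
  sequences <- lapply(1:10, function(j) {
    generate_sequence(sequence_spec(n_events = n_events,
                                    tone_ear = tone_ear[j],
                                    seed = seq_seed[j]))
  })
  schedule <- data.frame(
    seq_id = rep(1:10, times = 2),
    tone_ear = rep(tone_ear, times = 2),
    attended = rep(c("left", "right"), each = 10),
    seq_seed = rep(seq_seed, times = 2))
  set.seed(derive_seed(master_seed, 0L, 0L))
  schedule <- schedule[sample.int(nrow(schedule)), ]   # pseudo-random order
  schedule$trial <- seq_len(nrow(schedule))
  rownames(schedule) <- NULL
  schedule <- schedule[, c("trial", "seq_id", "tone_ear", "attended", "seq_seed")]
  participants <- lapply(seq_len(n_participants), function(pid) {
    set.seed(derive_seed(master_seed, pid, 0L))
    params_sampler(pid)
  })
  gt <- structure(list(participants = participants, schedule = schedule,
                       sequences = sequences, master_seed = master_seed,
                       n_participants = n_participants),
                  class = "study_ground_truth")
  if (eager) {
    gt$recordings <- lapply(seq_len(n_participants), function(pid) {
      lapply(schedule$trial, function(tr) trial_recording(gt, pid, tr))
    })
  }
  gt
}

#' Simulate one scheduled trial of a study
#'
#' @param gt A `study_ground_truth` from [simulate_study()].
#' @param participant_id Participant index.
#' @param trial Trial number in the schedule.
#' @return A `pam_recording`.
#' @export
trial_recording <- function(gt, participant_id, trial) {
  row <- gt$schedule[gt$schedule$trial == trial, ]
  stopifnot(nrow(row) == 1)
  simulate_trial(gt$participants[[participant_id]],
                 gt$sequences[[row$seq_id]],
                 attended = row$attended,
                 seed = derive_seed(gt$master_seed, participant_id, trial))
}
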