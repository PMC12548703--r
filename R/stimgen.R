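#' Synthesize the 800 Hz tone-burst stimulus
#'
#' Builds the 50 ms, 800 Hz tone burst used as the standard stimulus in one
#' ear of the dichotic sequences. The first and last 12 ms are weighted by the
#' rising and falling halves of a 24 ms Hanning window; the central plateau is
#' unwindowed. The analysis "time-zero" of a tone-burst event is the end of
#' the rise time, i.e. 12 ms after waveform onset, where the burst first
#' reaches full amplitude.
#'
#' @param rate Sampling rate in samples/s. Must be at least twice the 800 Hz
#'   carrier; in practice >= 8000 to represent the carrier cleanly.
#' @return A `stimulus_waveform` object: a list with `samples`
#'   (peak-normalized amplitude series), `rate`, `kind`, `duration_ms` and
#'   `timezero_offset_ms`.
#' @seealso [make_chirp()], [generate_sequence()]
#' @export
make_tone_burst <- function(rate) {
  if (rate < 8000) {
    stop("sampling rate ", rate, " is too low for an 800 Hz tone burst; ",
         "aliasing risk (need >= 8000 samples/s)")
  }
  dur_ms <- 50
  n <- round(dur_ms / 1000 * rate)
  t <- (seq_len(n) - 1) / rate
  s <- sin(2 * pi * 800 * t)
  nr <- round(0.012 * rate)
  # symmetric Hanning of 24 ms: h[1] == 0, split into rise and fall halves
  h <- 0.5 * (1 - cos(2 * pi * (seq_len(2 * nr) - 1) / (2 * nr - 1)))
  s[seq_len(nr)] <- s[seq_len(nr)] * h[seq_len(nr)]
  s[(n - nr + 1):n] <- s[(n - nr + 1):n] * h[(nr + 1):(2 * nr)]
  s <- s / max(abs(s))
  new_stimulus_waveform(s, rate, "tone_burst", dur_ms, timezero_offset_ms = 12)
}

#' Synthesize the rising-frequency chirp stimulus
#'
#' Builds a 14.9 ms frequency-modulated chirp whose instantaneous frequency
#' rises exponentially in time (logarithmically spaced in frequency) from
#' 100 Hz to 9,800 Hz, approximating a cochlear-compensating chirp. The
#' waveform is deliberately unwindowed. Because the reflex-triggering energy
#' arrives with the high-frequency components at the end of the sweep, the
#' analysis "time-zero" is the chirp offset (14.9 ms after onset).
#'
#' The phase is the closed-form integral of the exponential sweep,
#' `phi(t) = 2 pi f0 T / log(k) * (k^(t/T) - 1)` with `k = f1/f0`, so the
#' instantaneous frequency (the phase derivative over `2 pi`) is exactly
#' `f0 * k^(t/T)`.
#'
#' @param rate Sampling rate in samples/s; must be at least `2 * 9800`.
#' @return A `stimulus_waveform` object (see [make_tone_burst()]).
#' @export
make_chirp <- function(rate) {
  f0 <- 100; f1 <- 9800; dur_s <- 0.0149
  if (rate < 2 * f1) {
    stop("sampling rate ", rate, " is below the Nyquist requirement for a ",
         f1, " Hz sweep endpoint; aliasing risk")
  }
  n <- round(dur_s * rate)
  t <- (seq_len(n) - 1) / rate
  k <- f1 / f0
  phase <- 2 * pi * f0 * dur_s / log(k) * (k^(t / dur_s) - 1)
  s <- sin(phase)
  s <- s / max(abs(s))
  new_stimulus_waveform(s, rate, "chirp", dur_s * 1000,
                        timezero_offset_ms = 14.9)
}

new_stimulus_waveform <- function(samples, rate, kind, duration_ms,
                                  timezero_offset_ms) {
  structure(list(samples = samples, rate = rate, kind = kind,
                 duration_ms = duration_ms,
                 timezero_offset_ms = timezero_offset_ms),
            class = "stimulus_waveform")
}

#' Latency from waveform onset to analysis time-zero
#'
#' Chirp epochs are anchored at chirp offset (14.9 ms); tone-burst epochs at
#' the end of the rise time (12 ms).
#'
#' @param kind `"tone_burst"` or `"chirp"` (vectorized).
#' @return Offset(s) in seconds.
#' @export
timezero_offset_s <- function(kind) {
  unname(c(tone_burst = 0.012, chirp = 0.0149)[kind])
}

#' Stimulus-waveform duration in seconds
#' @param kind `"tone_burst"` or `"chirp"` (vectorized).
#' @return Duration(s) in seconds.
#' @export
stimulus_duration_s <- function(kind) {
  unname(c(tone_burst = 0.050, chirp = 0.0149)[kind])
}

#' Specify a dichotic stimulation sequence
#'
#' Collects the generator parameters of one randomized dichotic sequence:
#' event count, the onset-to-onset inter-stimulus-interval range, the
#' within-ear deviant gap range, which ear carries tone bursts (the other ear
#' carries chirps), and the seed.
#'
#' Defaults reproduce the study design: 600 events per sequence (on average
#' 300 per ear), ISIs uniform on 250-400 ms, and within each ear a deviant
#' every 3-20 events.
#'
#' @param n_events Total events across both ears.
#' @param isi_range_s Length-2 numeric, min/max onset-to-onset ISI in seconds.
#' @param deviant_gap_range Length-2 integer, inclusive range of the within-ear
#'   gap (counting the deviant) between successive deviants.
#' @param tone_ear `"left"` or `"right"`: the ear receiving tone bursts.
#' @param seed Integer seed making the sequence reproducible.
#' @return A `sequence_spec` list.
#' @export
sequence_spec <- function(n_events = 600, isi_range_s = c(0.250, 0.400),
                          deviant_gap_range = c(3L, 20L),
                          tone_ear = "left", seed = 1L) {
  stopifnot(n_events > 0, length(isi_range_s) == 2,
            isi_range_s[1] <= isi_range_s[2],
            length(deviant_gap_range) == 2,
            deviant_gap_range[1] >= 1, deviant_gap_range[1] <= deviant_gap_range[2],
            tone_ear %in% c("left", "right"))
  structure(list(n_events = as.integer(n_events), isi_range_s = isi_range_s,
                 deviant_gap_range = as.integer(deviant_gap_range),
                 tone_ear = tone_ear, seed = as.integer(seed)),
            class = "sequence_spec")
}

#' Generate one randomized dichotic event sequence
#'
#' Draws a timed event list: each event is assigned to the left or right ear
#' independently with probability 1/2; onset-to-onset ISIs are i.i.d. uniform
#' on the spec's range; stimulus kind is determined by the ear (tone bursts in
#' `tone_ear`, chirps in the other). Within each ear, infrequent attenuated
#' deviants are placed so that the number of events between successive
#' deviants (counting the deviant itself) is uniform on the gap range; the
#' first deviant's position is drawn from the same distribution. Deviants are
#' 15 dB below the standards.
#'
#' @param spec A [sequence_spec()].
#' @return A `dichotic_sequence`: a data.frame with columns `onset_s`, `ear`,
#'   `kind`, `is_deviant`, `level_db_re_standard`, with the spec attached as
#'   attribute `spec`. If an ear receives fewer events than the minimum gap it
#'   gets zero deviants and the attribute `zero_deviant_ears` names it.
#' @export
generate_sequence <- function(spec) {
  stopifnot(inherits(spec, "sequence_spec"))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  n <- spec$n_events
  ear <- sample(c("left", "right"), n, replace = TRUE)
  isi <- stats::runif(n - 1, spec$isi_range_s[1], spec$isi_range_s[2])
  onset <- c(0, cumsum(isi))
  kind <- ifelse(ear == spec$tone_ear, "tone_burst", "chirp")
  is_deviant <- logical(n)
  zero_dev <- character(0)
  for (e in c("left", "right")) {
    idx <- which(ear == e)
    m <- length(idx)
    if (m < spec$deviant_gap_range[1]) {
      zero_dev <- c(zero_dev, e)
      next
    }
    gaps <- integer(0)
    total <- 0
    while (total <= m) {
      g <- sample(seq(spec$deviant_gap_range[1], spec$deviant_gap_range[2]), 1)
      gaps <- c(gaps, g)
      total <- total + g
    }
    pos <- cumsum(gaps)
    pos <- pos[pos <= m]
    is_deviant[idx[pos]] <- TRUE
  }
  out <- data.frame(onset_s = onset, ear = ear, kind = kind,
                    is_deviant = is_deviant,
                    level_db_re_standard = ifelse(is_deviant, -15, 0),
                    stringsAsFactors = FALSE)
  attr(out, "spec") <- spec
  if (length(zero_dev)) attr(out, "zero_deviant_ears") <- zero_dev
  class(out) <- c("dichotic_sequence", "data.frame")
  out
}

#' Sequence duration from first event onset to last event offset
#'
#' @param seq A `dichotic_sequence`.
#' @return Duration in seconds.
#' @export
sequence_duration_s <- function(seq) {
  n <- nrow(seq)
  (seq$onset_s[n] - seq$onset_s[1]) + stimulus_duration_s(seq$kind[n])
}

#' Render a dichotic sequence to a two-channel waveform
#'
#' Places each event's stimulus waveform at its onset in its ear's channel,
#' scaling deviants by `10^(-15/20)`. Overlap between ears is summed (possible
#' at the 250 ms minimum ISI); overlap of successive waveforms within one ear
#' is impossible under the design (minimum ISI 250 ms exceeds the longest
#' 50 ms waveform) and raises an internal-consistency error if detected.
#'
#' @param seq A `dichotic_sequence`.
#' @param rate Audio sampling rate in samples/s (>= 2 x 9800 for the chirp).
#' @return A list with `audio` (n x 2 matrix, columns left/right), `rate`, and
#'   `events`: the event log with an added sample-accurate `onset_sample`
#'   (1-based).
#' @export
render_sequence <- function(seq, rate) {
  if (nrow(seq) == 0) {
    ev <- as.data.frame(seq)
    ev$onset_sample <- integer(0)
    return(list(audio = matrix(0, 0, 2,
                               dimnames = list(NULL, c("left", "right"))),
                rate = rate, events = ev))
  }
  waves <- list(tone_burst = make_tone_burst(rate)$samples,
                chirp = make_chirp(rate)$samples)
  n_total <- round((sequence_duration_s(seq) + seq$onset_s[1]) * rate) + 1L
  audio <- matrix(0, nrow = n_total, ncol = 2,
                  dimnames = list(NULL, c("left", "right")))
  onset_sample <- round(seq$onset_s * rate) + 1L
  for (e in c("left", "right")) {
    idx <- which(seq$ear == e)
    if (length(idx) > 1) {
      ends <- onset_sample[idx] + lengths(waves[seq$kind[idx]]) - 1L
      if (any(onset_sample[idx][-1] <= ends[-length(ends)])) {
        stop("internal consistency error: overlapping same-ear waveforms")
      }
    }
    for (i in idx) {
      w <- waves[[seq$kind[i]]]
      amp <- 10^(seq$level_db_re_standard[i] / 20)
      span <- onset_sample[i]:(onset_sample[i] + length(w) - 1L)
      audio[span, e] <- audio[span, e] + amp * w
    }
  }
  ev <- as.data.frame(seq)
  ev$onset_sample <- onset_sample
  list(audio = audio, rate = rate, events = ev)
}

#' Write an event log as CSV
#'
#' One row per event with columns `onset_s`, `ear`, `kind`, `is_deviant`,
#' `level_db` (and `onset_sample` when rendered).
#'
#' @param events Event data.frame (a `dichotic_sequence` or a rendered log).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  df <- as.data.frame(events)
  names(df)[names(df) == "level_db_re_standard"] <- "level_db"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a two-channel waveform as a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer for rendered stimulus audio. Samples are clipped
#' to [-1, 1] and quantized to 16-bit integers.
#'
#' @param audio Numeric matrix (samples x channels) or vector.
#' @param rate Sampling rate in samples/s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav_pcm16 <- function(audio, rate, path) {
  if (is.vector(audio)) audio <- matrix(audio, ncol = 1)
  n_ch <- ncol(audio)
  x <- pmin(pmax(t(audio), -1), 1)          # interleave channels
  pcm <- as.integer(round(x * 32767))
  data_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * n_ch * 2L), con, size = 4, endian = "little")
  writeBin(as.integer(n_ch * 2L), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
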