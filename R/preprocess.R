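#' EMG conditioning filter specification
#'
#' Parameters of the fixed conditioning chain applied to each bipolar PAM
#' signal: resampling to `target_rate` with an anti-aliasing filter, a
#' comb notch at the power-line fundamental and all its harmonics up to
#' Nyquist, and a linear-phase FIR band-pass, both applied forward and
#' backward for zero net phase.
#'
#' The defaults are the study chain at 4,800 samples/s: 50 Hz comb with
#' Q = 35, 20-1,000 Hz band-pass of order 4,800 (a 1 s impulse response).
#' Scaled-down simulation runs use proportionally reduced rates and bands
#' (the band edge must stay below the target Nyquist).
#'
#' @param comb_base_hz Power-line fundamental in Hz.
#' @param comb_q Notch quality factor (notch -3 dB width = base / Q).
#' @param bandpass_hz Length-2 numeric band edges in Hz.
#' @param fir_order Band-pass FIR order (even; taps = order + 1).
#' @param target_rate Analysis sampling rate in samples/s.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(comb_base_hz = 50, comb_q = 35,
                        bandpass_hz = c(20, 1000),
                        fir_order = 4800, target_rate = 4800) {
  stopifnot(bandpass_hz[1] > 0, bandpass_hz[1] < bandpass_hz[2],
            bandpass_hz[2] < target_rate / 2,
            fir_order %% 2 == 0)
  structure(list(comb_base_hz = comb_base_hz, comb_q = comb_q,
                 bandpass_hz = bandpass_hz, fir_order = as.integer(fir_order),
                 target_rate = target_rate),
            class = "filter_spec")
}

#' Derive bipolar PAM signals from a unipolar recording
#'
#' Per muscle, the difference potential between its two unipolar electrodes
#' (`pam_<side>_1 - pam_<side>_2`); common-mode components cancel exactly.
#'
#' @param rec A `pam_recording`.
#' @return List with `left`, `right` (numeric vectors), `rate`, `events`,
#'   `attended`.
#' @export
bipolar_derive <- function(rec) {
  need <- c("pam_left_1", "pam_left_2", "pam_right_1", "pam_right_2")
  missing <- setdiff(need, colnames(rec$channels))
  if (length(missing)) {
    stop("missing channel role(s): ", paste(missing, collapse = ", "))
  }
  list(left = rec$channels[, "pam_left_1"] - rec$channels[, "pam_left_2"],
       right = rec$channels[, "pam_right_1"] - rec$channels[, "pam_right_2"],
       rate = rec$rate, events = rec$events, attended = rec$attended)
}

# linear-phase FIR applied with exact group-delay compensation via FFT
# overlap-free convolution (single FFT; signals here fit in memory)
fft_fir <- function(x, h) {
  n <- length(x); m <- length(h)
  nf <- stats::nextn(n + m - 1, c(2, 3, 5))
  y <- Re(stats::fft(stats::fft(c(x, rep(0, nf - n))) *
                       stats::fft(c(h, rep(0, nf - m))), inverse = TRUE)) / nf
  d <- (m - 1) / 2
  y[(1 + d):(n + d)]
}

reflect_pad <- function(x, p) {
  p <- min(p, length(x) - 1)
  c(2 * x[1] - x[(p + 1):2], x, 2 * x[length(x)] - x[(length(x) - 1):(length(x) - p)])
}

#' Resample a signal to the analysis rate with anti-aliasing
#'
#' Integer-factor decimation: a Blackman windowed-sinc low-pass with cutoff
#' at 90% of the target Nyquist (applied with zero phase via group-delay
#' compensation) precedes sample picking. Content above the target Nyquist is
#' suppressed by >= 60 dB. Upsampling is not supported (the pipeline never
#' needs it).
#'
#' @param x Numeric signal.
#' @param from_rate,to_rate Sampling rates in samples/s; `from_rate` must be
#'   an integer multiple of `to_rate`.
#' @param events Optional event data.frame whose `onset_sample` /
#'   `timezero_sample` columns are rescaled.
#' @return The resampled signal, or `list(signal, events)` when `events` is
#'   given.
#' @export
resample_to_target <- function(x, from_rate, to_rate = 4800, events = NULL) {
  if (to_rate > from_rate) stop("upsampling not supported (", from_rate,
                                " -> ", to_rate, ")")
  if (from_rate %% to_rate != 0) {
    stop("from_rate must be an integer multiple of to_rate")
  }
  factor <- from_rate / to_rate
  if (factor > 1) {
    cutoff <- 0.45 * to_rate                      # 90% of target Nyquist
    ntaps <- ceiling(5.5 * from_rate / (0.05 * to_rate))
    if (ntaps %% 2 == 0) ntaps <- ntaps + 1
    k <- seq_len(ntaps) - (ntaps + 1) / 2
    h <- 2 * cutoff / from_rate * sinc_(2 * cutoff / from_rate * k)
    w <- 0.42 - 0.5 * cos(2 * pi * (seq_len(ntaps) - 1) / (ntaps - 1)) +
      0.08 * cos(4 * pi * (seq_len(ntaps) - 1) / (ntaps - 1))
    h <- h * w
    h <- h / sum(h)
    pad <- ntaps
    xp <- reflect_pad(x, pad)
    y <- fft_fir(xp, h)[(pad + 1):(pad + length(x))]
    x <- y[seq(1, length(y), by = factor)]
  }
  if (is.null(events)) return(x)
  ev <- events
  for (col in intersect(c("onset_sample", "timezero_sample"), names(ev))) {
    ev[[col]] <- as.integer(round((ev[[col]] - 1) / factor) + 1)
  }
  list(signal = x, events = ev)
}

sinc_ <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# notching-comb coefficients: zeros at all multiples of base (incl. DC,
# removed anyway by the band-pass), poles pulled inside for the -3 dB width
# base/Q
comb_coefficients <- function(rate, base_hz, q) {
  N <- rate / base_hz
  if (N != round(N)) stop("comb alignment undefined: sampling rate ", rate,
                          " is not an integer multiple of ", base_hz, " Hz")
  N <- as.integer(N)
  bw <- base_hz / q                               # -3 dB width in Hz
  theta <- N * pi * bw / rate                     # half-width in N*omega
  a <- (1 - tan(theta / 2)) / (1 + tan(theta / 2))
  b0 <- (1 + a) / 2
  list(b = c(b0, rep(0, N - 1), -b0), a = c(1, rep(0, N - 1), -a), N = N)
}

#' Comb-notch power-line removal (zero phase)
#'
#' IIR notching comb with notches at the power-line fundamental and every
#' harmonic up to Nyquist, applied forward and backward so the net phase is
#' zero. The sampling rate must be an integer multiple of the fundamental so
#' the notches align exactly with the harmonics.
#'
#' @param x Numeric signal.
#' @param rate Sampling rate in samples/s.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length.
#' @export
comb_notch <- function(x, rate, spec = filter_spec()) {
  co <- comb_coefficients(rate, spec$comb_base_hz, spec$comb_q)
  pad <- min(3L * spec$fir_order, length(x) - 1L)
  xp <- reflect_pad(x, pad)
  y <- signal::filter(co$b, co$a, xp)
  y <- rev(signal::filter(co$b, co$a, rev(y)))
  unclass(y)[(pad + 1):(pad + length(x))]
}

#' Zero-phase FIR band-pass
#'
#' Linear-phase FIR band-pass (Hamming windowed-sinc of the specified order)
#' applied forward and backward: the result equals filtering with the
#' magnitude-squared response and has exactly zero phase. Edges are handled
#' by reflection padding of three filter lengths, so start-up transients stay
#' outside the retained samples.
#'
#' @param x Numeric signal, longer than `3 * fir_order`.
#' @param rate Sampling rate in samples/s.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length.
#' @export
bandpass_zero_phase <- function(x, rate, spec = filter_spec()) {
  if (length(x) <= 3 * spec$fir_order) {
    stop("signal too short for zero-phase filtering: need > ",
         3 * spec$fir_order, " samples, got ", length(x))
  }
  h <- signal::fir1(spec$fir_order, spec$bandpass_hz / (rate / 2), type = "pass")
  pad <- 3L * spec$fir_order
  xp <- reflect_pad(x, pad)
  n <- length(xp)
  nf <- stats::nextn(n + 2 * length(h), c(2, 3, 5))
  H <- stats::fft(c(h, rep(0, nf - length(h))))
  # |H|^2 is real, so the combined forward-backward response has zero phase
  # and no group delay
  y <- Re(stats::fft(stats::fft(c(xp, rep(0, nf - n))) * (Mod(H)^2),
                     inverse = TRUE)) / nf
  y[(pad + 1):(pad + length(x))]
}

# per-process cache of frequency responses keyed by FFT size and spec
.resp_cache <- new.env(parent = emptyenv())

# zero-phase comb + band-pass applied in one frequency-domain pass: the
# response is |H_comb|^2 * |H_fir|^2, i.e. exactly the forward-backward
# cascade of comb_notch() and bandpass_zero_phase() up to boundary
# transients, which the shared reflection padding absorbs
condition_bipolar <- function(x, rate, spec) {
  pad <- min(3L * spec$fir_order, length(x) - 1L)
  xp <- reflect_pad(x, pad)
  n <- length(xp)
  nf <- stats::nextn(n, c(2, 3, 5))
  key <- paste(nf, rate, spec$comb_base_hz, spec$comb_q,
               spec$bandpass_hz[1], spec$bandpass_hz[2], spec$fir_order,
               sep = "|")
  resp <- .resp_cache[[key]]
  if (is.null(resp)) {
    co <- comb_coefficients(rate, spec$comb_base_hz, spec$comb_q)
    w <- 2 * pi * (seq_len(nf) - 1) / nf
    comb_mag2 <- (co$b[1]^2 * (2 - 2 * cos(co$N * w))) /
      (1 + co$a[co$N + 1]^2 + 2 * co$a[co$N + 1] * cos(co$N * w))
    h <- signal::fir1(spec$fir_order, spec$bandpass_hz / (rate / 2),
                      type = "pass")
    fir_mag2 <- Mod(stats::fft(c(h, rep(0, nf - length(h)))))^2
    resp <- comb_mag2 * fir_mag2
    .resp_cache[[key]] <- resp
  }
  y <- Re(stats::fft(stats::fft(c(xp, rep(0, nf - n))) * resp,
                     inverse = TRUE)) / nf
  y[(pad + 1):(pad + length(x))]
}

#' Run the full conditioning chain on one recording
#'
#' Bipolar derivation, resampling to the target rate, comb notch, zero-phase
#' band-pass, for both PAMs; event sample indices are recomputed at the
#' target rate from the event times. The comb and band-pass responses are
#' applied in a single fused frequency-domain pass equivalent to the
#' individual zero-phase operators.
#'
#' @param rec A `pam_recording`.
#' @param spec A [filter_spec()].
#' @return List with `left`, `right` (conditioned bipolar signals at
#'   `spec$target_rate`), `rate`, `events`, `attended`.
#' @export
preprocess_recording <- function(rec, spec = filter_spec()) {
  bp <- bipolar_derive(rec)
  out <- lapply(bp[c("left", "right")], function(x) {
    x <- resample_to_target(x, rec$rate, spec$target_rate)
    condition_bipolar(x, spec$target_rate, spec)
  })
  ev <- bp$events
  ev$onset_sample <- round(ev$onset_s * spec$target_rate) + 1L
  ev$timezero_sample <- round((ev$onset_s + timezero_offset_s(ev$kind)) *
                                spec$target_rate) + 1L
  list(left = out$left, right = out$right, rate = spec$target_rate,
       events = ev, attended = bp$attended)
}
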