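#' Extract stimulus-locked epochs from a conditioned bipolar signal
#'
#' Epochs are time-locked to each event's analysis time-zero (chirp offset
#' for chirps, end of the rise time for tone bursts; see
#' [timezero_offset_s()]) with a half-open window, by default
#' `[-1000, 1000)` ms. Events whose window would exceed the recording are
#' dropped and counted in the attribute `n_dropped`.
#'
#' @param x Conditioned bipolar signal (one PAM).
#' @param events Event data.frame carrying `timezero_sample` (1-based),
#'   `ear`, `kind`, `is_deviant` — e.g. from [preprocess_recording()].
#' @param rate Sampling rate of `x` in samples/s.
#' @param pam_side,attended_side,trial Labels stored with every epoch.
#' @param window_ms Length-2 numeric window in ms relative to time-zero.
#' @return An `epoch_set`: list with `epochs` (samples x epochs matrix),
#'   `time_ms`, `rate`, and `labels` (one row per epoch: `trial`,
#'   `event_index`, `pam_side`, `stim_side`, `attended_side`, `kind`,
#'   `stim_class` in standard/deviant).
#' @export
extract_epochs <- function(x, events, rate, pam_side, attended_side,
                           trial = 1L, window_ms = c(-1000, 1000)) {
  w_pre <- round(-window_ms[1] / 1000 * rate)
  w_post <- round(window_ms[2] / 1000 * rate)
  idx0 <- events$timezero_sample
  ok <- (idx0 - w_pre) >= 1 & (idx0 + w_post - 1) <= length(x)
  n_dropped <- sum(!ok)
  events <- events[ok, , drop = FALSE]
  idx0 <- idx0[ok]
  if (!nrow(events)) {
    warning("no qualifying events in window")
  }
  rel <- seq.int(-w_pre, w_post - 1L)
  ep <- matrix(x[outer(rel, idx0, "+")], nrow = length(rel))
  labels <- data.frame(
    trial = trial, event_index = which(ok),
    pam_side = pam_side, stim_side = events$ear,
    attended_side = attended_side, kind = events$kind,
    stim_class = ifelse(events$is_deviant, "deviant", "standard"),
    stringsAsFactors = FALSE)
  out <- structure(list(epochs = ep, time_ms = rel / rate * 1000, rate = rate,
                        labels = labels),
                   class = "epoch_set")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Concatenate epoch sets (e.g. across trials)
#' @param sets List of `epoch_set`s sharing the same window and rate.
#' @return A single `epoch_set`.
#' @export
bind_epoch_sets <- function(sets) {
  sets <- Filter(function(s) ncol(s$epochs) > 0, sets)
  stopifnot(length(sets) > 0)
  out <- sets[[1]]
  out$epochs <- do.call(cbind, lapply(sets, `[[`, "epochs"))
  out$labels <- do.call(rbind, lapply(sets, `[[`, "labels"))
  rownames(out$labels) <- NULL
  out
}

#' Linearly detrend and baseline-correct epochs
#'
#' Removes the least-squares line fitted over the full epoch from every
#' epoch, then subtracts the mean amplitude over the `[-250, 0)` ms baseline
#' window from every sample.
#'
#' @param es An `epoch_set`.
#' @return The corrected `epoch_set`.
#' @export
detrend_and_baseline <- function(es) {
  ep <- es$epochs
  n <- nrow(ep)
  tc <- seq_len(n) - (n + 1) / 2
  slope <- drop(crossprod(tc, ep)) / sum(tc^2)
  inter <- colMeans(ep)
  ep <- ep - outer(tc, slope) - rep(inter, each = n)
  base <- es$time_ms >= -250 & es$time_ms < 0
  stopifnot(any(base))
  ep <- ep - rep(colMeans(ep[base, , drop = FALSE]), each = n)
  es$epochs <- ep
  es
}

#' Per-epoch signal-to-noise ratio in dB
#'
#' `10 log10` of the ratio of sample variances in the 250 ms window
#' immediately after time-zero (expected to encompass the PAM reflex) and the
#' 250 ms window immediately before it.
#'
#' @param es A baseline-corrected `epoch_set`.
#' @return Numeric vector of SNRs in dB, one per epoch (also stored in
#'   `es$labels$snr_db` when assigned by [reject_by_snr()] callers).
#' @export
compute_snr <- function(es) {
  pre <- es$time_ms >= -250 & es$time_ms < 0
  post <- es$time_ms >= 0 & es$time_ms < 250
  v <- function(m) {
    n <- nrow(m)
    (colSums(m^2) - n * colMeans(m)^2) / (n - 1)
  }
  v_pre <- v(es$epochs[pre, , drop = FALSE])
  if (any(v_pre == 0)) stop("degenerate epoch: zero pre-stimulus variance")
  unname(10 * log10(v(es$epochs[post, , drop = FALSE]) / v_pre))
}

#' Retain epochs whose SNR is within three SD of the design mean
#'
#' The mean and standard deviation are computed once over all epochs of the
#' full design (outliers included); an epoch is retained iff its SNR deviates
#' from that mean by at most three standard deviations. Standards and
#' deviants are processed as separate designs by the caller.
#'
#' @param snr_db Numeric vector of per-epoch SNRs.
#' @return Logical retention vector, with the design mean and SD in
#'   attributes `mean` and `sd`.
#' @export
reject_by_snr <- function(snr_db) {
  if (length(snr_db) < 2) stop("need at least 2 epochs to estimate SNR spread")
  m <- mean(snr_db)
  s <- stats::sd(snr_db)
  out <- abs(snr_db - m) <= 3 * s
  attr(out, "mean") <- m
  attr(out, "sd") <- s
  out
}

#' Select the most representative epochs of each design cell
#'
#' Per cell of the design (stimulus side x attended side, within one PAM and
#' stimulus class), the `n_per_cell` retained epochs whose SNRs are closest
#' to the overall mean SNR across retained epochs are selected; ties are
#' broken by ascending presentation index (stable).
#'
#' @param labels Epoch label data.frame with columns `stim_side`,
#'   `attended_side`, `snr_db`, `retained`.
#' @param n_per_cell Number of epochs to select per cell; every cell must
#'   have at least this many retained epochs.
#' @param overall Overall mean SNR to rank against; defaults to the mean over
#'   the retained epochs in `labels`, but callers screening a larger design
#'   (e.g. both PAMs) pass the design-wide mean.
#' @return Logical selection vector aligned with `labels` rows.
#' @export
select_representative <- function(labels, n_per_cell, overall = NULL) {
  ret <- which(labels$retained)
  if (is.null(overall)) overall <- mean(labels$snr_db[ret])
  sel <- logical(nrow(labels))
  cells <- interaction(labels$stim_side, labels$attended_side, drop = FALSE)
  for (cl in levels(cells)) {
    idx <- ret[cells[ret] == cl]
    if (length(idx) < n_per_cell) {
      stop("cell ", cl, " has only ", length(idx),
           " retained epochs; need ", n_per_cell)
    }
    ord <- idx[order(abs(labels$snr_db[idx] - overall), idx)]
    sel[ord[seq_len(n_per_cell)]] <- TRUE
  }
  sel
}

#' Count retained epochs per design cell
#' @param labels Epoch label data.frame with `stim_side`, `attended_side`,
#'   `retained`.
#' @return Named integer vector of per-cell retained counts.
#' @export
retained_cell_counts <- function(labels) {
  cells <- interaction(labels$stim_side, labels$attended_side, drop = FALSE)
  vapply(levels(cells), function(cl) sum(labels$retained & cells == cl),
         integer(1))
}

#' Reflex-based amplitude normalization for one PAM
#'
#' Averages the selected epochs per cell of the 2 x 2 designs for standards
#' and for deviants (eight averaged waveforms), takes the maximum absolute
#' amplitude across all eight averages within the typical PAM reflex peak
#' latency range of 5-30 ms as the global normalization factor, and divides
#' every single epoch of both sets by it. All relative differences within the
#' PAM are preserved because the divisor is common.
#'
#' @param std,dev `epoch_set`s of selected standard and deviant epochs for
#'   one PAM and participant (labels must include `stim_side`,
#'   `attended_side`).
#' @return List with the scaled `std` and `dev` sets and `factor`.
#' @export
reflex_normalize <- function(std, dev) {
  win <- function(es) es$time_ms >= 5 & es$time_ms <= 30
  cell_avgs <- function(es) {
    cells <- interaction(es$labels$stim_side, es$labels$attended_side,
                         drop = FALSE)
    if (nlevels(cells) != 4 || any(table(cells) == 0)) {
      stop("all four stimulus-side x attended-side cells must be present")
    }
    vapply(levels(cells), function(cl) {
      rowMeans(es$epochs[, cells == cl, drop = FALSE])
    }, numeric(nrow(es$epochs)))
  }
  avgs <- cbind(cell_avgs(std), cell_avgs(dev))
  factor <- max(abs(avgs[win(std), ]))
  if (factor <= .Machine$double.eps^0.5) {
    stop("normalization factor is numerically zero: no reflex energy in ",
         "5-30 ms (participant should have failed reliability)")
  }
  std$epochs <- std$epochs / factor
  dev$epochs <- dev$epochs / factor
  list(std = std, dev = dev, factor = factor)
}
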