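#' Moving root-mean-square envelope
#'
#' Centered sliding-window RMS of a signal, same length as the input; edge
#' windows shrink to the available samples (irrelevant downstream because the
#' region of interest starts after the first seconds of each trial).
#'
#' @param x Numeric signal.
#' @param rate Sampling rate in samples/s.
#' @param window_s Window duration in seconds (default 1).
#' @return Nonnegative envelope vector of `length(x)`.
#' @export
rms_envelope <- function(x, rate, window_s = 1) {
  w <- round(window_s * rate)
  stopifnot(w >= 2)
  n <- length(x)
  h1 <- floor((w - 1) / 2)
  h2 <- w - 1 - h1
  cs <- cumsum(c(0, x^2))
  lo <- pmax(seq_len(n) - h1, 1)
  hi <- pmin(seq_len(n) + h2, n)
  sqrt((cs[hi + 1] - cs[lo]) / (hi - lo + 1))
}

#' Trim an envelope to the region of interest and compute segment means
#'
#' The region of interest starts `roi_start_s` after the first stimulus event
#' onset and lasts `roi_dur_s`; it is divided into `n_segments` consecutive,
#' non-overlapping segments whose envelope means are returned. Study values:
#' 5 s offset, 180 s duration, five 36 s segments.
#'
#' @param env Envelope vector (see [rms_envelope()]).
#' @param rate Sampling rate in samples/s.
#' @param first_onset_s Time of the first stimulus event onset in seconds
#'   from the start of `env`.
#' @param roi_start_s Offset of the region of interest after the first onset.
#' @param roi_dur_s Region-of-interest duration in seconds.
#' @param n_segments Number of equal segments.
#' @return Numeric vector of segment means with attribute
#'   `segment_centers_s` (for plotting).
#' @export
trim_and_segment <- function(env, rate, first_onset_s, roi_start_s = 5,
                             roi_dur_s = 180, n_segments = 5) {
  i0 <- round((first_onset_s + roi_start_s) * rate) + 1L
  seg_len <- round(roi_dur_s / n_segments * rate)
  i1 <- i0 + n_segments * seg_len - 1L
  if (i1 > length(env)) {
    stop("envelope too short for the region of interest: need ",
         i1, " samples, have ", length(env))
  }
  seg <- rep(seq_len(n_segments), each = seg_len)
  means <- as.numeric(tapply(env[i0:i1], seg, mean))
  attr(means, "segment_centers_s") <-
    roi_start_s + (seq_len(n_segments) - 0.5) * roi_dur_s / n_segments
  means
}

#' Remove values outside the central 95% percentile range
#'
#' Pooled per PAM and participant, values strictly below the 2.5th or
#' strictly above the 97.5th percentile (linear-interpolation percentile
#' method, R type 7) are flagged as outliers; values equal to a percentile
#' are retained.
#'
#' @param x Numeric vector of pooled segment amplitudes.
#' @return Logical vector, `TRUE` for retained values.
#' @export
remove_percentile_outliers <- function(x) {
  q <- stats::quantile(x, c(0.025, 0.975), type = 7, names = FALSE)
  x >= q[1] & x <= q[2]
}

#' z-score a pooled value set
#'
#' `(x - mean) / SD` over the retained pool, with the sample SD (n - 1
#' denominator). Being a single affine map per pool, it preserves every
#' relative (contrast) effect within the pool.
#'
#' @param x Numeric vector (>= 2 values, nonzero SD).
#' @return z-scored vector.
#' @export
zscore_within <- function(x) {
  stopifnot(length(x) >= 2)
  s <- stats::sd(x)
  if (s == 0) stop("zero standard deviation: cannot z-score")
  (x - mean(x)) / s
}

#' Categorize z-scored segment amplitudes into the tonic design
#'
#' Builds the 2 x 2 x 2 x `n_segments` tonic table of one participant: for
#' each PAM side, the stimulus type delivered to that side (determined by the
#' trial's tone-burst ear), the attended side, and the segment, the retained
#' z-values are averaged across the trials contributing to that cell
#' (five per cell in the full design).
#'
#' @param df Data.frame with one row per retained segment value and columns
#'   `pam_side`, `tone_ear`, `attended_side`, `segment`, `trial`, `z`.
#' @return A tidy `tonic_table` data.frame: `pam_side`, `stim_kind`,
#'   `attended_side`, `segment`, `z_amplitude`, `n_values`.
#' @export
categorize <- function(df) {
  df$stim_kind <- ifelse(df$pam_side == df$tone_ear, "tone_burst", "chirp")
  agg <- stats::aggregate(z ~ pam_side + stim_kind + attended_side + segment,
                          data = df, FUN = mean)
  cnt <- stats::aggregate(z ~ pam_side + stim_kind + attended_side + segment,
                          data = df, FUN = length)
  names(agg)[names(agg) == "z"] <- "z_amplitude"
  agg$n_values <- cnt$z
  n_seg <- length(unique(df$segment))
  if (nrow(agg) != 2 * 2 * 2 * n_seg) {
    stop("empty design cell(s): expected ", 2 * 2 * 2 * n_seg,
         " cells, got ", nrow(agg))
  }
  class(agg) <- c("tonic_table", "data.frame")
  agg
}

#' Reduce a tonic table to the first and last time segments
#'
#' Keeps segments 1 and `max(segment)` as the two levels of the time factor
#' for the repeated-measures analysis.
#'
#' @param table A `tonic_table` (possibly row-bound across participants).
#' @return The reduced table with `segment` recoded to `"first"` / `"last"`.
#' @export
first_last_reduce <- function(table) {
  last <- max(table$segment)
  out <- table[table$segment %in% c(1, last), , drop = FALSE]
  out$segment <- ifelse(out$segment == 1, "first", "last")
  rownames(out) <- NULL
  out
}

#' Ongoing-activity tonic analysis for one participant
#'
#' The primary tonic analysis: per trial and PAM, the 1 s moving-RMS envelope
#' of the conditioned bipolar signal is trimmed to the region of interest and
#' reduced to segment means; per PAM, all segment values are pooled across
#' trials, percentile outliers are removed, the remainder is z-scored, and
#' the values are categorized into the 2 x 2 x 2 x segments design.
#'
#' @param trials List of preprocessed recordings (see
#'   [preprocess_recording()]), one per listening trial.
#' @param schedule Data.frame aligned with `trials`: columns `trial`,
#'   `tone_ear`, `attended`.
#' @param window_s Envelope window in seconds.
#' @param roi_start_s,roi_dur_s,n_segments Region-of-interest parameters
#'   (see [trim_and_segment()]).
#' @return A `tonic_table` for this participant with attribute
#'   `n_outliers_removed` (named per PAM).
#' @export
tonic_ongoing_participant <- function(trials, schedule, window_s = 1,
                                      roi_start_s = 5, roi_dur_s = 180,
                                      n_segments = 5) {
  stopifnot(length(trials) == nrow(schedule))
  rows <- list()
  for (i in seq_along(trials)) {
    pp <- trials[[i]]
    first_onset <- min(pp$events$onset_s)
    for (pam in c("left", "right")) {
      m <- trim_and_segment(rms_envelope(pp[[pam]], pp$rate, window_s),
                            pp$rate, first_onset, roi_start_s, roi_dur_s,
                            n_segments)
      rows[[length(rows) + 1]] <- data.frame(
        trial = schedule$trial[i], pam_side = pam,
        tone_ear = schedule$tone_ear[i], attended_side = schedule$attended[i],
        segment = seq_len(n_segments), amplitude = m)
    }
  }
  df <- do.call(rbind, rows)
  out <- list()
  n_out <- c(left = 0L, right = 0L)
  for (pam in c("left", "right")) {
    sub <- df[df$pam_side == pam, , drop = FALSE]
    keep <- remove_percentile_outliers(sub$amplitude)
    n_out[pam] <- sum(!keep)
    sub <- sub[keep, , drop = FALSE]
    sub$z <- zscore_within(sub$amplitude)
    out[[pam]] <- sub
  }
  tab <- categorize(do.call(rbind, out))
  attr(tab, "n_outliers_removed") <- n_out
  tab
}
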