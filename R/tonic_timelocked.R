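#' Short-window rectified (RMS) chirp-locked epochs
#'
#' Computes the 10 ms moving-RMS envelope of a conditioned bipolar signal —
#' short enough that stimulus-locked components such as the PAM reflex stay
#' localized in time — and epochs it at chirp time-zeros (chirp offsets) with
#' pre- and post-stimulus periods of 100 ms each. Only the single trials
#' whose non-rectified counterparts survived artifact screening are kept:
#' `selected` identifies them by `(trial, event_index)` and every selected
#' pair must be found among the extracted epochs.
#'
#' @param pp A preprocessed recording (see [preprocess_recording()]).
#' @param pam `"left"` or `"right"`.
#' @param trial Trial number for the labels.
#' @param attended_side Attended side for the labels.
#' @param selected Data.frame with `trial`, `event_index` of the retained
#'   non-rectified epochs (may span several trials; rows for other trials are
#'   ignored).
#' @param window_s Envelope window in seconds (default 0.010).
#' @param window_ms Epoch window (default `c(-100, 100)` ms).
#' @return An `epoch_set` of rectified epochs.
#' @export
rectified_epochs <- function(pp, pam, trial, attended_side, selected,
                             window_s = 0.010, window_ms = c(-100, 100)) {
  env <- rms_envelope(pp[[pam]], pp$rate, window_s)
  ev <- pp$events[pp$events$kind == "chirp", , drop = FALSE]
  es <- extract_epochs(env, ev, pp$rate, pam_side = pam,
                       attended_side = attended_side, trial = trial,
                       window_ms = window_ms)
  # map event_index back to row numbers of the full event table
  es$labels$event_index <- which(pp$events$kind == "chirp")[es$labels$event_index]
  want <- selected[selected$trial == trial, , drop = FALSE]
  keep <- es$labels$event_index %in% want$event_index
  if (sum(keep) != nrow(want)) {
    stop("rectified/non-rectified trial-index mismatch: ",
         nrow(want), " selected epochs, ", sum(keep), " matched")
  }
  es$epochs <- es$epochs[, keep, drop = FALSE]
  es$labels <- es$labels[keep, , drop = FALSE]
  es
}

#' Average rectified epochs per condition and normalize to the baseline
#'
#' For one PAM, epochs are combined across left and right chirp locations and
#' averaged per cell of the 2 x 2 design (attended side x chirp class). Each
#' of the four averaged waveforms is then z-normalized with the mean and
#' standard deviation of the concatenated pre-stimulus samples
#' (`[-100, 0)` ms) of all four averages — one shared affine map, so all
#' relative attention effects within the PAM are preserved. No subtractive
#' per-epoch baseline correction is applied here.
#'
#' @param es `epoch_set` of rectified chirp epochs for one PAM (labels with
#'   `attended_side`, `stim_class`).
#' @return List with `waveforms` (samples x 4 matrix, columns
#'   `<attended>_<class>`), `time_ms`, `n_epochs` (per cell), and the
#'   normalization `mean` and `sd`.
#' @export
average_and_normalize <- function(es) {
  cells <- interaction(es$labels$attended_side, es$labels$stim_class,
                       sep = "_", drop = FALSE)
  if (any(table(cells) == 0)) stop("empty attended x chirp-class cell")
  avg <- vapply(levels(cells), function(cl) {
    rowMeans(es$epochs[, cells == cl, drop = FALSE])
  }, numeric(nrow(es$epochs)))
  pre <- es$time_ms >= -100 & es$time_ms < 0
  m <- mean(avg[pre, ])
  s <- stats::sd(as.vector(avg[pre, ]))
  if (s <= .Machine$double.eps^0.5) stop("degenerate pre-stimulus baseline")
  list(waveforms = (avg - m) / s, time_ms = es$time_ms,
       n_epochs = as.integer(table(cells)), mean = m, sd = s)
}

#' Toward/away pre-stimulus contrast for one participant
#'
#' From the normalized per-PAM 2 x 2 averages, computes for each chirp class
#' the mean normalized pre-stimulus amplitude (`[-100, 0)` ms) with attention
#' directed toward versus away from the PAM's side, averaged over the two
#' PAMs. These per-participant summaries feed the within-subject paired
#' t-tests.
#'
#' @param norm Named list `left` / `right` of [average_and_normalize()]
#'   outputs.
#' @return Data.frame: `stim_class`, `toward`, `away`, `contrast`.
#' @export
prestim_contrast <- function(norm) {
  out <- lapply(c("standard", "deviant"), function(cls) {
    vals <- vapply(c("left", "right"), function(pam) {
      w <- norm[[pam]]
      pre <- w$time_ms >= -100 & w$time_ms < 0
      toward <- mean(w$waveforms[pre, paste0(pam, "_", cls)])
      other <- setdiff(c("left", "right"), pam)
      away <- mean(w$waveforms[pre, paste0(other, "_", cls)])
      c(toward = toward, away = away)
    }, numeric(2))
    data.frame(stim_class = cls, toward = mean(vals["toward", ]),
               away = mean(vals["away", ]),
               contrast = mean(vals["toward", ]) - mean(vals["away", ]))
  })
  do.call(rbind, out)
}
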