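#' Split-half reliability of one design cell's reflex waveform
#'
#' Splits the cell's epochs into odd- and even-indexed sets by 1-based
#' presentation order, averages each set, and correlates the two averages
#' (Pearson) within the PAM reflex latency range of 5-30 ms. A reliable
#' reflex yields highly similar averages and hence a large positive r.
#'
#' @param epochs Samples x epochs matrix (presentation order in columns).
#' @param time_ms Time axis in ms relative to time-zero.
#' @return Pearson r in `[-1, 1]`, or `-Inf` when either average has zero
#'   variance over the window (undefined correlation, reported as a
#'   fail-value distinct from -1).
#' @export
half_split_r <- function(epochs, time_ms) {
  stopifnot(ncol(epochs) >= 2)
  win <- time_ms >= 5 & time_ms <= 30
  odd <- rowMeans(epochs[win, seq(1, ncol(epochs), by = 2), drop = FALSE])
  even <- rowMeans(epochs[win, seq(2, ncol(epochs), by = 2), drop = FALSE])
  if (stats::sd(odd) == 0 || stats::sd(even) == 0) return(-Inf)
  stats::cor(odd, even)
}

#' Certify a participant's PAM recordings by split-half reliability
#'
#' Computes [half_split_r()] for each of the eight standard-stimulus cells
#' (2 PAMs x 2 stimulus sides x 2 attended sides) and certifies the
#' participant when at least `min_pass` of the eight pooled cells reach
#' `r >= r_threshold`. The default 6-of-8 rule forces at least two passing
#' cells per PAM, so both muscles must contribute trustworthy recordings.
#'
#' @param sets Named list `left` / `right` of `epoch_set`s holding the
#'   retained standard epochs of each PAM (labels with `stim_side`,
#'   `attended_side`).
#' @param r_threshold Per-cell correlation criterion (default 0.4).
#' @param min_pass Minimum number of passing cells (default 6 of 8).
#' @param participant Identifier stored in the report.
#' @return A `reliability_report`: one-row data.frame with the participant,
#'   the eight per-cell correlations (`r_<pam>_<stim>_<attended>`), `n_pass`
#'   and `passed`.
#' @export
certify_participant <- function(sets, r_threshold = 0.4, min_pass = 6L,
                                participant = NA) {
  stopifnot(all(c("left", "right") %in% names(sets)))
  rs <- numeric(0)
  for (pam in c("left", "right")) {
    es <- sets[[pam]]
    for (stim in c("left", "right")) {
      for (att in c("left", "right")) {
        sel <- es$labels$stim_side == stim & es$labels$attended_side == att
        if (!any(sel)) stop("missing cell: pam=", pam, " stim=", stim,
                            " attended=", att)
        r <- half_split_r(es$epochs[, sel, drop = FALSE], es$time_ms)
        rs[paste("r", pam, stim, att, sep = "_")] <- r
      }
    }
  }
  n_pass <- sum(rs >= r_threshold)
  out <- data.frame(participant = participant, t(rs), n_pass = n_pass,
                    passed = n_pass >= min_pass)
  class(out) <- c("reliability_report", "data.frame")
  out
}
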