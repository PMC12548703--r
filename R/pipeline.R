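#' Study configuration
#'
#' Single source of truth for a simulated study run: design sizes, generator
#' parameters, filter chain, analysis windows and thresholds. The defaults
#' are the full study conditions (9,600 Hz acquisition, 4,800 Hz analysis
#' rate, 600-event sequences, a 180 s region of interest starting 5 s after
#' the first onset). `scaled_study_config()` provides the reduced
#' simulation-study sizes used for parameter-recovery runs.
#'
#' @param n_participants Number of participants.
#' @param master_seed Integer master seed for all randomness.
#' @param n_events Events per stimulus sequence.
#' @param base_params An [emg_model_params()] population center.
#' @param rms_cv,reflex_cv Between-participant CVs for
#'   [default_params_sampler()].
#' @param fspec A [filter_spec()].
#' @param epoch_window_ms Non-rectified epoch window in ms.
#' @param roi_start_s,roi_dur_s,n_segments Tonic region-of-interest settings.
#' @param env_window_s Envelope window for the ongoing tonic analysis.
#' @param rect_window_s Envelope window for the time-locked tonic analysis.
#' @param r_threshold,min_pass Reliability certification rule.
#' @param n_per_cell Representative epochs per cell; `NULL` means derive the
#'   study-level minimum across cells and participants.
#' @param alpha Significance threshold.
#' @return A `study_config` list.
#' @export
study_config <- function(n_participants = 17, master_seed = 1L,
                         n_events = 600,
                         base_params = emg_model_params(),
                         rms_cv = 0.3, reflex_cv = 0.3,
                         fspec = filter_spec(),
                         epoch_window_ms = c(-1000, 1000),
                         roi_start_s = 5, roi_dur_s = 180, n_segments = 5,
                         env_window_s = 1, rect_window_s = 0.010,
                         r_threshold = 0.4, min_pass = 6L,
                         n_per_cell = NULL, alpha = 0.05) {
  structure(as.list(environment()), class = "study_config")
}

#' Reduced-size study configuration for simulation studies
#'
#' One-third-scale trials (200 events, about 65 s each; 60 s region of
#' interest in five 12 s segments) simulated at 1,200 Hz and analyzed at
#' 600 Hz with a proportionally scaled filter chain (20-250 Hz band, order
#' 600, 50 Hz comb). Used for replicate parameter-recovery studies where the
#' full acquisition rate would add cost but no information.
#'
#' @param n_participants,master_seed,... Passed to [study_config()].
#' @return A `study_config`.
#' @export
scaled_study_config <- function(n_participants = 17, master_seed = 1L, ...) {
  base <- emg_model_params(rate = 1200, noise_band_hz = c(20, 250),
                           attention_gain = 0.3, decay_tau_s = 150)
  study_config(n_participants = n_participants, master_seed = master_seed,
               n_events = 200, base_params = base,
               fspec = filter_spec(bandpass_hz = c(20, 250), fir_order = 600,
                                   target_rate = 600),
               roi_start_s = 5 / 3, roi_dur_s = 60, ...)
}

#' Score target detections from button presses
#'
#' Greedy earliest-first one-to-one matching: presses are visited in
#' ascending time and matched to the earliest yet-unmatched target whose
#' response window (`[0.050, 1.500]` s after target onset) contains the
#' press. Unmatched presses are false alarms; a target is matched by at most
#' one press.
#'
#' @param presses Nonnegative, sorted press times in seconds.
#' @param targets Nonnegative, sorted target (deviant) onset times in
#'   seconds.
#' @param window_s Length-2 response window after target onset.
#' @return List with `n_hits`, `n_targets`, `hit_rate`, `n_false_alarms`,
#'   and `matched` (index of the matched target per press, NA for false
#'   alarms).
#' @export
score_detections <- function(presses, targets, window_s = c(0.050, 1.500)) {
  stopifnot(!is.unsorted(presses), !is.unsorted(targets),
            all(presses >= 0), all(targets >= 0))
  matched <- rep(NA_integer_, length(presses))
  taken <- logical(length(targets))
  for (i in seq_along(presses)) {
    lag <- presses[i] - targets
    ok <- which(!taken & lag >= window_s[1] & lag <= window_s[2])
    if (length(ok)) {
      matched[i] <- ok[1]
      taken[ok[1]] <- TRUE
    }
  }
  n_hits <- sum(!is.na(matched))
  list(n_hits = n_hits, n_targets = length(targets),
       hit_rate = if (length(targets)) n_hits / length(targets) else NA_real_,
       n_false_alarms = sum(is.na(matched)), matched = matched)
}

#' Run the per-participant pipeline
#'
#' Simulates (or accepts) the participant's 20 listening trials, conditions
#' each recording, accumulates the ongoing-envelope segment table and the
#' chirp-locked non-rectified and rectified epoch sets, performs SNR-based
#' artifact screening, and certifies reliability. Epoch-level follow-ups
#' that need the study-level `n_per_cell` (representative selection, reflex
#' normalization, the time-locked tonic averages) are left to [run_study()],
#' which owns that derivation; single-participant use can pass `n_per_cell`
#' to [participant_timelocked()] directly.
#'
#' @param gt A `study_ground_truth` from [simulate_study()].
#' @param pid Participant index.
#' @param config A [study_config()].
#' @return List with `reliability` (report row), `tonic` (participant
#'   `tonic_table`), per-PAM epoch sets (`epochs`, labels carrying `snr_db`
#'   and `retained`), rectified epoch sets (`rect`), and the per-cell
#'   retained counts for standards and deviants.
#' @export
run_subject <- function(gt, pid, config = study_config()) {
  sched <- gt$schedule
  tonic_rows <- list()
  ep <- list(left = list(), right = list())
  rect <- list(left = list(), right = list())
  for (i in seq_len(nrow(sched))) {
    rec <- trial_recording(gt, pid, sched$trial[i])
    pp <- preprocess_recording(rec, config$fspec)
    rm(rec)
    first_onset <- min(pp$events$onset_s)
    chirps <- pp$events[pp$events$kind == "chirp", , drop = FALSE]
    for (pam in c("left", "right")) {
      m <- trim_and_segment(rms_envelope(pp[[pam]], pp$rate,
                                         config$env_window_s),
                            pp$rate, first_onset, config$roi_start_s,
                            config$roi_dur_s, config$n_segments)
      tonic_rows[[length(tonic_rows) + 1]] <- data.frame(
        trial = sched$trial[i], pam_side = pam, tone_ear = sched$tone_ear[i],
        attended_side = sched$attended[i],
        segment = seq_len(config$n_segments), amplitude = m)
      es <- extract_epochs(pp[[pam]], chirps, pp$rate, pam_side = pam,
                           attended_side = sched$attended[i],
                           trial = sched$trial[i],
                           window_ms = config$epoch_window_ms)
      es$labels$event_index <-
        which(pp$events$kind == "chirp")[es$labels$event_index]
      ep[[pam]][[i]] <- detrend_and_baseline(es)
      env <- rms_envelope(pp[[pam]], pp$rate, config$rect_window_s)
      re <- extract_epochs(env, chirps, pp$rate, pam_side = pam,
                           attended_side = sched$attended[i],
                           trial = sched$trial[i], window_ms = c(-100, 100))
      re$labels$event_index <-
        which(pp$events$kind == "chirp")[re$labels$event_index]
      rect[[pam]][[i]] <- re
    }
  }
  # tonic table: pool per PAM, remove percentile outliers, z-score, categorize
  df <- do.call(rbind, tonic_rows)
  pooled <- list()
  for (pam in c("left", "right")) {
    sub <- df[df$pam_side == pam, , drop = FALSE]
    keep <- remove_percentile_outliers(sub$amplitude)
    sub <- sub[keep, , drop = FALSE]
    sub$z <- zscore_within(sub$amplitude)
    pooled[[pam]] <- sub
  }
  tonic <- categorize(do.call(rbind, pooled))
  # SNR screening over the full 2 x 2 x 2 design (both PAMs pooled),
  # separately for standards and deviants
  counts <- list()
  sets <- lapply(ep, bind_epoch_sets)
  for (pam in c("left", "right")) {
    sets[[pam]]$labels$snr_db <- compute_snr(sets[[pam]])
    sets[[pam]]$labels$retained <- NA
  }
  overall_snr <- list()
  for (cls in c("standard", "deviant")) {
    sel <- lapply(sets, function(es) es$labels$stim_class == cls)
    pooled <- c(sets$left$labels$snr_db[sel$left],
                sets$right$labels$snr_db[sel$right])
    ret <- reject_by_snr(pooled)
    split_at <- sum(sel$left)
    sets$left$labels$retained[sel$left] <- ret[seq_len(split_at)]
    sets$right$labels$retained[sel$right] <- ret[-seq_len(split_at)]
    overall_snr[[cls]] <- mean(pooled[ret])
    for (pam in c("left", "right")) {
      counts[[paste(pam, cls, sep = ".")]] <- retained_cell_counts(
        sets[[pam]]$labels[sel[[pam]], , drop = FALSE])
    }
  }
  std_sets <- lapply(sets, function(es) {
    keep <- es$labels$stim_class == "standard" & es$labels$retained
    es$epochs <- es$epochs[, keep, drop = FALSE]
    es$labels <- es$labels[keep, , drop = FALSE]
    es
  })
  rel <- certify_participant(std_sets, config$r_threshold, config$min_pass,
                             participant = pid)
  list(reliability = rel, tonic = tonic, epochs = sets,
       rect = lapply(rect, bind_epoch_sets), counts = counts,
       overall_snr = overall_snr)
}

#' Representative selection, normalization and time-locked tonic analysis
#'
#' Completes the epoch-level follow-ups for one screened participant once
#' `n_per_cell` is known: selects the representative standard and deviant
#' epochs per cell, reflex-normalizes each PAM, restricts the rectified
#' epochs to the selected trials, and returns the normalized time-locked
#' averages and the pre-stimulus toward/away contrast.
#'
#' @param subj Output of [run_subject()].
#' @param n_per_cell Named list or vector with `standard` and `deviant`
#'   counts.
#' @return List with per-PAM `norm` (normalized rectified averages),
#'   `prestim` ([prestim_contrast()] output), `factors` (reflex normalization
#'   factor per PAM), and the selected epoch sets.
#' @export
participant_timelocked <- function(subj, n_per_cell) {
  norm <- list()
  factors <- c(left = NA_real_, right = NA_real_)
  selected_sets <- list()
  for (pam in c("left", "right")) {
    es <- subj$epochs[[pam]]
    sel_idx <- logical(nrow(es$labels))
    for (cls in c("standard", "deviant")) {
      lab <- es$labels
      lab$retained <- lab$retained & lab$stim_class == cls
      sel_idx <- sel_idx | (select_representative(lab, n_per_cell[[cls]],
                                                  subj$overall_snr[[cls]]) &
                              lab$stim_class == cls)
    }
    pick <- function(set, keep) {
      set$epochs <- set$epochs[, keep, drop = FALSE]
      set$labels <- set$labels[keep, , drop = FALSE]
      set
    }
    std <- pick(es, sel_idx & es$labels$stim_class == "standard")
    dev <- pick(es, sel_idx & es$labels$stim_class == "deviant")
    nrm <- reflex_normalize(std, dev)
    factors[pam] <- nrm$factor
    selected_sets[[pam]] <- list(std = nrm$std, dev = nrm$dev)
    re <- subj$rect[[pam]]
    sel_pairs <- rbind(std$labels[, c("trial", "event_index")],
                       dev$labels[, c("trial", "event_index")])
    keep <- interaction(re$labels$trial, re$labels$event_index) %in%
      interaction(sel_pairs$trial, sel_pairs$event_index)
    if (sum(keep) != nrow(sel_pairs)) {
      stop("rectified/non-rectified selection mismatch")
    }
    norm[[pam]] <- average_and_normalize(pick(re, keep))
  }
  list(norm = norm, prestim = prestim_contrast(norm), factors = factors,
       selected = selected_sets)
}

#' Run a full simulated study end to end
#'
#' Simulates every participant, applies the reliability gate, derives the
#' study-level `n_per_cell` (the smallest count of artifact-free epochs
#' across cells and certified participants, separately for standards and
#' deviants), runs the ongoing and time-locked tonic analyses, and computes
#' the within-subject statistics: one 2 x 2 x 2 repeated-measures ANOVA per
#' stimulus type (PAM location x listening condition x time) and paired
#' t-tests on the pre-stimulus toward/away contrasts. Ground truth is used
#' only for simulation, never read by the analysis.
#'
#' @param config A [study_config()].
#' @param gt Optional pre-built `study_ground_truth` (defaults to simulating
#'   one from the config).
#' @return A result bundle: `reliability` (table), `included`, `n_per_cell`,
#'   `tonic` (study tonic table), `anova` (named list per stimulus type),
#'   `prestim` (per-participant contrasts), `t_tests` (per chirp class),
#'   `factors` (reflex normalization factors), `config`.
#' @export
run_study <- function(config = study_config(), gt = NULL) {
  if (is.null(gt)) {
    gt <- simulate_study(config$n_participants,
                         default_params_sampler(config$base_params,
                                                config$rms_cv,
                                                config$reflex_cv),
                         master_seed = config$master_seed,
                         n_events = config$n_events)
  }
  subjects <- lapply(seq_len(config$n_participants), function(pid) {
    run_subject(gt, pid, config)
  })
  rel <- do.call(rbind, lapply(subjects, `[[`, "reliability"))
  included <- which(rel$passed)
  if (!length(included)) {
    stop("all participants failed the reliability gate; per-cell r summary:\n",
         paste(utils::capture.output(print(summary(rel))), collapse = "\n"))
  }
  n_per_cell <- config$n_per_cell
  if (is.null(n_per_cell)) {
    cnt <- unlist(lapply(subjects[included], `[[`, "counts"))
    n_per_cell <- list(
      standard = min(cnt[grepl("standard", names(cnt))]),
      deviant = min(cnt[grepl("deviant", names(cnt))]))
  }
  tonic <- do.call(rbind, lapply(included, function(pid) {
    tab <- subjects[[pid]]$tonic
    tab$participant <- pid
    tab
  }))
  reduced <- first_last_reduce(tonic)
  anova <- lapply(c(tone_burst = "tone_burst", chirp = "chirp"), function(k) {
    rm_anova_2x2x2(anova_input_from_tonic(reduced, k),
                   value = "value", subject = "subject",
                   factors = c("pam", "condition", "time"))
  })
  tl <- lapply(subjects[included], participant_timelocked, n_per_cell)
  prestim <- do.call(rbind, lapply(seq_along(tl), function(j) {
    d <- tl[[j]]$prestim
    d$participant <- included[j]
    d
  }))
  t_tests <- lapply(c(standard = "standard", deviant = "deviant"),
                    function(cls) {
    d <- prestim[prestim$stim_class == cls, ]
    paired_t(d$toward, d$away)
  })
  list(reliability = rel, included = included, n_per_cell = n_per_cell,
       tonic = tonic, anova = anova, prestim = prestim, t_tests = t_tests,
       factors = t(vapply(tl, `[[`, numeric(2), "factors")),
       timelocked = tl, config = config)
}
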