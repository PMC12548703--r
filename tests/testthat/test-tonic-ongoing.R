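test_that("moving RMS reproduces closed-form envelopes", {
  expect_equal(rms_envelope(rep(-3, 1000), 600, 1), rep(3, 1000))
  t <- (0:47999) / 4800
  env <- rms_envelope(2 * sin(2 * pi * 100 * t), 4800, 1)
  mid <- 4800:43200
  expect_equal(mean(env[mid]), 2 / sqrt(2), tolerance = 1e-3)
  expect_true(all(env >= 0))
})

test_that("segmenting averages the region of interest piecewise", {
  rate <- 600
  # constant envelope
  env <- rep(4, (5 + 180 + 1) * rate)
  m <- trim_and_segment(env, rate, first_onset_s = 0)
  expect_equal(as.numeric(m), rep(4, 5))
  expect_equal(attr(m, "segment_centers_s"), 5 + (1:5 - 0.5) * 36)
  # piecewise constant: c1 on first 90 s of the ROI, c2 after
  env2 <- rep(1, (5 + 180 + 1) * rate)
  roi0 <- 5 * rate
  env2[(roi0 + 90 * rate + 1):length(env2)] <- 3
  m2 <- trim_and_segment(env2, rate, first_onset_s = 0)
  expect_equal(as.numeric(m2), c(1, 1, 2, 3, 3))
  expect_error(trim_and_segment(rep(1, 100), rate, 0), "too short")
})

test_that("percentile outlier removal uses the linear-interpolation method", {
  # independent arithmetic: for 1..100, type-7 quantiles are
  # q2.5 = 1 + 0.025 * 99 = 3.475 and q97.5 = 1 + 0.975 * 99 = 97.525,
  # so 1,2,3 and 98,99,100 fall strictly outside and 94 values remain
  keep <- remove_percentile_outliers(1:100)
  expect_equal(sum(keep), 94)
  expect_equal(which(!keep), c(1, 2, 3, 98, 99, 100))
  # all equal -> nothing removed
  expect_true(all(remove_percentile_outliers(rep(5, 50))))
  # translation equivariance
  set.seed(4)
  x <- stats::rnorm(200)
  expect_identical(remove_percentile_outliers(x),
                   remove_percentile_outliers(x + 100))
})

test_that("z-scoring is the sample-SD affine map", {
  set.seed(5)
  x <- stats::rlnorm(50)
  z <- zscore_within(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  expect_identical(order(z), order(x))
  expect_error(zscore_within(rep(1, 10)), "zero standard deviation")
})

test_that("categorization averages trials per cell and is order-invariant", {
  # full design: 20 trials (5 per tone_ear x attended), 5 segments, 2 PAMs
  sched <- expand.grid(rep_i = 1:5, tone_ear = c("left", "right"),
                       attended = c("left", "right"),
                       stringsAsFactors = FALSE)
  sched$trial <- seq_len(nrow(sched))
  rows <- list()
  delta <- 0.7
  for (i in seq_len(nrow(sched))) {
    for (pam in c("left", "right")) {
      for (seg in 1:5) {
        z <- ifelse(sched$attended[i] == pam, delta, 0)
        rows[[length(rows) + 1]] <- data.frame(
          trial = sched$trial[i], pam_side = pam,
          tone_ear = sched$tone_ear[i], attended_side = sched$attended[i],
          segment = seg, z = z)
      }
    }
  }
  df <- do.call(rbind, rows)
  tab <- categorize(df)
  expect_equal(nrow(tab), 40)
  expect_true(all(tab$n_values == 5))
  # attended-ipsilateral cells carry +delta
  toward <- tab$attended_side == tab$pam_side
  expect_equal(unique(tab$z_amplitude[toward]), delta)
  expect_equal(unique(tab$z_amplitude[!toward]), 0)
  # permuting trial order leaves cell means unchanged
  tab2 <- categorize(df[sample(nrow(df)), ])
  expect_equal(tab2, tab)
  # first/last reduction keeps segments 1 and 5
  red <- first_last_reduce(tab)
  expect_equal(nrow(red), 16)
  expect_setequal(unique(red$segment), c("first", "last"))
  expect_equal(red$z_amplitude[red$segment == "first"],
               tab$z_amplitude[tab$segment == 1])
})

test_that("end-to-end tonic analysis recovers attention and decay directions", {
  cfg <- scaled_study_config(n_participants = 2, master_seed = 21)
  gt <- simulate_study(2, default_params_sampler(cfg$base_params),
                       cfg$master_seed, n_events = cfg$n_events)
  trials <- lapply(gt$schedule$trial, function(tr) {
    preprocess_recording(trial_recording(gt, 1, tr), cfg$fspec)
  })
  tab <- tonic_ongoing_participant(trials, gt$schedule,
                                   roi_start_s = cfg$roi_start_s,
                                   roi_dur_s = cfg$roi_dur_s)
  toward <- tab$attended_side == tab$pam_side
  expect_gt(mean(tab$z_amplitude[toward]), mean(tab$z_amplitude[!toward]))
  expect_gt(mean(tab$z_amplitude[tab$segment == 1]),
            mean(tab$z_amplitude[tab$segment == 5]))
})

test_that("with no attention gain and no decay the cell means are near zero", {
  base <- emg_model_params(rate = 1200, noise_band_hz = c(20, 250),
                           attention_gain = 0, decay_tau_s = 1e9)
  cfg <- scaled_study_config(n_participants = 2, master_seed = 22)
  cfg$base_params <- base
  gt <- simulate_study(2, default_params_sampler(base), 22,
                       n_events = cfg$n_events)
  trials <- lapply(gt$schedule$trial, function(tr) {
    preprocess_recording(trial_recording(gt, 1, tr), cfg$fspec)
  })
  tab <- tonic_ongoing_participant(trials, gt$schedule,
                                   roi_start_s = cfg$roi_start_s,
                                   roi_dur_s = cfg$roi_dur_s)
  red <- first_last_reduce(tab)
  # z-scores of exchangeable values: cell means within sampling error of 0
  # (each cell averages 5 z-values with SD ~ 1)
  expect_true(all(abs(red$z_amplitude) < 3 / sqrt(5)))
})
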