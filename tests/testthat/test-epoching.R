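make_events <- function(onsets, kind = "chirp", deviant = FALSE, rate = 4800) {
  data.frame(onset_s = onsets, ear = "left", kind = kind,
             is_deviant = deviant,
             timezero_sample = round((onsets + timezero_offset_s(kind)) *
                                       rate) + 1L,
             stringsAsFactors = FALSE)
}

test_that("epoch extraction applies the time-zero conventions and boundary rule", {
  rate <- 4800
  x <- stats::rnorm(5 * rate)
  ev <- make_events(c(0.5, 2.0, 3.0), rate = rate)
  es <- extract_epochs(x, ev, rate, "left", "left")
  # the 0.5 s event's pre-window is truncated -> dropped and counted
  expect_equal(ncol(es$epochs), 2)
  expect_equal(attr(es, "n_dropped"), 1)
  expect_equal(nrow(es$epochs), 9600)             # 2 s at 4800
  # chirp time-zero at onset + 14.9 ms: sample round(2.0149 * 4800) + 1
  i0 <- round(2.0149 * rate) + 1
  expect_equal(es$epochs[which(es$time_ms == 0), 1], x[i0])
  # tone bursts lock to onset + 12 ms
  evt <- make_events(2.0, kind = "tone_burst", rate = rate)
  est <- extract_epochs(x, evt, rate, "left", "left")
  expect_equal(est$epochs[which(est$time_ms == 0), 1],
               x[round(2.012 * rate) + 1])
})

test_that("detrending and baseline correction remove lines and keep residuals", {
  rate <- 600
  n <- 2 * rate
  time_ms <- (seq_len(n) - rate - 1) / rate * 1000
  ramp <- seq(-3, 7, length.out = n)
  # residual with zero mean over the baseline window and no linear component
  resid <- sin(2 * pi * 200 * (seq_len(n) - 1) / rate)
  es <- structure(list(epochs = cbind(ramp, ramp + 5, ramp + resid),
                       time_ms = time_ms, rate = rate,
                       labels = data.frame(trial = 1:3)),
                  class = "epoch_set")
  out <- detrend_and_baseline(es)
  expect_lt(max(abs(out$epochs[, 1])), 1e-9)      # pure ramp -> 0
  expect_lt(max(abs(out$epochs[, 2])), 1e-9)      # ramp + constant -> 0
  expect_equal(out$epochs[, 3], resid - mean(resid) -
                 mean(resid[time_ms >= -250 & time_ms < 0] -
                        mean(resid)), tolerance = 0.02)
})

test_that("SNR is the dB ratio of post to pre window variance", {
  rate <- 600
  n <- 2 * rate
  time_ms <- (seq_len(n) - rate - 1) / rate * 1000
  set.seed(1)
  base <- stats::rnorm(n)
  ep1 <- base                                      # equal variances
  ep2 <- base
  post <- time_ms >= 0 & time_ms < 250
  ep2[post] <- sqrt(10) * base[time_ms >= -250 & time_ms < 0]
  es <- structure(list(epochs = cbind(ep1, ep2), time_ms = time_ms,
                       rate = rate, labels = data.frame(trial = 1:2)),
                  class = "epoch_set")
  snr <- compute_snr(es)
  expect_equal(snr[2], 10, tolerance = 1e-10)
  # i.i.d. noise epochs have mean SNR ~ 0 dB
  set.seed(2)
  eps <- matrix(stats::rnorm(n * 1200), n)
  es2 <- structure(list(epochs = eps, time_ms = time_ms, rate = rate,
                        labels = data.frame(trial = 1:1200)),
                   class = "epoch_set")
  snr2 <- compute_snr(es2)
  expect_lt(abs(mean(snr2)), 3 * stats::sd(snr2) / sqrt(length(snr2)))
  # degenerate epoch errors
  es$epochs[time_ms >= -250 & time_ms < 0, 1] <- 0
  expect_error(compute_snr(es), "zero pre-stimulus variance")
})

test_that("3-SD SNR screening retains the bulk and rejects gross outliers", {
  expect_true(all(reject_by_snr(rep(1.5, 10))))   # identical -> all retained
  set.seed(3)
  cluster <- stats::rnorm(999, 0, 0.5)
  out <- reject_by_snr(c(cluster, 0 + 10 * 0.5 * 10))
  expect_false(out[1000])
  expect_true(all(out[1:999]))
  g <- stats::rnorm(10000)
  frac <- mean(reject_by_snr(g))
  expect_lt(abs(frac - 0.9973), 3 * sqrt(0.9973 * 0.0027 / 10000))
  expect_error(reject_by_snr(1), "at least 2")
})

test_that("representative selection ranks by closeness to the mean SNR, stably", {
  lab <- data.frame(stim_side = "left", attended_side = "left",
                    snr_db = c(0, 1, 2, 3, 4), retained = TRUE)
  sel <- select_representative(lab, 3)
  expect_equal(lab$snr_db[sel], c(1, 2, 3))
  # tie-break by ascending index
  lab2 <- data.frame(stim_side = "left", attended_side = "left",
                     snr_db = c(1, 3), retained = TRUE)
  expect_equal(which(select_representative(lab2, 1)), 1)
  # n = cell size selects all retained
  expect_true(all(select_representative(lab, 5)))
  expect_error(select_representative(lab, 6), "retained epochs")
  # idempotent: re-running on its own output returns the same set
  lab3 <- lab[sel, ]
  expect_true(all(select_representative(lab3, 3)))
})

test_that("reflex normalization scales by the 5-30 ms max and preserves ratios", {
  rate <- 600
  n <- 2 * rate
  time_ms <- (seq_len(n) - rate - 1) / rate * 1000
  bump <- exp(-((time_ms - 15)^2) / 50)
  mk <- function(amps, stim, att) {
    structure(list(epochs = vapply(amps, function(a) a * bump, numeric(n)),
                   time_ms = time_ms, rate = rate,
                   labels = data.frame(stim_side = rep(stim, length(amps)),
                                       attended_side = rep(att, length(amps)))),
              class = "epoch_set")
  }
  cells <- expand.grid(stim = c("left", "right"), att = c("left", "right"),
                       stringsAsFactors = FALSE)
  build <- function(scale) {
    sets <- lapply(seq_len(4), function(i) {
      mk(scale * c(1, 2), cells$stim[i], cells$att[i])
    })
    bind_epoch_sets(sets)
  }
  std <- build(1)
  dev <- build(0.5)
  out <- reflex_normalize(std, dev)
  # factor = max |cell average| in [5, 30]: averages peak at 1.5 * max(bump)
  win <- time_ms >= 5 & time_ms <= 30
  expect_equal(out$factor, 1.5 * max(bump[win]))
  # amplitude ratios unchanged (away from numerically zero samples)
  big <- bump > 1e-6
  expect_equal(out$std$epochs[big, 2] / out$std$epochs[big, 1],
               std$epochs[big, 2] / std$epochs[big, 1])
  # doubling every input leaves normalized outputs identical
  std2 <- build(2); dev2 <- build(1)
  out2 <- reflex_normalize(std2, dev2)
  expect_equal(out2$std$epochs, out$std$epochs, tolerance = 1e-12)
  # zero-reflex input errors
  z <- build(0); zd <- build(0)
  expect_error(reflex_normalize(z, zd), "no reflex energy")
})
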