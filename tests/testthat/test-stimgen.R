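test_that("tone burst has the specified duration, envelope and time-zero", {
  tb <- make_tone_burst(44100)
  expect_equal(length(tb$samples), 2205)          # 0.050 * 44100
  expect_equal(tb$samples[1], 0)                  # Hanning rise starts at zero
  expect_equal(tb$timezero_offset_ms, 12)
  # plateau (12-38 ms) equals the unwindowed 800 Hz sinusoid (up to the
  # discrete-sampling peak normalization, < 1e-5)
  t <- (seq_len(2205) - 1) / 44100
  ref <- sin(2 * pi * 800 * t)
  plateau <- t >= 0.012 & t <= 0.038
  expect_lt(abs(max(abs(tb$samples[plateau])) - max(abs(ref[plateau]))), 1e-4)
  expect_lt(max(abs(tb$samples[plateau] - ref[plateau])), 1e-4)
  expect_error(make_tone_burst(4000), "aliasing")
})

test_that("chirp follows an exponential frequency sweep from 100 to 9800 Hz", {
  rate <- 96000
  ch <- make_chirp(rate)
  expect_equal(length(ch$samples), round(0.0149 * rate))
  expect_equal(ch$timezero_offset_ms, 14.9)
  expect_error(make_chirp(16000), "aliasing|Nyquist")
  # independent construction: numerically integrate the target trajectory
  # f(t) = 100 * 98^(t/T) and compare waveforms
  n <- length(ch$samples)
  t <- (seq_len(n) - 1) / rate
  f_inst <- 100 * 98^(t / 0.0149)
  phase <- 2 * pi * cumsum(c(0, (f_inst[-1] + f_inst[-n]) / 2)) / rate
  ref <- sin(phase)
  expect_gt(stats::cor(ch$samples, ref / max(abs(ref))), 0.9999)
  # independent measurement: local frequency from zero-crossing intervals;
  # log-frequency must be linear in time with endpoints 100 and 9800 Hz,
  # and the midpoint frequency sqrt(100 * 9800) ~ 989.9 Hz
  s <- ch$samples
  cross <- which(s[-n] * s[-1] < 0)
  tz <- t[cross] - s[cross] * (t[cross + 1] - t[cross]) /
    (s[cross + 1] - s[cross])
  f_local <- 1 / (2 * diff(tz))
  t_mid <- (tz[-1] + tz[-length(tz)]) / 2
  fit <- stats::lm(log(f_local) ~ t_mid)
  f0_hat <- exp(stats::predict(fit, data.frame(t_mid = 0)))
  f1_hat <- exp(stats::predict(fit, data.frame(t_mid = 0.0149)))
  fm_hat <- exp(stats::predict(fit, data.frame(t_mid = 0.0149 / 2)))
  expect_equal(unname(f0_hat), 100, tolerance = 0.03)
  expect_equal(unname(f1_hat), 9800, tolerance = 0.03)
  expect_equal(unname(fm_hat), sqrt(100 * 9800), tolerance = 0.03)
})

test_that("sequence generation honors counts, ISI range and deviant gaps", {
  spec <- sequence_spec(n_events = 600, seed = 11)
  sq <- generate_sequence(spec)
  expect_equal(nrow(sq), 600)
  expect_true(all(diff(sq$onset_s) >= 0.250 & diff(sq$onset_s) <= 0.400))
  expect_identical(sq, generate_sequence(spec))   # bit-stable given seed
  # kind is a deterministic function of ear
  expect_true(all(sq$kind[sq$ear == "left"] == "tone_burst"))
  expect_true(all(sq$kind[sq$ear == "right"] == "chirp"))
  # within-ear inter-deviant gaps (counting the deviant) lie in [3, 20]
  for (e in c("left", "right")) {
    dev_pos <- which(sq$is_deviant[sq$ear == e])
    gaps <- diff(c(0, dev_pos))
    expect_true(all(gaps >= 3 & gaps <= 20))
  }
  expect_equal(sq$level_db_re_standard[sq$is_deviant][1], -15)
})

test_that("per-ear event counts are binomial and ISIs uniform", {
  n_seq <- 300
  counts <- numeric(n_seq)
  isis <- numeric(0)
  for (i in seq_len(n_seq)) {
    sq <- generate_sequence(sequence_spec(seed = 1000 + i))
    counts[i] <- sum(sq$ear == "left")
    if (i <= 30) isis <- c(isis, diff(sq$onset_s))
  }
  se_mean <- sqrt(600 * 0.25 / n_seq)
  expect_lt(abs(mean(counts) - 300), 3 * se_mean)
  # variance ~ binomial npq = 150, within 3 SE of a variance estimate
  expect_lt(abs(stats::var(counts) - 150), 3 * 150 * sqrt(2 / (n_seq - 1)))
  # ISI histogram flat on [250, 400] ms: chi-square GOF not rejected
  h <- table(cut(isis, breaks = seq(0.250, 0.400, length.out = 11)))
  p <- stats::chisq.test(h)$p.value
  expect_gt(p, 0.01)
})

test_that("rendering places waveforms sample-accurately and attenuates deviants", {
  rate <- 44100
  sq <- generate_sequence(sequence_spec(n_events = 6, seed = 3))
  # hand-build a one-chirp sequence at t = 1 s
  one <- sq[1, ]
  one$onset_s <- 1; one$ear <- "right"; one$kind <- "chirp"
  one$is_deviant <- FALSE; one$level_db_re_standard <- 0
  r <- render_sequence(one, rate)
  nz <- which(r$audio[, "right"] != 0)
  expect_gte(min(nz), 44101)
  expect_lt(max(nz), 44101 + 657)
  expect_true(all(r$audio[, "left"] == 0))
  # deviant-to-standard peak ratio = 10^(-15/20)
  two <- rbind(one, one)
  two$onset_s <- c(1, 2)
  two$is_deviant <- c(FALSE, TRUE)
  two$level_db_re_standard <- c(0, -15)
  r2 <- render_sequence(two, rate)
  p_std <- max(abs(r2$audio[44101:(44101 + 700), "right"]))
  p_dev <- max(abs(r2$audio[88201:(88201 + 656), "right"]))
  expect_equal(p_dev / p_std, 10^(-15 / 20), tolerance = 1e-12)
  # empty sequence renders to all-zero channels
  r0 <- render_sequence(one[0, ], rate)
  expect_equal(nrow(r0$audio), 0)
})

test_that("WAV writer emits a well-formed 16-bit PCM RIFF file", {
  path <- tempfile(fileext = ".wav")
  x <- cbind(sin(2 * pi * 440 * (0:999) / 8000), rep(0, 1000))
  write_wav_pcm16(x, 8000, path)
  con <- file(path, "rb")
  on.exit(close(con))
  expect_equal(readChar(con, 4), "RIFF")
  invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
  expect_equal(readChar(con, 8), "WAVEfmt ")
  expect_equal(readBin(con, integer(), 1, size = 4, endian = "little"), 16)
  expect_equal(readBin(con, integer(), 2, size = 2, endian = "little"),
               c(1, 2))                           # PCM, 2 channels
  expect_equal(readBin(con, integer(), 1, size = 4, endian = "little"), 8000)
  expect_equal(file.info(path)$size, 44 + 2 * 2 * 1000)
})
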