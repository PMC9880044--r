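test_that("spectrogram geometry matches the STFT contract", {
  p <- spectrogram_params()
  expect_equal(column_period(p), 0.004)

  w <- tone_recording()
  s <- compute_log_spectrogram(w, p)
  expect_equal(ncol(s$values), (length(w) - 512) %/% 128 + 1)
  expect_equal(nrow(s$values), 257)

  # peak bin of a pure 1 kHz tone agrees with a direct DFT of one window
  tone <- sin(2 * pi * 1000 * (0:511) / 32000)
  dft <- Mod(fft(signal::hamming(512) * tone))[1:257]
  mid <- 120  # column well inside the tone burst
  expect_equal(which.max(s$values[, mid]), which.max(dft))
  expect_equal(which.max(dft) - 1L, round(1000 / (32000 / 512)))
})

test_that("silence maps to the log floor and short input errors", {
  s <- compute_log_spectrogram(rep(0, 32000), spectrogram_params())
  expect_true(all(s$values == s$log_floor))
  expect_error(compute_log_spectrogram(rep(0, 100), spectrogram_params()),
               "shorter than one analysis window")
})

test_that("band power sums in-band linear power", {
  w <- tone_recording()
  s <- compute_log_spectrogram(w, spectrogram_params())
  # full band equals total per-column power
  full <- band_power(s, 0, 16000)
  expect_equal(full, log(colSums(exp(s$values))), tolerance = 1e-10)
  # manual bin-mask oracle for the default band
  rows <- which(s$freq >= 312 & s$freq <= 8000)
  expect_equal(band_power(s), log(colSums(exp(s$values[rows, ]))),
               tolerance = 1e-10)
  expect_error(band_power(s, 15880, 15930), "no frequency bins")
  # an out-of-band 10 kHz tone is indistinguishable from silence (at a
  # realistic recording floor; only window sidelobes leak into the band)
  w10 <- tone_recording(tone_hz = 10000, floor_sd = 2e-3)
  tr10 <- band_power(compute_log_spectrogram(w10, spectrogram_params()))
  sil <- band_power(compute_log_spectrogram(
    tone_recording(amp = 0, floor_sd = 2e-3), spectrogram_params()))
  inner <- 80:180  # steady-state columns, away from the burst's edge clicks
  expect_lt(max(abs(tr10[inner] - sil[inner])), 0.2)
})

test_that("silence threshold is mean + k sd of the silent trace", {
  withr::with_seed(1, {
    tr <- rnorm(5000, mean = -10, sd = 0.5)
    th <- silence_threshold(tr, rep(TRUE, 5000))
    expect_equal(th, -10 + 5 * 0.5, tolerance = 0.05)
    expect_equal(silence_threshold(tr, rep(TRUE, 5000), n_sd = 0),
                 mean(tr), tolerance = 1e-12)
  })
  expect_equal(silence_threshold(rep(-7, 100), rep(TRUE, 100)), -7)
  expect_error(silence_threshold(1:100, c(TRUE, rep(FALSE, 99))),
               "silence region")
})

test_that("sound-interval detection: runs, gap closing, duration filter", {
  tr <- rep(-10, 50); tr[11:20] <- 0
  expect_equal(detect_sound_intervals(tr, -5),
               data.frame(interval_id = 1L, onset_col = 10L, offset_col = 20L))
  expect_equal(nrow(detect_sound_intervals(rep(-10, 50), -5)), 0)

  # two runs separated by a 2-column gap merge when min_gap = 3
  tr2 <- rep(-10, 30); tr2[6:10] <- 0; tr2[13:18] <- 0
  got <- detect_sound_intervals(tr2, -5, min_gap = 3)
  expect_equal(got$onset_col, 5L)
  expect_equal(got$offset_col, 18L)
  # run-length oracle without gap closing
  got2 <- detect_sound_intervals(tr2, -5)
  r <- rle(tr2 >= -5)
  expect_equal(nrow(got2), sum(r$values))
  # min_dur drops the short run
  expect_equal(nrow(detect_sound_intervals(tr2, -5, min_dur = 6)), 1)
})

test_that("detection round-trip and threshold monotonicity hold", {
  withr::with_seed(7, {
    for (k in 1:20) {
      tr <- rnorm(300)
      th <- runif(1, -1, 1)
      iv <- detect_sound_intervals(tr, th)
      inside <- rep(FALSE, 300)
      for (i in seq_len(nrow(iv)))
        inside[(iv$onset_col[i] + 1):iv$offset_col[i]] <- TRUE
      expect_true(all(tr[inside] >= th))
      expect_true(all(tr[!inside] < th))
      # lowering the threshold never shrinks coverage
      iv2 <- detect_sound_intervals(tr, th - 0.5)
      inside2 <- rep(FALSE, 300)
      for (i in seq_len(nrow(iv2)))
        inside2[(iv2$onset_col[i] + 1):iv2$offset_col[i]] <- TRUE
      expect_true(all(inside2[inside]))
    }
  })
})

test_that("wav i/o round-trips mono audio and rejects stereo", {
  w <- tone_recording(n_lead = 100, n_tone = 2000, n_tail = 100)
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(w, 32000, f)
  got <- read_wav(f)
  expect_equal(got$sample_rate, 32000)
  expect_equal(got$wave, w, tolerance = 1e-7)
  write_wav(w, 32000, f, format = "pcm16")
  expect_equal(read_wav(f)$wave, w, tolerance = 1e-4)
})
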