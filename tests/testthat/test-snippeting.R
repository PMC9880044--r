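# A miniature spectrogram object with known geometry, no audio needed.
fake_spec <- function(n_cols, n_bins = 20) {
  structure(list(
    values = matrix(seq_len(n_bins * n_cols) / 100, n_bins, n_cols),
    freq = seq(0, 8000, length.out = n_bins),
    params = spectrogram_params(band_low = 1, band_high = 8000),
    log_floor = log_floor_value()
  ), class = "voc2n_spectrogram")
}

test_that("snippet count follows the closed form", {
  sp <- snippet_params()  # w 16, don 4, doff 6
  spec <- fake_spec(400)
  iv <- data.frame(interval_id = 1L, onset_col = 100L, offset_col = 200L)
  sn <- dissect_snippets(spec, iv, sp)
  expect_equal(nrow(sn$snippets), 100 + 4 + 6 - 16 + 1)
  # enumerate-start-columns oracle over a range of lengths
  for (L in seq(10, 60, by = 7)) {
    iv <- data.frame(interval_id = 1L, onset_col = 50L,
                     offset_col = 50L + L)
    got <- nrow(dissect_snippets(spec, iv, sp)$snippets)
    starts <- (50 - 4):(50 + L + 6 - 16)
    expect_equal(got, length(starts))
  }
})

test_that("lag bookkeeping matches the chain invariants", {
  sp <- snippet_params()
  spec <- fake_spec(300)
  iv <- data.frame(interval_id = 1:2, onset_col = c(30L, 150L),
                   offset_col = c(80L, 230L))
  sn <- dissect_snippets(spec, iv, sp)$snippets
  for (i in 1:2) {
    s <- sn[sn$interval_id == i, ]
    n <- nrow(s)
    expect_equal(unique(s$forward_lag - s$backward_lag), n + 1L)
    expect_equal(s$start_col[s$forward_lag == 1], iv$onset_col[i] - 4L)
    expect_equal(s$start_col[s$backward_lag == -1] + 16L,
                 iv$offset_col[i] + 6L)
    expect_equal(diff(s$start_col), rep(1L, n - 1))
  }
})

test_that("implied crossings close on the interval boundaries", {
  sp <- snippet_params()
  spec <- fake_spec(300)
  iv <- data.frame(interval_id = 1L, onset_col = 40L, offset_col = 120L)
  s <- dissect_snippets(spec, iv, sp)$snippets
  expect_equal(implied_crossing(s$start_col[s$forward_lag == 1], 1L, sp), 40)
  expect_equal(implied_crossing(s$start_col[s$forward_lag == 3], 3L, sp), 40)
  expect_equal(implied_crossing(s$start_col[s$backward_lag == -1], -1L, sp),
               120)
  # every snippet at its true lag implies the boundary it came from
  on_ok <- vapply(seq_len(nrow(s)), function(k)
    implied_crossing(s$start_col[k], s$forward_lag[k], sp) == 40, logical(1))
  off_ok <- vapply(seq_len(nrow(s)), function(k)
    implied_crossing(s$start_col[k], s$backward_lag[k], sp) == 120, logical(1))
  expect_true(all(on_ok))
  expect_true(all(off_ok))
})

test_that("adjacent snippet features overlap in all but one column", {
  spec <- fake_spec(100)
  iv <- data.frame(interval_id = 1L, onset_col = 20L, offset_col = 60L)
  sn <- dissect_snippets(spec, iv, snippet_params())
  nb <- length(sn$band_rows)
  f1 <- matrix(sn$features[1, ], nb, 16)
  f2 <- matrix(sn$features[2, ], nb, 16)
  expect_equal(f1[, 2:16], f2[, 1:15])
})

test_that("margins beyond the recording are filled with the log floor", {
  spec <- fake_spec(50)
  iv <- data.frame(interval_id = 1L, onset_col = 2L, offset_col = 30L)
  sn <- dissect_snippets(spec, iv, snippet_params())
  first <- matrix(sn$features[1, ], length(sn$band_rows), 16)
  expect_true(all(first[, 1:2] == log_floor_value()))
  expect_false(any(first[, 3:16] == log_floor_value()))
})

test_that("too-short intervals yield zero snippets with a message", {
  spec <- fake_spec(100)
  iv <- data.frame(interval_id = 1L, onset_col = 20L, offset_col = 23L)
  expect_message(sn <- dissect_snippets(spec, iv, snippet_params()),
                 "too short")
  expect_equal(nrow(sn$snippets), 0)
})
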