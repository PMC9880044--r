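iv1 <- data.frame(interval_id = 1L, onset_col = 90L, offset_col = 200L)

test_that("adjacent same-type events collapse to one anchor", {
  ev <- rbind(make_events("A", "onset", 100L), make_events("A", "onset", 101L))
  ev$snippet_id <- 1:2
  got <- collapse_adjacent(ev)
  expect_equal(nrow(got), 1)
  expect_equal(got$crossing_col, 100L)
  # offsets keep the latest member of a run
  ev2 <- rbind(make_events("A", "offset", 150L),
               make_events("A", "offset", 151L))
  ev2$start_col <- c(140L, 141L)
  got2 <- collapse_adjacent(ev2)
  expect_equal(got2$crossing_col, 151L)
  # single events and non-adjacent events pass through
  expect_equal(nrow(collapse_adjacent(make_events("A", "onset", 100L))), 1)
  ev3 <- rbind(make_events("A", "onset", 100L),
               make_events("A", "onset", 105L))
  expect_equal(collapse_adjacent(ev3)$crossing_col, c(100L, 105L))
})

test_that("2N pairing emits, truncates and discards as specified", {
  # onset + same-type offset
  ev <- rbind(make_events("A", "onset", 100L), make_events("A", "offset", 150L))
  got <- pair_2n(ev, iv1)
  expect_equal(got$vocalizations$onset_col, 100L)
  expect_equal(got$vocalizations$offset_col, 150L)
  expect_equal(got$vocalizations$provenance, "paired")
  expect_equal(nrow(got$discards), 0)

  # onset + wrong-type offset: both discarded, nothing emitted
  ev <- rbind(make_events("A", "onset", 100L), make_events("B", "offset", 140L))
  got <- pair_2n(ev, iv1)
  expect_equal(nrow(got$vocalizations), 0)
  expect_equal(nrow(got$discards), 2)
  expect_setequal(got$discards$reason, "offset_type_mismatch")

  # onset followed by onset: truncate one column before the event
  ev <- rbind(make_events("A", "onset", 100L), make_events("A", "onset", 130L),
              make_events("A", "offset", 160L))
  got <- pair_2n(ev, iv1, mode = "truncate")
  expect_equal(got$vocalizations$onset_col, c(100L, 130L))
  expect_equal(got$vocalizations$offset_col, c(129L, 160L))
  expect_equal(got$vocalizations$provenance,
               c("truncated_at_event", "paired"))
  # strict mode discards the interrupted onset instead
  got_s <- pair_2n(ev, iv1, mode = "strict")
  expect_equal(nrow(got_s$vocalizations), 1)
  expect_equal(got_s$vocalizations$onset_col, 130L)
  expect_equal(got_s$discards$reason, "onset_then_onset")
})

test_that("dangling events are handled at interval ends", {
  # lone onset truncates one column before the interval end
  got <- pair_2n(make_events("A", "onset", 100L), iv1)
  expect_equal(got$vocalizations$offset_col, 199L)
  expect_equal(got$vocalizations$provenance, "truncated_at_event")
  # offset with no pending onset is discarded
  got <- pair_2n(make_events("A", "offset", 150L), iv1)
  expect_equal(nrow(got$vocalizations), 0)
  expect_equal(got$discards$reason, "offset_without_onset")
  # unsorted input is rejected
  ev <- rbind(make_events("A", "onset", 150L), make_events("A", "offset", 100L))
  expect_error(pair_2n(ev, iv1), "sorted")
})

test_that("noise onsets terminate vocal onsets but emit nothing", {
  ev <- rbind(make_events("A", "onset", 100L),
              make_events("noise", "onset", 130L, noise = TRUE),
              make_events("A", "offset", 160L))
  ev <- ev[order(ev$crossing_col), ]
  got <- pair_2n(ev, iv1)
  expect_equal(got$vocalizations$offset_col, 129L)
  expect_equal(nrow(got$noise_onsets), 1)
  expect_false(any(got$vocalizations$type_label == "noise"))
})

test_that("emitted vocalizations are clamped to their sound interval", {
  # an offset crossing past the interval end is pulled back to it
  ev <- rbind(make_events("A", "onset", 100L), make_events("A", "offset", 205L))
  got <- pair_2n(ev, iv1)
  expect_equal(got$vocalizations$offset_col, 200L)
  # within each interval emissions are ordered and non-overlapping
  ev <- rbind(make_events("A", "onset", 100L), make_events("A", "offset", 120L),
              make_events("B", "onset", 140L), make_events("B", "offset", 170L))
  v <- pair_2n(ev, iv1)$vocalizations
  expect_true(all(v$onset_col < v$offset_col))
  expect_true(all(v$offset_col[-nrow(v)] <= v$onset_col[-1]))
})

test_that("onset-anchored 1N segments run to the next onset or interval end", {
  got <- extract_1n_onset(make_events("A", "onset", 100L), iv1)
  expect_equal(got$onset_col, 100L)
  expect_equal(got$offset_col, 200L)
  ev <- rbind(make_events("A", "onset", 100L), make_events("A", "onset", 150L))
  got <- extract_1n_onset(ev, iv1)
  expect_equal(got$onset_col, c(100L, 150L))
  expect_equal(got$offset_col, c(150L, 200L))
  # a 1-column segment right at the interval end is kept
  got <- extract_1n_onset(make_events("A", "onset", 199L), iv1)
  expect_equal(got$offset_col - got$onset_col, 1L)
})

test_that("offset-anchored 1N segments reach back to the previous offset", {
  got <- extract_1n_offset(make_events("A", "offset", 150L), iv1)
  expect_equal(got$onset_col, 90L)
  expect_equal(got$offset_col, 150L)
  ev <- rbind(make_events("A", "offset", 120L), make_events("A", "offset", 160L))
  got <- extract_1n_offset(ev, iv1)
  expect_equal(got$onset_col, c(90L, 120L))
  expect_equal(got$offset_col, c(120L, 160L))
  # an offset at the interval start is degenerate and dropped
  expect_message(got <- extract_1n_offset(make_events("A", "offset", 90L), iv1),
                 "dropped")
  expect_equal(nrow(got), 0)
})

test_that("1N outputs cover at least as many bins as 2N on the same events", {
  ev <- rbind(make_events("A", "onset", 100L), make_events("A", "offset", 130L),
              make_events("B", "onset", 150L), make_events("B", "offset", 190L))
  v2 <- pair_2n(ev, iv1)$vocalizations
  v1on <- extract_1n_onset(ev, iv1)
  v1off <- extract_1n_offset(ev, iv1)
  bins <- function(a) sum(a$offset_col - a$onset_col)
  expect_gte(bins(v1on), bins(v2))
  expect_gte(bins(v1off), bins(v2))
})

test_that("noise segments end at the interval end or next vocal onset", {
  got <- extract_noise(make_events("noise", "onset", 120L, noise = TRUE), iv1)
  expect_equal(got$offset_col, 200L)
  got <- extract_noise(make_events("noise", "onset", 120L, noise = TRUE), iv1,
                       vocal_onsets = c(150L, 180L))
  expect_equal(got$offset_col, 150L)
  expect_message(
    got <- extract_noise(make_events("noise", "onset", 250L, noise = TRUE), iv1),
    "stale")
  expect_equal(nrow(got), 0)
})
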