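#' Snippet dissection parameters
#'
#' A snippet is a fixed-width window of spectrogram columns. Each sound
#' interval, extended by `delta_on` columns before its onset and `delta_off`
#' columns after its offset, is dissected into snippets hopped by one column.
#' The protruding margins put a slice of the surrounding silence into the
#' first/last snippets, which is what gives vocalization types crisp ends in
#' the embedding plane.
#'
#' @param width_w snippet width in columns (12-16 typical; 16 = 64 ms at a
#'   4 ms column period).
#' @param delta_on columns by which the first snippet precedes the interval
#'   onset.
#' @param delta_off columns by which the last snippet exceeds the interval
#'   offset.
#' @param zscore if `TRUE`, z-score each snippet feature vector before
#'   embedding.
#' @return object of class `voc2n_snip_params`.
#' @export
snippet_params <- function(width_w = 16L, delta_on = 4L, delta_off = 6L,
                           zscore = FALSE) {
  stopifnot(width_w >= 2, delta_on >= 0, delta_off >= 0)
  structure(list(width_w = as.integer(width_w),
                 delta_on = as.integer(delta_on),
                 delta_off = as.integer(delta_off),
                 zscore = isTRUE(zscore)),
            class = "voc2n_snip_params")
}

#' Dissect sound intervals into overlapping snippets
#'
#' Within each interval `[a, b)` extended by the margins, snippets start at
#' every column from `a - delta_on` to `b + delta_off - width_w`, so an
#' interval of length `L` yields `L + delta_on + delta_off - width_w + 1`
#' snippets. The first snippet gets forward lag 1 and the last backward lag
#' -1; adjacent snippets overlap in `width_w - 1` columns. Intervals too
#' short to hold a single snippet yield none (with a message). Margin
#' columns outside the recording are filled with the spectrogram log floor.
#'
#' Feature vectors are the log-power patch restricted to the analysis band,
#' flattened column-major.
#'
#' @param spec a [compute_log_spectrogram()] result.
#' @param intervals data.frame from [detect_sound_intervals()].
#' @param params a [snippet_params()] object.
#' @return list with `snippets` (data.frame: `snippet_id`, `interval_id`,
#'   `start_col`, `forward_lag`, `backward_lag`), `features` (matrix,
#'   snippets x features), `params`, `band_rows`.
#' @export
dissect_snippets <- function(spec, intervals, params = snippet_params()) {
  w <- params$width_w
  don <- params$delta_on
  doff <- params$delta_off
  rows <- band_rows(spec)
  n_cols <- ncol(spec$values)

  per_int <- lapply(seq_len(nrow(intervals)), function(i) {
    a <- intervals$onset_col[i]
    b <- intervals$offset_col[i]
    n <- (b - a) + don + doff - w + 1L
    if (n < 1L) {
      message("interval ", intervals$interval_id[i], " [", a, ",", b,
              ") too short for a ", w, "-column snippet; skipped")
      return(NULL)
    }
    data.frame(interval_id = intervals$interval_id[i],
               start_col = (a - don) + seq_len(n) - 1L,
               forward_lag = seq_len(n),
               backward_lag = seq_len(n) - (n + 1L))
  })
  snips <- do.call(rbind, per_int)
  if (is.null(snips))
    return(list(snippets = data.frame(snippet_id = integer(),
                                      interval_id = integer(),
                                      start_col = integer(),
                                      forward_lag = integer(),
                                      backward_lag = integer()),
                features = matrix(numeric(), 0, length(rows) * w),
                params = params, band_rows = rows))
  snips <- cbind(snippet_id = seq_len(nrow(snips)), snips)

  # Gather feature patches in one indexing pass; an extra sentinel column of
  # log-floor values serves the out-of-recording margins.
  vb <- cbind(spec$values[rows, , drop = FALSE],
              rep(spec$log_floor, length(rows)))
  col_idx <- outer(0:(w - 1L), snips$start_col, "+") + 1L  # w x n, 1-based
  col_idx[col_idx < 1L | col_idx > n_cols] <- n_cols + 1L
  feats <- t(matrix(vb[, as.vector(col_idx)], nrow = length(rows) * w))
  if (params$zscore) {
    mu <- rowMeans(feats)
    sdv <- apply(feats, 1, stats::sd)
    sdv[sdv == 0] <- 1
    feats <- (feats - mu) / sdv
  }
  rownames(feats) <- snips$snippet_id
  list(snippets = snips, features = feats, params = params, band_rows = rows)
}

#' Amplitude crossing implied by a snippet at an assumed lag
#'
#' A snippet truly sitting at forward lag `d > 0` starts `delta_on - (d - 1)`
#' columns before its interval's onset, so anchoring it at lag `d` implies a
#' lower amplitude crossing at `start_col + delta_on - (d - 1)`. Mirror rule
#' for backward lags `d < 0`: the implied upper crossing is
#' `end_col_exclusive - delta_off + (|d| - 1)`. Harvested points keep their
#' own timestamps but are anchored at the owning blob's lag, which is how
#' noisy renditions inherit correct boundaries from their cleanly segmented
#' lookalikes.
#'
#' @param start_col snippet start column(s), 0-based.
#' @param anchor_lag signed lag (nonzero); positive = onset side.
#' @param params a [snippet_params()] object.
#' @return implied crossing column(s), 0-based.
#' @export
implied_crossing <- function(start_col, anchor_lag, params) {
  stopifnot(anchor_lag != 0)
  if (anchor_lag > 0) {
    start_col + params$delta_on - (anchor_lag - 1L)
  } else {
    (start_col + params$width_w) - params$delta_off + (abs(anchor_lag) - 1L)
  }
}
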