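#' Spectrogram parameters
#'
#' Short-time Fourier transform settings. At the defaults (32 kHz audio,
#' 512-sample Hamming windows, hop 128) the spectrogram column period is
#' exactly 4 ms, which is the time unit of every downstream module: all
#' onset/offset times in this package are integer column indices (0-based,
#' half-open intervals).
#'
#' @param sample_rate sampling rate in Hz.
#' @param window_length analysis window in samples.
#' @param hop hop between adjacent windows in samples.
#' @param window_shape taper; only `"hamming"` is provided.
#' @param band_low,band_high analysis band in Hz used for amplitude
#'   thresholding and snippet features. The 312 Hz - 8 kHz default suits
#'   microphone recordings of zebra finches; accelerometer signals typically
#'   use an upper edge near 4 kHz.
#' @return object of class `voc2n_spec_params`.
#' @export
spectrogram_params <- function(sample_rate = 32000, window_length = 512L,
                               hop = 128L, window_shape = "hamming",
                               band_low = 312, band_high = 8000) {
  stopifnot(hop <= window_length, window_length >= 2,
            band_low < band_high, band_high <= sample_rate / 2)
  if (!identical(window_shape, "hamming"))
    stop("only the 'hamming' taper is implemented")
  structure(list(sample_rate = sample_rate,
                 window_length = as.integer(window_length),
                 hop = as.integer(hop), window_shape = window_shape,
                 band_low = band_low, band_high = band_high),
            class = "voc2n_spec_params")
}

#' Column period of a spectrogram in seconds
#' @param params a [spectrogram_params()] object.
#' @export
column_period <- function(params) params$hop / params$sample_rate

#' Compute a log-power spectrogram
#'
#' Frames the waveform into `window_length`-sample Hamming-tapered windows
#' hopped by `hop` samples, takes the squared modulus of the DFT (bins 0
#' through Nyquist) and log-transforms after clipping at a small positive
#' floor so silence maps to a finite constant. The column count is
#' `floor((n_samples - window_length)/hop) + 1`.
#'
#' @param wave numeric sample vector (length >= `window_length`).
#' @param params a [spectrogram_params()] object.
#' @return object of class `voc2n_spectrogram`: list with `values`
#'   (matrix, frequency bins x columns, natural-log power), `freq` (Hz per
#'   row), `params`, and `log_floor`.
#' @export
compute_log_spectrogram <- function(wave, params = spectrogram_params()) {
  n <- length(wave)
  win <- params$window_length
  hop <- params$hop
  if (n < win)
    stop("waveform (", n, " samples) is shorter than one analysis window (",
         win, " samples)")
  n_cols <- (n - win) %/% hop + 1L
  taper <- signal::hamming(win)
  idx <- outer(seq_len(win), (seq_len(n_cols) - 1L) * hop, "+")
  frames <- matrix(wave[idx], nrow = win) * taper
  ft <- stats::mvfft(frames)
  n_bins <- win %/% 2L + 1L
  power <- Mod(ft[seq_len(n_bins), , drop = FALSE])^2
  structure(list(
    values = log(pmax(power, .power_floor)),
    freq = (seq_len(n_bins) - 1L) * params$sample_rate / win,
    params = params,
    log_floor = log_floor_value()
  ), class = "voc2n_spectrogram")
}

#' @export
print.voc2n_spectrogram <- function(x, ...) {
  cat(sprintf("log-power spectrogram: %d bins x %d columns (%.1f ms/column, %g-%g Hz band)\n",
              nrow(x$values), ncol(x$values), 1000 * column_period(x$params),
              x$params$band_low, x$params$band_high))
  invisible(x)
}

# Row indices of spectrogram bins whose center frequency lies in the band.
band_rows <- function(spec, band_low = NULL, band_high = NULL) {
  lo <- band_low %||% spec$params$band_low
  hi <- band_high %||% spec$params$band_high
  rows <- which(spec$freq >= lo & spec$freq <= hi)
  if (length(rows) == 0)
    stop("no frequency bins inside the band [", lo, ", ", hi, "] Hz")
  rows
}

#' Band-limited power trace
#'
#' Sums linear power over frequency bins whose center frequency lies inside
#' the analysis band and returns the log of that sum: one value per
#' spectrogram column. This is the amplitude trace that silence statistics
#' and sound-interval detection operate on.
#'
#' @param spec a [compute_log_spectrogram()] result.
#' @param band_low,band_high optional band override in Hz; defaults to the
#'   band in `spec$params`.
#' @return numeric vector, one log-power value per column.
#' @export
band_power <- function(spec, band_low = NULL, band_high = NULL) {
  rows <- band_rows(spec, band_low, band_high)
  lin <- exp(spec$values[rows, , drop = FALSE])
  log(pmax(colSums(lin), .power_floor))
}

#' Silence-derived detection threshold
#'
#' Threshold = mean + `n_sd` standard deviations of the trace over columns
#' marked silent. The default multiplier of 5 is the standard setting for
#' separating vocal sound from the recording noise floor.
#'
#' @param trace log-power trace from [band_power()].
#' @param silence_mask logical vector (same length) marking silent columns,
#'   or `"auto"` to use the lowest-power decile of columns.
#' @param n_sd multiplier on the silence standard deviation.
#' @param min_silence_cols minimum number of silent columns required for a
#'   usable estimate.
#' @return scalar threshold on the log-power trace.
#' @export
silence_threshold <- function(trace, silence_mask = "auto", n_sd = 5,
                              min_silence_cols = 25L) {
  if (identical(silence_mask, "auto")) {
    k <- max(min_silence_cols, ceiling(length(trace) / 10))
    silence_mask <- rank(trace, ties.method = "first") <= k
  }
  stopifnot(is.logical(silence_mask), length(silence_mask) == length(trace))
  s <- trace[silence_mask]
  if (length(s) < min_silence_cols)
    stop("only ", length(s), " silence columns available (need >= ",
         min_silence_cols, "); supply a silence region, e.g. a recording ",
         "stretch known to contain no sound")
  m <- mean(s)
  sd_s <- if (length(s) > 1) stats::sd(s) else 0
  m + n_sd * sd_s
}

#' Detect sound intervals by amplitude thresholding
#'
#' Maximal runs of supra-threshold (optionally smoothed) trace columns,
#' after closing sub-threshold gaps shorter than `min_gap` columns and
#' dropping runs shorter than `min_dur`. Smoothing the amplitude trace
#' before thresholding lets split syllables (sub-syllables separated by a
#' tiny silent gap) come out as a single interval.
#'
#' @param trace log-power trace from [band_power()].
#' @param threshold scalar from [silence_threshold()].
#' @param smoothing_width running-mean width in columns (1 = no smoothing).
#' @param min_gap gaps strictly shorter than this many columns are closed.
#' @param min_dur runs strictly shorter than this many columns are dropped.
#' @return data.frame with `interval_id`, `onset_col` (0-based, inclusive)
#'   and `offset_col` (exclusive); zero rows if nothing is supra-threshold.
#' @export
detect_sound_intervals <- function(trace, threshold, smoothing_width = 1L,
                                   min_gap = 0L, min_dur = 0L) {
  sm <- running_mean(trace, smoothing_width)
  runs <- true_runs(sm >= threshold)
  if (nrow(runs) > 1 && min_gap > 0) {
    keep_sep <- runs[-1, "start"] - runs[-nrow(runs), "end"] >= min_gap
    grp <- cumsum(c(TRUE, keep_sep))
    runs <- cbind(start = tapply(runs[, "start"], grp, min),
                  end = tapply(runs[, "end"], grp, max))
  }
  if (nrow(runs) > 0 && min_dur > 0)
    runs <- runs[runs[, "end"] - runs[, "start"] >= min_dur, , drop = FALSE]
  data.frame(interval_id = seq_len(nrow(runs)),
             onset_col = as.integer(runs[, "start"]),
             offset_col = as.integer(runs[, "end"]),
             row.names = NULL)
}

#' Write sound intervals as CSV
#'
#' @param intervals data.frame from [detect_sound_intervals()].
#' @param path output CSV path.
#' @param params [spectrogram_params()] used, for second conversion.
#' @param file label written into the `file` column.
#' @export
write_intervals_csv <- function(intervals, path, params, file = NA_character_) {
  dt <- column_period(params)
  out <- data.frame(file = file,
                    onset_col = intervals$onset_col,
                    offset_col = intervals$offset_col,
                    onset_s = intervals$onset_col * dt,
                    offset_s = intervals$offset_col * dt)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
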