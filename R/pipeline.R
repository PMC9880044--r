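#' Prepare a recording for blob definition
#'
#' Runs the front half of the pipeline: log-power spectrogram, band-limited
#' amplitude trace, silence-derived threshold, sound intervals, snippet
#' dissection, and the planar embedding. The result holds everything needed
#' to define blobs (interactively, from a YAML config, or via
#' [oracle_blob_defs()] on synthetic scenes) and to extract.
#'
#' @param wave numeric waveform.
#' @param spec_params [spectrogram_params()].
#' @param snip_params [snippet_params()].
#' @param silence `"auto"`, a logical column mask, or a length-2 vector of
#'   0-based columns `[from, to)` known to be silent.
#' @param n_sd silence-threshold multiplier.
#' @param smoothing_width,min_gap,min_dur passed to
#'   [detect_sound_intervals()].
#' @param method,seed,... passed to [embed_snippets()].
#' @return list of class `voc2n_prep` with `spec`, `trace`, `threshold`,
#'   `intervals`, `snips`, `emb` (embedding frame) and `grid`.
#' @export
voc2n_prepare <- function(wave, spec_params = spectrogram_params(),
                          snip_params = snippet_params(), silence = "auto",
                          n_sd = 5, smoothing_width = 1L, min_gap = 0L,
                          min_dur = 0L, method = "umap", seed = 1L, ...) {
  spec <- compute_log_spectrogram(wave, spec_params)
  trace <- band_power(spec)
  if (is.numeric(silence) && length(silence) == 2)
    silence <- seq_along(trace) - 1L >= silence[1] &
               seq_along(trace) - 1L < silence[2]
  threshold <- silence_threshold(trace, silence, n_sd = n_sd)
  intervals <- detect_sound_intervals(trace, threshold, smoothing_width,
                                      min_gap, min_dur)
  snips <- dissect_snippets(spec, intervals, snip_params)
  coords <- embed_snippets(snips$features, method = method, seed = seed, ...)
  emb <- embedding_frame(snips, coords)
  structure(list(spec = spec, trace = trace, threshold = threshold,
                 intervals = intervals, snips = snips, emb = emb,
                 grid = grid_spec(emb)),
            class = "voc2n_prep")
}

#' @export
print.voc2n_prep <- function(x, ...) {
  cat(sprintf("voc2n preparation: %d sound intervals, %d snippets embedded\n",
              nrow(x$intervals), nrow(x$emb)))
  invisible(x)
}

#' Run two-neighborhood extraction
#'
#' Harvests anchor events from the blob definitions, collapses adjacent
#' harvests, pairs onsets with offsets into vocalizations (2N), extracts
#' noise segments from the noise pseudo-type's onsets, and computes both
#' single-neighborhood baselines from the same events.
#'
#' @param prep a [voc2n_prepare()] result.
#' @param defs blob-definition table.
#' @param mode pairing mode, see [pair_2n()].
#' @return list with `vocalizations`, `noise_segments`, `one_n_onset`,
#'   `one_n_offset`, `events` (collapsed anchor events), `discards`.
#' @export
voc2n_extract <- function(prep, defs, mode = c("truncate", "strict")) {
  mode <- match.arg(mode)
  ev <- anchor_events(prep$emb, defs, prep$snips$params, prep$grid)
  coll <- collapse_adjacent(ev)
  paired <- pair_2n(coll, prep$intervals, mode = mode)
  noise_seg <- extract_noise(paired$noise_onsets, prep$intervals,
                             paired$vocalizations$onset_col)
  list(vocalizations = paired$vocalizations,
       noise_segments = noise_seg,
       one_n_onset = extract_1n_onset(coll, prep$intervals),
       one_n_offset = extract_1n_offset(coll, prep$intervals),
       events = coll,
       discards = paired$discards)
}

#' Write / read extracted annotations as CSV
#'
#' Columns: `type_label`, `onset_col`, `offset_col` (0-based half-open
#' spectrogram columns), `onset_s`, `offset_s`, `provenance`.
#'
#' @param ann annotation data.frame.
#' @param path CSV path.
#' @param params [spectrogram_params()] for second conversion.
#' @rdname annotations_csv
#' @export
write_annotations_csv <- function(ann, path, params = spectrogram_params()) {
  dt <- column_period(params)
  out <- data.frame(type_label = ann$type_label,
                    onset_col = ann$onset_col, offset_col = ann$offset_col,
                    onset_s = ann$onset_col * dt, offset_s = ann$offset_col * dt,
                    provenance = ann$provenance %||%
                      rep(NA_character_, nrow(ann)))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname annotations_csv
#' @export
read_annotations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$onset_col <- as.integer(df$onset_col)
  df$offset_col <- as.integer(df$offset_col)
  df
}

#' Export annotations as an Audacity label track
#'
#' Tab-separated `start_s end_s label` text usable for listening checks in
#' any editor that reads Audacity label tracks.
#'
#' @param ann annotation data.frame.
#' @param path output .txt path.
#' @param params [spectrogram_params()] for second conversion.
#' @export
write_audacity_labels <- function(ann, path, params = spectrogram_params()) {
  dt <- column_period(params)
  lines <- sprintf("%.6f\t%.6f\t%s", ann$onset_col * dt, ann$offset_col * dt,
                   ann$type_label)
  writeLines(lines, path)
  invisible(path)
}
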