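#' Syllable template
#'
#' Deterministic spectro-temporal recipe for one stereotyped syllable type.
#' Kinds: `"harmonic"` (harmonic stack with a linear fundamental contour),
#' `"buzz"` (low fundamental, many flat-amplitude harmonics - a broadband
#' sounding vocalization), `"complex"` (two-part contour: hold then glide),
#' and `"sweep_complex"` (a brief loud down-sweep prefix followed by the
#' same complex body - paired with a `"complex"` template this reproduces
#' the classic confound of two long syllables distinguishable only by their
#' initial down-sweep).
#'
#' @param label type label.
#' @param kind recipe kind.
#' @param duration_cols nominal duration in spectrogram columns (must be at
#'   least the snippet width so each rendition spans several snippets).
#' @param f0,f1 fundamental start/end frequency in Hz.
#' @param n_harmonics number of partials.
#' @param amp peak amplitude in [0, 1].
#' @param prefix_cols down-sweep prefix length (sweep_complex only).
#' @param sweep_f0,sweep_f1 down-sweep start/end frequency (sweep_complex).
#' @return list of class `voc2n_template`.
#' @export
syllable_template <- function(label, kind = c("harmonic", "buzz", "complex",
                                              "sweep_complex"),
                              duration_cols, f0, f1 = f0, n_harmonics = 6L,
                              amp = 0.5, prefix_cols = 6L, sweep_f0 = 5200,
                              sweep_f1 = 1600) {
  kind <- match.arg(kind)
  stopifnot(duration_cols >= 16, f0 > 0, amp > 0, amp <= 1)
  structure(list(label = label, kind = kind,
                 duration_cols = as.integer(duration_cols), f0 = f0, f1 = f1,
                 n_harmonics = as.integer(n_harmonics), amp = amp,
                 prefix_cols = as.integer(prefix_cols),
                 sweep_f0 = sweep_f0, sweep_f1 = sweep_f1),
            class = "voc2n_template")
}

#' Default five-type repertoire
#'
#' Five spectro-temporally distinct templates labelled A-E. D and E form
#' the confound pair: E is D's long complex body preceded by a brief
#' down-sweep, so the two share their entire 48-column body (89% of E's
#' duration) and are separable only near their onsets.
#'
#' @param confound_pair include the D/E confound pair (`TRUE`) or replace E
#'   by an independent harmonic type (`FALSE`).
#' @return list of [syllable_template()] objects.
#' @export
default_repertoire <- function(confound_pair = TRUE) {
  reps <- list(
    syllable_template("A", "harmonic", 22, f0 = 660, n_harmonics = 6),
    syllable_template("B", "harmonic", 26, f0 = 500, f1 = 1000,
                      n_harmonics = 5),
    syllable_template("C", "buzz", 18, f0 = 420, n_harmonics = 14),
    syllable_template("D", "complex", 48, f0 = 760, f1 = 540, n_harmonics = 6)
  )
  reps[[5]] <- if (confound_pair)
    syllable_template("E", "sweep_complex", 54, f0 = 760, f1 = 540,
                      n_harmonics = 6, prefix_cols = 6)
  else
    syllable_template("E", "harmonic", 30, f0 = 880, f1 = 700,
                      n_harmonics = 4)
  reps
}

# Harmonic-stack synthesis of one rendition: n_samples of audio, pitch and
# duration jittered by the caller. Envelope has raised-cosine edges.
render_syllable <- function(tmpl, dur_cols, pitch_factor, sample_rate, hop) {
  synth_stack <- function(n, fa, fb, n_harm, flat_amp = FALSE) {
    f0 <- seq(fa, fb, length.out = n) * pitch_factor
    phase <- 2 * pi * cumsum(f0) / sample_rate
    out <- numeric(n)
    for (k in seq_len(n_harm)) {
      if (k * max(f0) > sample_rate / 2 * 0.9) break
      a <- if (flat_amp) 1 / sqrt(k) else 1 / k
      out <- out + a * sin(k * phase + k)
    }
    out / max(abs(out))
  }
  n <- dur_cols * hop
  body <- switch(tmpl$kind,
    harmonic = synth_stack(n, tmpl$f0, tmpl$f1, tmpl$n_harmonics),
    buzz = synth_stack(n, tmpl$f0, tmpl$f1, tmpl$n_harmonics, flat_amp = TRUE),
    complex = {
      n1 <- n %/% 2
      c(synth_stack(n1, tmpl$f0, tmpl$f0, tmpl$n_harmonics),
        synth_stack(n - n1, tmpl$f0, tmpl$f1, tmpl$n_harmonics))
    },
    sweep_complex = {
      np <- min(tmpl$prefix_cols * hop, n - hop)
      nb <- n - np
      n1 <- nb %/% 2
      c(synth_stack(np, tmpl$sweep_f0, tmpl$sweep_f1, 2L),
        synth_stack(n1, tmpl$f0, tmpl$f0, tmpl$n_harmonics),
        synth_stack(nb - n1, tmpl$f0, tmpl$f1, tmpl$n_harmonics))
    })
  edge <- min(2L * hop, n %/% 4)
  env <- rep(1, n)
  ramp <- 0.5 * (1 - cos(pi * seq_len(edge) / edge))
  env[seq_len(edge)] <- ramp
  env[n - edge + seq_len(edge)] <- rev(ramp)
  tmpl$amp * body * env
}

render_noise_burst <- function(dur_cols, amp, hop) {
  n <- dur_cols * hop
  env <- rep(1, n)
  edge <- min(hop, n %/% 4)
  ramp <- seq_len(edge) / edge
  env[seq_len(edge)] <- ramp
  env[n - edge + seq_len(edge)] <- rev(ramp)
  amp * stats::rnorm(n) * env
}

#' Scene configuration for the synthetic generator
#'
#' The generator emulates the statistical structure the two-neighborhood
#' method assumes: stereotyped repeated syllable types with small rendition
#' jitter, variable silent gaps, and non-vocal broadband noise that can
#' (i) stand alone in silence, (ii) abut a syllable boundary, destroying its
#' clean amplitude segmentation, or (iii) bridge the gap between two
#' syllables, merging them into one sound interval (the classic call-string
#' error mode).
#'
#' @param n_syllables total renditions (balanced over types).
#' @param repertoire list of [syllable_template()]s.
#' @param gap_cols inclusive range of inter-syllable gaps (columns).
#' @param noise_event_rate standalone noise events per syllable.
#' @param p_boundary_noise probability that a rendition gets a noise burst
#'   abutting one of its boundaries (side chosen at random).
#' @param p_bridge probability that the gap after a rendition is fully
#'   bridged by noise, merging it with the next rendition.
#' @param noise_amp nominal peak amplitude of *standalone* noise events
#'   (distinct cage noises that earn their own sound interval and populate
#'   the embedding's noise cluster); each event draws its level in
#'   `noise_amp * [0.5, 1.5]`. The default 0.15 is 10-20 dB below
#'   vocalization peaks (0.5).
#' @param noise_floor standard deviation of the permanent recording floor
#'   (broadband sensor/ambient noise, roughly -48 dB re vocalization peak).
#' @param boundary_noise_db amplitude range, in dB above the floor, of the
#'   noises attached to syllable boundaries and bridging gaps. These model
#'   respiratory and movement artifacts: with the silence threshold sitting
#'   only a few log-units above the floor, even such faint sounds corrupt
#'   amplitude segmentation, and they are the class the similarity-based
#'   rescue is designed for. Loud noise hard against a boundary changes the
#'   snippet margins beyond recognition and is not recoverable by any
#'   similarity method.
#' @param jitter fractional pitch/duration jitter per rendition.
#' @param lead_cols silent lead-in; its first 200 columns are the silence
#'   region for threshold estimation.
#' @param seed RNG seed; fixed seed gives a bit-identical scene.
#' @return list of class `voc2n_scene_config`.
#' @export
scene_config <- function(n_syllables = 300L,
                         repertoire = default_repertoire(),
                         gap_cols = c(16L, 40L), noise_event_rate = 0.1,
                         p_boundary_noise = 0, p_bridge = 0,
                         noise_amp = 0.15, noise_floor = 2e-3,
                         boundary_noise_db = c(3, 10),
                         jitter = 0.02, lead_cols = 250L, seed = 1L) {
  stopifnot(p_boundary_noise >= 0, p_boundary_noise <= 1,
            p_bridge >= 0, p_bridge <= 1, noise_event_rate >= 0,
            length(gap_cols) == 2, gap_cols[1] <= gap_cols[2])
  if (gap_cols[1] < 8)
    stop("infeasible packing: minimum gap below 8 columns cannot keep ",
         "adjacent syllables acoustically separated")
  if ((p_boundary_noise > 0 || noise_event_rate > 0) && gap_cols[1] < 14)
    stop("infeasible packing: noise events need a minimum gap of 14 columns")
  structure(list(n_syllables = as.integer(n_syllables),
                 repertoire = repertoire, gap_cols = as.integer(gap_cols),
                 noise_event_rate = noise_event_rate,
                 p_boundary_noise = p_boundary_noise, p_bridge = p_bridge,
                 noise_amp = noise_amp, noise_floor = noise_floor,
                 boundary_noise_db = boundary_noise_db,
                 jitter = jitter, lead_cols = as.integer(lead_cols),
                 seed = as.integer(seed)),
            class = "voc2n_scene_config")
}

#' Render a synthetic scene with exact ground truth
#'
#' Lays out jittered renditions of the repertoire separated by random gaps,
#' attaches noise per the config, and synthesizes the waveform at the
#' spectrogram clock (syllable boundaries fall on column edges). Ground
#' truth is obtained by running the package's own amplitude segmentation on
#' the noise-free rendering of the same scene (same syllables, same
#' recording floor, same silence-derived threshold), so a rendition's truth
#' boundaries coincide with the noisy recording's amplitude crossings
#' exactly when no noise was attached to it - making the "cleanly
#' segmented" bookkeeping exact rather than approximate.
#'
#' @param config a [scene_config()].
#' @param spec_params [spectrogram_params()] defining the column clock.
#' @return list with `wave` (noisy scene), `sample_rate`, `truth`
#'   (data.frame: rendition_id, type_label, onset_col, offset_col,
#'   onset_clean, offset_clean), `noise_events` (nominal spans of attached
#'   and standalone noise), `clean_report` (realized clean fractions),
#'   `silence_cols` (columns safe to use as the silence region), `config`.
#' @export
render_scene <- function(config = scene_config(),
                         spec_params = spectrogram_params()) {
  with_seed(config$seed, render_scene_impl(config, spec_params))
}

render_scene_impl <- function(config, spec_params) {
  hop <- spec_params$hop
  sr <- spec_params$sample_rate
  reps <- config$repertoire
  n <- config$n_syllables
  labels <- vapply(reps, `[[`, character(1), "label")
  seq_types <- sample(rep(seq_along(reps), length.out = n))

  # -- lay out the timeline in columns ------------------------------------
  jit <- function() stats::runif(1, 1 - config$jitter, 1 + config$jitter)
  gap_draw <- function() sample(config$gap_cols[1]:config$gap_cols[2], 1)
  pos <- config$lead_cols
  syl <- vector("list", n)
  for (i in seq_len(n)) {
    tmpl <- reps[[seq_types[i]]]
    dur <- max(16L, as.integer(round(tmpl$duration_cols * jit())))
    syl[[i]] <- list(type = seq_types[i], on = pos, off = pos + dur,
                     pitch = jit(), dur = dur)
    pos <- pos + dur + gap_draw()
  }

  # -- noise plan ---------------------------------------------------------
  bridge <- stats::runif(n) < config$p_bridge
  bridge[n] <- FALSE
  contam <- stats::runif(n) < config$p_boundary_noise
  contam_side <- sample(c("onset", "offset"), n, replace = TRUE)
  onset_clean <- rep(TRUE, n)
  offset_clean <- rep(TRUE, n)
  noise_spans <- list()  # (start_col, end_col, kind)
  add_span <- function(a, b, kind)
    noise_spans[[length(noise_spans) + 1L]] <<-
      data.frame(start_col = a, end_col = b, kind = kind)

  for (i in seq_len(n)) {
    if (bridge[i]) {
      add_span(syl[[i]]$off, syl[[i + 1]]$on, "bridge")
      offset_clean[i] <- FALSE
      onset_clean[i + 1] <- FALSE
    }
  }
  # rightmost column occupied by sound belonging to rendition i (grows when
  # an offset-abutting burst is attached)
  tail_end <- vapply(syl, `[[`, numeric(1), "off")
  for (i in seq_len(n)) {
    if (!contam[i]) next
    nb <- sample(6:12, 1)
    if (contam_side[i] == "onset") {
      if (i > 1 && bridge[i - 1]) next  # already unclean via the bridge
      prev_end <- if (i == 1) config$lead_cols %/% 2 else tail_end[i - 1]
      room <- syl[[i]]$on - prev_end - 4L
      nb <- min(nb, room)
      if (nb < 4) next
      add_span(syl[[i]]$on - nb, syl[[i]]$on, "abut_onset")
      onset_clean[i] <- FALSE
    } else {
      if (bridge[i]) next
      next_on <- if (i == n) syl[[i]]$off + 60L else syl[[i + 1]]$on
      room <- next_on - syl[[i]]$off - 4L
      nb <- min(nb, room)
      if (nb < 4) next
      add_span(syl[[i]]$off, syl[[i]]$off + nb, "abut_offset")
      tail_end[i] <- syl[[i]]$off + nb
      offset_clean[i] <- FALSE
    }
  }
  # standalone noise events centered in randomly chosen gaps
  n_noise <- round(config$noise_event_rate * n)
  if (n_noise > 0) {
    gap_ok <- which(vapply(seq_len(n - 1), function(i) {
      !bridge[i] && !(contam[i] && contam_side[i] == "offset") &&
        !(contam[i + 1] && contam_side[i + 1] == "onset") &&
        (syl[[i + 1]]$on - syl[[i]]$off) >= 28
    }, logical(1)))
    pick <- if (length(gap_ok) > 1)
      utils::head(sample(gap_ok), n_noise) else gap_ok
    for (i in pick) {
      g0 <- syl[[i]]$off; g1 <- syl[[i + 1]]$on
      nb <- sample(6L:min(12L, g1 - g0 - 16L), 1)
      a <- g0 + (g1 - g0 - nb) %/% 2
      add_span(a, a + nb, "standalone")
    }
  }
  noise_spans <- if (length(noise_spans)) do.call(rbind, noise_spans)
                 else data.frame(start_col = integer(), end_col = integer(),
                                 kind = character())

  # -- synthesize ---------------------------------------------------------
  total_cols <- syl[[n]]$off + 80L
  n_samples <- total_cols * hop + spec_params$window_length
  floor_noise <- config$noise_floor * stats::rnorm(n_samples)
  clean <- floor_noise
  for (i in seq_len(n)) {
    s <- syl[[i]]
    smp <- render_syllable(reps[[s$type]], s$dur, s$pitch, sr, hop)
    at <- s$on * hop
    clean[at + seq_along(smp)] <- clean[at + seq_along(smp)] + smp
  }
  noisy <- clean
  for (k in seq_len(nrow(noise_spans))) {
    amp <- if (noise_spans$kind[k] == "standalone")
      config$noise_amp * stats::runif(1, 0.5, 1.5)
    else  # faint boundary artifact, a few dB above the floor
      config$noise_floor *
        10^(stats::runif(1, config$boundary_noise_db[1],
                         config$boundary_noise_db[2]) / 20)
    burst <- render_noise_burst(noise_spans$end_col[k] - noise_spans$start_col[k],
                                amp, hop)
    at <- noise_spans$start_col[k] * hop
    noisy[at + seq_along(burst)] <- noisy[at + seq_along(burst)] + burst
  }

  # -- ground truth from the clean rendering ------------------------------
  silence_cols <- c(4L, 200L)
  spec_c <- compute_log_spectrogram(clean, spec_params)
  trace_c <- band_power(spec_c)
  sil_mask <- seq_along(trace_c) - 1L >= silence_cols[1] &
              seq_along(trace_c) - 1L < silence_cols[2]
  thr <- silence_threshold(trace_c, sil_mask)
  truth_int <- detect_sound_intervals(trace_c, thr)
  if (nrow(truth_int) != n)
    stop("infeasible packing: expected ", n, " clean sound intervals, got ",
         nrow(truth_int), "; increase the gaps or lower the rates")
  nominal_on <- vapply(syl, `[[`, numeric(1), "on")
  if (any(abs(truth_int$onset_col - nominal_on) > 4))
    stop("infeasible packing: clean segmentation deviates from the layout")

  # realized cleanliness: which truth boundaries coincide with amplitude
  # crossings of the noisy recording (a planned burst can stay sub-threshold)
  spec_n <- compute_log_spectrogram(noisy, spec_params)
  noisy_int <- detect_sound_intervals(band_power(spec_n), thr)
  onset_clean <- truth_int$onset_col %in% noisy_int$onset_col
  offset_clean <- truth_int$offset_col %in% noisy_int$offset_col

  truth <- data.frame(rendition_id = seq_len(n),
                      type_label = labels[seq_types],
                      onset_col = truth_int$onset_col,
                      offset_col = truth_int$offset_col,
                      onset_clean = onset_clean,
                      offset_clean = offset_clean,
                      stringsAsFactors = FALSE)
  list(wave = noisy, sample_rate = sr, truth = truth,
       noise_events = noise_spans,
       clean_report = list(onset_clean_frac = mean(onset_clean),
                           offset_clean_frac = mean(offset_clean),
                           both_clean_frac = mean(onset_clean & offset_clean)),
       silence_cols = silence_cols, config = config)
}
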