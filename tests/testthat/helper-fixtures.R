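# Shared fixtures, built in code.

# A tiny tone-burst recording: silence | 1 kHz tone | silence, with a faint
# recording floor so silence statistics are well defined.
tone_recording <- function(tone_hz = 1000, n_lead = 8000, n_tone = 16000,
                           n_tail = 8000, amp = 0.5, floor_sd = 1e-4,
                           seed = 42) {
  withr::with_seed(seed, {
    w <- c(rep(0, n_lead), amp * sin(2 * pi * tone_hz *
                                       seq_len(n_tone) / 32000),
           rep(0, n_tail))
    w + stats::rnorm(length(w), 0, floor_sd)
  })
}

# Anchor-event row constructor for extraction tests (already collapsed).
make_events <- function(type, side, crossing, interval_id = 1L,
                        noise = FALSE) {
  n <- max(length(type), length(side), length(crossing))
  data.frame(type_label = rep_len(type, n), side = rep_len(side, n),
             lag_d = ifelse(rep_len(side, n) == "onset", 1L, -1L),
             snippet_id = seq_len(n), interval_id = rep_len(interval_id, n),
             start_col = rep_len(crossing, n) - 4L,
             crossing_col = rep_len(crossing, n),
             noise = rep_len(noise, n), stringsAsFactors = FALSE)
}

# Independent brute-force density oracle: double loop over (pixel, point).
density_oracle <- function(points, grid, r) {
  n_px <- grid$n_px
  out <- matrix(0L, n_px, n_px)
  cx <- grid$x_min + (seq_len(n_px) - 0.5) * grid$dx
  cy <- grid$y_min + (seq_len(n_px) - 0.5) * grid$dy
  for (i in seq_len(n_px)) for (j in seq_len(n_px)) {
    d2 <- (points$x - cx[i])^2 + (points$y - cy[j])^2
    out[i, j] <- sum(d2 <= r * r)
  }
  out
}

# Independent 8-connected flood-fill oracle (breadth-first with an explicit
# frontier, unlike the package's depth-first labeler).
components_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    frontier <- start
    lab[start] <- cur
    while (length(frontier) > 0) {
      nxt <- integer()
      for (p in frontier) {
        pr <- (p - 1L) %% nr + 1L
        pc <- (p - 1L) %/% nr + 1L
        for (dr in -1:1) for (dc in -1:1) {
          rr <- pr + dr; cc <- pc + dc
          if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
          q <- (cc - 1L) * nr + rr
          if (mask[q] && lab[q] == 0L) { lab[q] <- cur; nxt <- c(nxt, q) }
        }
      }
      frontier <- nxt
    }
  }
  lab
}

# Full pipeline on a rendered scene; used by the integration and
# end-to-end tests.
run_scene_pipeline <- function(sc, method = "umap", embed_seed = 1L) {
  prep <- voc2n_prepare(sc$wave, silence = sc$silence_cols, method = method,
                        seed = embed_seed)
  defs <- oracle_blob_defs(sc$truth, prep$emb, prep$intervals,
                           prep$snips$params, prep$grid,
                           noise_onsets = sc$noise_events$start_col)
  ex <- voc2n_extract(prep, defs)
  list(sc = sc, prep = prep, defs = defs, ex = ex)
}

# Fraction of truth renditions recovered with both boundaries within `tol`
# columns by a same-type extracted vocalization.
recovered_fraction <- function(vocs, truth, tol = 1L) {
  hits <- vapply(seq_len(nrow(truth)), function(i) {
    any(vocs$type_label == truth$type_label[i] &
          abs(vocs$onset_col - truth$onset_col[i]) <= tol &
          abs(vocs$offset_col - truth$offset_col[i]) <= tol)
  }, logical(1))
  mean(hits)
}

# Number of extracted vocalizations whose majority-overlap truth type
# differs from their own label.
count_misclassified <- function(vocs, truth) {
  n_cols <- max(truth$offset_col, vocs$offset_col) + 1L
  lab <- rep(NA_character_, n_cols)
  for (i in seq_len(nrow(truth)))
    lab[(truth$onset_col[i] + 1L):truth$offset_col[i]] <- truth$type_label[i]
  sum(vapply(seq_len(nrow(vocs)), function(k) {
    ov <- lab[(vocs$onset_col[k] + 1L):vocs$offset_col[k]]
    tab <- sort(table(ov), decreasing = TRUE)
    length(tab) > 0 && names(tab)[1] != vocs$type_label[k]
  }, logical(1)))
}
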