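#' Assemble the embedding frame
#'
#' Joins embedded coordinates back onto the snippet table, yielding the
#' per-point frame (`snippet_id`, `interval_id`, `start_col`, `forward_lag`,
#' `backward_lag`, `x`, `y`) that the blobs and extraction modules consume.
#'
#' @param snips result of [dissect_snippets()].
#' @param coords result of [embed_snippets()] on `snips$features`.
#' @return data.frame, one row per embedded snippet.
#' @export
embedding_frame <- function(snips, coords) {
  stopifnot(nrow(coords) == nrow(snips$snippets))
  df <- snips$snippets
  ord <- match(as.character(df$snippet_id), coords$snippet_id)
  stopifnot(!anyNA(ord))
  df$x <- coords$x[ord]
  df$y <- coords$y[ord]
  df
}

#' Harvest anchor events from blob definitions
#'
#' For each blob definition: take the lag slice, rasterize the disk-count
#' density at the definition's radius, threshold it, select the definition's
#' component(s), and harvest all points inside (any lag). Each harvested
#' point becomes an anchor event whose crossing column is the amplitude
#' crossing the point implies at the blob's lag ([implied_crossing()]).
#'
#' @param emb frame from [embedding_frame()].
#' @param defs blob-definition table ([blob_definition()] rows).
#' @param snip_params the [snippet_params()] used at dissection.
#' @param grid optional shared [grid_spec()]; defaults to the bounding box
#'   of all points.
#' @return data.frame of anchor events: `type_label`, `side`, `lag_d`,
#'   `snippet_id`, `interval_id`, `start_col`, `crossing_col`, `noise`.
#' @export
anchor_events <- function(emb, defs, snip_params, grid = NULL) {
  if (is.null(grid)) grid <- grid_spec(emb)
  out <- lapply(seq_len(nrow(defs)), function(i) {
    d <- defs$lag_d[i]
    sl <- slice_points(emb, d)
    dens <- density_map(sl, grid, defs$radius_r[i])
    comps <- threshold_blobs(dens, defs$threshold_theta[i])
    want <- defs$blob_index[[i]]
    want <- want[want <= length(comps)]
    if (length(want) == 0) return(NULL)
    idx <- unique(unlist(lapply(comps[want], harvest_points,
                                grid = grid, emb = emb)))
    if (length(idx) == 0) return(NULL)
    pts <- emb[idx, , drop = FALSE]
    data.frame(type_label = defs$type_label[i], side = defs$side[i],
               lag_d = d, snippet_id = pts$snippet_id,
               interval_id = pts$interval_id, start_col = pts$start_col,
               crossing_col = implied_crossing(pts$start_col, d, snip_params),
               noise = isTRUE(defs$noise[i]),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  ev <- do.call(rbind, out)
  if (is.null(ev))
    ev <- data.frame(type_label = character(), side = character(),
                     lag_d = integer(), snippet_id = integer(),
                     interval_id = integer(), start_col = integer(),
                     crossing_col = integer(), noise = logical())
  ev[order(ev$crossing_col, ev$side, ev$type_label, ev$start_col), ,
     drop = FALSE]
}

#' Collapse runs of adjacent anchor events
#'
#' Several adjacent snippets of one rendition often fall into the same blob.
#' Runs of same-type, same-side events from consecutive snippet start
#' columns within one interval collapse to a single event: the earliest
#' snippet for onsets, and by mirror symmetry the latest for offsets (that
#' choice makes the implied crossing land exactly on the interval boundary
#' for cleanly segmented renditions). Duplicate harvests of one snippet by
#' overlapping blobs of the same definition collapse first.
#'
#' @param events data.frame from [anchor_events()].
#' @return collapsed events, sorted by `crossing_col`.
#' @export
collapse_adjacent <- function(events) {
  if (nrow(events) == 0) return(events)
  key <- paste(events$type_label, events$side, events$lag_d, events$interval_id)
  events <- events[!duplicated(paste(key, events$start_col)), , drop = FALSE]
  key <- paste(events$type_label, events$side, events$lag_d, events$interval_id)
  ord <- order(key, events$start_col)
  events <- events[ord, , drop = FALSE]
  key <- key[ord]
  new_run <- c(TRUE, key[-1] != key[-length(key)] |
                 diff(events$start_col) != 1L)
  run_id <- cumsum(new_run)
  keep <- unlist(lapply(split(seq_len(nrow(events)), run_id), function(ii) {
    if (events$side[ii[1]] == "onset") ii[1] else ii[length(ii)]
  }), use.names = FALSE)
  out <- events[sort(keep), , drop = FALSE]
  out[order(out$crossing_col, out$side, out$type_label), , drop = FALSE]
}

# Empty annotation table shared by the extraction routines.
empty_annotations <- function() {
  data.frame(type_label = character(), onset_col = integer(),
             offset_col = integer(), interval_id = integer(),
             provenance = character(), stringsAsFactors = FALSE)
}

empty_discards <- function() {
  data.frame(type_label = character(), side = character(),
             crossing_col = integer(), interval_id = integer(),
             reason = character(), stringsAsFactors = FALSE)
}

#' Pair onset and offset events into extracted vocalizations (2N)
#'
#' Scans the collapsed, time-sorted anchor events of each sound interval.
#' An onset of type T followed by an offset of T emits the vocalization
#' between the two crossings. An onset followed instead by another onset
#' (any type, including a noise pseudo-type), the end of its sound interval,
#' or the end of the file is, in `mode = "truncate"`, emitted up to one
#' column before that event (provenance `truncated_at_event`); in
#' `mode = "strict"` it is discarded. An onset followed by an offset of a
#' *different* type is discarded together with that offset, and offsets with
#' no pending onset of their type are discarded - both rules exist to keep
#' the false-positive rate low. Noise-type onsets never emit vocalizations
#' (see [extract_noise()]) but do terminate a pending vocal onset.
#'
#' @param events collapsed events from [collapse_adjacent()]; must be sorted
#'   by `crossing_col` (ties: offsets first).
#' @param intervals sound-interval table ([detect_sound_intervals()]).
#' @param mode `"truncate"` or `"strict"`.
#' @return list with `vocalizations` (type_label, onset_col, offset_col,
#'   interval_id, provenance), `noise_onsets` (the noise-type onset events,
#'   for [extract_noise()]), and `discards` (event, reason) - a first-class
#'   audit log.
#' @export
pair_2n <- function(events, intervals, mode = c("truncate", "strict")) {
  mode <- match.arg(mode)
  if (nrow(events) > 1 && is.unsorted(events$crossing_col))
    stop("events must be sorted by crossing_col; use collapse_adjacent()")
  vocs <- list(); discards <- list(); vi <- 0L; di <- 0L
  # vocalizations cannot extend beyond their sound interval (without sound
  # there is no vocalization), so emitted boundaries are clamped to it
  add_voc <- function(type, on, off, iid, prov) {
    m <- match(iid, intervals$interval_id)
    on <- max(on, intervals$onset_col[m])
    off <- min(off, intervals$offset_col[m])
    if (off <= on) return(invisible())
    vi <<- vi + 1L
    vocs[[vi]] <<- data.frame(type_label = type, onset_col = as.integer(on),
                              offset_col = as.integer(off), interval_id = iid,
                              provenance = prov, stringsAsFactors = FALSE)
  }
  add_disc <- function(type, side, col, iid, reason) {
    di <<- di + 1L
    discards[[di]] <<- data.frame(type_label = type, side = side,
                                  crossing_col = as.integer(col),
                                  interval_id = iid, reason = reason,
                                  stringsAsFactors = FALSE)
  }
  noise_onsets <- events[events$noise & events$side == "onset", , drop = FALSE]

  for (iid in unique(events$interval_id)) {
    ev <- events[events$interval_id == iid, , drop = FALSE]
    ev <- ev[order(ev$crossing_col, ev$side != "offset"), , drop = FALSE]
    int_end <- intervals$offset_col[match(iid, intervals$interval_id)]
    pend <- NULL  # pending vocal onset: list(type, col)
    close_pending <- function(event_col, reason_label) {
      # onset followed by a non-matching event at event_col
      if (mode == "truncate") {
        off <- event_col - 1L
        if (off > pend$col) add_voc(pend$type, pend$col, off, iid,
                                    "truncated_at_event")
        else add_disc(pend$type, "onset", pend$col, iid, "degenerate_truncation")
      } else {
        add_disc(pend$type, "onset", pend$col, iid, reason_label)
      }
    }
    for (k in seq_len(nrow(ev))) {
      e <- ev[k, ]
      if (e$side == "onset") {
        if (!is.null(pend)) close_pending(e$crossing_col, "onset_then_onset")
        pend <- if (e$noise) NULL else list(type = e$type_label,
                                            col = e$crossing_col)
      } else {  # offset
        if (is.null(pend)) {
          add_disc(e$type_label, "offset", e$crossing_col, iid,
                   "offset_without_onset")
        } else if (e$type_label == pend$type) {
          if (e$crossing_col > pend$col) {
            add_voc(pend$type, pend$col, e$crossing_col, iid, "paired")
          } else {
            add_disc(pend$type, "onset", pend$col, iid, "degenerate_pair")
          }
          pend <- NULL
        } else {
          add_disc(pend$type, "onset", pend$col, iid, "offset_type_mismatch")
          add_disc(e$type_label, "offset", e$crossing_col, iid,
                   "offset_type_mismatch")
          pend <- NULL
        }
      }
    }
    if (!is.null(pend)) close_pending(int_end, "onset_at_interval_end")
  }
  list(vocalizations = if (vi) do.call(rbind, vocs) else empty_annotations(),
       noise_onsets = noise_onsets,
       discards = if (di) do.call(rbind, discards) else empty_discards())
}

#' Onset-anchored single-neighborhood baseline (1N)
#'
#' Each onset event opens a segment running to the next onset event (in any
#' onset blob, noise included) or the end of its sound interval, whichever
#' comes first. This is the natural baseline when only onset blobs are
#' defined; it cannot know where a vocalization ends, so it over-extends
#' into trailing noise. Noise-type events terminate segments but emit none.
#'
#' @param events collapsed events from [collapse_adjacent()].
#' @param intervals sound-interval table.
#' @return annotation data.frame (provenance `"1n_onset"`).
#' @export
extract_1n_onset <- function(events, intervals) {
  events <- events[events$side == "onset", , drop = FALSE]
  if (nrow(events) == 0) return(empty_annotations())
  out <- lapply(split(events, events$interval_id), function(ev) {
    ev <- ev[order(ev$crossing_col), , drop = FALSE]
    iid <- ev$interval_id[1]
    a <- intervals$onset_col[match(iid, intervals$interval_id)]
    b <- intervals$offset_col[match(iid, intervals$interval_id)]
    starts <- pmax(ev$crossing_col, a)
    ends <- pmin(c(ev$crossing_col[-1], b), b)
    keep <- ends > starts & !ev$noise
    if (!any(keep)) return(NULL)
    data.frame(type_label = ev$type_label[keep],
               onset_col = as.integer(starts[keep]),
               offset_col = as.integer(ends[keep]), interval_id = iid,
               provenance = "1n_onset", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty_annotations())
  res[order(res$onset_col), , drop = FALSE]
}

#' Offset-anchored single-neighborhood baseline (1N)
#'
#' Mirror of [extract_1n_onset()]: each offset event closes a segment
#' reaching back to the previous offset event (any blob) or the start of
#' its sound interval. Segments that would be empty (offset at the interval
#' start) are dropped with an audit message.
#'
#' @inheritParams extract_1n_onset
#' @return annotation data.frame (provenance `"1n_offset"`).
#' @export
extract_1n_offset <- function(events, intervals) {
  events <- events[events$side == "offset", , drop = FALSE]
  if (nrow(events) == 0) return(empty_annotations())
  out <- lapply(split(events, events$interval_id), function(ev) {
    ev <- ev[order(ev$crossing_col), , drop = FALSE]
    iid <- ev$interval_id[1]
    a <- intervals$onset_col[match(iid, intervals$interval_id)]
    b <- intervals$offset_col[match(iid, intervals$interval_id)]
    ends <- pmin(ev$crossing_col, b)
    starts <- pmax(c(a, ends[-length(ends)]), a)
    keep <- ends > starts & !ev$noise
    if (any(!keep & !ev$noise))
      message(sum(!keep & !ev$noise),
              " empty 1N-offset segment(s) dropped in interval ", iid)
    if (!any(keep)) return(NULL)
    data.frame(type_label = ev$type_label[keep],
               onset_col = as.integer(starts[keep]),
               offset_col = as.integer(ends[keep]),
               interval_id = iid,
               provenance = "1n_offset", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty_annotations())
  res[order(res$onset_col), , drop = FALSE]
}

#' Extract noise segments
#'
#' Noise clusters have no distinct offset behavior, so a noise segment runs
#' from its extracted onset to the end of the underlying sound interval or
#' the next vocalization onset, whichever comes first. Stale events (at or
#' past the interval end) and zero-length results are dropped with an audit
#' message.
#'
#' @param noise_events noise-type onset events (e.g. `pair_2n()$noise_onsets`).
#' @param intervals sound-interval table.
#' @param vocal_onsets integer vector of extracted vocalization onset
#'   columns.
#' @return data.frame with `onset_col`, `offset_col`, `interval_id`.
#' @export
extract_noise <- function(noise_events, intervals, vocal_onsets = integer()) {
  if (nrow(noise_events) == 0)
    return(data.frame(onset_col = integer(), offset_col = integer(),
                      interval_id = integer()))
  vocal_onsets <- sort(vocal_onsets)
  out <- lapply(seq_len(nrow(noise_events)), function(k) {
    c0 <- noise_events$crossing_col[k]
    iid <- noise_events$interval_id[k]
    b <- intervals$offset_col[match(iid, intervals$interval_id)]
    if (is.na(b) || c0 >= b) {
      message("stale noise onset at column ", c0, " dropped")
      return(NULL)
    }
    nxt <- vocal_onsets[vocal_onsets > c0]
    end <- if (length(nxt)) min(b, nxt[1]) else b
    if (end <= c0) return(NULL)
    data.frame(onset_col = as.integer(c0), offset_col = as.integer(end),
               interval_id = iid)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(onset_col = integer(), offset_col = integer(),
                      interval_id = integer())
  res[order(res$onset_col), , drop = FALSE]
}
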