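#' Fit blob definitions automatically from ground truth
#'
#' Headless stand-in for interactive blob selection on synthetic scenes:
#' for each vocalization type and side it scans lags of increasing |d| and,
#' at each lag, fits the smallest density threshold whose blob (the
#' component holding the type's cleanly segmented slice points) is *pure* -
#' after collapsing runs of adjacent harvested snippets exactly as the
#' extractor will, every resulting anchor event implies an amplitude
#' crossing within `tol` columns of a true boundary of the owning type -
#' while still covering at least `cover_min` of the clean slice points.
#' The first (smallest-|d|) lag admitting such a blob wins, mirroring the
#' manual rule of placing blobs as close to the boundary as possible but
#' away from points of confounding types. For a confound pair sharing
#' endings, every small-|d| offset slice is impure by construction and the
#' scan runs deep into the syllable, ending near the region where the two
#' types first differ (for a shared-body pair, near their onsets).
#'
#' Radii are set from the clean slice points' nearest-neighbor spacing
#' (disks must merge the cluster into one component without swallowing
#' neighboring types); three radius scales are tried per lag. A cheap
#' ambient-impurity gate skips lags where grossly wrong-content points sit
#' deep inside the slice cluster, where no threshold could help.
#'
#' Sound intervals containing no true rendition are treated as a noise
#' pseudo-type: an onset-side blob is fitted for them the same way (its
#' events become noise segments, never vocalizations). Failure to find a
#' noise blob is reported with a message, not an error; failure for a
#' vocal type is an error naming the type.
#'
#' @param truth ground-truth table from [render_scene()].
#' @param emb embedding frame from [embedding_frame()].
#' @param intervals sound-interval table of the *noisy* recording.
#' @param snip_params the [snippet_params()] used at dissection.
#' @param grid optional shared [grid_spec()].
#' @param d_max largest |d| to try (capped at the longest interval's
#'   snippet count).
#' @param tol boundary-accuracy tolerance in columns (events within `tol`
#'   of a true boundary are exact; used to rank candidate blobs).
#' @param tol_confound confound tolerance in columns: an anchor event
#'   farther than this from every true boundary of the type is evidence of
#'   a confounding type inside the blob. Interior blobs (large |d|) carry a
#'   few columns of positional jitter, which is segmentation error rather
#'   than a confound, hence the wider band.
#' @param purity_min minimum confound-free fraction of collapsed anchor
#'   events (1 = no confound tolerated).
#' @param cover_min minimum fraction of clean slice points the blob must
#'   harvest.
#' @param noise_label label for the noise pseudo-type.
#' @param include_noise fit a noise onset blob when noise intervals exist.
#' @param noise_onsets optional vector of columns where noise truly starts
#'   (e.g. `render_scene()$noise_events$start_col`); defaults to the onsets
#'   of the intervals holding no rendition. Noise attached to syllable
#'   boundaries starts mid-interval, so passing the full set lets the noise
#'   blob keep events that are genuinely noise onsets.
#' @return blob-definition table (rows as [blob_definition()]).
#' @export
oracle_blob_defs <- function(truth, emb, intervals, snip_params, grid = NULL,
                             d_max = 50L, tol = 1L, tol_confound = 4L,
                             purity_min = 1, cover_min = 0.6,
                             noise_label = "noise", include_noise = TRUE,
                             noise_onsets = NULL) {
  if (is.null(grid)) grid <- grid_spec(emb)
  px <- max(grid$dx, grid$dy)
  diag_len <- sqrt((grid$x_max - grid$x_min)^2 + (grid$y_max - grid$y_min)^2)
  d_max <- min(d_max, max(emb$forward_lag))

  # distance from each boundary candidate to the nearest target column
  target_dist <- function(cr, targets) {
    targets <- sort(targets)
    i <- findInterval(cr, targets)
    lo <- abs(cr - targets[pmax(i, 1)])
    hi <- abs(cr - targets[pmin(i + 1, length(targets))])
    pmin(lo, hi)
  }

  # collapse harvested snippets into anchor events as the extractor will,
  # then measure (a) the fraction free of confounds (within tol_confound of
  # a true boundary of the type) and (b) the fraction boundary-accurate
  # (within tol); interior blobs carry a little positional jitter, which is
  # segmentation error, not a confound
  # Collapse harvested snippets into anchor events as the extractor will,
  # then score the blob: `conf` is the per-event confound-free fraction
  # (events within tol_confound of a true boundary of the type), `hit0` the
  # fraction of cleanly segmented targets receiving an exactly placed event,
  # `hit1` the fraction of all targets receiving an event within tol.
  collapsed_events <- function(idx, d, side) {
    sub <- emb[idx, c("interval_id", "start_col")]
    sub <- sub[order(sub$interval_id, sub$start_col), ]
    new_run <- c(TRUE, diff(sub$start_col) != 1L |
                   diff(sub$interval_id) != 0L)
    run_id <- cumsum(new_run)
    kept <- vapply(split(sub$start_col, run_id), function(s)
      if (side == "onset") s[1] else s[length(s)], numeric(1))
    iid <- vapply(split(sub$interval_id, run_id), `[`, numeric(1), 1)
    cr <- implied_crossing(kept, d, snip_params)
    # the extractor clamps emissions to the owning sound interval
    m <- match(iid, intervals$interval_id)
    if (side == "onset") pmax(cr, intervals$onset_col[m])
    else pmin(cr, intervals$offset_col[m])
  }
  blob_score <- function(idx, d, side, targets, targets_clean) {
    cr <- collapsed_events(idx, d, side)
    td <- target_dist(cr, targets)
    hit0 <- if (length(targets_clean))
      mean(vapply(targets_clean, function(tg) any(cr == tg), logical(1)))
    else 1
    hit1 <- mean(vapply(targets, function(tg) any(abs(cr - tg) <= tol),
                        logical(1)))
    c(conf = mean(td <= tol_confound), hit0 = hit0, hit1 = hit1)
  }

  fit_side <- function(label, clean_int_ids, target_cols, side,
                       target_clean_cols = target_cols) {
    sgn <- if (side == "onset") 1L else -1L
    overall <- NULL   # best across lags; scan continues 4 lags past the
    found_at <- NA    # first success to fine-tune the anchor position
    for (ad in seq_len(d_max)) {
      if (!is.na(found_at) && ad > found_at + 4) break
      if (!is.null(overall) && overall$score[1] >= 100) break  # already exact
      d <- sgn * ad
      sl <- slice_points(emb, d)
      p <- sl[sl$interval_id %in% clean_int_ids, , drop = FALSE]
      if (nrow(p) < 8) next
      # ambient-impurity gate: grossly wrong-content points deep inside the
      # clean cluster rule this lag out at any threshold
      cr_sl <- implied_crossing(sl$start_col, d, snip_params)
      gross <- sl[target_dist(cr_sl, target_cols) > tol_confound + 2,
                  , drop = FALSE]
      nn <- nn_dist(p$x, p$y)
      r0 <- max(3 * px, 1.5 * stats::quantile(nn, 0.9))
      if (nrow(gross) > 0) {
        dmin <- chunk_min_dist(gross$x, gross$y, p$x, p$y)
        if (sum(dmin < 0.3 * r0) >= max(3, 0.05 * nrow(p))) next
      }
      # among all pure (r, theta) combinations at this lag, keep the blob
      # harvesting the most points: radius as large and threshold as low as
      # possible without extending into confounding content
      best <- NULL
      for (r in unique(pmin(c(0.7, 1, 1.4, 2, 2.8) * r0, 0.05 * diag_len))) {
        dens <- density_map(sl, grid, r)
        pp <- point_pixels(grid, p$x, p$y)
        p_lin <- pp[, 1] + (pp[, 2] - 1L) * grid$n_px
        d_at_p <- dens[p_lin[!is.na(p_lin)]]
        thetas <- sort(unique(pmax(1, round(
          stats::quantile(d_at_p, c(0, 0.05, 0.1, 0.25, 0.5), na.rm = TRUE)))))
        thetas <- unique(c(1L, 2L, as.integer(thetas)))
        for (theta in thetas) {
          comps <- threshold_blobs(dens, theta)
          if (length(comps) == 0) next
          in_comp <- vapply(comps, function(m)
            sum(p_lin %in% m, na.rm = TRUE), numeric(1))
          # a type may own K blobs: adopt every component holding a real
          # share of the clean slice points whose own harvest is confound-free
          cand <- which(in_comp >= max(2, ceiling(0.05 * nrow(p))))
          if (length(cand) == 0) next
          keep <- cand[vapply(cand, function(ci) {
            ii <- harvest_points(comps[[ci]], grid, emb)
            blob_score(ii, d, side, target_cols,
                       target_clean_cols)["conf"] >= purity_min
          }, logical(1))]
          if (sum(in_comp[keep]) / nrow(p) < cover_min) next
          idx <- unique(unlist(lapply(comps[keep], harvest_points,
                                      grid = grid, emb = emb)))
          pur <- blob_score(idx, d, side, target_cols, target_clean_cols)
          if (pur["conf"] < purity_min) next
          # rank: targets exactly hit (clean) + targets within tol (all),
          # in 2% bands, then harvest size
          score <- c(floor((pur["hit0"] + pur["hit1"]) * 50), length(idx))
          if (is.null(best) || score[1] > best$score[1] ||
              (score[1] == best$score[1] && score[2] > best$score[2]))
            best <- list(score = score, n = length(idx), r = r,
                         theta = theta, bi = keep)
        }
      }
      if (!is.null(best)) {
        if (is.na(found_at)) found_at <- ad
        if (is.null(overall) || best$score[1] > overall$score[1] ||
            (best$score[1] == overall$score[1] && best$score[2] > overall$score[2]))
          overall <- c(best, list(d = d))
      }
    }
    if (is.null(overall)) return(NULL)
    blob_definition(label, side, overall$d, overall$r, overall$theta,
                    blob_index = overall$bi,
                    noise = identical(label, noise_label))
  }

  # map renditions to the noisy recording's intervals (by containment)
  int_of <- function(cols) {
    i <- findInterval(cols, intervals$onset_col)
    ok <- i >= 1 & cols < intervals$offset_col[pmax(i, 1)]
    ifelse(ok, intervals$interval_id[pmax(i, 1)], NA_integer_)
  }
  truth$interval_id <- int_of(truth$onset_col)

  defs <- list()
  for (tp in unique(truth$type_label)) {
    tt <- truth[truth$type_label == tp, , drop = FALSE]
    # clean-boundary renditions anchor the slice; all true boundaries of the
    # type (clean or not) count as correct targets for purity
    on_ids <- tt$interval_id[tt$onset_clean & !is.na(tt$interval_id)]
    off_ids <- tt$interval_id[tt$offset_clean & !is.na(tt$interval_id)]
    don <- fit_side(tp, on_ids, tt$onset_col, "onset",
                    tt$onset_col[tt$onset_clean])
    if (is.null(don))
      stop("no separating onset lag found for type ", tp,
           " within |d| <= ", d_max)
    doff <- fit_side(tp, off_ids, tt$offset_col, "offset",
                     tt$offset_col[tt$offset_clean])
    if (is.null(doff))
      stop("no separating offset lag found for type ", tp,
           " within |d| <= ", d_max)
    defs[[length(defs) + 1L]] <- don
    defs[[length(defs) + 1L]] <- doff
  }

  if (include_noise) {
    vocal_ints <- unique(truth$interval_id)
    noise_ints <- setdiff(intervals$interval_id, vocal_ints)
    if (length(noise_ints) >= 5) {
      targets <- noise_onsets %||%
        intervals$onset_col[match(noise_ints, intervals$interval_id)]
      dn <- fit_side(noise_label, noise_ints, targets, "onset")
      if (is.null(dn)) message("no separating onset blob found for the ",
                               "noise cluster; noise segments disabled")
      else defs[[length(defs) + 1L]] <- dn
    }
  }
  do.call(rbind, defs)
}

# Nearest-neighbor distance of each point to any other point of the set.
nn_dist <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  apply(d, 1, min)
}

# For each query point, distance to the nearest reference point.
chunk_min_dist <- function(qx, qy, rx, ry) {
  vapply(seq_along(qx), function(i)
    sqrt(min((qx[i] - rx)^2 + (qy[i] - ry)^2)), numeric(1))
}
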