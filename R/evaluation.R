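# Expand half-open [onset, offset) annotation rows into a per-column label
# vector of the requested length; later rows overwrite earlier on conflict
# (extracted annotations are non-overlapping by construction).
label_vector <- function(ann, n_cols) {
  lab <- rep(NA_character_, n_cols)
  for (k in seq_len(nrow(ann))) {
    a <- max(ann$onset_col[k], 0L)
    b <- min(ann$offset_col[k], n_cols)
    if (b > a) lab[(a + 1L):b] <- ann$type_label[k]
  }
  lab
}

#' Bin-wise extraction score
#'
#' Precision-style score on the 4-ms column clock: for each type, `f` is the
#' fraction of extracted columns of that type whose ground-truth label is
#' that type, and the extraction error is `epsilon = 1 - f`. Unannotated
#' truth columns count as background, so bins extracted over background are
#' errors. A complementary truth-perspective recall (`recall`: fraction of
#' truth columns of the type carrying the correct extracted label) is
#' emitted for diagnostics. Types with zero extracted bins get `f = NA`
#' (undefined), never 0.
#'
#' @param extracted annotation data.frame (`type_label`, `onset_col`,
#'   `offset_col`), half-open columns.
#' @param truth ground-truth annotation data.frame, same clock.
#' @param n_cols length of the column clock; defaults to the max offset seen.
#' @return list with `per_type` (data.frame: type_label, f, epsilon,
#'   recall, n_bins_extracted, n_bins_truth), `pooled` (f, epsilon,
#'   n_bins_extracted over all types), and `mean_type` (unweighted mean of
#'   per-type f over types with defined f).
#' @export
binwise_score <- function(extracted, truth, n_cols = NULL) {
  if (is.null(n_cols))
    n_cols <- max(c(extracted$offset_col, truth$offset_col, 0L))
  ex <- label_vector(extracted, n_cols)
  tr <- label_vector(truth, n_cols)
  types <- sort(unique(c(extracted$type_label, truth$type_label)))
  per <- do.call(rbind, lapply(types, function(tp) {
    e_bins <- !is.na(ex) & ex == tp
    t_bins <- !is.na(tr) & tr == tp
    n_e <- sum(e_bins); n_t <- sum(t_bins)
    f <- if (n_e > 0) sum(e_bins & !is.na(tr) & tr == tp) / n_e else NA_real_
    rec <- if (n_t > 0) sum(t_bins & !is.na(ex) & ex == tp) / n_t else NA_real_
    data.frame(type_label = tp, f = f, epsilon = 1 - f, recall = rec,
               n_bins_extracted = n_e, n_bins_truth = n_t,
               stringsAsFactors = FALSE)
  }))
  n_pool <- sum(!is.na(ex))
  f_pool <- if (n_pool > 0) sum(!is.na(ex) & !is.na(tr) & ex == tr) / n_pool
            else NA_real_
  list(per_type = per,
       pooled = list(f = f_pool, epsilon = 1 - f_pool,
                     n_bins_extracted = n_pool),
       mean_type = mean(per$f, na.rm = TRUE))
}

#' Retrieved-bin ratio against baselines
#'
#' Total number of extracted columns in `extracted` divided by the mean of
#' the totals over the baseline annotation sets. Used to quantify the
#' recall cost of the paired (2N) extraction relative to the mean of the
#' two single-neighborhood baselines.
#'
#' @param extracted annotation data.frame.
#' @param baselines list of annotation data.frames.
#' @return scalar ratio.
#' @export
recall_bins <- function(extracted, baselines) {
  if (!is.data.frame(baselines[[1]]) && is.data.frame(baselines))
    baselines <- list(baselines)
  n_base <- vapply(baselines, function(b) sum(b$offset_col - b$onset_col),
                   numeric(1))
  if (all(n_base == 0)) stop("empty baseline annotation set(s)")
  sum(extracted$offset_col - extracted$onset_col) / mean(n_base)
}

#' Cumulative density of boundary lags to amplitude crossings
#'
#' For each extracted boundary, the lag to its sound interval's amplitude
#' crossing: `onset_col - interval_onset` on the onset side,
#' `interval_offset - offset_col` on the offset side. Cleanly segmented
#' vocalizations have lag 0, so segments taken directly from amplitude
#' thresholding produce a unit step at 0. Boundaries with no valid interval
#' (or a negative lag) land in an overflow count reported as an attribute.
#'
#' @param cols boundary columns (onsets or offsets of extracted
#'   vocalizations).
#' @param interval_ids the owning sound interval of each boundary.
#' @param intervals sound-interval table.
#' @param side `"onset"` or `"offset"`.
#' @return data.frame (`lag`, `cum_fraction`), non-decreasing and reaching
#'   1 at the max lag; attribute `overflow` counts unassignable boundaries.
#'   Zero rows (with a warning) on empty input.
#' @export
lag_cdf <- function(cols, interval_ids, intervals, side = c("onset", "offset")) {
  side <- match.arg(side)
  if (length(cols) == 0) {
    warning("no boundaries supplied; empty lag CDF")
    out <- data.frame(lag = integer(), cum_fraction = numeric())
    attr(out, "overflow") <- 0L
    return(out)
  }
  m <- match(interval_ids, intervals$interval_id)
  lag <- if (side == "onset") cols - intervals$onset_col[m]
         else intervals$offset_col[m] - cols
  bad <- is.na(lag) | lag < 0
  if (any(bad)) message(sum(bad), " boundary(ies) outside any interval; ",
                        "counted in the overflow bucket")
  lag <- lag[!bad]
  tab <- table(lag)
  out <- data.frame(lag = as.integer(names(tab)),
                    cum_fraction = cumsum(as.numeric(tab)) / length(lag))
  attr(out, "overflow") <- sum(bad)
  out
}

#' Evaluate a CDF at a lag
#' @param cdf a [lag_cdf()] result.
#' @param at lag value.
#' @return cumulative fraction at `at` (0 below the smallest lag).
#' @export
cdf_at <- function(cdf, at) {
  if (nrow(cdf) == 0) return(NA_real_)
  i <- findInterval(at, cdf$lag)
  if (i == 0) 0 else cdf$cum_fraction[i]
}
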