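#' Pixel grid over the embedding plane
#'
#' Blobs are defined on a discretized version of the embedding plane. The
#' grid covers the bounding box of the supplied points, expanded by
#' `margin_frac` of each axis range, at `n_px` pixels per axis. Radii and
#' density thresholds are expressed in data (embedding) coordinates, so
#' they rescale with the grid only through pixel quantization.
#'
#' @param points data.frame with `x`, `y` (e.g. from [embed_snippets()]),
#'   or `NULL` when explicit bounds are given.
#' @param n_px pixels per axis.
#' @param margin_frac bounding-box expansion fraction per side.
#' @param x_min,x_max,y_min,y_max explicit bounds (override `points`).
#' @return object of class `voc2n_grid`.
#' @export
grid_spec <- function(points = NULL, n_px = 512L, margin_frac = 0.02,
                      x_min = NULL, x_max = NULL, y_min = NULL, y_max = NULL) {
  stopifnot(n_px >= 16)
  if (is.null(x_min)) {
    stopifnot(!is.null(points), nrow(points) > 0)
    rx <- range(points$x); ry <- range(points$y)
    mx <- max(diff(rx), 1e-9) * margin_frac
    my <- max(diff(ry), 1e-9) * margin_frac
    x_min <- rx[1] - mx; x_max <- rx[2] + mx
    y_min <- ry[1] - my; y_max <- ry[2] + my
  }
  stopifnot(x_min < x_max, y_min < y_max)
  structure(list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max,
                 n_px = as.integer(n_px),
                 dx = (x_max - x_min) / n_px, dy = (y_max - y_min) / n_px),
            class = "voc2n_grid")
}

# Pixel index (1..n_px) containing each coordinate; NA outside the grid.
pixel_index <- function(v, v_min, dv, n_px) {
  i <- floor((v - v_min) / dv) + 1L
  i[v == v_min + n_px * dv] <- n_px  # upper edge belongs to the last pixel
  i[i < 1L | i > n_px] <- NA_integer_
  as.integer(i)
}

point_pixels <- function(grid, x, y) {
  cbind(ix = pixel_index(x, grid$x_min, grid$dx, grid$n_px),
        iy = pixel_index(y, grid$y_min, grid$dy, grid$n_px))
}

#' Select the points of a lag slice
#'
#' The slice at lag `d > 0` contains the points whose forward lag is `d` or
#' `d + 1`; at `d < 0` those whose backward lag is `d` or `d - 1`. Pooling
#' two adjacent lags makes the slice robust to one-column segmentation
#' jitter in otherwise clean renditions.
#'
#' @param emb data.frame carrying at least `forward_lag` and `backward_lag`
#'   per point (see [embedding_frame()]).
#' @param d signed nonzero lag.
#' @return the subset of rows of `emb` in the slice.
#' @export
slice_points <- function(emb, d) {
  stopifnot(d != 0)
  if (d > 0) emb[emb$forward_lag %in% c(d, d + 1L), , drop = FALSE]
  else emb[emb$backward_lag %in% c(d, d - 1L), , drop = FALSE]
}

#' Disk-count density map over the grid
#'
#' The value at each pixel is the number of supplied points lying within
#' Euclidean distance `r` (data coordinates) of the pixel center -
#' equivalently, the number of overlapping radius-`r` disks stamped at the
#' points. Exact integer counts; no kernel smoothing.
#'
#' @param points data.frame with `x`, `y`.
#' @param grid a [grid_spec()] object.
#' @param r disk radius in embedding coordinates.
#' @return integer matrix `n_px x n_px`; rows index x, columns index y.
#' @export
density_map <- function(points, grid, r) {
  stopifnot(r > 0)
  n_px <- grid$n_px
  dens <- matrix(0L, n_px, n_px)
  if (nrow(points) == 0) return(dens)
  cx <- grid$x_min + (seq_len(n_px) - 0.5) * grid$dx
  cy <- grid$y_min + (seq_len(n_px) - 0.5) * grid$dy
  r2 <- r * r
  for (k in seq_len(nrow(points))) {
    px <- points$x[k]; py <- points$y[k]
    ix <- which(abs(cx - px) <= r)
    iy <- which(abs(cy - py) <= r)
    if (length(ix) == 0 || length(iy) == 0) next
    d2 <- outer((cx[ix] - px)^2, (cy[iy] - py)^2, "+")
    hit <- d2 <= r2
    dens[ix, iy] <- dens[ix, iy] + hit
  }
  dens
}

# 8-connected components of a logical matrix via flood fill.
# Returns an integer label matrix (0 = background).
label_components_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (length(fg) == 0) return(labels)
  stack <- integer(length(fg))
  lab <- 0L
  for (seed_px in fg) {
    if (labels[seed_px] != 0L) next
    lab <- lab + 1L
    labels[seed_px] <- lab
    stack[1L] <- seed_px
    top <- 1L
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      pr <- ((p - 1L) %% nr) + 1L
      pc <- ((p - 1L) %/% nr) + 1L
      for (dc in -1:1) {
        cc <- pc + dc
        if (cc < 1L || cc > nc) next
        base <- (cc - 1L) * nr
        for (dr in -1:1) {
          rr <- pr + dr
          if (rr < 1L || rr > nr) next
          q <- base + rr
          if (mask[q] && labels[q] == 0L) {
            labels[q] <- lab
            top <- top + 1L
            if (top > length(stack)) stack <- c(stack, integer(length(stack)))
            stack[top] <- q
          }
        }
      }
    }
  }
  labels
}

#' Threshold a density map into blobs
#'
#' Pixels whose density meets the threshold (`density >= theta` by default;
#' set `inclusive = FALSE` for a strict `>`) are grouped into 8-connected
#' components. Components are returned largest first; ties broken by the
#' smallest linear pixel index, so blob indices are stable for identical
#' inputs.
#'
#' @param density integer matrix from [density_map()].
#' @param theta density threshold (>= 1).
#' @param inclusive whether the threshold itself counts as supra-threshold.
#' @return list of integer vectors of linear pixel indices, one per blob
#'   (possibly empty list).
#' @export
threshold_blobs <- function(density, theta, inclusive = TRUE) {
  stopifnot(theta >= 1)
  mask <- if (inclusive) density >= theta else density > theta
  labels <- label_components_8(mask)
  n_lab <- max(labels)
  if (n_lab == 0L) return(list())
  comps <- unname(split(which(labels > 0L), labels[labels > 0L]))
  sizes <- lengths(comps)
  firsts <- vapply(comps, min, integer(1))
  comps[order(-sizes, firsts)]
}

#' Harvest all points inside a blob
#'
#' Returns every embedded point whose containing pixel belongs to the mask,
#' regardless of the point's lag. This lag-obliviousness is the mechanism
#' by which vocalizations with corrupted amplitude segmentation are rescued:
#' their snippets land near cleanly segmented lookalikes in the plane and
#' fall into the same blob. Points outside the grid are never harvested
#' (a warning reports how many).
#'
#' @param blob_mask integer vector of linear pixel indices (one element of
#'   a [threshold_blobs()] result).
#' @param grid the [grid_spec()] the mask was computed on.
#' @param emb data.frame with `x`, `y` for all points.
#' @return integer row indices into `emb` of the harvested points.
#' @export
harvest_points <- function(blob_mask, grid, emb) {
  pp <- point_pixels(grid, emb$x, emb$y)
  outside <- is.na(pp[, 1]) | is.na(pp[, 2])
  if (any(outside))
    warning(sum(outside), " point(s) fall outside the grid and cannot be harvested")
  lin <- pp[, 1] + (pp[, 2] - 1L) * grid$n_px
  which(!outside & lin %in% blob_mask)
}

#' Propose candidate blob definitions from a density map
#'
#' Advisory helper standing in for interactive blob selection: finds the
#' local maxima of the density map (plateaus of touching maxima collapse to
#' one candidate), and for each proposes a threshold at half the peak height
#' together with the index of the component containing the peak at that
#' threshold. Candidates are ranked by peak height, ties broken by pixel
#' position, so the order is deterministic.
#'
#' @param density integer matrix from [density_map()].
#' @param side `"onset"` or `"offset"` label to copy into the candidates.
#' @param d the lag the density was computed at, copied into the candidates.
#' @return data.frame with `peak`, `theta`, `blob_index`, `px`, `py`,
#'   `side`, `lag_d`, ranked best first.
#' @export
propose_blobs <- function(density, side = "onset", d = 1L) {
  n_px <- nrow(density)
  pad <- matrix(-Inf, n_px + 2L, n_px + 2L)
  pad[2:(n_px + 1L), 2:(n_px + 1L)] <- density
  core <- pad[2:(n_px + 1L), 2:(n_px + 1L)]
  is_max <- core > 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[2:(n_px + 1L) + dr, 2:(n_px + 1L) + dc]
    is_max <- is_max & (core >= nb)
  }
  if (!any(is_max))
    return(data.frame(peak = integer(), theta = integer(),
                      blob_index = integer(), px = integer(), py = integer(),
                      side = character(), lag_d = integer()))
  # collapse plateau-connected maxima to a single representative pixel
  plat <- label_components_8(is_max)
  reps <- vapply(split(which(plat > 0L), plat[plat > 0L]), min, integer(1))
  peak <- density[reps]
  theta <- pmax(1L, as.integer(ceiling(peak / 2)))
  blob_index <- vapply(seq_along(reps), function(k) {
    comps <- threshold_blobs(density, theta[k])
    hit <- which(vapply(comps, function(m) reps[k] %in% m, logical(1)))
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1))
  ord <- order(-peak, reps)
  data.frame(peak = as.integer(peak[ord]), theta = theta[ord],
             blob_index = blob_index[ord],
             px = ((reps[ord] - 1L) %% n_px) + 1L,
             py = ((reps[ord] - 1L) %/% n_px) + 1L,
             side = side, lag_d = as.integer(d), row.names = NULL)
}

#' Construct a blob definition
#'
#' A blob definition names the vocalization type owning the blob, the side
#' it anchors (`onset` for `d > 0`, `offset` for `d < 0`), and the three
#' selection parameters: lag `d`, disk radius `r`, and density threshold
#' `theta`. `blob_index` picks the connected component(s) of the
#' supra-threshold set (in the deterministic [threshold_blobs()] order)
#' that belong to this definition; a type may own several blobs per side.
#'
#' @param type_label vocalization type name.
#' @param side `"onset"` or `"offset"`.
#' @param lag_d signed lag consistent with `side`.
#' @param radius_r disk radius in embedding coordinates.
#' @param threshold_theta density threshold (>= 1).
#' @param blob_index integer vector of component indices (default 1).
#' @param noise `TRUE` marks a noise pseudo-type (onset blobs only; its
#'   events are turned into noise segments, never vocalizations).
#' @return one-row data.frame; rbind rows to form a definition table.
#' @export
blob_definition <- function(type_label, side = c("onset", "offset"), lag_d,
                            radius_r, threshold_theta, blob_index = 1L,
                            noise = FALSE) {
  side <- match.arg(side)
  stopifnot(radius_r > 0, threshold_theta >= 1,
            (side == "onset") == (lag_d > 0))
  data.frame(type_label = type_label, side = side, lag_d = as.integer(lag_d),
             radius_r = radius_r, threshold_theta = as.integer(threshold_theta),
             blob_index = I(list(as.integer(blob_index))), noise = noise,
             stringsAsFactors = FALSE)
}

#' Read / write blob definitions as YAML
#'
#' The YAML file is a list of entries with fields `type`, `side`, `d`, `r`,
#' `theta`, optional `blob_index` (scalar or list) and optional `noise`.
#'
#' @param path YAML file path.
#' @rdname blob_defs_yaml
#' @export
read_blob_defs <- function(path) {
  entries <- yaml::read_yaml(path)
  do.call(rbind, lapply(entries, function(e) {
    blob_definition(e$type, e$side, e$d, e$r, e$theta,
                    blob_index = unlist(e$blob_index %||% 1L),
                    noise = isTRUE(e$noise))
  }))
}

#' @param defs blob-definition table (rbind of [blob_definition()] rows).
#' @rdname blob_defs_yaml
#' @export
write_blob_defs <- function(defs, path) {
  entries <- lapply(seq_len(nrow(defs)), function(i) {
    list(type = defs$type_label[i], side = defs$side[i],
         d = defs$lag_d[i], r = defs$radius_r[i],
         theta = defs$threshold_theta[i],
         blob_index = as.list(defs$blob_index[[i]]),
         noise = isTRUE(defs$noise[i]))
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}
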