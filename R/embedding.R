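#' Embed snippet feature vectors into the plane
#'
#' Projects feature vectors to 2-D with a pluggable embedder. `umap` (the
#' default) and `tsne` run through the Python backends (umap-learn and
#' scikit-learn) in a single-threaded subprocess with `random_state = seed`,
#' so identical inputs and seed give bit-identical coordinates. `pca` is a
#' native deterministic linear projection intended for fast tests and
#' debugging, not for separating real repertoires.
#'
#' All downstream geometry (density maps, blobs, harvesting) is
#' embedder-agnostic: it consumes coordinates only.
#'
#' @param features numeric matrix, one row per snippet; row names are used
#'   as snippet ids when present.
#' @param method `"umap"`, `"tsne"` or `"pca"`.
#' @param seed integer seed for the stochastic embedders.
#' @param n_neighbors,min_dist UMAP neighborhood parameters (library
#'   defaults 15 and 0.1).
#' @param perplexity t-SNE perplexity.
#' @param python python executable to use for `umap`/`tsne`.
#' @return data.frame with `snippet_id`, `x`, `y`.
#' @export
embed_snippets <- function(features, method = c("umap", "tsne", "pca"),
                           seed = 1L, n_neighbors = 15L, min_dist = 0.1,
                           perplexity = 30, python = "python") {
  method <- match.arg(method)
  if (!is.matrix(features)) features <- as.matrix(features)
  if (nrow(features) < 10)
    stop("need at least 10 snippets to embed, got ", nrow(features))
  ids <- rownames(features) %||% as.character(seq_len(nrow(features)))
  bad <- which(!apply(is.finite(features), 1, all))
  if (length(bad) > 0)
    stop("non-finite feature values in snippet(s): ",
         paste(utils::head(ids[bad], 10), collapse = ", "))

  xy <- switch(method,
    pca = embed_pca(features),
    embed_python(features, method, seed, n_neighbors, min_dist, perplexity,
                 python))
  data.frame(snippet_id = ids, x = xy[, 1], y = xy[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

# Deterministic PCA projection: fixed sign so the largest-magnitude loading
# of each component is positive.
embed_pca <- function(features) {
  pc <- stats::prcomp(features, rank. = 2, center = TRUE, scale. = FALSE)
  rot <- pc$rotation
  flip <- vapply(seq_len(ncol(rot)),
                 function(j) sign(rot[which.max(abs(rot[, j])), j]),
                 numeric(1))
  xy <- pc$x[, 1:2, drop = FALSE]
  if (ncol(xy) < 2) xy <- cbind(xy, 0)  # degenerate rank-1 input
  sweep(xy, 2, c(flip, 1)[1:2], "*")
}

embed_python <- function(features, method, seed, n_neighbors, min_dist,
                         perplexity, python) {
  if (Sys.which(python) == "")
    stop("python executable '", python, "' not found; needed for method '",
         method, "' (use method = 'pca' for a python-free projection)")
  script <- system.file("python", "embed_backend.py", package = "voc2n",
                        mustWork = TRUE)
  fin <- tempfile(fileext = ".f64")
  fout <- tempfile(fileext = ".f64")
  on.exit(unlink(c(fin, fout)))
  con <- file(fin, "wb")
  writeBin(as.numeric(t(features)), con, size = 8, endian = "little")
  close(con)
  args <- c(script, method, fin, nrow(features), ncol(features),
            as.integer(seed), fout, n_neighbors, min_dist, perplexity)
  status <- system2(python, shQuote(args), stdout = TRUE, stderr = TRUE,
                    env = c("NUMBA_NUM_THREADS=1", "OMP_NUM_THREADS=1",
                            "OPENBLAS_NUM_THREADS=1", "MKL_NUM_THREADS=1"))
  code <- attr(status, "status") %||% 0L
  if (code != 0L || !file.exists(fout))
    stop("embedding backend failed:\n", paste(status, collapse = "\n"))
  xy <- readBin(fout, "double", n = 2L * nrow(features), size = 8,
                endian = "little")
  matrix(xy, ncol = 2, byrow = TRUE)
}
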