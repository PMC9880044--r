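# Internal helpers shared across modules.

# Power values are clipped at this floor before taking logs. Audio samples
# live in [-1, 1], so per-bin linear powers of interest are >> 1e-12 while
# 1e-12 is still ~1e4 above double-precision rounding noise of a 512-point
# FFT; the resulting log floor (~ -27.6 nats) sits far below any signal.
.power_floor <- 1e-12

log_floor_value <- function(eps = .power_floor) log(eps)

# Run body with a private RNG stream; restores the caller's .Random.seed.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Centered running mean with edge replication; width 1 is the identity.
running_mean <- function(x, width) {
  stopifnot(width >= 1)
  width <- as.integer(width)
  if (width == 1L) return(x)
  half_l <- (width - 1L) %/% 2L
  half_r <- width - 1L - half_l
  xp <- c(rep(x[1L], half_l), x, rep(x[length(x)], half_r))
  cs <- cumsum(xp)
  (cs[seq.int(width, length(xp))] -
     c(0, cs[seq_len(length(xp) - width)])) / width
}

# Maximal runs of TRUE as 0-based half-open [start, end) pairs.
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
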