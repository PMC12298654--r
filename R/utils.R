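# Internal numeric helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Centered moving average with partial windows at the edges, so that
# sum(roll_mean_center(x, w) * window_len) == sum(x) exactly.
roll_mean_center <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  h <- (w - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + (w - 1L - h), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Centered sliding maximum with replicate padding at the boundaries.
roll_max <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  h <- (w - 1L) %/% 2L
  out <- x
  for (k in seq(-h, w - 1L - h)) {
    if (k == 0L) next
    idx <- clamp(seq_len(n) + k, 1L, n)
    out <- pmax(out, x[idx])
  }
  out
}

roll_min <- function(x, w) -roll_max(-x, w)

# Rolling quantile evaluated on a strided grid and linearly interpolated back;
# used for the slowly varying baseline where exactness per-frame is not needed.
roll_quantile <- function(x, w, p, stride = max(1L, w %/% 20L)) {
  n <- length(x)
  h <- (w - 1L) %/% 2L
  at <- unique(c(seq(1L, n, by = stride), n))
  q <- vapply(at, function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    as.numeric(quantile(x[lo:hi], probs = p, names = FALSE, type = 7))
  }, numeric(1))
  if (length(at) == 1L) return(rep(q, n))
  approx(at, q, xout = seq_len(n), rule = 2)$y
}

# Local maxima (strict rise into the peak; plateaus credited to their first
# sample) with topographic prominence. Returns a tibble(index, height, prominence).
find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(tibble::tibble(index = integer(), height = numeric(),
                                    prominence = numeric()))
  # candidate peaks: rise then (possibly after a plateau) fall
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) idx <- c(idx, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(idx)) return(tibble::tibble(index = integer(), height = numeric(),
                                          prominence = numeric()))
  prom <- vapply(idx, function(p) {
    h <- x[p]
    lmin <- h
    i <- p
    while (i > 1L) {
      i <- i - 1L
      if (x[i] > h) break
      lmin <- min(lmin, x[i])
    }
    if (i == 1L && x[i] <= h) lmin <- min(lmin, x[1L])
    rmin <- h
    i <- p
    while (i < n) {
      i <- i + 1L
      if (x[i] > h) break
      rmin <- min(rmin, x[i])
    }
    if (i == n && x[i] <= h) rmin <- min(rmin, x[n])
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence & prom > 0
  tibble::tibble(index = idx[keep], height = x[idx[keep]], prominence = prom[keep])
}

# Contiguous TRUE runs of a logical vector as an integer matrix [start, end].
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# Merge intervals (rows of [start, end]) whose gap is <= gap; assumes sorted.
merge_runs <- function(runs, gap = 0L) {
  if (nrow(runs) <= 1L) return(runs)
  out <- runs[1L, , drop = FALSE]
  for (i in 2L:nrow(runs)) {
    if (runs[i, 1L] - out[nrow(out), 2L] - 1L <= gap) {
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], runs[i, 2L])
    } else out <- rbind(out, runs[i, , drop = FALSE])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
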