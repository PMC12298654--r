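# Shared fixtures and independent oracle implementations.

# temporal intersection-over-union of two intervals
interval_iou <- function(a0, a1, b0, b1) {
  pmax(0, pmin(a1, b1) - pmax(a0, b0)) / (pmax(a1, b1) - pmin(a0, b0))
}

# ---- independent oracles ---------------------------------------------------

# naive per-pixel moving-pixel count, written as explicit loops
brute_force_count <- function(a, b, thr) {
  n <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      if (abs(a[i, j] - b[i, j]) > thr) n <- n + 1L
    }
  }
  n
}

# naive 'same'-padded conv of a (C,H,W) array with (1,C,k,k) weights
naive_spatial_conv <- function(x, w, b) {
  k <- dim(w)[3L]
  p <- (k - 1L) %/% 2L
  H <- dim(x)[2L]; W <- dim(x)[3L]
  out <- matrix(b, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (c in seq_len(dim(x)[1L])) {
      for (di in seq_len(k)) for (dj in seq_len(k)) {
        ii <- i + di - 1L - p; jj <- j + dj - 1L - p
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
          acc <- acc + w[1L, c, di, dj] * x[c, ii, jj]
      }
    }
    out[i, j] <- out[i, j] + acc
  }
  out
}

sig_ <- function(z) 1 / (1 + exp(-z))

# step-by-step CBAM oracle: channel gates, then spatial map, composed by hand
oracle_cbam <- function(x, wt) {
  avg <- apply(x, 1L, mean); mx <- apply(x, 1L, max)
  mlp <- function(v) as.numeric(wt$w2 %*% pmax(wt$w1 %*% v + wt$b1, 0) + wt$b2)
  g <- sig_(mlp(avg) + mlp(mx))
  x1 <- x
  for (c in seq_len(dim(x)[1L])) x1[c, , ] <- x[c, , ] * g[c]
  desc <- array(0, c(2L, dim(x)[2L], dim(x)[3L]))
  desc[1L, , ] <- apply(x1, c(2L, 3L), mean)
  desc[2L, , ] <- apply(x1, c(2L, 3L), max)
  s <- sig_(naive_spatial_conv(desc, wt$w_sp, wt$b_sp))
  out <- x1
  for (c in seq_len(dim(x)[1L])) out[c, , ] <- x1[c, , ] * s
  out
}

# parallel-branch oracle: gates and map both from x, fused, residual added
oracle_cspm <- function(x, wt) {
  avg <- apply(x, 1L, mean); mx <- apply(x, 1L, max)
  mlp <- function(v) as.numeric(wt$w2 %*% pmax(wt$w1 %*% v + wt$b1, 0) + wt$b2)
  g <- sig_(mlp(avg) + mlp(mx))
  desc <- array(0, c(2L, dim(x)[2L], dim(x)[3L]))
  desc[1L, , ] <- apply(x, c(2L, 3L), mean)
  desc[2L, , ] <- apply(x, c(2L, 3L), max)
  s <- sig_(naive_spatial_conv(desc, wt$w_sp, wt$b_sp))
  out <- x
  for (c in seq_len(dim(x)[1L])) out[c, , ] <- x[c, , ] * g[c] * s + x[c, , ]
  out
}

oracle_se <- function(x, wt) {
  avg <- apply(x, 1L, mean)
  g <- sig_(as.numeric(wt$w2 %*% pmax(wt$w1 %*% avg + wt$b1, 0) + wt$b2))
  out <- x
  for (c in seq_len(dim(x)[1L])) out[c, , ] <- x[c, , ] * g[c]
  out
}

# attention weights whose gates are saturated at 1
unit_gate_weights <- function(channels, spatial_kernel = 3) {
  wt <- with_seed_(1, withdrawr::attention_weights(channels, 1, spatial_kernel))
  wt$w1[] <- 0; wt$b1[] <- 0; wt$w2[] <- 0; wt$b2[] <- 40
  wt$w_sp[] <- 0; wt$b_sp <- 40
  wt
}

with_seed_ <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# ---- synthetic inputs ------------------------------------------------------

# raised-cosine click train: k clicks spaced `spacing_s`, in optional noise
click_train_wave <- function(k, spacing_s = 0.08, sr = 48000, dur_s = 5,
                             noise = FALSE, seed = 1, t0 = 1) {
  n <- round(dur_s * sr)
  x <- if (noise) {
    with_seed_(seed, as.numeric(signal::filter(
      signal::butter(2, 0.8, "low"), rnorm(n, 0, 0.01))))
  } else numeric(n)
  m <- 48L
  env <- 0.5 * (1 - cos(2 * pi * (0:(m - 1)) / (m - 1)))
  click <- 0.5 * env * sin(2 * pi * 6500 * (0:(m - 1)) / sr)
  for (j in seq_len(k)) {
    i0 <- round((t0 + (j - 1) * spacing_s) * sr)
    x[i0:(i0 + m - 1L)] <- x[i0:(i0 + m - 1L)] + click
  }
  x
}

# bright disc in one quadrant of a 32x32 frame
quadrant_image <- function(q, size = 32, jit = 2) {
  cx <- c(8, 24, 8, 24)[q] + runif(1, -jit, jit)
  cy <- c(8, 8, 24, 24)[q] + runif(1, -jit, jit)
  xg <- matrix(rep(seq_len(size), each = size), size, size) - cx
  yg <- matrix(rep(seq_len(size), size), size, size) - cy
  img <- matrix(30, size, size)
  img[xg^2 + yg^2 <= 25] <- 220
  pmin(pmax(round(img + rnorm(size * size, 0, 5)), 0), 255)
}

# smooth rhythmic count train with scripted peak rate and per-peak amplitudes
smooth_train_counts <- function(freq_hz, dur_s, fps = 30, amp = 60,
                                alt_ratio = 1, lead_s = 2) {
  t <- (seq_len(round((dur_s + 2 * lead_s) * fps)) - 0.5) / fps
  x <- numeric(length(t))
  on <- t >= lead_s & t < lead_s + dur_s
  ph <- (t - lead_s) * freq_hz
  amps <- ifelse(floor(ph) %% 2 == 0, amp, amp * alt_ratio)
  x[on] <- amps[on] * (0.5 - 0.5 * cos(2 * pi * ph[on]))^2
  x
}

# chatter-vs-other labeled clip set for the audio classifier
make_audio_clipset <- function(n_per_class = 25, seed = 0) {
  with_seed_(seed, {
    clips <- list(); labels <- character()
    for (i in seq_len(n_per_class)) {
      sp <- session_spec(5, dplyr::bind_rows(episode(
        "teeth_chattering", runif(1, 0.5, 2.0), runif(1, 3.2, 4.5),
        click_spacing_ms = runif(1, 60, 120))), seed = 1000 + i)
      clips[[length(clips) + 1L]] <- segment_audio(synth_audio(sp)$wave[, 1],
                                                   48000)[[1L]]
      labels <- c(labels, "chatter")
      sp2 <- session_spec(5, seed = 2000 + i)
      w <- synth_audio(sp2)$wave[, 1]
      if (i %% 2 == 0) {
        t <- (seq_along(w) - 1) / 48000
        w <- w + 0.1 * sin(2 * pi * runif(1, 3000, 9000) * t)
      }
      clips[[length(clips) + 1L]] <- segment_audio(w, 48000)[[1L]]
      labels <- c(labels, "other")
    }
    list(clips = clips, labels = labels)
  })
}

# lazily built, cached shape dataset + model shared across test files
fx_shapes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synth_shape_dataset(n_per_class = 40, seed = 0)
    cache
  }
})

fx_shape_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- train_smoke(fx_shapes()$images, fx_shapes()$labels,
                            variant = "cspm", spatial_kernel = 3, seed = 0)
    cache
  }
})

# small mixed session used by several detector tests (3 shakes + 2 scratches)
fx_rhythm_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- session_spec(40, dplyr::bind_rows(
        episode("wet_dog_shake", 5, 5.8),
        episode("wet_dog_shake", 12, 12.8),
        episode("wet_dog_shake", 20, 20.9),
        episode("scratching", 26, 28),
        episode("scratching", 33, 35.2)), seed = 11)
      ses <- synth_video_session(spec, views = "top")
      cache <<- list(spec = spec, session = ses,
                     sig = build_motion_signal(ses$streams$top))
    }
    cache
  }
})
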