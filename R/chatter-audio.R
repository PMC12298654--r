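# Teeth-chattering detection: waveform preprocessing to candidate click-train
# intervals, mel-spectrogram features, and a squeeze-and-excitation
# convolutional classifier with dual-microphone merging.

#' Segment a recording into fixed-length clips
#'
#' Consecutive clips of `clip_s` seconds; a trailing remainder is zero-padded
#' to full length. Clip offsets are exact multiples of `clip_s`.
#'
#' @param wave Numeric vector (one channel).
#' @param sr Sampling rate, Hz.
#' @param clip_s Clip length, seconds (default 5).
#' @param channel Channel id recorded in the clips (default 0).
#' @return List of `audio_clip` objects (`samples`, `sr`, `t_offset`,
#'   `channel`).
#' @export
segment_audio <- function(wave, sr, clip_s = 5, channel = 0L) {
  if (length(wave) == 0L) return(list())
  n_clip <- round(clip_s * sr)
  n <- ceiling(length(wave) / n_clip)
  lapply(seq_len(n) - 1L, function(i) {
    s <- wave[(i * n_clip + 1L):min(length(wave), (i + 1L) * n_clip)]
    if (length(s) < n_clip) s <- c(s, numeric(n_clip - length(s)))
    structure(list(samples = s, sr = sr, t_offset = i * clip_s,
                   channel = channel),
              class = "audio_clip")
  })
}

#' Median + zero-phase bandpass denoising
#'
#' Median filtering (kernel `median_k`) removes impulsive spikes, then a
#' zero-phase Butterworth bandpass keeps the click band.
#'
#' @param clip An `audio_clip` or numeric vector.
#' @param median_k Odd median kernel length (default 5).
#' @param band_lo_hz,band_hi_hz Passband edges (defaults 2 and 16 kHz).
#' @param sr Sampling rate (taken from the clip if omitted).
#' @return Object of the same kind as the input, filtered.
#' @export
denoise <- function(clip, median_k = 5, band_lo_hz = 2000, band_hi_hz = 16000,
                    sr = NULL) {
  x <- if (inherits(clip, "audio_clip")) clip$samples else clip
  sr <- sr %||% (if (inherits(clip, "audio_clip")) clip$sr else
    rlang::abort("sr required for a bare vector"))
  if (!(band_lo_hz < band_hi_hz && band_hi_hz < sr / 2))
    rlang::abort("need band_lo_hz < band_hi_hz < sr/2")
  y <- runmed(x, median_k, endrule = "constant")
  bp <- signal::butter(4, c(band_lo_hz, band_hi_hz) / (sr / 2), type = "pass")
  y <- as.numeric(signal::filtfilt(bp, y))
  if (inherits(clip, "audio_clip")) { clip$samples <- y; clip } else y
}

#' Envelope gate: zero everything below the mean upper envelope
#'
#' The upper envelope is the magnitude of the analytic signal (FFT Hilbert
#' transform) smoothed over 5 ms. Samples whose envelope value is below the
#' envelope mean are set to zero; values equal to the mean are kept, so a
#' constant-amplitude signal passes unchanged.
#'
#' @inheritParams denoise
#' @return Same kind as the input, gated.
#' @export
envelope_gate <- function(clip, sr = NULL) {
  x <- if (inherits(clip, "audio_clip")) clip$samples else clip
  sr <- sr %||% (if (inherits(clip, "audio_clip")) clip$sr else
    rlang::abort("sr required for a bare vector"))
  env <- upper_envelope(x, sr)
  y <- ifelse(env >= mean(env) * (1 - 1e-12), x, 0)
  if (inherits(clip, "audio_clip")) { clip$samples <- y; clip } else y
}

# analytic-signal magnitude with short moving-average smoothing
upper_envelope <- function(x, sr, smooth_s = 0.005) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2L:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2L:((n + 1L) / 2)] <- 2
  }
  env <- Mod(fft(X * h, inverse = TRUE) / n)
  roll_mean_center(env, max(1L, round(smooth_s * sr)))
}

#' Downsample, rectify the gradient, normalize and threshold
#'
#' Decimates the gated signal by `down_factor` (block maxima of the absolute
#' signal, so 1 ms clicks survive decimation to the ~1 kHz envelope rate),
#' takes the absolute first difference, normalizes to \[0, 1\], and zeroes
#' values below `amp_threshold`.
#'
#' A clip whose gradient has no conspicuous events — crest factor
#' `max(g) / median(g > 0)` below `min_crest` — is zeroed entirely: steady
#' background produces a dense, flat gradient whose relative threshold would
#' otherwise pass noise wiggles, whereas isolated clicks tower over the
#' clip's own floor.
#'
#' @inheritParams denoise
#' @param down_factor Decimation factor (default: to ~1 kHz).
#' @param amp_threshold Relative amplitude threshold (default 0.2).
#' @param min_crest Minimum gradient crest factor for a clip to count as
#'   containing conspicuous sound (default 8).
#' @return List: `samples` (preprocessed signal in \[0, 1\]), `rate` (Hz),
#'   `t_offset` (s).
#' @export
sparsify <- function(clip, down_factor = NULL, amp_threshold = 0.2, sr = NULL,
                     min_crest = 8) {
  x <- if (inherits(clip, "audio_clip")) clip$samples else clip
  sr <- sr %||% (if (inherits(clip, "audio_clip")) clip$sr else
    rlang::abort("sr required for a bare vector"))
  t0 <- if (inherits(clip, "audio_clip")) clip$t_offset else 0
  down_factor <- down_factor %||% max(1L, round(sr / 1000))
  if (down_factor < 1L) rlang::abort("down_factor must be >= 1")
  n <- length(x) %/% down_factor
  if (n < 2L) return(list(samples = numeric(), rate = sr / down_factor,
                          t_offset = t0))
  blocks <- matrix(abs(x[seq_len(n * down_factor)]), down_factor, n)
  dec <- apply(blocks, 2L, max)
  g <- abs(diff(dec))
  if (max(g) > 0) {
    floor_g <- median(g[g > 0])
    if (floor_g > 0 && max(g) / floor_g < min_crest) {
      g[] <- 0 # no conspicuous sound in this clip
    } else {
      g <- g / max(g)
      g[g < amp_threshold] <- 0
    }
  }
  list(samples = g, rate = sr / down_factor, t_offset = t0)
}

#' Candidate chatter intervals from a preprocessed signal
#'
#' Peaks (maxima of the nonzero runs; runs closer than 5 ms — the rise and
#' fall edges of one click — are fused first) are clustered by inter-peak
#' spacing; clusters of three or more closely spaced peaks become candidate
#' intervals spanning first to last peak.
#'
#' @param prep Result of [sparsify()].
#' @param max_spacing_s Maximum inter-peak spacing within a cluster
#'   (default 0.15 s).
#' @param channel Channel id carried into the result.
#' @return Tibble: `t_start`, `t_end`, `n_peaks`, `channel`.
#' @export
find_candidates <- function(prep, max_spacing_s = 0.15, channel = 0L) {
  empty <- tibble::tibble(t_start = numeric(), t_end = numeric(),
                          n_peaks = integer(), channel = integer())
  x <- prep$samples
  if (length(x) == 0L || all(x == 0)) return(empty)
  runs <- merge_runs(logical_runs(x > 0),
                     gap = max(1L, round(0.005 * prep$rate)))
  peak_idx <- vapply(seq_len(nrow(runs)), function(i) {
    span <- runs[i, 1L]:runs[i, 2L]
    span[which.max(x[span])]
  }, numeric(1))
  times <- prep$t_offset + peak_idx / prep$rate
  grp <- cumsum(c(1, diff(times) > max_spacing_s))
  out <- tibble::tibble(times = times, grp = grp) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(t_start = min(.data$times), t_end = max(.data$times),
                     n_peaks = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_peaks >= 3L) |>
    dplyr::mutate(channel = as.integer(channel)) |>
    dplyr::select(-dplyr::any_of("grp"))
  if (nrow(out) == 0L) empty else out
}

#' Mel spectrogram of an audio clip
#'
#' Short-time Fourier transform (Hann window) mapped onto `n_mels`
#' triangular mel filters, in dB. Frame count is
#' `floor((len - win) / hop) + 1`.
#'
#' @inheritParams denoise
#' @param n_mels Number of mel bands (default 40).
#' @param win_ms,hop_ms Window and hop, ms (defaults 25 and 10).
#' @return Matrix `n_mels x n_frames` (dB), with attributes `sr`, `hop_s`.
#' @export
mel_spectrogram <- function(clip, n_mels = 40, win_ms = 25, hop_ms = 10,
                            sr = NULL) {
  x <- if (inherits(clip, "audio_clip")) clip$samples else clip
  sr <- sr %||% (if (inherits(clip, "audio_clip")) clip$sr else
    rlang::abort("sr required for a bare vector"))
  win <- round(win_ms / 1000 * sr)
  hop <- round(hop_ms / 1000 * sr)
  if (length(x) < win) rlang::abort("clip shorter than one analysis window")
  n_frames <- (length(x) - win) %/% hop + 1L
  nfft <- 2^ceiling(log2(win))
  hann <- 0.5 * (1 - cos(2 * pi * (seq_len(win) - 1L) / (win - 1L)))
  fb <- mel_filterbank(n_mels, nfft, sr)
  pow <- matrix(0, nfft %/% 2 + 1L, n_frames)
  for (f in seq_len(n_frames)) {
    seg <- x[((f - 1L) * hop + 1L):((f - 1L) * hop + win)] * hann
    sp <- fft(c(seg, numeric(nfft - win)))
    pow[, f] <- Mod(sp[seq_len(nfft %/% 2 + 1L)])^2
  }
  mel <- 10 * log10(fb %*% pow + 1e-12)
  attr(mel, "sr") <- sr
  attr(mel, "hop_s") <- hop / sr
  mel
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(n_mels, nfft, sr, f_lo = 0, f_hi = sr / 2) {
  pts <- mel_to_hz(seq(hz_to_mel(f_lo), hz_to_mel(f_hi),
                       length.out = n_mels + 2L))
  bins <- (seq_len(nfft %/% 2 + 1L) - 1L) * sr / nfft
  fb <- matrix(0, n_mels, length(bins))
  for (m in seq_len(n_mels)) {
    lo <- pts[m]; mid <- pts[m + 1L]; hi <- pts[m + 2L]
    up <- (bins - lo) / max(mid - lo, 1e-9)
    down <- (hi - bins) / max(hi - mid, 1e-9)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# ---- SE audio classifier ---------------------------------------------------

# Residual SE trunk on a pooled mel image: mel matrices are average-pooled to
# a fixed (n_mels x 48) grid, passed through Conv-ReLU stages with SE blocks
# and one residual stage, then pooled into features.
make_audio_trunk <- function(c1 = 8L, c2 = 16L, se_reduction = 16L, seed = 0L) {
  with_seed(seed, {
    list(c1 = c1, c2 = c2,
         conv1 = init_conv(c1, 1L, 3L), b1 = numeric(c1),
         conv2 = init_conv(c2, c1, 3L), b2 = numeric(c2),
         conv_res = init_conv(c2, c2, 3L), b_res = numeric(c2),
         se1 = attention_weights(c1, max(1L, min(se_reduction, c1)), 3),
         se2 = attention_weights(c2, max(1L, min(se_reduction, c2)), 3))
  })
}

pool_mel <- function(mel, t_bins = 48L) {
  n <- ncol(mel)
  edges <- round(seq(0L, n, length.out = t_bins + 1L))
  out <- matrix(0, nrow(mel), t_bins)
  for (j in seq_len(t_bins)) {
    a <- edges[j] + 1L; b <- max(edges[j + 1L], a)
    out[, j] <- rowMeans(mel[, a:min(b, n), drop = FALSE])
  }
  out
}

audio_forward <- function(trunk, mel) {
  m <- pool_mel(mel)
  m <- (m - mean(m)) / max(sd(m), 1e-8)
  x <- array(m, c(1L, nrow(m), ncol(m)))
  h1 <- relu(conv2d(x, trunk$conv1, trunk$b1, stride = 2L, pad = "same"))
  h1 <- se_block(h1, trunk$se1)
  h2 <- relu(conv2d(h1, trunk$conv2, trunk$b2, stride = 2L, pad = "same"))
  h2 <- se_block(h2, trunk$se2)
  res <- relu(conv2d(h2, trunk$conv_res, trunk$b_res, stride = 1L, pad = "same"))
  h2 <- h2 + res
  c(gap_pool(h1), gmp_pool(h1), gap_pool(h2), gmp_pool(h2))
}

#' Train the chatter-vs-other audio classifier (desk-scale)
#'
#' Converts labeled clips to mel spectrograms, extracts features with a
#' fixed-seed SE convolutional trunk, and trains a logistic readout with a
#' stratified 6:2:2 split.
#'
#' @param clips List of `audio_clip` objects or numeric vectors.
#' @param labels `"chatter"` / `"other"` per clip.
#' @param sr Sampling rate for bare vectors.
#' @param seed Seed for trunk weights and split.
#' @return Object of class `chatter_model` (same fields as a `clip_model`).
#' @export
train_chatter_smoke <- function(clips, labels, sr = NULL, seed = 0) {
  labels <- factor(labels)
  mels <- lapply(clips, function(cl) mel_spectrogram(cl, sr = sr))
  trunk <- make_audio_trunk(seed = seed)
  feats <- t(vapply(mels, function(m) audio_forward(trunk, m),
                    numeric(2L * (8L + 16L))))
  colnames(feats) <- sprintf("f%03d", seq_len(ncol(feats)))
  mu <- colMeans(feats); sdv <- pmax(apply(feats, 2L, sd), 1e-8)
  fs <- sweep(sweep(feats, 2L, mu), 2L, sdv, "/")
  idx <- split_622(labels, seed = seed)
  df <- data.frame(fs); df$.y <- labels
  fit <- with_seed(seed, nnet::multinom(.y ~ ., data = df[idx$train, ],
                                        trace = FALSE, maxit = 400,
                                        decay = 1e-3, MaxNWts = 20000))
  pred <- function(i) factor(as.character(
    predict(fit, newdata = df[i, , drop = FALSE], type = "class")),
    levels = levels(labels))
  report <- per_class_metrics(labels[idx$test], pred(idx$test))
  attr(report, "top1") <- mean(pred(idx$test) == labels[idx$test])
  attr(report, "val_top1") <- mean(pred(idx$val) == labels[idx$val])
  attr(report, "converged") <- isTRUE(fit$convergence == 0)
  structure(list(trunk = trunk, head = fit, classes = levels(labels),
                 scaling = list(mu = mu, sd = sdv), report = report,
                 seed = seed, split = idx),
            class = "chatter_model")
}

#' @export
print.chatter_model <- function(x, ...) {
  cat(sprintf("<chatter_model: %d classes, test top-1 %.3f>\n",
              length(x$classes), attr(x$report, "top1")))
  invisible(x)
}

#' Classify a mel spectrogram as chatter vs other
#'
#' @param mel A [mel_spectrogram()] matrix.
#' @param model A [train_chatter_smoke()] model.
#' @return One-row tibble: `label`, `confidence`.
#' @export
resnet_se_classify <- function(mel, model) {
  f <- audio_forward(model$trunk, mel)
  fs <- (f - model$scaling$mu) / model$scaling$sd
  df <- data.frame(matrix(fs, nrow = 1L,
                          dimnames = list(NULL, names(model$scaling$mu))))
  p <- predict(model$head, newdata = df, type = "probs")
  if (is.null(dim(p)) && length(model$classes) == 2L) {
    probs <- c(1 - p, p); names(probs) <- model$classes
  } else probs <- as.numeric(p)
  k <- which.max(probs)
  tibble::tibble(label = model$classes[k], confidence = unname(probs[k]))
}

#' Merge candidate intervals from two microphones
#'
#' Logical-OR union over time: overlapping or abutting intervals from either
#' channel are merged, so an event heard on one microphone is kept.
#'
#' @param intervals_ch0,intervals_ch1 Candidate tibbles from
#'   [find_candidates()].
#' @return Merged tibble: `t_start`, `t_end`, `n_peaks` (summed over merged
#'   members).
#' @export
merge_channels <- function(intervals_ch0, intervals_ch1) {
  all_iv <- dplyr::bind_rows(intervals_ch0, intervals_ch1)
  if (nrow(all_iv) == 0L)
    return(tibble::tibble(t_start = numeric(), t_end = numeric(),
                          n_peaks = integer()))
  all_iv <- dplyr::arrange(all_iv, .data$t_start)
  out <- all_iv[1L, c("t_start", "t_end", "n_peaks")]
  if (nrow(all_iv) > 1L) {
    for (i in 2L:nrow(all_iv)) {
      j <- nrow(out)
      if (all_iv$t_start[i] <= out$t_end[j]) {
        out$t_end[j] <- max(out$t_end[j], all_iv$t_end[i])
        out$n_peaks[j] <- out$n_peaks[j] + all_iv$n_peaks[i]
      } else out <- dplyr::bind_rows(out, all_iv[i, c("t_start", "t_end",
                                                      "n_peaks")])
    }
  }
  out
}

#' Full audio chain: clips to chatter events
#'
#' Segments the recording into 5 s clips, preprocesses each channel, screens
#' for candidate click trains (clips without candidates skip classification
#' entirely), optionally classifies candidates with a trained model, and
#' merges channels.
#'
#' @param wave Vector or `n x channels` matrix.
#' @param sr Sampling rate.
#' @param model Optional [train_chatter_smoke()] model; without it, screening
#'   alone defines the events.
#' @param clip_s Clip length (default 5 s).
#' @param ... Passed to [denoise()].
#' @return Event tibble (`label`, `t_start`, `t_end`, `duration_s`,
#'   `n_peaks`, `source`).
#' @export
analyze_audio <- function(wave, sr, model = NULL, clip_s = 5, ...) {
  if (is.null(dim(wave))) wave <- matrix(wave, ncol = 1)
  per_ch <- lapply(seq_len(ncol(wave)), function(ch) {
    clips <- segment_audio(wave[, ch], sr, clip_s = clip_s, channel = ch - 1L)
    cands <- lapply(clips, function(cl) {
      prep <- sparsify(envelope_gate(denoise(cl, ...)))
      cand <- find_candidates(prep, channel = cl$channel)
      if (nrow(cand) && !is.null(model)) {
        lab <- resnet_se_classify(mel_spectrogram(cl), model)
        if (lab$label != "chatter") cand <- cand[0, ]
      }
      cand
    })
    dplyr::bind_rows(cands)
  })
  merged <- if (length(per_ch) >= 2L) merge_channels(per_ch[[1L]], per_ch[[2L]])
  else merge_channels(per_ch[[1L]], NULL)
  if (nrow(merged) == 0L)
    return(tibble::tibble(label = character(), t_start = numeric(),
                          t_end = numeric(), duration_s = numeric(),
                          n_peaks = integer(), source = character()))
  dplyr::mutate(merged, label = "teeth_chattering",
                duration_s = .data$t_end - .data$t_start, source = "audio",
                .before = 1L) |>
    dplyr::select("label", "t_start", "t_end", "duration_s", "n_peaks",
                  "source")
}
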