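# Audio chain: clip segmentation, denoising, gating, sparsification,
# candidate extraction, mel spectrograms and channel merging.

test_that("recordings segment into 5 s clips with exact offsets and padding", {
  clips <- segment_audio(numeric(60 * 48000), 48000)
  expect_equal(length(clips), 12L)
  expect_equal(vapply(clips, function(c) c$t_offset, numeric(1)),
               seq(0, 55, by = 5))
  clips2 <- segment_audio(numeric(12.5 * 48000), 48000)
  expect_equal(length(clips2), 3L)
  expect_equal(length(clips2[[3]]$samples), 5 * 48000)
  expect_true(all(clips2[[3]]$samples[(2.5 * 48000 + 1):(5 * 48000)] == 0))
  expect_equal(segment_audio(numeric(0), 48000), list())
})

test_that("denoise keeps the passband and attenuates out-of-band tones", {
  sr <- 48000
  t <- (0:(sr - 1)) / sr
  inband <- 0.3 * sin(2 * pi * 3000 * t)
  y <- denoise(inband, sr = sr)
  mid <- (0.2 * sr):(0.8 * sr)
  gain_db <- 20 * log10(sd(y[mid]) / sd(inband[mid]))
  expect_lt(abs(gain_db), 1)

  tone8k <- 0.3 * sin(2 * pi * 8000 * t)
  y2 <- denoise(tone8k, band_lo_hz = 1000, band_hi_hz = 2000, sr = sr)
  att_db <- 20 * log10(sd(y2[mid]) / sd(tone8k[mid]))
  expect_lt(att_db, -20)

  spike <- numeric(sr); spike[sr / 2] <- 1
  y3 <- runmed(spike, 5)
  expect_equal(max(abs(y3)), 0)
  expect_error(denoise(inband, band_lo_hz = 3000, band_hi_hz = 2000, sr = sr),
               "band")
})

test_that("the envelope gate keeps constant signals and isolates bursts", {
  sr <- 8000
  const <- rep(0.5, sr)
  expect_equal(envelope_gate(const, sr = sr), const)

  x <- numeric(sr)
  burst <- (3000:3200)
  x[burst] <- sin(2 * pi * 3000 * (seq_along(burst) - 1) / sr)
  y <- envelope_gate(x, sr = sr)
  nz <- which(y != 0)
  expect_true(all(nz > 2800 & nz < 3400))
  # output support never exceeds input support
  expect_true(all(y[x == 0] == 0))
})

test_that("sparsify normalizes to [0,1] and keeps separated clicks apart", {
  z <- sparsify(numeric(48000), sr = 48000)
  expect_true(all(z$samples == 0))
  x <- click_train_wave(2, spacing_s = 0.08, dur_s = 2)
  prep <- sparsify(envelope_gate(denoise(segment_audio(x, 48000, clip_s = 2)[[1]])))
  expect_gte(min(prep$samples), 0)
  expect_lte(max(prep$samples), 1)
  nzruns <- withdrawr:::merge_runs(
    withdrawr:::logical_runs(prep$samples > 0), gap = 5L)
  expect_gte(nrow(nzruns), 2L)
})

test_that("candidate intervals require three closely spaced peaks", {
  prep <- function(peaks_at, rate = 1000) {
    s <- numeric(3 * rate)
    s[round(peaks_at * rate)] <- 1
    list(samples = s, rate = rate, t_offset = 0)
  }
  expect_equal(nrow(find_candidates(prep(c(1, 1.08, 1.16)))), 1L)
  expect_equal(nrow(find_candidates(prep(c(1, 1.08)))), 0L)
  expect_equal(nrow(find_candidates(prep(c(0.5, 1.5, 2.5)))), 0L)
  cand <- find_candidates(prep(c(1, 1.08, 1.16, 1.24)))
  expect_equal(cand$n_peaks, 4L)
  expect_lt(abs(cand$t_start - 1), 0.01)
  expect_lt(abs(cand$t_end - 1.24), 0.01)
})

test_that("the smallest click count that yields a candidate is three", {
  smallest <- NA
  for (k in 1:6) {
    clip <- segment_audio(click_train_wave(k, noise = TRUE, seed = k),
                          48000)[[1]]
    cand <- find_candidates(sparsify(envelope_gate(denoise(clip))))
    if (is.na(smallest) && nrow(cand) > 0) smallest <- k
  }
  expect_equal(smallest, 3L)
})

test_that("mel spectrograms have the documented frame count and dB scaling", {
  x <- with_seed_(1, rnorm(5 * 48000, 0, 0.1))
  m <- mel_spectrogram(x, n_mels = 40, win_ms = 25, hop_ms = 10, sr = 48000)
  expect_equal(dim(m), c(40L, 498L))
  # silence: a uniform floor
  ms <- mel_spectrogram(numeric(48000), sr = 48000)
  expect_lt(diff(range(ms)), 1e-6)
  # doubling the amplitude raises everything by ~6 dB
  tone <- 0.2 * sin(2 * pi * 5000 * (0:47999) / 48000)
  d <- mel_spectrogram(2 * tone, sr = 48000) - mel_spectrogram(tone, sr = 48000)
  strong <- mel_spectrogram(tone, sr = 48000) > -40
  expect_lt(abs(median(d[strong]) - 6.02), 0.2)
  expect_error(mel_spectrogram(numeric(100), sr = 48000), "window")
})

test_that("channel merging is a logical-OR union over time", {
  iv <- function(...) {
    v <- c(...)
    m <- matrix(v, ncol = 2, byrow = TRUE)
    tibble::tibble(t_start = m[, 1], t_end = m[, 2], n_peaks = 3L,
                   channel = 0L)
  }
  none <- iv(1, 2)[0, ]
  expect_equal(merge_channels(iv(1, 2), none)$t_end, 2)
  merged <- merge_channels(iv(1, 2), iv(1.5, 3))
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$t_start, merged$t_end), c(1, 3))
  two <- merge_channels(iv(1, 2), iv(4, 5))
  expect_equal(nrow(two), 2L)
})

test_that("every scripted chatter cluster inside a clip becomes a candidate", {
  spec <- session_spec(15, dplyr::bind_rows(
    episode("teeth_chattering", 2, 2.5),
    episode("teeth_chattering", 11, 11.8, click_spacing_ms = 110)),
    audio_channels = 2, seed = 6)
  au <- synth_audio(spec)
  ev <- analyze_audio(au$wave, au$sr)
  expect_equal(nrow(ev), 2L)
  for (i in 1:2) {
    expect_gte(max(interval_iou(au$events$t_start[i], au$events$t_end[i],
                                ev$t_start, ev$t_end)), 0.8)
  }
  expect_true(all(ev$label == "teeth_chattering"))
})

test_that("a minute of audio processes well inside real time", {
  spec <- session_spec(60, dplyr::bind_rows(
    episode("teeth_chattering", 30, 30.5)), seed = 8)
  au <- synth_audio(spec)
  elapsed <- system.time(ev <- analyze_audio(au$wave, au$sr))[["elapsed"]]
  expect_equal(nrow(ev), 1L)
  expect_lt(elapsed, 60)
})
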