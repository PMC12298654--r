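# Synthetic session generator: determinism, ground-truth arithmetic, energy
# calibration, and input validation.

test_that("stationary sessions contain only sensor noise and an empty log", {
  spec <- session_spec(10, dplyr::bind_rows(episode("stationary", 0, 10)),
                       seed = 7)
  ses <- synth_video_session(spec, views = "top")
  sig <- build_motion_signal(ses$streams$top)
  expect_lte(max(sig$counts), 5)
  expect_equal(nrow(ses$events), 0L)
  au <- synth_audio(spec)
  expect_equal(nrow(au$events), 0L)
})

test_that("ground-truth frame spans follow round(t * fps)", {
  spec <- session_spec(15, dplyr::bind_rows(episode("wet_dog_shake", 10, 11)),
                       seed = 1)
  ses <- synth_video_session(spec, views = "top")
  expect_equal(nrow(ses$events), 1L)
  expect_equal(ses$events$label, "wet_dog_shake")
  expect_equal(ses$events$first_frame, 300)
  expect_equal(ses$events$last_frame, 330)
})

test_that("identical seeds render bit-identical video and audio", {
  spec <- session_spec(3, dplyr::bind_rows(
    episode("wet_dog_shake", 0.5, 1.3),
    episode("teeth_chattering", 1.8, 2.3)), seed = 42)
  a <- synth_video_session(spec)
  b <- synth_video_session(spec)
  for (v in names(a$streams))
    expect_identical(a$streams[[v]]$frames, b$streams[[v]]$frames)
  au1 <- synth_audio(spec); au2 <- synth_audio(spec)
  expect_identical(au1$wave, au2$wave)
  # a different seed changes the pixels
  spec2 <- session_spec(3, spec$episodes, seed = 43)
  expect_false(identical(synth_video_session(spec2, views = "top")$streams$top$frames,
                         a$streams$top$frames))
})

test_that("scripted motion is energetically separated from stationary noise", {
  spec <- session_spec(14, dplyr::bind_rows(
    episode("wet_dog_shake", 3, 3.8),
    episode("scratching", 6, 8),
    episode("locomotion", 10, 12, x_cm = 12, y_cm = 22, x_end_cm = 33,
            y_end_cm = 22)), seed = 5)
  ses <- synth_video_session(spec, views = "top")
  sig <- build_motion_signal(ses$streams$top)
  fps <- spec$fps
  stationary <- sig$counts[c(seq_len(2 * fps), (13 * fps):(14 * fps - 1))]
  bound <- 5 * max(1, quantile(stationary, 0.99))
  # sustained-motion episodes clear the bound frame by frame
  loco <- sig$counts[(10.2 * fps):(11.8 * fps)]
  expect_true(all(loco >= bound))
  # pulsatile episodes clear it in motion energy (envelope) throughout
  for (i in 1:2) {
    span <- (round(ses$events$t_start[i] * fps) + 2):
      (round(ses$events$t_end[i] * fps) - 2)
    expect_true(all(sig$envelope[span] >= bound))
  }
})

test_that("conflicting and invalid episode scripts are rejected", {
  expect_error(session_spec(10, dplyr::bind_rows(
    episode("grooming", 1, 4, x_cm = 10, y_cm = 10),
    episode("rearing", 3, 6, x_cm = 30, y_cm = 30))),
    "contradictory")
  expect_error(session_spec(10, dplyr::bind_rows(
    episode("locomotion", 1, 5),
    episode("wet_dog_shake", 4, 4.8, x_cm = 20, y_cm = 20))),
    "contradictory")
  expect_error(episode("wet_dog_shake", 2, 1), "t_end > t_start")
  expect_error(episode("backflip", 0, 1))
  expect_error(session_spec(5, dplyr::bind_rows(episode("grooming", 2, 7))),
               "within")
  expect_error(session_spec(10, audio_sr = 4000), "8000")
})

test_that("chatter click trains match the scripted spacing and count", {
  # 5 clicks spaced 80 ms: ground-truth interval approximately 0.32 s
  spec <- session_spec(4, dplyr::bind_rows(
    episode("teeth_chattering", 1, 1.35, click_spacing_ms = 80)), seed = 2)
  au <- synth_audio(spec)
  expect_equal(au$events$n_clicks, 5L)
  expect_lt(abs((au$events$t_end - au$events$t_start) - 0.32), 0.01)
  # spacing below 2 samples is impossible to render
  spec_bad <- session_spec(4, dplyr::bind_rows(
    episode("teeth_chattering", 1, 1.4, click_spacing_ms = 0.02)), seed = 2)
  expect_error(synth_audio(spec_bad), "2/audio_sr")
})

test_that("dual-microphone audio shares clicks but not noise", {
  spec <- session_spec(4, dplyr::bind_rows(
    episode("teeth_chattering", 1, 1.4)), audio_channels = 2, seed = 3)
  au <- synth_audio(spec)
  expect_equal(ncol(au$wave), 2L)
  expect_false(identical(au$wave[, 1], au$wave[, 2]))
  # the click region is strongly correlated, background is not
  sr <- au$sr
  click_idx <- (1 * sr):(1.4 * sr)
  bg_idx <- (2.5 * sr):(3.5 * sr)
  expect_gt(cor(au$wave[click_idx, 1], au$wave[click_idx, 2]), 0.8)
  expect_lt(abs(cor(au$wave[bg_idx, 1], au$wave[bg_idx, 2])), 0.2)
})

test_that("WAV round trip preserves the waveform to 16-bit precision", {
  spec <- session_spec(1, dplyr::bind_rows(
    episode("teeth_chattering", 0.2, 0.6)), audio_channels = 2, seed = 4)
  au <- synth_audio(spec)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(au$wave, au$sr, path)
  back <- read_wav(path)
  expect_equal(back$sr, au$sr)
  expect_equal(dim(back$wave), dim(au$wave))
  expect_lt(max(abs(back$wave - au$wave)), 1 / 32767 + 1e-9)
})
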