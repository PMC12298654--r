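# Synthetic audio: band-limited background noise with teeth-chattering click
# trains embedded per the session script.

CLICK_DUR_S <- 0.001     # 1 ms raised-cosine burst
CLICK_CARRIER_HZ <- 6500 # inside the 3-10 kHz band
CLICK_AMP <- 0.5
NOISE_SD <- 0.01

#' Synthesize session audio with ground-truth chatter intervals
#'
#' The background is low-pass filtered Gaussian noise; every
#' `teeth_chattering` episode is rendered as a train of 1 ms raised-cosine
#' clicks (6.5 kHz carrier) at the scripted inter-click spacing. With
#' `audio_channels = 2` the second microphone carries independent noise but
#' the same clicks.
#'
#' @param spec A [session_spec()].
#' @return A list with `wave` (numeric matrix `n_samples x n_channels`),
#'   `sr`, and `events`: a tibble of ground-truth chatter intervals
#'   (`label`, `t_start`, `t_end`, `n_clicks`).
#' @export
synth_audio <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  sr <- spec$audio_sr
  n <- round(spec$duration_s * sr)
  ep <- spec$episodes[spec$episodes$label == "teeth_chattering", , drop = FALSE]
  if (nrow(ep) && any(ep$click_spacing_ms / 1000 < 2 / sr))
    rlang::abort("click spacing must be >= 2/audio_sr seconds")

  click <- click_waveform(sr)
  wave <- with_seed(spec$seed + 1L, {
    w <- matrix(0, n, spec$audio_channels)
    lp <- signal::butter(2, min(0.95, 20000 / (sr / 2)), type = "low")
    for (ch in seq_len(spec$audio_channels)) {
      w[, ch] <- as.numeric(signal::filter(lp, rnorm(n, 0, NOISE_SD)))
    }
    w
  })

  truth <- NULL
  if (nrow(ep)) {
    for (i in seq_len(nrow(ep))) {
      spacing <- ep$click_spacing_ms[i] / 1000
      t_clicks <- seq(ep$t_start[i], ep$t_end[i] - CLICK_DUR_S, by = spacing)
      if (length(t_clicks) < 3L)
        rlang::abort(sprintf(
          "teeth_chattering episode %d too short for 3 clicks at %.0f ms spacing",
          i, ep$click_spacing_ms[i]))
      for (tc in t_clicks) {
        s0 <- round(tc * sr) + 1L
        idx <- s0:(s0 + length(click) - 1L)
        ok <- idx >= 1L & idx <= n
        wave[idx[ok], ] <- wave[idx[ok], ] + click[ok]
      }
      truth <- dplyr::bind_rows(truth, tibble::tibble(
        label = "teeth_chattering",
        t_start = t_clicks[1L],
        t_end = t_clicks[length(t_clicks)] + CLICK_DUR_S,
        n_clicks = length(t_clicks)))
    }
  }
  list(wave = wave, sr = sr,
       events = truth %||% tibble::tibble(label = character(),
                                          t_start = numeric(),
                                          t_end = numeric(),
                                          n_clicks = integer()))
}

click_waveform <- function(sr) {
  m <- max(4L, round(CLICK_DUR_S * sr))
  t <- (seq_len(m) - 1L) / sr
  env <- 0.5 * (1 - cos(2 * pi * (seq_len(m) - 1L) / (m - 1L)))
  CLICK_AMP * env * sin(2 * pi * CLICK_CARRIER_HZ * t)
}

#' Write / read a PCM16 mono or stereo WAV file
#'
#' Minimal RIFF/WAVE PCM 16-bit I/O used to persist synthetic recordings.
#'
#' @param wave Numeric vector or `n x channels` matrix in \[-1, 1\].
#' @param sr Sampling rate, Hz.
#' @param path File path.
#' @return `write_wav()` returns `path` invisibly; `read_wav()` returns
#'   `list(wave, sr)` with `wave` an `n x channels` matrix.
#' @export
write_wav <- function(wave, sr, path) {
  if (is.null(dim(wave))) wave <- matrix(wave, ncol = 1)
  n_ch <- ncol(wave)
  pcm <- as.integer(round(clamp(t(wave), -1, 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(sr), con, size = 4, endian = "little")
  writeBin(as.integer(sr * n_ch * 2L), con, size = 4, endian = "little")
  writeBin(as.integer(n_ch * 2L), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) rlang::abort("not a RIFF/WAVE file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  readChar(con, 4) # WAVE
  sr <- NULL; n_ch <- NULL; wave <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      n_ch <- fmt[2L]
      sr <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "raw", sz - 8L))
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", sz / 2L, size = 2, endian = "little")
      wave <- t(matrix(pcm / 32767, nrow = n_ch))
      break
    } else invisible(readBin(con, "raw", sz))
  }
  if (is.null(wave)) rlang::abort("no data chunk found in WAV file")
  list(wave = wave, sr = sr)
}
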