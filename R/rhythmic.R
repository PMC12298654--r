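# Rhythmic-behavior detection on the top-view motion signal: a permissive
# candidate screen (peak trains) followed by strict per-behavior feature
# tests for wet-dog shakes and scratching.

#' Configuration for rhythmic-event detection
#'
#' All thresholds of the two-stage detector in one object; the configuration
#' is attached to every event the detector emits, for provenance.
#'
#' @param prominence_frac Candidate peaks need prominence at least this
#'   fraction of the local (rolling ~1 s) signal maximum (default 0.15).
#' @param min_prominence_abs Absolute prominence floor in moving-pixel
#'   counts (default 10), rejecting sensor-noise wiggles.
#' @param merge_gap_s Peaks closer than this are grouped into one candidate
#'   window (default 0.35 s).
#' @param min_peaks,max_dur_s,f_lo,f_hi,max_height_cv,max_interpeak_cv
#'   Wet-dog-shake test: at least `min_peaks` peaks (default 4), duration at
#'   most `max_dur_s` (default 1.5 s), mean inter-peak interval within
#'   `[1/f_hi, 1/f_lo]` (defaults 16 and 6 Hz), peak-height coefficient of
#'   variation at most `max_height_cv` (default 0.5), and inter-peak-interval
#'   CV at most `max_interpeak_cv` (default 0.4) — a shake burst is regular,
#'   which separates it from quasi-random pixel flicker in the same
#'   frequency band.
#' @param scr_min_dur,scr_max_dur,scr_min_peaks,scr_max_height_cv,
#'   scr_freq_lo,scr_freq_hi,scr_min_concentration Scratching test: duration
#'   in `[scr_min_dur, scr_max_dur]` (defaults 0.5-3 s), at least
#'   `scr_min_peaks` peaks (default 5), height CV at most 0.35, dominant
#'   frequency in `[4, 12]` Hz, and at least `scr_min_concentration`
#'   (default 0.4) of non-DC spectral power within 1 Hz of the dominant
#'   frequency.
#' @return A list of class `rhythm_config`.
#' @export
rhythm_config <- function(prominence_frac = 0.15, min_prominence_abs = 10,
                          merge_gap_s = 0.35,
                          min_peaks = 4, max_dur_s = 1.5,
                          f_lo = 6, f_hi = 16, max_height_cv = 0.5,
                          max_interpeak_cv = 0.4,
                          scr_min_dur = 0.5, scr_max_dur = 3,
                          scr_min_peaks = 5, scr_max_height_cv = 0.45,
                          scr_freq_lo = 4, scr_freq_hi = 12,
                          scr_min_concentration = 0.4) {
  structure(as.list(environment()), class = "rhythm_config")
}

#' Screen a motion signal for candidate rhythmic windows
#'
#' Detects peaks on the raw count train (the count pulses of a shake at 30 fps
#' are narrower than the segment-level smoothing window, so screening runs on
#' the unsmoothed counts) with prominence at least `prominence_frac` times
#' the local rolling maximum, then groups peaks whose spacing is at most
#' `merge_gap_s` into candidate windows.
#'
#' @param sig A [build_motion_signal()] result.
#' @param cfg A [rhythm_config()].
#' @return Tibble of candidate windows: `t_start`, `t_end`, `n_peaks`, and
#'   list-columns `peak_times`, `peak_heights`.
#' @export
screen_candidates <- function(sig, cfg = rhythm_config()) {
  stopifnot(inherits(sig, "motion_signal"))
  x <- sig$counts
  if (max(x) <= 0) return(empty_windows())
  pk <- find_peaks(x, min_prominence = 0)
  if (nrow(pk) == 0L) return(empty_windows())
  # prominence is judged against the local signal scale (rolling maximum over
  # ~1 s) with an absolute floor, so a soft scratch train next to a hard
  # locomotion burst is still screened in
  local_max <- roll_max(x, max(3L, round(sig$fps)))
  keep <- pk$prominence >= pmax(cfg$min_prominence_abs,
                                cfg$prominence_frac * local_max[pk$index])
  pk <- pk[keep, , drop = FALSE]
  if (nrow(pk) == 0L) return(empty_windows())
  # transition i (1-based) happens between frames i-1 and i: time (i - 0.5)/fps
  times <- (pk$index - 0.5) / sig$fps
  grp <- cumsum(c(1, diff(times) > cfg$merge_gap_s))
  tibble::tibble(times = times, heights = pk$height, grp = grp) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(t_start = min(.data$times), t_end = max(.data$times),
                     n_peaks = dplyr::n(),
                     peak_times = list(.data$times),
                     peak_heights = list(.data$heights),
                     .groups = "drop") |>
    dplyr::select(-dplyr::any_of("grp"))
}

empty_windows <- function() {
  tibble::tibble(t_start = numeric(), t_end = numeric(), n_peaks = integer(),
                 peak_times = list(), peak_heights = list())
}

#' Time- and frequency-domain features of a candidate window
#'
#' @param window One-row candidate window from [screen_candidates()].
#' @param sig The originating [build_motion_signal()] (needed for the
#'   spectral features); may be `NULL`, leaving them `NA`.
#' @return One-row tibble: `n_peaks`, `duration_s`, `mean_interpeak_s`,
#'   `interpeak_cv`, `height_cv`, `dominant_freq_hz`,
#'   `spectral_concentration`.
#' @export
rhythm_features <- function(window, sig = NULL) {
  times <- window$peak_times[[1L]]
  heights <- window$peak_heights[[1L]]
  n <- length(times)
  gaps <- diff(times)
  cv <- function(v) if (length(v) < 2L || mean(v) == 0) 0 else sd(v) / mean(v)
  dominant <- NA_real_; conc <- NA_real_
  if (!is.null(sig) && n >= 2L) {
    sp <- window_spectrum(sig, window$t_start, window$t_end)
    dominant <- sp$dominant; conc <- sp$concentration
  }
  tibble::tibble(n_peaks = n,
                 duration_s = window$t_end - window$t_start,
                 mean_interpeak_s = if (n >= 2L) mean(gaps) else NA_real_,
                 interpeak_cv = cv(gaps), height_cv = cv(heights),
                 dominant_freq_hz = dominant, spectral_concentration = conc)
}

# Spectrum of the mean-removed, Hann-windowed count train over a time window,
# zero-padded for frequency resolution. Concentration = fraction of non-DC
# power within +-1 Hz of the dominant frequency.
window_spectrum <- function(sig, t0, t1, pad_s = 0.25) {
  i0 <- max(1L, floor((t0 - pad_s) * sig$fps))
  i1 <- min(length(sig$counts), ceiling((t1 + pad_s) * sig$fps) + 1L)
  x <- sig$counts[i0:i1]
  x <- x - mean(x)
  m <- length(x)
  if (m < 4L) return(list(dominant = NA_real_, concentration = NA_real_))
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(m) - 1L) / (m - 1L)))
  nfft <- 2^ceiling(log2(max(256L, m)))
  spec <- Mod(fft(c(x * w, numeric(nfft - m))))^2
  half <- spec[seq_len(nfft %/% 2 + 1L)]
  freqs <- (seq_along(half) - 1L) * sig$fps / nfft
  use <- freqs > 0.5 # drop DC leakage
  if (!any(use) || sum(half[use]) == 0)
    return(list(dominant = NA_real_, concentration = NA_real_))
  dom <- freqs[use][which.max(half[use])]
  inband <- use & abs(freqs - dom) <= 1
  list(dominant = dom, concentration = sum(half[inband]) / sum(half[use]))
}

#' Wet-dog-shake test on a candidate window
#'
#' True iff the window has at least `min_peaks` peaks, lasts at most
#' `max_dur_s`, its mean inter-peak interval lies in the shake frequency
#' band, its peak heights are similar (CV at most `max_height_cv`) and its
#' inter-peak intervals are regular (CV at most `max_interpeak_cv`).
#'
#' @param window One-row candidate window.
#' @param cfg A [rhythm_config()].
#' @param features Optional precomputed [rhythm_features()].
#' @return Logical.
#' @export
classify_shake <- function(window, cfg = rhythm_config(), features = NULL) {
  f <- features %||% rhythm_features(window)
  isTRUE(f$n_peaks >= cfg$min_peaks &&
           f$duration_s <= cfg$max_dur_s &&
           !is.na(f$mean_interpeak_s) &&
           f$mean_interpeak_s >= 1 / cfg$f_hi &&
           f$mean_interpeak_s <= 1 / cfg$f_lo &&
           f$height_cv <= cfg$max_height_cv &&
           f$interpeak_cv <= cfg$max_interpeak_cv)
}

#' Scratching test on a candidate window
#'
#' True iff duration lies in `[scr_min_dur, scr_max_dur]`, there are at least
#' `scr_min_peaks` peaks of similar height (CV at most `scr_max_height_cv`),
#' the dominant frequency falls in the scratch band and the spectrum is
#' concentrated around it.
#'
#' @inheritParams classify_shake
#' @param sig The originating motion signal (for the spectral features);
#'   required unless `features` is supplied.
#' @return Logical.
#' @export
classify_scratch <- function(window, cfg = rhythm_config(), sig = NULL,
                             features = NULL) {
  f <- features %||% rhythm_features(window, sig)
  isTRUE(f$duration_s >= cfg$scr_min_dur &&
           f$duration_s <= cfg$scr_max_dur &&
           f$n_peaks >= cfg$scr_min_peaks &&
           f$height_cv <= cfg$scr_max_height_cv &&
           !is.na(f$dominant_freq_hz) &&
           f$dominant_freq_hz >= cfg$scr_freq_lo &&
           f$dominant_freq_hz <= cfg$scr_freq_hi &&
           !is.na(f$spectral_concentration) &&
           f$spectral_concentration >= cfg$scr_min_concentration)
}

#' Detect wet-dog shakes and scratching in a motion signal
#'
#' Screens for candidate peak trains, then applies the shake test first (a
#' shake is the stricter, shorter pattern) and the scratch test to windows the
#' shake test rejects.
#'
#' @param sig A [build_motion_signal()] result.
#' @param cfg A [rhythm_config()].
#' @return Event tibble (`label`, `t_start`, `t_end`, `duration_s`,
#'   `n_peaks`, `source`), with `cfg` attached as attribute `config`.
#' @export
detect_rhythmic_events <- function(sig, cfg = rhythm_config()) {
  wins <- screen_candidates(sig, cfg)
  rows <- lapply(seq_len(nrow(wins)), function(i) {
    w <- wins[i, ]
    f <- rhythm_features(w, sig)
    label <- if (classify_shake(w, cfg, features = f)) "wet_dog_shake"
    else if (classify_scratch(w, cfg, features = f)) "scratching"
    else NA_character_
    if (is.na(label)) return(NULL)
    tibble::tibble(label = label, t_start = w$t_start, t_end = w$t_end,
                   duration_s = w$t_end - w$t_start,
                   n_peaks = w$n_peaks, source = "video_top")
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L)
    out <- tibble::tibble(label = character(), t_start = numeric(),
                          t_end = numeric(), duration_s = numeric(),
                          n_peaks = integer(), source = character())
  attr(out, "config") <- cfg
  dplyr::arrange(out, .data$t_start)
}
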