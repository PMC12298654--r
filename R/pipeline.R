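# End-to-end session analysis: motion filtering -> pose/camera dispatch ->
# rhythmic detection (+ optional clip classification and audio chain) ->
# composite scoring, with the data-reduction accounting the design is built
# around.

#' Run the full analysis pipeline on one session
#'
#' Builds the top-view motion signal, extracts motion segments, selects the
#' optimal side camera per segment, detects rhythmic events (wet-dog shakes,
#' scratching), optionally classifies side-view key-frame clips and runs the
#' audio chain, then scores the combined event log.
#'
#' The report carries the data-reduction arithmetic: `frames_discarded` is
#' the redundancy ratio of the motion filter; `side_fraction` is the share of
#' side-stream data touched (one camera of four per segment, 0.25 by
#' construction); `recognition_fraction` is the share of all side frames that
#' reaches recognition, i.e. `(1 - frames_discarded) * side_fraction`.
#'
#' @param session Output of [synth_video_session()] (or a compatible list
#'   with `streams` and `spec`).
#' @param audio Optional output of [synth_audio()].
#' @param clip_model Optional [train_smoke()] model for side-view clips.
#' @param chatter_model Optional [train_chatter_smoke()] model.
#' @param rhythm_cfg A [rhythm_config()].
#' @param k_sigma,min_gap_s,pad_s Passed to [extract_motion_segments()].
#' @param scheme A [score_scheme()].
#' @param threshold_s Duration threshold for scoring (default 0).
#' @param keyframes_k Key frames per clip (default 9).
#' @return Object of class `session_report`: `signal`, `segments`, `events`,
#'   `reduction` (tibble), `score`, plus the configuration used.
#' @export
run_pipeline <- function(session, audio = NULL, clip_model = NULL,
                         chatter_model = NULL, rhythm_cfg = rhythm_config(),
                         k_sigma = 4, min_gap_s = 0.5, pad_s = 0.25,
                         scheme = score_scheme(), threshold_s = 0,
                         keyframes_k = 9) {
  top <- session$streams$top
  if (is.null(top)) rlang::abort("session has no top-view stream")
  sig <- build_motion_signal(top)
  segments <- extract_motion_segments(sig, k_sigma = k_sigma,
                                      min_gap_s = min_gap_s, pad_s = pad_s)
  segments <- dispatch_segments(segments, top)
  redundancy <- redundancy_ratio(segments, length(top))
  side_fraction <- if (nrow(segments)) 0.25 else 0
  recognition_fraction <- (1 - redundancy) * side_fraction

  events <- detect_rhythmic_events(sig, rhythm_cfg)

  if (!is.null(clip_model) && nrow(segments)) {
    clip_rows <- lapply(seq_len(nrow(segments)), function(i) {
      cam <- segments$camera_id[i]
      side <- session$streams[[paste0("side", cam)]]
      if (is.null(side)) return(NULL)
      kf <- select_key_frames(sig, segments[i, ], k = keyframes_k)
      frames <- lapply(kf, function(f) get_frame(side, f))
      res <- classify_clip(frames, clip_model)
      if (res$label == "normal") return(NULL)
      tibble::tibble(label = res$label,
                     t_start = segments$t_start[i],
                     t_end = segments$t_end[i],
                     duration_s = segments$t_end[i] - segments$t_start[i],
                     n_peaks = NA_integer_, source = "video_side")
    })
    events <- dplyr::bind_rows(events, dplyr::bind_rows(clip_rows))
  }

  if (!is.null(audio)) {
    events <- dplyr::bind_rows(
      events, analyze_audio(audio$wave, audio$sr, model = chatter_model))
  }
  events <- dplyr::arrange(events, .data$t_start)

  filtered <- apply_duration_threshold(events, threshold_s)
  score <- score_session(filtered, scheme,
                         session_duration_s = session$spec$duration_s)

  structure(list(
    signal = sig, segments = segments, events = events,
    reduction = tibble::tibble(
      frames_discarded = redundancy,
      side_fraction = side_fraction,
      recognition_fraction = recognition_fraction),
    score = score, threshold_s = threshold_s,
    config = list(rhythm = rhythm_cfg, k_sigma = k_sigma,
                  min_gap_s = min_gap_s, pad_s = pad_s,
                  keyframes_k = keyframes_k)),
    class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat("Session analysis report\n")
  cat(sprintf("  frames discarded by motion filter: %.1f%%\n",
              100 * x$reduction$frames_discarded))
  cat(sprintf("  side-stream fraction processed:    %.1f%%\n",
              100 * x$reduction$side_fraction))
  cat(sprintf("  recognition-frame fraction:        %.2f%%\n",
              100 * x$reduction$recognition_fraction))
  cat(sprintf("  segments: %d, events: %d, score: %.1f (threshold %.3g s)\n",
              nrow(x$segments), nrow(x$events), x$score$score, x$threshold_s))
  if (nrow(x$events)) {
    tab <- table(x$events$label)
    cat("  events by label:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
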