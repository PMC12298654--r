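# Reduction of top-view video to a 1-D moving-pixel count signal, and
# extraction of the motion segments that are worth analyzing further.

#' Moving-pixel count between two frames
#'
#' Counts pixels whose absolute grayscale difference exceeds
#' `pixel_threshold` — the elementary frame-differencing step.
#'
#' @param frame_a,frame_b Equal-shaped grayscale matrices (8-bit scale).
#' @param pixel_threshold Intensity threshold in \[0, 255\] (default 25).
#' @return Integer count of moving pixels.
#' @export
frame_difference <- function(frame_a, frame_b, pixel_threshold = 25) {
  if (!identical(dim(frame_a), dim(frame_b)))
    rlang::abort("frame shapes differ")
  if (pixel_threshold < 0 || pixel_threshold > 255)
    rlang::abort("pixel_threshold must be in [0, 255]")
  sum(abs(frame_a - frame_b) > pixel_threshold)
}

#' Build the 1-D motion signal of a frame stack
#'
#' Computes per-transition moving-pixel counts, an adaptively smoothed version
#' (centered moving average over `round(fps/6)` frames), an upper envelope
#' (sliding maximum over `round(fps/2)` frames) and a slowly varying baseline
#' (rolling 10th percentile over 5 s). The robust noise scale is the median
#' absolute deviation of envelope minus baseline over the whole stream.
#'
#' @param stack A [frame_stack()] with at least 2 frames.
#' @param pixel_threshold Frame-differencing threshold (default 25).
#' @param smooth_w,envelope_w,baseline_w Window lengths in frames; defaults
#'   derive from `fps` as above.
#' @return An object of class `motion_signal` with fields `counts`,
#'   `smoothed`, `envelope`, `baseline`, `noise_scale`, `fps`, `n_frames`,
#'   `view_id`. Element `i` (1-based) of `counts` describes the transition
#'   between 0-based frames `i - 1` and `i`.
#' @export
build_motion_signal <- function(stack, pixel_threshold = 25,
                                smooth_w = NULL, envelope_w = NULL,
                                baseline_w = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- length(stack)
  if (n < 2L) rlang::abort("need at least 2 frames to build a motion signal")
  fps <- stack$fps
  smooth_w <- smooth_w %||% max(1L, round(fps / 6))
  envelope_w <- envelope_w %||% max(3L, round(fps / 2))
  baseline_w <- baseline_w %||% max(5L, round(fps * 5))

  d <- dim(stack$frames)
  m <- matrix(stack$frames, d[1L] * d[2L], d[3L])
  counts <- numeric(n - 1L)
  chunk <- 512L
  for (s in seq(1L, n - 1L, by = chunk)) {
    e <- min(n - 1L, s + chunk - 1L)
    counts[s:e] <- colSums(abs(m[, (s + 1L):(e + 1L), drop = FALSE] -
                                 m[, s:e, drop = FALSE]) > pixel_threshold)
  }

  smoothed <- roll_mean_center(counts, smooth_w)
  envelope <- roll_max(smoothed, envelope_w)
  baseline <- roll_quantile(counts, baseline_w, 0.10)
  structure(list(counts = counts, smoothed = smoothed, envelope = envelope,
                 baseline = baseline,
                 noise_scale = robust_noise_scale(envelope - baseline),
                 fps = fps, n_frames = n, view_id = stack$view_id,
                 smooth_w = smooth_w, envelope_w = envelope_w),
            class = "motion_signal")
}

# MAD of the quiet half of the envelope-minus-baseline distribution: in long
# recordings (mostly stationary animal) this equals the plain MAD, while in
# short dense-motion clips it still measures the quiet-period noise rather
# than the motion itself.
robust_noise_scale <- function(d) {
  mad(d[d <= median(d)])
}

#' @export
print.motion_signal <- function(x, ...) {
  cat(sprintf("<motion_signal '%s': %d transitions @ %g fps, noise scale %.3g>\n",
              x$view_id, length(x$counts), x$fps, x$noise_scale))
  invisible(x)
}

#' @export
as_tibble.motion_signal <- function(x, ...) {
  tibble::tibble(transition = seq_along(x$counts) - 1L,
                 time_s = (seq_along(x$counts) - 0.5) / x$fps,
                 counts = x$counts, smoothed = x$smoothed,
                 envelope = x$envelope, baseline = x$baseline)
}

#' Extract motion segments from a motion signal
#'
#' Transitions where `envelope - baseline > k_sigma * noise_scale` are marked
#' active; the envelope's sliding-maximum dilation is undone by a matching
#' erosion (morphological closing), so an isolated rectangular pulse is
#' recovered exactly while sub-window gaps inside a burst are bridged. Active
#' runs closer than `min_gap_s` are merged, padded by `pad_s` and clipped to
#' the stream bounds.
#'
#' @param sig A [build_motion_signal()] result.
#' @param k_sigma Threshold multiplier on the robust noise scale (default 4).
#' @param min_gap_s Runs closer than this are merged (default 0.5 s).
#' @param pad_s Padding added to both ends of each run (default 0.25 s).
#' @return Tibble of disjoint, sorted segments: `first_frame`, `last_frame`
#'   (0-based, inclusive), `t_start`, `t_end`, `view_id`, `camera_id` (NA
#'   until dispatched).
#' @export
extract_motion_segments <- function(sig, k_sigma = 4, min_gap_s = 0.5,
                                    pad_s = 0.25) {
  stopifnot(inherits(sig, "motion_signal"))
  thr <- k_sigma * sig$noise_scale
  raw <- (sig$envelope - sig$baseline) > thr
  if (!any(raw)) return(empty_segments(sig$view_id))
  # undo the dilation introduced by smoothing + sliding max: erode by the
  # composed half-widths (replicate padding), so an isolated rectangular count
  # pulse is recovered at its exact support
  w_sm <- sig$smooth_w %||% 1L
  h_l <- (sig$envelope_w - 1L) %/% 2L + (w_sm - 1L) %/% 2L
  h_r <- (sig$envelope_w - 1L) - (sig$envelope_w - 1L) %/% 2L +
    (w_sm - 1L) - (w_sm - 1L) %/% 2L
  act <- raw
  n <- length(raw)
  for (k in seq(-h_l, h_r)) {
    if (k == 0L) next
    act <- act & raw[clamp(seq_len(n) + k, 1L, n)]
  }
  if (!any(act)) return(empty_segments(sig$view_id))
  runs <- merge_runs(logical_runs(act), gap = round(min_gap_s * sig$fps))
  pad <- round(pad_s * sig$fps)
  # transition i (1-based) spans 0-based frames [i-1, i]
  first <- clamp(runs[, 1L] - 1L - pad, 0L, sig$n_frames - 1L)
  last <- clamp(runs[, 2L] + pad, 0L, sig$n_frames - 1L)
  seg <- merge_runs(cbind(first, last), gap = 0L)
  tibble::tibble(first_frame = as.integer(seg[, 1L]),
                 last_frame = as.integer(seg[, 2L]),
                 t_start = seg[, 1L] / sig$fps,
                 t_end = seg[, 2L] / sig$fps,
                 view_id = sig$view_id,
                 camera_id = NA_integer_)
}

empty_segments <- function(view_id) {
  tibble::tibble(first_frame = integer(), last_frame = integer(),
                 t_start = numeric(), t_end = numeric(),
                 view_id = character()[seq_len(0)], camera_id = integer())
}

#' Fraction of frames discarded by motion filtering
#'
#' @param segments Segment tibble from [extract_motion_segments()].
#' @param n_frames Total frame count of the stream.
#' @return `1 - frames_inside_segments / n_frames`.
#' @export
redundancy_ratio <- function(segments, n_frames) {
  if (n_frames <= 0) rlang::abort("n_frames must be positive")
  if (nrow(segments) == 0L) return(1.0)
  inside <- sum(segments$last_frame - segments$first_frame + 1L)
  1 - inside / n_frames
}

#' Plot a motion signal with its envelope, baseline and segments
#'
#' @param object A `motion_signal`.
#' @param segments Optional segment tibble to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motion_signal <- function(object, segments = NULL, ...) {
  df <- as_tibble.motion_signal(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$counts), color = "grey60",
                       linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$envelope), color = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$baseline), color = "tomato") +
    ggplot2::labs(x = "time (s)", y = "moving pixels",
                  title = sprintf("Motion signal (%s)", object$view_id))
  if (!is.null(segments) && nrow(segments)) {
    p <- p + ggplot2::geom_rect(
      data = segments, inherit.aes = FALSE, alpha = 0.15, fill = "seagreen",
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                   ymin = -Inf, ymax = Inf))
  }
  p
}

#' Build a motion signal from a precomputed count train
#'
#' Wraps an existing moving-pixel count vector (e.g. computed upstream or
#' constructed analytically) in a `motion_signal`, deriving the smoothed
#' trace, envelope, baseline and noise scale exactly as
#' [build_motion_signal()] does.
#'
#' @param counts Non-negative numeric vector, one value per frame transition.
#' @param fps Frames per second.
#' @param view_id View label (default "top").
#' @inheritParams build_motion_signal
#' @return A `motion_signal` object with `n_frames = length(counts) + 1`.
#' @export
motion_signal_from_counts <- function(counts, fps, view_id = "top",
                                      smooth_w = NULL, envelope_w = NULL,
                                      baseline_w = NULL) {
  stopifnot(all(counts >= 0), fps > 0)
  smooth_w <- smooth_w %||% max(1L, round(fps / 6))
  envelope_w <- envelope_w %||% max(3L, round(fps / 2))
  baseline_w <- baseline_w %||% max(5L, round(fps * 5))
  smoothed <- roll_mean_center(counts, smooth_w)
  envelope <- roll_max(smoothed, envelope_w)
  baseline <- roll_quantile(counts, baseline_w, 0.10)
  structure(list(counts = counts, smoothed = smoothed, envelope = envelope,
                 baseline = baseline,
                 noise_scale = robust_noise_scale(envelope - baseline),
                 fps = fps, n_frames = length(counts) + 1L, view_id = view_id,
                 smooth_w = smooth_w, envelope_w = envelope_w),
            class = "motion_signal")
}
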