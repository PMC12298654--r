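# Synthetic multi-view session generator.
#
# Emulates a single-animal recording cage: a 45 cm square arena filmed from the
# top plus four side cameras, dark background, the animal rendered as a bright
# filled ellipse (2.5:1 axis ratio) with a 1-px tail appendage. Scripted
# episodes drive the scene so that every downstream detector can be exercised
# against exact ground truth.

VIDEO_LABELS <- c("wet_dog_shake", "scratching", "rearing", "grooming",
                  "head_raising", "genital_licking", "face_washing",
                  "wall_supported_rearing", "locomotion", "stationary")
AUDIO_LABELS <- c("teeth_chattering")
BEHAVIOR_LABELS <- c(VIDEO_LABELS, AUDIO_LABELS)

# Labels rendered as a slow rocking of the body in the top view (visible
# motion, but not rhythmic in the 4-16 Hz band the shake/scratch detectors use)
POSTURAL_LABELS <- c("rearing", "grooming", "head_raising", "genital_licking",
                     "face_washing", "wall_supported_rearing")

#' Scripted behavioral episode
#'
#' One row of a session script. Label-specific parameters default to values
#' typical for the behavior (wet-dog shakes burst at 12 Hz for ~0.8 s;
#' scratching trains run at 8 Hz for a couple of seconds; teeth chattering
#' clicks are spaced 80 ms apart).
#'
#' @param label Behavior name; one of
#'   `r paste0('\x60', BEHAVIOR_LABELS, '\x60', collapse = ", ")`.
#' @param t_start,t_end Episode bounds in seconds (`t_end > t_start`).
#' @param freq_hz Rhythm rate: count-peak rate for `wet_dog_shake` /
#'   `scratching`, rocking rate for postural behaviors.
#' @param amplitude Texture modulation amplitude (8-bit intensity units).
#' @param click_spacing_ms Inter-click spacing for `teeth_chattering`.
#' @param heading_deg Body major-axis angle, degrees in image coordinates.
#' @param x_cm,y_cm Body center; defaults to the arena center.
#' @param x_end_cm,y_end_cm End position for `locomotion`.
#' @return A one-row tibble.
#' @export
episode <- function(label, t_start, t_end,
                    freq_hz = NA_real_, amplitude = NA_real_,
                    click_spacing_ms = NA_real_, heading_deg = NA_real_,
                    x_cm = NA_real_, y_cm = NA_real_,
                    x_end_cm = NA_real_, y_end_cm = NA_real_) {
  label <- match.arg(label, BEHAVIOR_LABELS)
  if (!(t_end > t_start)) rlang::abort("episode must have t_end > t_start")
  if (is.na(freq_hz)) {
    freq_hz <- switch(label, wet_dog_shake = 12, scratching = 8,
                      teeth_chattering = NA_real_, 1)
  }
  if (is.na(amplitude)) {
    amplitude <- switch(label, wet_dog_shake = 90, scratching = 80, 0)
  }
  if (label == "teeth_chattering" && is.na(click_spacing_ms)) click_spacing_ms <- 80
  tibble::tibble(label = label, t_start = t_start, t_end = t_end,
                 freq_hz = freq_hz, amplitude = amplitude,
                 click_spacing_ms = click_spacing_ms, heading_deg = heading_deg,
                 x_cm = x_cm, y_cm = y_cm, x_end_cm = x_end_cm,
                 y_end_cm = y_end_cm)
}

#' Session specification for the synthetic generator
#'
#' Collects everything that defines a synthetic recording session: duration,
#' camera timing and resolution, arena size, the scripted episode list, audio
#' parameters and the RNG seed. Identical specs (same seed) render to
#' bit-identical pixel arrays and waveforms.
#'
#' @param duration_s Session length, seconds.
#' @param episodes Tibble of [episode()] rows; may be empty.
#' @param fps Frames per second (default 30).
#' @param frame_size `c(height, width)` in pixels.
#' @param arena_cm Square arena side, cm.
#' @param audio_sr Audio sampling rate, Hz (>= 8000).
#' @param audio_channels 1 or 2 (dual-microphone emulation).
#' @param noise_sd Additive Gaussian pixel noise SD on the 8-bit scale.
#' @param seed Integer RNG seed.
#' @param sync Either `NULL` (no synchronization flash) or a list
#'   `list(frame = <int>, offsets = <named int vector per view>)`: a global
#'   brightness step of +60 intensity units is applied from frame
#'   `frame + offset` onward in each stream.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(duration_s, episodes = NULL, fps = 30,
                         frame_size = c(64, 64), arena_cm = 45,
                         audio_sr = 48000, audio_channels = 1,
                         noise_sd = 2, seed = 1, sync = NULL) {
  stopifnot(duration_s > 0, fps > 0, length(frame_size) == 2L, arena_cm > 0)
  if (audio_sr < 8000) rlang::abort("audio_sr must be >= 8000 Hz")
  if (is.null(episodes)) episodes <- episode("stationary", 0, duration_s)[0, ]
  if (nrow(episodes)) {
    if (any(episodes$t_start < 0) || any(episodes$t_end > duration_s))
      rlang::abort("every episode must lie within [0, duration_s]")
    check_episode_conflicts(episodes)
  }
  structure(list(duration_s = duration_s, fps = fps,
                 frame_size = as.integer(frame_size), arena_cm = arena_cm,
                 episodes = dplyr::arrange(episodes, .data$t_start),
                 audio_sr = audio_sr, audio_channels = audio_channels,
                 noise_sd = noise_sd, seed = as.integer(seed), sync = sync),
            class = "session_spec")
}

# Two time-overlapping body-driving episodes with contradictory scripted
# positions cannot be rendered; refuse early.
check_episode_conflicts <- function(ep) {
  vid <- ep[ep$label %in% VIDEO_LABELS, ]
  if (nrow(vid) < 2L) return(invisible(TRUE))
  for (i in seq_len(nrow(vid) - 1L)) {
    for (j in (i + 1L):nrow(vid)) {
      overlap <- vid$t_start[i] < vid$t_end[j] && vid$t_start[j] < vid$t_end[i]
      if (!overlap) next
      pos_i <- c(vid$x_cm[i], vid$y_cm[i]); pos_j <- c(vid$x_cm[j], vid$y_cm[j])
      contradictory <-
        vid$label[i] == "locomotion" || vid$label[j] == "locomotion" ||
        (!anyNA(pos_i) && !anyNA(pos_j) && any(pos_i != pos_j))
      if (contradictory)
        rlang::abort(sprintf(
          "overlapping episodes with contradictory positions: rows %d (%s) and %d (%s)",
          i, vid$label[i], j, vid$label[j]))
    }
  }
  invisible(TRUE)
}

#' @export
print.session_spec <- function(x, ...) {
  cat(sprintf("<session_spec: %.4g s @ %g fps, %dx%d px, %d episode(s), seed %d>\n",
              x$duration_s, x$fps, x$frame_size[1], x$frame_size[2],
              nrow(x$episodes), x$seed))
  invisible(x)
}

# ---- top-view rendering ----------------------------------------------------

# Geometry of the rendered body, in cm (converted with the px/cm scale).
BODY_SEMI_MAJOR_CM <- 9
BODY_AXIS_RATIO <- 2.5
TAIL_LENGTH_CM <- 7
BG_LEVEL <- 20
BODY_LEVEL <- 200

# Filled-ellipse mask plus 1-px tail. `cx, cy` in px (x = column, y = row),
# theta in degrees. Returns a numeric H x W matrix of noiseless intensities.
render_body <- function(H, W, cx, cy, theta_deg, a_px, b_px, tail_px = 0) {
  th <- theta_deg * pi / 180
  xg <- matrix(rep(seq_len(W), each = H), H, W) - cx
  yg <- matrix(rep(seq_len(H), W), H, W) - cy
  u <- (xg * cos(th) + yg * sin(th)) / a_px
  v <- (-xg * sin(th) + yg * cos(th)) / b_px
  img <- matrix(BG_LEVEL, H, W)
  img[u * u + v * v <= 1] <- BODY_LEVEL
  if (tail_px > 0) {
    # thin appendage from the rear pole outward along -major axis
    s <- seq(0, tail_px, by = 0.5)
    tx <- round(cx - (a_px + s) * cos(th))
    ty <- round(cy - (a_px + s) * sin(th))
    ok <- tx >= 1 & tx <= W & ty >= 1 & ty <= H
    img[cbind(ty[ok], tx[ok])] <- BODY_LEVEL
  }
  img
}

# ---- pose timeline ---------------------------------------------------------
# The body pose is continuous in time: between episodes it holds its last
# pose, and when an episode scripts a different position/heading the body
# glides there during (up to) the final 0.8 s of the preceding gap. This
# keeps frame-difference counts free of teleport artifacts at episode
# boundaries.

GLIDE_MAX_S <- 0.8

build_pose_timeline <- function(spec) {
  mid <- spec$arena_cm / 2
  cur <- list(x = mid, y = mid, th = 30)
  phases <- list()
  prev_end <- 0
  ep <- spec$episodes[spec$episodes$label %in% VIDEO_LABELS, , drop = FALSE]
  for (i in seq_len(nrow(ep))) {
    e <- ep[i, ]
    if (e$label == "locomotion") {
      x0 <- ifelse(is.na(e$x_cm), spec$arena_cm * 0.25, e$x_cm)
      y0 <- ifelse(is.na(e$y_cm), spec$arena_cm * 0.5, e$y_cm)
      x1 <- ifelse(is.na(e$x_end_cm), spec$arena_cm * 0.75, e$x_end_cm)
      y1 <- ifelse(is.na(e$y_end_cm), spec$arena_cm * 0.5, e$y_end_cm)
      th <- if (is.na(e$heading_deg)) atan2(y1 - y0, x1 - x0) * 180 / pi
        else e$heading_deg
      start <- list(x = x0, y = y0, th = th %% 180)
      final <- list(x = x1, y = y1, th = th %% 180)
    } else {
      start <- list(x = ifelse(is.na(e$x_cm), cur$x, e$x_cm),
                    y = ifelse(is.na(e$y_cm), cur$y, e$y_cm),
                    th = ifelse(is.na(e$heading_deg), cur$th,
                                e$heading_deg %% 180))
      final <- start
    }
    moved <- abs(start$x - cur$x) + abs(start$y - cur$y) > 1e-9 ||
      abs(start$th - cur$th) > 1e-9
    if (moved) {
      # the glide finishes (up to) 0.5 s before the episode so that glide
      # motion never fuses with the episode's own signature
      gap <- e$t_start - prev_end
      glide <- min(GLIDE_MAX_S, gap)
      settle <- min(0.5, max(0, gap - glide))
      if (glide > 1e-9) {
        phases[[length(phases) + 1L]] <-
          list(t0 = e$t_start - settle - glide, t1 = e$t_start - settle,
               kind = "glide", from = cur, to = start, e = NULL,
               end_pose = start)
      }
    }
    phases[[length(phases) + 1L]] <-
      list(t0 = e$t_start, t1 = e$t_end, kind = e$label,
           from = start, to = final, e = e, end_pose = final)
    cur <- final
    prev_end <- e$t_end
  }
  list(phases = phases, init = list(x = mid, y = mid, th = 30))
}

# shortest-arc interpolation of an axial ([0, 180)) heading
lerp_heading <- function(a, b, frac) {
  d <- ((b - a + 90) %% 180) - 90
  (a + frac * d) %% 180
}

# triangle wave starting at 0 and rising, period 1, range [-1, 1]
tri01 <- function(p) {
  p <- p %% 1
  ifelse(p < 0.25, 4 * p, ifelse(p < 0.75, 2 - 4 * p, 4 * p - 4))
}

pose_at <- function(tl, t) {
  inside <- NULL
  last_pose <- tl$init
  for (ph in tl$phases) {
    if (t >= ph$t0 && t < ph$t1) { inside <- ph; break }
    if (ph$t1 <= t) last_pose <- ph$end_pose
  }
  if (is.null(inside))
    return(list(x = last_pose$x, y = last_pose$y, th = last_pose$th,
                episode = NULL))
  ph <- inside
  frac <- (t - ph$t0) / (ph$t1 - ph$t0)
  if (ph$kind == "glide") {
    list(x = ph$from$x + frac * (ph$to$x - ph$from$x),
         y = ph$from$y + frac * (ph$to$y - ph$from$y),
         th = lerp_heading(ph$from$th, ph$to$th, frac), episode = NULL)
  } else if (ph$kind == "locomotion") {
    list(x = ph$from$x + frac * (ph$to$x - ph$from$x),
         y = ph$from$y + frac * (ph$to$y - ph$from$y),
         th = ph$from$th, episode = ph$e)
  } else if (ph$kind %in% POSTURAL_LABELS) {
    f <- ifelse(is.na(ph$e$freq_hz) || ph$e$freq_hz <= 0, 1, ph$e$freq_hz)
    dur <- ph$t1 - ph$t0
    amp <- 10 * min(1, (t - ph$t0) / 0.3, (ph$t1 - t) / 0.3)
    list(x = ph$from$x, y = ph$from$y,
         th = (ph$from$th + amp * tri01((t - ph$t0) * f)) %% 180,
         episode = ph$e)
  } else {
    list(x = ph$from$x, y = ph$from$y, th = ph$from$th, episode = ph$e)
  }
}

# ---- side-view rendering ---------------------------------------------------

# Behavior-specific silhouette glyphs used as the side-camera substrate and as
# the clip-classification image classes.
render_side_glyph <- function(label, H = 64, W = 64, dx = 0, dy = 0, scale = 1) {
  img <- matrix(BG_LEVEL, H, W)
  put_ellipse <- function(img, cx, cy, a, b) {
    xg <- matrix(rep(seq_len(W), each = H), H, W) - (cx + dx)
    yg <- matrix(rep(seq_len(H), W), H, W) - (cy + dy)
    img[(xg / (a * scale))^2 + (yg / (b * scale))^2 <= 1] <- BODY_LEVEL
    img
  }
  put_ring <- function(img, cx, cy, r_out, r_in) {
    xg <- matrix(rep(seq_len(W), each = H), H, W) - (cx + dx)
    yg <- matrix(rep(seq_len(H), W), H, W) - (cy + dy)
    d2 <- (xg / scale)^2 + (yg / scale)^2
    img[d2 <= r_out^2 & d2 >= r_in^2] <- BODY_LEVEL
    img
  }
  base <- switch(label,
    rearing = put_ellipse(img, W / 2, H * 0.45, 8, 20),
    wall_supported_rearing = {
      img2 <- put_ellipse(img, W * 0.2, H * 0.45, 8, 20)
      img2[, seq_len(3)] <- 120
      img2
    },
    grooming = put_ellipse(img, W / 2, H * 0.7, 12, 12),
    head_raising = {
      img2 <- put_ellipse(img, W / 2, H * 0.72, 16, 8)
      put_ellipse(img2, W * 0.72, H * 0.38, 5, 5)
    },
    genital_licking = put_ring(img, W / 2, H * 0.7, 12, 6),
    face_washing = {
      img2 <- put_ellipse(img, W / 2, H * 0.7, 12, 12)
      img2 <- put_ellipse(img2, W * 0.4, H * 0.45, 2.5, 2.5)
      put_ellipse(img2, W * 0.6, H * 0.45, 2.5, 2.5)
    },
    # everything else reads as a normal horizontal posture
    put_ellipse(img, W / 2, H * 0.7, 16, 8)
  )
  base
}

# Map an arbitrary episode label to the side-view glyph class
side_glyph_label <- function(label) {
  if (label %in% c("rearing", "wall_supported_rearing", "grooming",
                   "head_raising", "genital_licking", "face_washing")) label
  else "normal"
}

# ---- session synthesis -----------------------------------------------------

#' Synthesize a multi-view video session with ground truth
#'
#' Renders the scripted session of a [session_spec()] into per-camera
#' [frame_stack()]s (one top view and four side views) together with an exact
#' ground-truth event log. Wet-dog-shake and scratching episodes modulate the
#' body texture so that the frame-difference count train pulses at the scripted
#' rate; locomotion translates the body at constant velocity; postural
#' behaviors rock the body slowly; stationary epochs contain only sensor noise.
#'
#' @param spec A [session_spec()].
#' @param views Character vector of views to render (subset of
#'   `c("top", "side0".."side3")`); rendering only the top view makes large
#'   motion-filter benchmarks cheap.
#' @return A list with elements `streams` (named list of [frame_stack()]),
#'   `events` (ground-truth tibble: `label`, `t_start`, `t_end`, `first_frame`,
#'   `last_frame`, `view`) and `spec`.
#' @export
synth_video_session <- function(spec,
                                views = c("top", paste0("side", 0:3))) {
  stopifnot(inherits(spec, "session_spec"))
  views <- match.arg(views, c("top", paste0("side", 0:3)), several.ok = TRUE)
  H <- spec$frame_size[1]; W <- spec$frame_size[2]
  n <- round(spec$duration_s * spec$fps)
  scale <- W / spec$arena_cm
  a_px <- BODY_SEMI_MAJOR_CM * scale
  b_px <- a_px / BODY_AXIS_RATIO
  tail_px <- TAIL_LENGTH_CM * scale

  timeline <- build_pose_timeline(spec)
  streams <- with_seed(spec$seed, {
    out <- list()
    for (v in views) {
      arr <- array(0L, dim = c(H, W, n))
      last_key <- NULL; last_base <- NULL
      tex <- NULL # per-episode texture cache for shake/scratch
      for (i in seq_len(n)) {
        t <- (i - 1L) / spec$fps
        p <- pose_at(timeline, t)
        st <- list(cx = p$x * scale, cy = p$y * scale, theta = p$th,
                   episode = p$episode)
        e <- st$episode
        if (v == "top") {
          key <- list(round(st$cx, 4), round(st$cy, 4), round(st$theta, 4))
          if (is.null(last_key) || !identical(key, last_key)) {
            last_base <- render_body(H, W, st$cx, st$cy, st$theta,
                                     a_px, b_px, tail_px)
            last_key <- key
          }
          base <- last_base
          if (!is.null(e) && e$label %in% c("wet_dog_shake", "scratching")) {
            if (is.null(tex) || !identical(tex$id, e$t_start)) {
              tex <- make_texture(base, e, st, a_px, b_px)
            }
            state <- 1 - 2 * (floor((t - e$t_start) * e$freq_hz + tex$u) %% 2)
            base[tex$idx] <- base[tex$idx] + tex$amp * state * 0.5
          } else tex <- NULL
        } else {
          lbl <- if (is.null(e)) "normal" else side_glyph_label(e$label)
          key <- lbl
          if (is.null(last_key) || !identical(key, last_key)) {
            last_base <- render_side_glyph(lbl, H, W)
            last_key <- key
          }
          base <- last_base
        }
        if (!is.null(spec$sync)) {
          off <- spec$sync$offsets[[v]] %||% 0L
          if ((i - 1L) >= spec$sync$frame + off) base <- base + 60
        }
        frame <- base + rnorm(H * W, 0, spec$noise_sd)
        arr[, , i] <- as.integer(round(clamp(frame, 0, 255)))
      }
      out[[v]] <- frame_stack(arr, fps = spec$fps, view_id = v)
    }
    out
  })

  ev <- spec$episodes
  ev <- ev[!(ev$label %in% c("stationary")), , drop = FALSE]
  events <- tibble::tibble(
    label = ev$label, t_start = ev$t_start, t_end = ev$t_end,
    first_frame = round(ev$t_start * spec$fps),
    last_frame = round(ev$t_end * spec$fps),
    view = ifelse(ev$label %in% AUDIO_LABELS, "audio", "top"))
  list(streams = streams, events = dplyr::arrange(events, .data$t_start),
       spec = spec)
}

# Texture pattern for rhythmic episodes: a random subset of body pixels
# carries a square-wave intensity toggle at the scripted rate. Each pixel's
# toggle instant falls between two frame samples, so every toggle produces
# exactly one frame-difference pulse no matter how the episode aligns with
# the frame clock; small per-pixel phase jitter widens the pulses slightly,
# attenuating comb harmonics so the spectrum of a scratch train is dominated
# by its fundamental.
make_texture <- function(base, e, st, a_px, b_px) {
  body_idx <- which(base >= BODY_LEVEL)
  if (e$label == "scratching") {
    # restrict to a flank patch: pixels on one side of the minor axis
    H <- nrow(base)
    rows <- ((body_idx - 1L) %% H) + 1L
    cols <- ((body_idx - 1L) %/% H) + 1L
    th <- st$theta * pi / 180
    v <- -(cols - st$cx) * sin(th) + (rows - st$cy) * cos(th)
    body_idx <- body_idx[v > 0.15 * b_px]
  }
  n_pat <- max(8L, round(length(body_idx) * 0.5))
  idx <- sample(body_idx, min(n_pat, length(body_idx)))
  amp <- e$amplitude * runif(length(idx), 0.6, 1.4)
  sigma_ph <- if (e$label == "scratching") 0.16 else 0.10
  u <- (0.5 + rnorm(length(idx), 0, sigma_ph)) %% 1
  list(id = e$t_start, idx = idx, amp = amp, u = u)
}

# ---- scripted benchmark sessions -------------------------------------------

#' Benchmark session script with a fixed motion budget
#'
#' Builds a [session_spec()] whose scripted motion episodes occupy exactly
#' `motion_frac` of the timeline (locomotion bouts, scratch trains, postural
#' behaviors and wet-dog shakes in fixed proportion, scaled to the budget),
#' placed at seeded random non-overlapping times with at least 2.5 s between
#' episodes. Used to benchmark the motion filter's redundancy ratio.
#'
#' @param duration_s Session length (default 300 s).
#' @param motion_frac Fraction of the timeline occupied by scripted motion
#'   (default 0.15).
#' @param fps,frame_size,seed Passed to [session_spec()].
#' @return A [session_spec()].
#' @export
benchmark_session_spec <- function(duration_s = 300, motion_frac = 0.15,
                                   fps = 30, frame_size = c(64, 64),
                                   seed = 0) {
  # the motion budget covers the scripted episodes plus the 0.8 s
  # repositioning glide that precedes each one (every episode scripts a new
  # position, so every episode is preceded by a glide)
  base <- c(loco1 = 8, loco2 = 8, loco3 = 7,
            scr1 = 2.5, scr2 = 2.7, post1 = 3,
            shk = 0.8, shk = 0.8, shk = 0.8)
  labels <- c(rep("locomotion", 3L), rep("scratching", 2L),
              "grooming", rep("wet_dog_shake", 3L))
  budget <- duration_s * motion_frac - GLIDE_MAX_S * length(base)
  if (budget <= 0) rlang::abort("motion budget too small for the composition")
  durs <- base * budget / sum(base)
  eps <- with_seed(seed + 77L, place_episodes(labels, durs, duration_s))
  session_spec(duration_s, eps, fps = fps, frame_size = frame_size,
               seed = seed)
}

#' Benchmark session script for the rhythmic detectors
#'
#' Short sessions containing a seeded number of wet-dog shakes and scratch
#' trains plus locomotion and postural distractors, for measuring detector
#' precision and recall against ground truth.
#'
#' @param duration_s Session length (default 60 s).
#' @param n_shake,n_scratch Rhythmic episode counts (defaults 3 and 2).
#' @param seed RNG seed.
#' @param fps,frame_size Passed to [session_spec()].
#' @return A [session_spec()].
#' @export
rhythm_session_spec <- function(duration_s = 60, n_shake = 3, n_scratch = 2,
                                seed = 0, fps = 30, frame_size = c(64, 64)) {
  labels <- c(rep("wet_dog_shake", n_shake), rep("scratching", n_scratch),
              "locomotion", "grooming")
  durs <- with_seed(seed + 131L, c(runif(n_shake, 0.7, 1.0),
                                   runif(n_scratch, 1.6, 2.6), 5, 3))
  eps <- with_seed(seed + 132L, place_episodes(labels, durs, duration_s))
  session_spec(duration_s, eps, fps = fps, frame_size = frame_size,
               seed = seed)
}

# Place episodes of given durations at random non-overlapping times with a
# minimum inter-episode gap; draws positions/headings for variety.
place_episodes <- function(labels, durs, duration_s, min_gap = 2.5) {
  n <- length(durs)
  ord <- sample(n)
  labels <- labels[ord]; durs <- durs[ord]
  free <- duration_s - sum(durs) - min_gap * (n + 1L)
  if (free < 0) rlang::abort("episodes do not fit in the session")
  shares <- runif(n + 1L)
  gaps <- min_gap + shares / sum(shares) * free
  t0 <- cumsum(gaps)[seq_len(n)] + c(0, cumsum(durs))[seq_len(n)]
  rows <- lapply(seq_len(n), function(i) {
    lab <- labels[i]
    if (lab == "locomotion") {
      ang <- runif(1, 0, 2 * pi)
      len <- runif(1, 15, 25)
      x0 <- runif(1, 10, 35); y0 <- runif(1, 10, 35)
      x1 <- clamp(x0 + len * cos(ang), 8, 37)
      y1 <- clamp(y0 + len * sin(ang), 8, 37)
      episode(lab, t0[i], t0[i] + durs[i], x_cm = x0, y_cm = y0,
              x_end_cm = x1, y_end_cm = y1)
    } else {
      episode(lab, t0[i], t0[i] + durs[i],
              heading_deg = runif(1, 0, 180),
              x_cm = runif(1, 12, 33), y_cm = runif(1, 12, 33))
    }
  })
  dplyr::bind_rows(rows)
}
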