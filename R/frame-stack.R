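#' Frame stack: one camera's grayscale video
#'
#' Lightweight container for an ordered stack of 8-bit grayscale frames from a
#' single camera, with per-frame timestamps. Frames are stored as an integer
#' array of dimension `height x width x n_frames`; frame indices are 0-based in
#' all user-facing coordinates (segment bounds, sync offsets).
#'
#' @param frames Integer or numeric array `H x W x N` with values in 0..255.
#' @param fps Frames per second.
#' @param view_id One of `"top"`, `"side0"`..`"side3"` (free-form allowed).
#' @param t0 Timestamp of frame 0 in seconds.
#' @param timestamps Optional explicit per-frame timestamps (seconds,
#'   strictly increasing); overrides `t0`/`fps` spacing.
#'
#' @return An object of class `frame_stack` with fields `frames`,
#'   `timestamps`, `view_id`, `fps`.
#' @export
frame_stack <- function(frames, fps, view_id = "top", t0 = 0, timestamps = NULL) {
  if (length(dim(frames)) == 2L) dim(frames) <- c(dim(frames), 1L)
  stopifnot(length(dim(frames)) == 3L, fps > 0)
  n <- dim(frames)[3L]
  if (is.null(timestamps)) timestamps <- t0 + (seq_len(n) - 1L) / fps
  if (length(timestamps) != n || any(diff(timestamps) <= 0))
    rlang::abort("timestamps must be strictly increasing, one per frame")
  structure(list(frames = frames, timestamps = timestamps,
                 view_id = view_id, fps = fps),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack '%s': %d frames %dx%d @ %.6g fps, t0 = %.3f s>\n",
              x$view_id, d[3L], d[1L], d[2L], x$fps, x$timestamps[1L]))
  invisible(x)
}

#' @export
length.frame_stack <- function(x) dim(x$frames)[3L]

# i is 0-based; returns an H x W numeric matrix
get_frame <- function(stack, i) {
  stack$frames[, , i + 1L]
}

#' Write / read a frame stack as a PNG image-sequence directory
#'
#' Frames are written as `frame_000000.png` ... plus a `manifest.yaml` holding
#' `fps`, `view_id` and the first timestamp, so a round trip reproduces the
#' stack exactly.
#'
#' @param stack A [frame_stack()].
#' @param dir Directory to create/read.
#' @return `write_frame_stack()` returns `dir` invisibly; `read_frame_stack()`
#'   returns a [frame_stack()].
#' @export
write_frame_stack <- function(stack, dir) {
  if (!requireNamespace("png", quietly = TRUE))
    rlang::abort("package 'png' is required to write PNG sequences")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(stack)
  for (i in seq_len(n)) {
    png::writePNG(stack$frames[, , i] / 255,
                  file.path(dir, sprintf("frame_%06d.png", i - 1L)))
  }
  yaml::write_yaml(list(fps = stack$fps, view_id = stack$view_id,
                        t0 = stack$timestamps[1L], n_frames = n),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(dir) {
  if (!requireNamespace("png", quietly = TRUE))
    rlang::abort("package 'png' is required to read PNG sequences")
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$", full.names = TRUE))
  if (length(files) == 0L) rlang::abort(sprintf("no PNG frames found in %s", dir))
  img1 <- png::readPNG(files[[1L]])
  if (length(dim(img1)) == 3L) img1 <- img1[, , 1L]
  arr <- array(0L, dim = c(nrow(img1), ncol(img1), length(files)))
  for (i in seq_along(files)) {
    img <- png::readPNG(files[[i]])
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    arr[, , i] <- as.integer(round(img * 255))
  }
  frame_stack(arr, fps = man$fps, view_id = man$view_id, t0 = man$t0)
}
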