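# Session artifact I/O: event logs (JSON Lines / CSV) and multi-stream
# synchronization via the brightness-trigger flash.

#' Detect the synchronization flash in multi-camera streams
#'
#' Recording sessions are started by a rapid global brightness change visible
#' in every camera. Each stream's flash frame is the first frame whose mean
#' intensity jumps by more than `flash_min_step` relative to the previous
#' frame; offsets are reported relative to the earliest flash across streams.
#' Synchronization is frame-exact (no sub-frame interpolation).
#'
#' @param streams List of [frame_stack()]s (at least two).
#' @param flash_min_step Minimum mean-intensity jump, 8-bit units (default 40).
#' @return Tibble with one row per stream: `view_id`, `flash_frame` (0-based),
#'   `offset_frames`, `offset_s`.
#' @export
detect_sync_flash <- function(streams, flash_min_step = 40) {
  if (length(streams) < 2L) rlang::abort("need at least two streams to synchronize")
  flash <- vapply(streams, function(s) {
    means <- apply(s$frames, 3L, mean)
    jumps <- diff(means)
    hit <- which(jumps > flash_min_step)
    if (length(hit) == 0L)
      rlang::abort(sprintf("no sync flash in stream '%s'", s$view_id))
    if (length(hit) > 1L)
      rlang::abort(sprintf("ambiguous flash in stream '%s' (%d qualifying jumps)",
                           s$view_id, length(hit)))
    hit # 0-based index of the first frame after the jump
  }, numeric(1))
  tibble::tibble(
    view_id = vapply(streams, function(s) s$view_id, character(1)),
    flash_frame = as.integer(flash),
    offset_frames = as.integer(flash - min(flash)),
    offset_s = (flash - min(flash)) /
      vapply(streams, function(s) s$fps, numeric(1)))
}

#' Align streams by dropping pre-flash leading frames
#'
#' Applies the per-stream offsets from [detect_sync_flash()] so that the flash
#' lands on the same frame index everywhere; after correction the aligned
#' timestamps of corresponding frames differ by less than one frame period.
#'
#' @param streams List of [frame_stack()]s.
#' @param offsets Result of [detect_sync_flash()] (matched by `view_id`).
#' @return List of aligned [frame_stack()]s.
#' @export
align_streams <- function(streams, offsets) {
  lapply(streams, function(s) {
    k <- offsets$offset_frames[match(s$view_id, offsets$view_id)]
    if (is.na(k)) rlang::abort(sprintf("no offset for view '%s'", s$view_id))
    if (k == 0L) return(s)
    n <- length(s)
    frame_stack(s$frames[, , (k + 1L):n, drop = FALSE], fps = s$fps,
                view_id = s$view_id, t0 = 0)
  })
}

# ---- event logs ------------------------------------------------------------

validate_events <- function(events) {
  req <- c("label", "t_start", "t_end")
  missing <- setdiff(req, names(events))
  if (length(missing))
    rlang::abort(paste("event log lacks columns:", paste(missing, collapse = ", ")))
  if (any(events$t_end < events$t_start))
    rlang::abort("event with t_end < t_start rejected")
  invisible(events)
}

#' Write / read behavior event logs
#'
#' Event logs are tibbles with at least `label`, `t_start`, `t_end` (seconds);
#' any further columns (`view`, `animal_id`, `source`, ...) survive the round
#' trip. JSON Lines holds one event object per line; CSV is a plain table.
#' Events are sorted by `t_start` on write, and events with
#' `t_end < t_start` are rejected.
#'
#' @param events Event tibble.
#' @param path File path; format chosen by extension (`.jsonl`/`.json` vs
#'   `.csv`) unless `format` is given.
#' @param format `"jsonl"` or `"csv"`.
#' @return `write_events()` returns `path` invisibly; `read_events()` returns
#'   a tibble sorted by `t_start`.
#' @export
write_events <- function(events, path, format = c("auto", "jsonl", "csv")) {
  format <- resolve_format(match.arg(format), path)
  events <- validate_events(tibble::as_tibble(events))
  events <- dplyr::arrange(events, .data$t_start)
  if (format == "csv") {
    write.csv(events, path, row.names = FALSE)
  } else {
    lines <- vapply(seq_len(nrow(events)), function(i) {
      jsonlite::toJSON(as.list(events[i, ]), auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- resolve_format(match.arg(format), path)
  if (format == "csv") {
    out <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    rows <- lapply(seq_along(lines), function(i) {
      parsed <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                         error = function(e) NULL)
      if (is.null(parsed))
        rlang::abort(sprintf("malformed JSON at line %d of %s", i, path))
      tibble::as_tibble(parsed)
    })
    out <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(label = character(), t_start = numeric(), t_end = numeric())
  }
  validate_events(out)
  dplyr::arrange(out, .data$t_start)
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
}
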