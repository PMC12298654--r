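# Top-view geometry: silhouette cleaning, ellipse pose fit, and selection of
# the side camera with the best lateral profile of the animal.

#' Cage geometry for camera selection
#'
#' The arena is square with four side cameras at the wall midpoints, viewing
#' inward: camera 0 on the wall `x = 0` (viewing along +x), camera 1 on
#' `y = 0` (+y), camera 2 on `x = side` (-x), camera 3 on `y = side` (-y).
#' Image coordinates: origin top-left of the top view, x rightward (columns),
#' y downward (rows).
#'
#' @param side_cm Arena side length, cm (default 45).
#' @param px_per_cm Top-view scale, pixels per cm.
#' @return An object of class `cage_geometry`.
#' @export
cage_geometry <- function(side_cm = 45, px_per_cm = 64 / 45) {
  stopifnot(side_cm > 0, px_per_cm > 0)
  structure(list(side_cm = side_cm, px_per_cm = px_per_cm,
                 # viewing axis (unit vector) per camera id 0..3
                 axes = rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))),
            class = "cage_geometry")
}

#' Binarize a top-view frame and clean the silhouette
#'
#' Thresholds the frame, then applies erosion followed by dilation (an
#' opening) with square structuring elements, removing thin appendages such
#' as the tail, and keeps the largest connected component.
#'
#' @param frame Grayscale matrix (8-bit scale).
#' @param bin_threshold Foreground threshold (default 110, between the dark
#'   arena floor and the bright animal).
#' @param erode_px,dilate_px Structuring-element radius in pixels (default 2).
#' @return Logical mask matrix of the cleaned silhouette.
#' @export
binarize_and_clean <- function(frame, bin_threshold = 110, erode_px = 2,
                               dilate_px = 2) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    rlang::abort("package 'EBImage' is required for morphological cleaning")
  mask <- frame > bin_threshold
  storage.mode(mask) <- "double"
  if (erode_px > 0)
    mask <- EBImage::erode(mask, EBImage::makeBrush(2L * erode_px + 1L, "box"))
  if (dilate_px > 0)
    mask <- EBImage::dilate(mask, EBImage::makeBrush(2L * dilate_px + 1L, "box"))
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  if (max(lab) == 0) rlang::abort("no animal: empty foreground after cleaning")
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  matrix(lab == keep, nrow(lab), ncol(lab))
}

#' Fit an ellipse to a binary silhouette via image moments
#'
#' Center is the foreground centroid; orientation is the major-axis angle from
#' second-order central moments, normalized to \[0, 180) degrees measured from
#' the x-axis in image coordinates (y down). Axis lengths are the
#' moment-equivalent full axes. Near-circular silhouettes
#' (major/minor < 1.05) are flagged degenerate and reported at 0 degrees.
#'
#' @param mask Logical/0-1 matrix with at least 5 foreground pixels.
#' @param geom Optional [cage_geometry()] to also report the center in cm.
#' @param frame_index Frame index bookkeeping (0-based), stored in the result.
#' @return One-row tibble: `cx_px`, `cy_px`, `cx_cm`, `cy_cm`,
#'   `orientation_deg`, `major_px`, `minor_px`, `degenerate`, `frame_index`.
#' @export
fit_ellipse <- function(mask, geom = NULL, frame_index = NA_integer_) {
  idx <- which(mask != 0)
  if (length(idx) < 5L) rlang::abort("mask must have at least 5 foreground pixels")
  H <- nrow(mask)
  y <- ((idx - 1L) %% H) + 1L
  x <- ((idx - 1L) %/% H) + 1L
  cx <- mean(x); cy <- mean(y)
  mu20 <- mean((x - cx)^2); mu02 <- mean((y - cy)^2)
  mu11 <- mean((x - cx) * (y - cy))
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  theta <- theta %% 180
  common <- sqrt(pmax(0, (mu20 - mu02)^2 + 4 * mu11^2))
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  major <- 4 * sqrt(pmax(l1, 0)); minor <- 4 * sqrt(pmax(l2, 0))
  degenerate <- minor <= 0 || (major / minor) < 1.05
  if (degenerate) theta <- 0
  scale <- if (is.null(geom)) NA_real_ else geom$px_per_cm
  tibble::tibble(cx_px = cx, cy_px = cy,
                 cx_cm = cx / scale, cy_cm = cy / scale,
                 orientation_deg = theta, major_px = major, minor_px = minor,
                 degenerate = degenerate, frame_index = frame_index)
}

#' Select the side camera with the best lateral profile
#'
#' Among the two camera axes, the pair most perpendicular to the body's major
#' axis (maximizing `|sin(angle between body axis and viewing axis)|`, i.e.
#' flank visibility) is preferred; within it the camera whose wall is nearest
#' the animal wins; remaining exact ties go to the lowest camera id.
#'
#' @param pose One-row pose tibble from [fit_ellipse()] (needs `cx_cm`,
#'   `cy_cm`, `orientation_deg`).
#' @param geom A [cage_geometry()].
#' @return Camera id in `0:3`.
#' @export
select_camera <- function(pose, geom) {
  stopifnot(inherits(geom, "cage_geometry"))
  th <- pose$orientation_deg[1L] * pi / 180
  u <- c(cos(th), sin(th))
  perp <- abs(geom$axes[, 1L] * u[2L] - geom$axes[, 2L] * u[1L]) # |sin(angle)|
  x <- pose$cx_cm[1L]; y <- pose$cy_cm[1L]
  dist <- c(x, y, geom$side_cm - x, geom$side_cm - y)
  ord <- order(-round(perp, 12), round(dist, 9), 0:3)
  as.integer(ord[1L] - 1L)
}

#' Annotate motion segments with the optimal side camera
#'
#' For each segment, the first frame of the top view is cleaned, an ellipse is
#' fitted, and the optimal side camera selected. Segments whose first frame
#' fails silhouette extraction are dropped with a warning. One camera out of
#' four is selected per segment, so downstream side processing touches 25% of
#' the side-stream data.
#'
#' @param segments Segment tibble from [extract_motion_segments()].
#' @param top_stack The top-view [frame_stack()].
#' @param geom A [cage_geometry()]; defaults to the stack's width over 45 cm.
#' @param ... Passed to [binarize_and_clean()].
#' @return `segments` with `camera_id` filled and pose columns appended.
#' @export
dispatch_segments <- function(segments, top_stack, geom = NULL, ...) {
  if (is.null(geom))
    geom <- cage_geometry(px_per_cm = dim(top_stack$frames)[2L] / 45)
  if (nrow(segments) == 0L) return(segments)
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    f <- get_frame(top_stack, segments$first_frame[i])
    pose <- tryCatch({
      mask <- binarize_and_clean(f, ...)
      fit_ellipse(mask, geom = geom, frame_index = segments$first_frame[i])
    }, error = function(e) {
      rlang::warn(sprintf(
        "segment %d (frame %d) dropped: %s", i, segments$first_frame[i],
        conditionMessage(e)))
      NULL
    })
    if (is.null(pose)) return(NULL)
    out <- segments[i, ]
    out$camera_id <- select_camera(pose, geom)
    dplyr::bind_cols(out, pose[, c("cx_cm", "cy_cm", "orientation_deg",
                                   "degenerate")])
  })
  dplyr::bind_rows(rows)
}
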