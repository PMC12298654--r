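# Silhouette cleaning, moments-based ellipse fit, and camera selection.

render_pose <- function(cx, cy, theta, size = 96, tail = TRUE, noise = 0) {
  img <- withdrawr:::render_body(size, size, cx, cy, theta,
                                 a_px = 19.2, b_px = 7.7,
                                 tail_px = if (tail) 15 else 0)
  if (noise > 0) img <- img + rnorm(size * size, 0, noise)
  img
}

test_that("opening removes the tail and keeps the body", {
  with_tail <- render_pose(48, 48, 30)
  no_tail <- render_pose(48, 48, 30, tail = FALSE)
  tail_px <- which(with_tail > 110 & !(no_tail > 110))
  expect_gt(length(tail_px), 5)
  mask <- binarize_and_clean(with_tail, erode_px = 2, dilate_px = 2)
  expect_equal(sum(mask[tail_px]), 0)
  expect_gt(sum(mask), 0.8 * sum(no_tail > 110))
})

test_that("cleaning is idempotent and rejects empty frames", {
  mask <- binarize_and_clean(render_pose(48, 48, 120))
  again <- binarize_and_clean(mask * 255)
  expect_identical(mask, again)
  expect_error(binarize_and_clean(matrix(10, 64, 64)), "no animal")
})

test_that("ellipse orientation is recovered within 2 degrees", {
  mask <- binarize_and_clean(render_pose(48, 48, 30))
  p <- fit_ellipse(mask)
  expect_lt(abs(p$orientation_deg - 30), 2)
  expect_false(p$degenerate)
  expect_gt(p$major_px / p$minor_px, 2)
})

test_that("orientation is axial: 170 and -10 degree renders agree", {
  p1 <- fit_ellipse(binarize_and_clean(render_pose(48, 48, 170)))
  p2 <- fit_ellipse(binarize_and_clean(render_pose(48, 48, -10)))
  expect_lt(abs(p1$orientation_deg - p2$orientation_deg), 0.5)
  expect_gte(p1$orientation_deg, 0)
  expect_lt(p1$orientation_deg, 180)
})

test_that("near-circular masks are flagged degenerate with 0-degree tie-break", {
  size <- 64
  xg <- matrix(rep(1:size, each = size), size, size) - 32
  yg <- matrix(rep(1:size, size), size, size) - 32
  circle <- xg^2 + yg^2 <= 15^2
  p <- fit_ellipse(circle)
  expect_true(p$degenerate)
  expect_equal(p$orientation_deg, 0)
  expect_error(fit_ellipse(matrix(c(rep(0, 62), 1, 1), 8, 8) > 0),
               "at least 5")
})

test_that("moments agree with the independent EBImage implementation", {
  skip_if_not_installed("EBImage")
  mask <- binarize_and_clean(render_pose(40, 55, 30))
  p <- fit_ellipse(mask)
  fm <- EBImage::computeFeatures.moment(ifelse(mask, 1, 0))
  # EBImage works on the transposed image: centers swap, angles complement
  expect_equal(p$cx_px, unname(fm[1, "m.cy"]), tolerance = 1e-6)
  expect_equal(p$cy_px, unname(fm[1, "m.cx"]), tolerance = 1e-6)
  expect_equal(p$major_px, unname(fm[1, "m.majoraxis"]), tolerance = 1e-6)
  theirs <- (90 - fm[1, "m.theta"] * 180 / pi) %% 180
  d <- abs(p$orientation_deg - theirs)
  expect_lt(min(d, 180 - d), 0.01)
})

test_that("pose recovery over 100 seeded random poses is accurate", {
  set.seed(1)
  errs <- numeric(100); cerrs <- numeric(100)
  for (i in 1:100) {
    th <- runif(1, 0, 180); cx <- runif(1, 30, 66); cy <- runif(1, 30, 66)
    img <- render_pose(cx, cy, th, noise = 2)
    p <- fit_ellipse(binarize_and_clean(img))
    d <- abs(p$orientation_deg - th)
    errs[i] <- min(d, 180 - d)
    cerrs[i] <- sqrt((p$cx_px - cx)^2 + (p$cy_px - cy)^2)
  }
  expect_lte(median(errs), 2)
  expect_lte(median(cerrs), 2)
})

test_that("camera selection follows perpendicularity then proximity then id", {
  g <- cage_geometry(side_cm = 45, px_per_cm = 96 / 45)
  pose <- function(th, x, y)
    tibble::tibble(orientation_deg = th, cx_cm = x, cy_cm = y)
  # body along x: side cameras 1/3 see the flank; rat nearer wall y = 0
  expect_equal(select_camera(pose(0, 22.5, 10), g), 1L)
  # body along y: cameras 0/2; rat nearer wall x = 45
  expect_equal(select_camera(pose(90, 40, 22.5), g), 2L)
  # 45 degrees at the center: full tie resolved to the lowest id
  expect_equal(select_camera(pose(45, 22.5, 22.5), g), 0L)
})

test_that("rotating the scene by 90 degrees rotates the selected camera", {
  g <- cage_geometry(side_cm = 45, px_per_cm = 96 / 45)
  rotate_pose <- function(th, x, y) list(th = (th + 90) %% 180,
                                         x = 45 - y, y = x)
  cam_map <- c(`0` = 1L, `1` = 2L, `2` = 3L, `3` = 0L)
  set.seed(4)
  for (i in 1:25) {
    th <- runif(1, 5, 85); x <- runif(1, 5, 20); y <- runif(1, 25, 40)
    p <- tibble::tibble(orientation_deg = th, cx_cm = x, cy_cm = y)
    r <- rotate_pose(th, x, y)
    pr <- tibble::tibble(orientation_deg = r$th, cx_cm = r$x, cy_cm = r$y)
    expect_equal(select_camera(pr, g),
                 unname(cam_map[as.character(select_camera(p, g))]))
  }
})

test_that("dispatch annotates each segment with exactly one camera", {
  fx <- fx_rhythm_fixture()
  seg <- extract_motion_segments(fx$sig)
  out <- dispatch_segments(seg, fx$session$streams$top)
  expect_equal(nrow(out), nrow(seg))
  expect_true(all(out$camera_id %in% 0:3))
  expect_true(all(!is.na(out$orientation_deg)))
  # one of four side streams selected per segment: a 25% side-data share
  expect_equal(length(unique(out$camera_id[1])), 1L)
})

test_that("segments whose first frame fails cleaning are dropped with warning", {
  dark <- frame_stack(array(10L, dim = c(32, 32, 20)), fps = 30)
  seg <- tibble::tibble(first_frame = 0L, last_frame = 5L, t_start = 0,
                        t_end = 5 / 30, view_id = "top",
                        camera_id = NA_integer_)
  expect_warning(out <- dispatch_segments(seg, dark), "dropped")
  expect_equal(nrow(out), 0L)
})
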