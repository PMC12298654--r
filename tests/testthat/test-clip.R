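# Key-frame selection, majority-vote clip classification, Grad-CAM, and the
# smoke-training surface.

test_that("key frames are the top-motion frames with earlier-frame ties", {
  counts <- c(1, 5, 3, 9, 2, 9, 4, 8, 1, 1)
  sig <- motion_signal_from_counts(counts, 30)
  seg <- tibble::tibble(first_frame = 1L, last_frame = 9L)
  # k larger than the segment: everything comes back
  expect_equal(select_key_frames(sig, tibble::tibble(first_frame = 3L,
                                                     last_frame = 5L), k = 5),
               3:5)
  # top-3: the two 9s (earlier first) and the 8
  expect_equal(select_key_frames(sig, seg, k = 3), c(4L, 6L, 8L))
  # monotone-increasing motion: the last k frames win
  sig2 <- motion_signal_from_counts(seq(1, 50), 30)
  expect_equal(select_key_frames(sig2, tibble::tibble(first_frame = 0L,
                                                      last_frame = 49L),
                                 k = 4), 46:49)
})

test_that("key frames of a shake segment fall inside the scripted episode", {
  fx <- fx_rhythm_fixture()
  seg <- extract_motion_segments(fx$sig)
  truth <- fx$session$events[1, ] # first shake
  i <- which.max(interval_iou(truth$t_start, truth$t_end,
                              seg$t_start, seg$t_end))
  kf <- select_key_frames(fx$sig, seg[i, ], k = 9)
  expect_true(all(kf >= truth$first_frame - 1 & kf <= truth$last_frame + 1))
})

test_that("clip labels follow the majority vote with stated tie-breaks", {
  model <- fx_shape_model()
  ds <- fx_shapes()
  pick <- function(cl, n) ds$images[which(ds$labels == cl)[seq_len(n)]]
  # [disc, disc, ring] -> disc
  res <- classify_clip(c(pick("disc", 2), pick("ring", 1)), model)
  expect_equal(res$label, "disc")
  expect_equal(res$vote_margin, 1 / 3)
  expect_equal(nrow(res$frame_results[[1]]), 3L)
  # 1-1 tie: the class with larger summed confidence wins
  frames <- c(pick("disc", 1), pick("ring", 1))
  res2 <- classify_clip(frames, model)
  probs <- withdrawr:::classify_images(model, frames)
  sums <- c(disc = probs[1, "disc"], ring = probs[2, "ring"])
  expect_equal(res2$label, names(which.max(sums)))
  expect_error(classify_clip(list(), model), "empty")
})

test_that("votes are permutation-invariant and robust to one flipped frame", {
  model <- fx_shape_model()
  ds <- fx_shapes()
  frames <- c(ds$images[which(ds$labels == "square")[1:8]],
              ds$images[which(ds$labels == "cross")[1]])
  base <- classify_clip(frames, model)
  expect_equal(base$label, "square")
  set.seed(8)
  for (i in 1:3) {
    perm <- sample(length(frames))
    expect_equal(classify_clip(frames[perm], model)$label, base$label)
  }
  # flipping one more frame cannot change a clip with margin > 2/9
  expect_gt(base$vote_margin, 2 / 9)
  frames2 <- frames
  frames2[[8]] <- ds$images[[which(ds$labels == "cross")[2]]]
  expect_equal(classify_clip(frames2, model)$label, "square")
})

test_that("the 6:2:2 split is stratified and exact up to rounding", {
  labels <- factor(rep(letters[1:5], each = 50))
  idx <- split_622(labels, seed = 1)
  expect_equal(length(idx$train), 150L)
  expect_equal(length(idx$val), 50L)
  expect_equal(length(idx$test), 50L)
  expect_equal(sort(c(idx$train, idx$val, idx$test)), seq_along(labels))
  for (cl in levels(labels)) {
    expect_equal(sum(labels[idx$train] == cl), 30L)
    expect_equal(sum(labels[idx$test] == cl), 10L)
  }
})

test_that("smoke training reports per-class metrics in tabular form", {
  model <- fx_shape_model()
  rep <- model$report
  expect_true(all(c("class", "precision", "recall", "f1") %in% names(rep)))
  expect_equal(sort(rep$class), sort(levels(fx_shapes()$labels)))
  expect_true(is.numeric(attr(rep, "top1")))
  expect_true(is.numeric(attr(rep, "val_top1")))
  expect_true(is.logical(attr(rep, "converged")))
  expect_gte(attr(rep, "top1"), 0.95)
})

test_that("grad_cam produces normalized maps of image shape", {
  model <- fx_shape_model()
  img <- fx_shapes()$images[[1]]
  cam <- grad_cam(model, img, "disc")
  expect_equal(dim(cam), dim(img))
  expect_gte(min(cam), 0)
  expect_lte(max(cam), 1)
  expect_error(grad_cam(model, img, 99), "out of range")
  expect_error(grad_cam(model, img, "no_such_class"), "out of range")
  # uniform-zero readout weights give an all-zero map
  zero_model <- model
  zero_model$head$wts[] <- 0
  expect_equal(max(grad_cam(zero_model, img, 1)), 0)
})

test_that("grad_cam localizes a one-bright-quadrant class after training", {
  set.seed(2)
  imgs <- list(); labs <- character()
  for (q in 1:4) {
    for (i in 1:30) {
      imgs[[length(imgs) + 1L]] <- quadrant_image(q)
      labs <- c(labs, paste0("q", q))
    }
  }
  model <- train_smoke(imgs, labs, variant = "cspm", seed = 1)
  expect_gte(attr(model$report, "top1"), 0.95)
  set.seed(3)
  for (q in 1:4) {
    img <- quadrant_image(q)
    cam <- grad_cam(model, img, paste0("q", q))
    rows <- if (q %in% c(1, 2)) 1:16 else 17:32
    cols <- if (q %in% c(1, 3)) 1:16 else 17:32
    expect_gte(sum(cam[rows, cols]) / max(sum(cam), 1e-12), 0.6)
  }
})
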