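# Side-view clip classification: key-frame selection, an attention-augmented
# convolutional feature extractor with a trained multinomial readout,
# majority voting across key frames, and Grad-CAM introspection.

CLIP_CLASSES <- c("grooming", "head_raising", "normal", "rearing",
                  "genital_licking", "wall_supported_rearing", "face_washing")

#' Select key frames of a motion segment
#'
#' Picks the `k` frames with the largest motion-signal values inside the
#' segment (ties go to the earlier frame); `k` is capped at the segment
#' length. The motion value of frame `f` is the moving-pixel count of the
#' transition entering it.
#'
#' @param sig The top-view [build_motion_signal()].
#' @param segment One-row segment tibble (`first_frame`, `last_frame`).
#' @param k Number of key frames (default 9).
#' @return Sorted 0-based frame indices.
#' @export
select_key_frames <- function(sig, segment, k = 9) {
  f0 <- segment$first_frame[1L]; f1 <- segment$last_frame[1L]
  stopifnot(f1 >= f0)
  frames <- f0:f1
  # transition entering frame f is counts[f] (1-based R index); frame 0 has
  # no entering transition and scores the leaving one
  score <- sig$counts[clamp(frames, 1L, length(sig$counts))]
  ord <- order(-score, frames)
  sort(frames[ord[seq_len(min(k, length(frames)))]])
}

# ---- feature extractor -----------------------------------------------------

# Fixed-seed convolutional trunk: Conv(1->c1, stride 2) -> ReLU ->
# Conv(c1->c2, stride 2) -> ReLU -> [attention] ; features are the
# concatenated global average and max pools of both stages.
make_trunk <- function(variant = c("baseline", "cbam", "cspm"),
                       spatial_kernel = 3, c1 = 12L, c2 = 24L,
                       reduction = 4L, seed = 0L) {
  variant <- match.arg(variant)
  with_seed(seed, {
    w <- list(variant = variant, c1 = c1, c2 = c2,
              conv1 = init_conv(c1, 1L, 3L), b1 = numeric(c1),
              conv2 = init_conv(c2, c1, 3L), b2 = numeric(c2),
              att = if (variant != "baseline")
                attention_weights(c2, reduction, spatial_kernel) else NULL)
    w
  })
}

# forward pass; returns list(features, last_map)
trunk_forward <- function(trunk, image) {
  x <- array(image / 255, c(1L, nrow(image), ncol(image)))
  h1 <- relu(conv2d(x, trunk$conv1, trunk$b1, stride = 2L, pad = "same"))
  h2 <- relu(conv2d(h1, trunk$conv2, trunk$b2, stride = 2L, pad = "same"))
  h2 <- switch(trunk$variant,
               baseline = h2,
               cbam = cbam_block(h2, trunk$att),
               cspm = cspm_block(h2, trunk$att))
  list(features = c(gap_pool(h1), gmp_pool(h1), gap_pool(h2), gmp_pool(h2),
                    region_pool(h2)),
       last_map = h2)
}

# 2x2 region-averaged pooling of a (C, h, w) map: preserves coarse location
# (needed so the readout can separate classes that differ only in position,
# and so Grad-CAM has position-sensitive gradients). Order: per quadrant
# (top-left, top-right, bottom-left, bottom-right), channels within.
region_pool <- function(x) {
  d <- dim(x)
  h2 <- max(1L, d[2L] %/% 2L); w2 <- max(1L, d[3L] %/% 2L)
  rows <- list(1:h2, (h2 + 1L):d[2L])
  cols <- list(1:w2, (w2 + 1L):d[3L])
  out <- numeric(0)
  for (ri in 1:2) for (ci in 1:2) {
    out <- c(out, apply(x[, rows[[ri]], cols[[ci]], drop = FALSE], 1L, mean))
  }
  out
}

trunk_feature_names <- function(trunk) {
  c(sprintf("gap1_%02d", seq_len(trunk$c1)),
    sprintf("gmp1_%02d", seq_len(trunk$c1)),
    sprintf("gap2_%02d", seq_len(trunk$c2)),
    sprintf("gmp2_%02d", seq_len(trunk$c2)),
    sprintf("rp%d_%02d", rep(1:4, each = trunk$c2), rep(seq_len(trunk$c2), 4)))
}

extract_features <- function(trunk, images) {
  feats <- t(vapply(images, function(im) trunk_forward(trunk, im)$features,
                    numeric(2L * trunk$c1 + 6L * trunk$c2)))
  colnames(feats) <- trunk_feature_names(trunk)
  feats
}

# ---- training --------------------------------------------------------------

#' Stratified train/validation/test split
#'
#' Splits indices per class in the given proportions (default 6:2:2), exact
#' up to rounding within each class.
#'
#' @param labels Factor or character vector.
#' @param prop Length-3 proportions summing to 1.
#' @param seed RNG seed for the shuffle.
#' @return List of integer index vectors `train`, `val`, `test`.
#' @export
split_622 <- function(labels, prop = c(0.6, 0.2, 0.2), seed = 0) {
  stopifnot(abs(sum(prop) - 1) < 1e-8)
  labels <- as.factor(labels)
  with_seed(seed, {
    out <- list(train = integer(), val = integer(), test = integer())
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      n <- length(idx)
      n_tr <- round(prop[1L] * n)
      n_va <- round(prop[2L] * n)
      out$train <- c(out$train, idx[seq_len(n_tr)])
      out$val <- c(out$val, idx[n_tr + seq_len(n_va)])
      out$test <- c(out$test, idx[setdiff(seq_len(n), seq_len(n_tr + n_va))])
    }
    lapply(out, sort)
  })
}

#' Train a behavior-clip image classifier (desk-scale smoke training)
#'
#' Fits the classifier on a labeled synthetic image set with a stratified
#' 6:2:2 train/validation/test split: a fixed-seed convolutional trunk (with
#' the requested attention variant) provides pooled features, and a
#' multinomial-logistic readout is trained on them. Reports per-class
#' precision, recall and F1 plus overall top-1 on the held-out test split.
#'
#' @param images List of grayscale matrices (8-bit scale), all the same size.
#' @param labels Class labels, one per image.
#' @param variant `"baseline"`, `"cbam"` or `"cspm"`.
#' @param spatial_kernel Spatial attention kernel, 3 or 7.
#' @param seed Seed for trunk weights and the split.
#' @param decay L2 penalty of the readout (default 1e-3).
#' @return Object of class `clip_model`: fields `trunk`, `head`, `classes`,
#'   `scaling`, `report` (metrics tibble with attributes `top1`, `val_top1`,
#'   `converged`), `seed`.
#' @export
train_smoke <- function(images, labels, variant = c("baseline", "cbam", "cspm"),
                        spatial_kernel = 3, seed = 0, decay = 1e-3) {
  variant <- match.arg(variant)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) rlang::abort("need at least 2 classes")
  trunk <- make_trunk(variant, spatial_kernel, seed = seed)
  feats <- extract_features(trunk, images)
  mu <- colMeans(feats)
  sdv <- pmax(apply(feats, 2L, sd), 1e-8)
  fs <- sweep(sweep(feats, 2L, mu), 2L, sdv, "/")
  idx <- split_622(labels, seed = seed)
  df <- data.frame(fs)
  df$.y <- labels
  fit <- with_seed(seed, nnet::multinom(
    .y ~ ., data = df[idx$train, ], trace = FALSE, maxit = 400,
    decay = decay, MaxNWts = 20000))
  converged <- isTRUE(fit$convergence == 0)
  if (!converged)
    rlang::warn("readout optimizer did not report convergence; metrics may suffer")
  pred <- function(i) {
    p <- predict(fit, newdata = df[i, , drop = FALSE], type = "class")
    factor(as.character(p), levels = levels(labels))
  }
  test_pred <- pred(idx$test)
  val_pred <- pred(idx$val)
  report <- per_class_metrics(labels[idx$test], test_pred)
  attr(report, "top1") <- mean(test_pred == labels[idx$test])
  attr(report, "val_top1") <- mean(val_pred == labels[idx$val])
  attr(report, "converged") <- converged
  structure(list(trunk = trunk, head = fit, classes = levels(labels),
                 scaling = list(mu = mu, sd = sdv), report = report,
                 variant = variant, spatial_kernel = spatial_kernel,
                 seed = seed, split = idx),
            class = "clip_model")
}

per_class_metrics <- function(truth, pred) {
  classes <- levels(truth)
  rows <- lapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else NA_real_
    tibble::tibble(class = cl, precision = precision, recall = recall, f1 = f1)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.clip_model <- function(x, ...) {
  cat(sprintf("<clip_model: %s (kernel %d), %d classes, test top-1 %.3f>\n",
              x$variant, x$spatial_kernel, length(x$classes),
              attr(x$report, "top1")))
  invisible(x)
}

# per-image class probabilities (matrix n x K)
classify_images <- function(model, images) {
  feats <- extract_features(model$trunk, images)
  fs <- sweep(sweep(feats, 2L, model$scaling$mu), 2L, model$scaling$sd, "/")
  p <- predict(model$head, newdata = data.frame(fs), type = "probs")
  if (is.null(dim(p))) {
    if (length(model$classes) == 2L) { # binomial shortcut of multinom
      p <- cbind(1 - p, p)
      colnames(p) <- model$classes
    } else p <- matrix(p, nrow = 1L, dimnames = list(NULL, names(p)))
  }
  p[, model$classes, drop = FALSE]
}

#' Classify a video clip by key-frame majority vote
#'
#' Each key frame is classified independently; the modal per-frame label wins.
#' Ties are broken by the larger summed confidence, then lexicographically.
#'
#' @param frames Non-empty list of grayscale key-frame matrices.
#' @param model A [train_smoke()] model.
#' @return One-row tibble: `label`, `vote_margin` (difference between the top
#'   two vote fractions), `n_frames`, and nested `frame_results`.
#' @export
classify_clip <- function(frames, model) {
  if (length(frames) == 0L) rlang::abort("empty frame list")
  probs <- classify_images(model, frames)
  frame_labels <- colnames(probs)[max.col(probs, ties.method = "first")]
  conf <- probs[cbind(seq_len(nrow(probs)), max.col(probs, ties.method = "first"))]
  votes <- table(factor(frame_labels, levels = model$classes))
  top <- max(votes)
  cands <- names(votes)[votes == top]
  if (length(cands) > 1L) {
    sums <- vapply(cands, function(cl)
      sum(probs[frame_labels == cl, cl]), numeric(1))
    cands <- cands[sums == max(sums)]
    label <- sort(cands)[1L]
  } else label <- cands
  second <- if (length(votes) > 1L) max(votes[names(votes) != label]) else 0L
  tibble::tibble(
    label = label,
    vote_margin = (top - second) / length(frames),
    n_frames = length(frames),
    frame_results = list(tibble::tibble(frame = seq_along(frames) - 1L,
                                        label = frame_labels,
                                        confidence = as.numeric(conf))))
}

#' Grad-CAM heatmap for one image and class
#'
#' Computes the gradient of the pre-softmax class score with respect to the
#' last convolutional feature map (after the attention block), averages it
#' per channel, forms the positive part of the gradient-weighted channel sum,
#' upsamples it bilinearly to the image size and normalizes to \[0, 1\].
#' Because the readout is linear in the pooled features, the gradients are
#' analytic.
#'
#' @param model A [train_smoke()] model.
#' @param image Grayscale matrix.
#' @param class_index Class index (1-based into `model$classes`) or label.
#' @return Heatmap matrix in \[0, 1\] with the image's dimensions.
#' @export
grad_cam <- function(model, image, class_index) {
  if (is.character(class_index)) class_index <- match(class_index, model$classes)
  if (is.na(class_index) || class_index < 1 || class_index > length(model$classes))
    rlang::abort("class_index out of range")
  fwd <- trunk_forward(model$trunk, image)
  F_map <- fwd$last_map
  d <- dim(F_map)
  # per-class linear readout weights on the standardized features; the first
  # class is the multinom reference with an all-zero row
  co <- coef(model$head)
  if (is.null(dim(co))) co <- matrix(co, nrow = 1L)
  W <- rbind(0, co[, -1L, drop = FALSE]) # drop intercept; ref class is row 1
  rownames(W) <- model$classes
  # gradient of the class log-probability: w_k - sum_j p_j w_j (well defined
  # for every class, including the multinom reference class)
  p_img <- as.numeric(classify_images(model, list(image)))
  W <- sweep(W, 2L, colSums(W * p_img))
  c1 <- model$trunk$c1; c2 <- model$trunk$c2
  gap2 <- 2L * c1 + seq_len(c2)
  gmp2 <- 2L * c1 + c2 + seq_len(c2)
  w_row <- W[class_index, ]
  sdv <- model$scaling$sd
  # exact per-position gradient of the class score through the GAP, GMP and
  # 2x2 region pools of the last map (for a pure-GAP head this reduces to the
  # classic channel-weight formulation)
  h <- d[2L]; w_ <- d[3L]
  h2 <- max(1L, h %/% 2L); w2 <- max(1L, w_ %/% 2L)
  row_q <- c(rep(0L, h2), rep(1L, h - h2))
  col_q <- c(rep(0L, w2), rep(1L, w_ - w2))
  qmap <- outer(row_q * 2L, col_q, `+`) + 1L # quadrant index per position
  qsize <- tabulate(qmap, 4L)
  cam <- matrix(0, h, w_)
  for (c in seq_len(c2)) {
    g <- matrix(w_row[gap2[c]] / sdv[gap2[c]] / (h * w_), h, w_)
    amax <- which.max(F_map[c, , ])
    g[amax] <- g[amax] + w_row[gmp2[c]] / sdv[gmp2[c]]
    for (q in 1:4) {
      rq <- 2L * c1 + (1L + q) * c2 + c
      g[qmap == q] <- g[qmap == q] + w_row[rq] / sdv[rq] / qsize[q]
    }
    cam <- cam + g * F_map[c, , ]
  }
  cam <- pmax(cam, 0)
  cam <- upsample_bilinear(cam, nrow(image), ncol(image))
  if (max(cam) > 0) cam <- cam / max(cam)
  cam
}

# ---- synthetic image classes ----------------------------------------------

#' Synthetic separable shape dataset
#'
#' Renders five clearly distinguishable bright shapes (disc, square,
#' triangle, cross, ring) on a dark noisy background with position and size
#' jitter — the desk-scale stand-in for behavior key frames.
#'
#' @param n_per_class Images per class.
#' @param classes Subset of the five shapes.
#' @param size Image side, px.
#' @param seed RNG seed.
#' @param noise_sd Pixel noise SD.
#' @return List with `images` (list of matrices) and `labels` (factor).
#' @export
synth_shape_dataset <- function(n_per_class = 60,
                                classes = c("disc", "square", "triangle",
                                            "cross", "ring"),
                                size = 32, seed = 0, noise_sd = 8) {
  with_seed(seed, {
    images <- list(); labels <- character()
    for (cl in classes) {
      for (i in seq_len(n_per_class)) {
        dx <- runif(1, -3, 3); dy <- runif(1, -3, 3)
        sc <- runif(1, 0.85, 1.15)
        img <- render_shape(cl, size, dx, dy, sc)
        img <- clamp(round(img + rnorm(size * size, 0, noise_sd)), 0, 255)
        images[[length(images) + 1L]] <- img
        labels <- c(labels, cl)
      }
    }
    list(images = images, labels = factor(labels, levels = classes))
  })
}

render_shape <- function(class, size, dx = 0, dy = 0, sc = 1) {
  cx <- size / 2 + dx; cy <- size / 2 + dy
  r <- size * 0.28 * sc
  xg <- matrix(rep(seq_len(size), each = size), size, size) - cx
  yg <- matrix(rep(seq_len(size), size), size, size) - cy
  img <- matrix(30, size, size)
  on <- switch(class,
    disc = xg^2 + yg^2 <= r^2,
    square = abs(xg) <= r * 0.9 & abs(yg) <= r * 0.9,
    triangle = yg >= -r & (abs(xg) <= (yg + r) * 0.5),
    cross = (abs(xg) <= r * 0.3 & abs(yg) <= r) |
      (abs(yg) <= r * 0.3 & abs(xg) <= r),
    ring = {
      d2 <- xg^2 + yg^2
      d2 <= r^2 & d2 >= (0.55 * r)^2
    },
    rlang::abort(sprintf("unknown shape class '%s'", class)))
  img[on] <- 220
  img
}

#' Synthetic behavior-glyph clip dataset
#'
#' Renders the side-view behavior silhouettes used by the session generator
#' (grooming, head-raising, normal, rearing, genital licking, wall-supported
#' rearing, face washing) with jitter and noise, for training the clip
#' classifier that the full pipeline applies to side-view key frames.
#'
#' @inheritParams synth_shape_dataset
#' @param classes Behavior classes to include (default all seven).
#' @param size Image side, px (default 64, matching the session generator).
#' @return List with `images` and `labels`.
#' @export
synth_clip_dataset <- function(n_per_class = 40, classes = CLIP_CLASSES,
                               size = 64, seed = 0, noise_sd = 4) {
  with_seed(seed, {
    images <- list(); labels <- character()
    for (cl in classes) {
      for (i in seq_len(n_per_class)) {
        dx <- runif(1, -3, 3); dy <- runif(1, -3, 3)
        sc <- runif(1, 0.9, 1.1)
        img <- render_side_glyph(cl, size, size, dx, dy, sc)
        img <- clamp(round(img + rnorm(size * size, 0, noise_sd)), 0, 255)
        images[[length(images) + 1L]] <- img
        labels <- c(labels, cl)
      }
    }
    list(images = images, labels = factor(labels, levels = classes))
  })
}
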