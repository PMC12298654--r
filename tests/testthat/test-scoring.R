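# Duration-threshold filtering, composite scoring, and group statistics.

mk_events <- function(labels, starts, durs, ...) {
  tibble::tibble(label = labels, t_start = starts, t_end = starts + durs, ...)
}

test_that("duration thresholds filter counting events but spare chattering", {
  ev <- mk_events(c("grooming", "rearing", "scratching"),
                  c(0, 20, 40), c(0.5, 2, 12))
  expect_equal(nrow(apply_duration_threshold(ev, 0)), 3L)
  expect_equal(nrow(apply_duration_threshold(ev, 4)), 1L)
  expect_error(apply_duration_threshold(ev, -1), ">= 0")

  ev2 <- dplyr::bind_rows(ev, mk_events("teeth_chattering", 60, 0.3))
  out <- apply_duration_threshold(ev2, 10)
  expect_true("teeth_chattering" %in% out$label)
  # wet-dog shakes are exempt only on request
  ev3 <- mk_events("wet_dog_shake", 0, 0.8)
  expect_equal(nrow(apply_duration_threshold(ev3, 4)), 0L)
  expect_equal(nrow(apply_duration_threshold(ev3, 4,
                                             exempt_instantaneous = TRUE)), 1L)
})

test_that("event counts and scores are non-increasing over the 1/4/7/10 s sweep", {
  set.seed(10)
  ev <- mk_events(sample(c("grooming", "rearing", "head_raising",
                           "scratching"), 40, TRUE),
                  runif(40, 0, 500), rexp(40, 1 / 4))
  counts <- scores <- numeric(4)
  for (i in seq_along(c(1, 4, 7, 10))) {
    kept <- apply_duration_threshold(ev, c(1, 4, 7, 10)[i])
    counts[i] <- nrow(kept)
    scores[i] <- score_session(kept, session_duration_s = 600)$score
  }
  expect_true(all(diff(counts) <= 0))
  expect_true(all(diff(scores) <= 0))
})

test_that("the composite scheme scores the worked examples exactly", {
  # one wet-dog shake: 1 point
  expect_equal(score_session(mk_events("wet_dog_shake", 10, 0.8),
                             session_duration_s = 300)$score, 1)
  # one stereotypic event: 0.5 point
  expect_equal(score_session(mk_events("grooming", 10, 3),
                             session_duration_s = 300)$score, 0.5)
  # two head-raising + three stereotypic: 2 + 1.5
  ev <- mk_events(c("head_raising", "head_raising", "grooming",
                    "face_washing", "genital_licking"),
                  seq(10, 50, by = 10), rep(2, 5))
  expect_equal(score_session(ev, session_duration_s = 300)$score, 3.5)
  # chattering in 4 of 6 five-minute windows: 8 points
  chat <- mk_events(rep("teeth_chattering", 4),
                    c(10, 400, 1000, 1600), rep(1, 4))
  s <- score_session(chat, session_duration_s = 1800)
  expect_equal(s$n_chatter_windows, 4L)
  expect_equal(s$score, 8)
  # one chatter event in a 5-minute session: one window, 2 points
  expect_equal(score_session(mk_events("teeth_chattering", 100, 0.5),
                             session_duration_s = 300)$score, 2)
  # nothing: 0
  expect_equal(score_session(mk_events(character(), numeric(), numeric()),
                             session_duration_s = 300)$score, 0)
})

test_that("unknown labels are reported by name", {
  expect_error(score_session(mk_events("tail_chasing", 0, 1),
                             session_duration_s = 60),
               "tail_chasing")
})

test_that("scores are additive over disjoint counting events", {
  set.seed(11)
  a <- mk_events(sample(c("wet_dog_shake", "grooming", "rearing"), 10, TRUE),
                 runif(10, 0, 100), rep(1, 10))
  b <- mk_events(sample(c("head_raising", "scratching"), 7, TRUE),
                 runif(7, 200, 300), rep(1, 7))
  s_ab <- score_session(dplyr::bind_rows(a, b), session_duration_s = 400)
  expect_equal(s_ab$score,
               score_session(a, session_duration_s = 400)$score +
                 score_session(b, session_duration_s = 400)$score)
})

test_that("the rearing mapping is a configuration switch", {
  ev <- mk_events("rearing", 10, 3)
  expect_equal(score_session(ev, score_scheme("counting"), 300)$score, 1)
  expect_equal(score_session(ev, score_scheme("stereotypic"), 300)$score, 0.5)
})

test_that("group cards aggregate animal scores into mean and SD", {
  ev <- dplyr::bind_rows(
    mk_events(rep("wet_dog_shake", 3), c(1, 2, 3), rep(0.5, 3),
              animal_id = "a1", group = "treated"),
    mk_events(rep("wet_dog_shake", 5), 1:5, rep(0.5, 5),
              animal_id = "a2", group = "treated"),
    mk_events("grooming", 1, 2, animal_id = "c1", group = "control"),
    mk_events("grooming", 4, 2, animal_id = "c2", group = "control"))
  card <- score_animals(ev, threshold_s = 0, session_duration_s = 300)
  expect_s3_class(card, "score_card")
  tr <- card$groups[card$groups$group == "treated", ]
  expect_equal(tr$mean, mean(c(3, 5)))
  expect_equal(tr$sd, sd(c(3, 5)))
  expect_s3_class(ggplot2::autoplot(card), "ggplot")
})

test_that("two-group comparisons reproduce the closed-form t statistic", {
  scores <- tibble::tibble(score = c(1, 2, 3, 2, 4, 6),
                           group = rep(c("ctrl", "high"), each = 3))
  st <- group_stats(scores)
  # pooled-variance two-sample t by hand
  s2p <- (var(c(1, 2, 3)) + var(c(2, 4, 6))) / 2
  t_manual <- (mean(c(2, 4, 6)) - mean(c(1, 2, 3))) / sqrt(s2p * (2 / 3))
  p_manual <- 2 * pt(-abs(t_manual), df = 4)
  g <- glance(st)
  expect_equal(abs(g$statistic), abs(t_manual), tolerance = 1e-12)
  expect_equal(g$p_value, p_manual, tolerance = 1e-12)
  expect_equal(g$df, 4)
  expect_s3_class(tidy(st), "tbl_df")
})

test_that("degenerate group comparisons behave as expected", {
  same <- tibble::tibble(score = c(1, 2, 3, 1, 2, 3),
                         group = rep(c("a", "b"), each = 3))
  st <- group_stats(same)
  expect_equal(unname(glance(st)$statistic), 0)
  expect_equal(glance(st)$p_value, 1)
  expect_equal(tidy(st)$significance, "ns")

  three <- tibble::tibble(score = rep(c(1, 2, 3), 3),
                          group = rep(c("a", "b", "c"), each = 3))
  st3 <- group_stats(three)
  expect_equal(glance(st3)$design, "multi_group")
  expect_equal(unname(glance(st3)$statistic), 0)
  expect_equal(nrow(tidy(st3)), 3L) # all pairwise Tukey comparisons

  expect_error(group_stats(tibble::tibble(score = c(1, 2, 3),
                                          group = c("a", "a", "b"))),
               "n >= 2")
})

test_that("multi-group designs match aov + TukeyHSD directly", {
  set.seed(12)
  scores <- tibble::tibble(score = c(rnorm(5, 1), rnorm(5, 3), rnorm(5, 3.5)),
                           group = rep(c("ctrl", "low", "high"), each = 5))
  st <- group_stats(scores)
  fit <- aov(score ~ group, data = transform(scores, group = factor(group)))
  expect_equal(unname(glance(st)$statistic),
               summary(fit)[[1]]$`F value`[1], tolerance = 1e-12)
  tk <- TukeyHSD(fit)$group
  td <- tidy(st)
  expect_equal(td$p_value[match(rownames(tk), td$comparison)],
               unname(tk[, "p adj"]), tolerance = 1e-12)
})

test_that("significance tiers follow the 0.05 / 0.01 / 0.001 convention", {
  expect_equal(withdrawr:::significance_stars(c(0.2, 0.04, 0.009, 0.0009)),
               c("ns", "*", "**", "***"))
})
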