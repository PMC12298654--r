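# Composite withdrawal scoring: duration-threshold filtering of detected
# events, per-session scores under the counting scheme, and group statistics.

STEREOTYPIC_LABELS <- c("grooming", "face_washing", "genital_licking",
                        "scratching")

#' Composite withdrawal scoring scheme
#'
#' Counting metrics earn points per recorded event: wet-dog shakes 1 point,
#' head-raising 1 point, stereotypic behaviors (grooming, face washing,
#' genital licking, scratching) 0.5 point. Teeth chattering is non-counting:
#' 2 points for every 5-minute interval in which it occurs. Rearing-type
#' events (`rearing`, `wall_supported_rearing`) are scored as their own
#' 1-point counting metric by default (`rearing = "counting"`); set
#' `rearing = "stereotypic"` to score them at 0.5 instead. Labels that carry
#' no points (`normal`, `locomotion`, `stationary`) are tolerated and
#' ignored.
#'
#' @param rearing `"counting"` (1 point) or `"stereotypic"` (0.5).
#' @param chatter_points Points per chatter-positive 5-min window (default 2).
#' @param window_s Assessment window for teeth chattering (default 300 s).
#' @return Object of class `score_scheme` with a `points` lookup.
#' @export
score_scheme <- function(rearing = c("counting", "stereotypic"),
                         chatter_points = 2, window_s = 300) {
  rearing <- match.arg(rearing)
  rear_pts <- if (rearing == "counting") 1 else 0.5
  points <- c(wet_dog_shake = 1, head_raising = 1,
              setNames(rep(0.5, length(STEREOTYPIC_LABELS)),
                       STEREOTYPIC_LABELS),
              rearing = rear_pts, wall_supported_rearing = rear_pts,
              normal = 0, locomotion = 0, stationary = 0)
  structure(list(points = points, chatter_points = chatter_points,
                 window_s = window_s, rearing = rearing),
            class = "score_scheme")
}

#' Filter events by a minimum duration threshold
#'
#' Keeps events whose duration is at least `threshold_s`. Teeth chattering is
#' a non-counting metric assessed per 5-minute window, so it is exempt from
#' the threshold by default; setting `exempt_instantaneous = TRUE` also
#' exempts wet-dog shakes (which are near-instantaneous counting events).
#'
#' @param events Event tibble (`label`, `t_start`, `t_end`, optionally
#'   `duration_s`).
#' @param threshold_s Minimum duration, seconds (>= 0).
#' @param exempt_instantaneous Also exempt `wet_dog_shake` (default FALSE).
#' @param exempt_labels Labels never filtered (default `teeth_chattering`).
#' @return Filtered event tibble.
#' @export
apply_duration_threshold <- function(events, threshold_s,
                                     exempt_instantaneous = FALSE,
                                     exempt_labels = "teeth_chattering") {
  if (threshold_s < 0) rlang::abort("threshold_s must be >= 0")
  events <- tibble::as_tibble(events)
  if (!"duration_s" %in% names(events))
    events$duration_s <- events$t_end - events$t_start
  if (exempt_instantaneous) exempt_labels <- c(exempt_labels, "wet_dog_shake")
  dplyr::filter(events, .data$duration_s >= threshold_s |
                  .data$label %in% exempt_labels)
}

#' Composite withdrawal score of one session
#'
#' Sums counting-event points and adds `chatter_points` for every consecutive
#' 5-minute block of the session in which at least one teeth-chattering event
#' occurs (blocks are anchored at session start and partition
#' `[0, session_duration_s]`).
#'
#' @param events Event tibble (already duration-filtered as desired).
#' @param scheme A [score_scheme()].
#' @param session_duration_s Session length, seconds.
#' @return One-row tibble: `score`, `counting_score`, `chatter_score`,
#'   `n_events`, `n_chatter_windows`.
#' @export
score_session <- function(events, scheme = score_scheme(),
                          session_duration_s = NULL) {
  events <- tibble::as_tibble(events)
  known <- c(names(scheme$points), "teeth_chattering")
  bad <- setdiff(unique(events$label), known)
  if (length(bad))
    rlang::abort(paste("unknown behavior label(s):", paste(bad, collapse = ", ")))
  counting <- events[events$label != "teeth_chattering", , drop = FALSE]
  counting_score <- sum(scheme$points[counting$label])
  chat <- events[events$label == "teeth_chattering", , drop = FALSE]
  n_windows <- 0L
  if (nrow(chat)) {
    if (is.null(session_duration_s))
      session_duration_s <- max(chat$t_end)
    edges <- seq(0, session_duration_s, by = scheme$window_s)
    if (edges[length(edges)] < session_duration_s)
      edges <- c(edges, session_duration_s)
    hit <- logical(length(edges) - 1L)
    for (i in seq_len(nrow(chat))) {
      # a window is positive if the event overlaps it
      lo <- findInterval(chat$t_start[i], edges, rightmost.closed = TRUE)
      hi <- findInterval(min(chat$t_end[i], session_duration_s), edges,
                         rightmost.closed = TRUE)
      hit[clamp(lo:hi, 1L, length(hit))] <- TRUE
    }
    n_windows <- sum(hit)
  }
  tibble::tibble(score = counting_score + scheme$chatter_points * n_windows,
                 counting_score = counting_score,
                 chatter_score = scheme$chatter_points * n_windows,
                 n_events = nrow(events), n_chatter_windows = n_windows)
}

#' Score many animals and summarize groups
#'
#' Scores each animal's event log under a common duration threshold and
#' scheme, and reports per-group mean and SD (the group mean is the
#' arithmetic mean of its member scores).
#'
#' @param events Event tibble with `animal_id` and `group` columns.
#' @param threshold_s Duration threshold applied before scoring.
#' @param scheme A [score_scheme()].
#' @param session_duration_s Session length, seconds.
#' @return List of class `score_card`: `animals` (animal, group, score) and
#'   `groups` (group, n, mean, sd), plus the threshold used.
#' @export
score_animals <- function(events, threshold_s = 0, scheme = score_scheme(),
                          session_duration_s = NULL) {
  stopifnot(all(c("animal_id", "group") %in% names(events)))
  filtered <- apply_duration_threshold(events, threshold_s)
  animals <- filtered |>
    dplyr::group_by(.data$animal_id, .data$group) |>
    dplyr::group_modify(~ score_session(.x, scheme, session_duration_s)) |>
    dplyr::ungroup()
  # animals with all events filtered out still score 0
  base <- dplyr::distinct(events, .data$animal_id, .data$group)
  animals <- dplyr::left_join(base, animals, by = c("animal_id", "group")) |>
    dplyr::mutate(score = ifelse(is.na(.data$score), 0, .data$score))
  groups <- animals |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$score),
                     sd = sd(.data$score), .groups = "drop")
  structure(list(animals = animals, groups = groups,
                 threshold_s = threshold_s, scheme = scheme),
            class = "score_card")
}

#' @export
print.score_card <- function(x, ...) {
  cat(sprintf("<score_card: %d animals, %d group(s), threshold %.3g s>\n",
              nrow(x$animals), nrow(x$groups), x$threshold_s))
  print(x$groups)
  invisible(x)
}

#' Plot per-group withdrawal scores
#'
#' @param object A [score_animals()] result.
#' @param ... Unused.
#' @return A ggplot object (group means with SD bars and animal points).
#' @export
autoplot.score_card <- function(object, ...) {
  ggplot2::ggplot(object$groups,
                  ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey80", color = "grey30") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::geom_jitter(data = object$animals,
                         ggplot2::aes(y = .data$score), width = 0.1,
                         alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "withdrawal score",
                  title = sprintf("Composite scores (threshold %.3g s)",
                                  object$threshold_s))
}

significance_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "ns")
}

#' Group comparison of withdrawal scores
#'
#' Two groups: two-tailed unpaired Student's t test. Three or more groups:
#' one-way ANOVA followed by Tukey's HSD for all pairwise comparisons.
#' Significance tiers: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#'
#' @param scores Tibble with `score` and `group` columns (e.g.
#'   `score_animals()$animals`).
#' @return Object of class `withdrawal_stats` with [tidy()] and [glance()]
#'   methods.
#' @export
group_stats <- function(scores) {
  scores <- tibble::as_tibble(scores)
  stopifnot(all(c("score", "group") %in% names(scores)))
  scores$group <- factor(scores$group)
  sizes <- table(scores$group)
  if (any(sizes < 2L))
    rlang::abort(paste("every group needs n >= 2; offending:",
                       paste(names(sizes)[sizes < 2L], collapse = ", ")))
  k <- nlevels(scores$group)
  if (k < 2L) rlang::abort("need at least two groups")
  if (k == 2L) {
    lv <- levels(scores$group)
    tt <- t.test(score ~ group, data = scores, var.equal = TRUE,
                 alternative = "two.sided")
    comp <- tibble::tibble(comparison = paste(lv[2L], "-", lv[1L]),
                           estimate = unname(diff(rev(tt$estimate)) * -1),
                           statistic = unname(tt$statistic),
                           p_value = tt$p.value,
                           significance = significance_stars(tt$p.value))
    structure(list(design = "two_group", fit = tt, comparisons = comp,
                   scores = scores),
              class = "withdrawal_stats")
  } else {
    fit <- aov(score ~ group, data = scores)
    tk <- TukeyHSD(fit)$group
    comp <- tibble::tibble(comparison = rownames(tk),
                           estimate = unname(tk[, "diff"]),
                           statistic = NA_real_,
                           p_value = unname(tk[, "p adj"]),
                           significance = significance_stars(tk[, "p adj"]))
    structure(list(design = "multi_group", fit = fit, comparisons = comp,
                   scores = scores),
              class = "withdrawal_stats")
  }
}

#' @export
print.withdrawal_stats <- function(x, ...) {
  g <- glance(x)
  if (x$design == "two_group") {
    cat(sprintf("Two-tailed unpaired t test: t = %.4g, p = %.4g (%s)\n",
                g$statistic, g$p_value,
                significance_stars(g$p_value)))
  } else {
    cat(sprintf("One-way ANOVA: F = %.4g, p = %.4g; Tukey HSD pairwise:\n",
                g$statistic, g$p_value))
  }
  print(x$comparisons)
  invisible(x)
}

#' @rdname group_stats
#' @param x A `withdrawal_stats` object.
#' @param ... Unused.
#' @export
tidy.withdrawal_stats <- function(x, ...) x$comparisons

#' @rdname group_stats
#' @export
glance.withdrawal_stats <- function(x, ...) {
  if (x$design == "two_group") {
    tibble::tibble(design = "two_group", statistic = unname(x$fit$statistic),
                   p_value = x$fit$p.value,
                   df = unname(x$fit$parameter))
  } else {
    s <- summary(x$fit)[[1L]]
    tibble::tibble(design = "multi_group", statistic = s$`F value`[1L],
                   p_value = s$`Pr(>F)`[1L], df = s$Df[1L])
  }
}
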