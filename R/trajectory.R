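# Emotion-trajectory analysis: eligibility filtering, normalization of
# conversations onto a common 0-100% progression scale by linear
# interpolation, pointwise aggregation, and begin/end percent change.
#
# The unit of analysis is the user visit (one user in one session). Knots
# are placed by scored-message order, not wall-clock time: a user's m scored
# messages sit at progression i/(m-1). Active-SI sessions are excluded from
# every trajectory analysis (the crisis referral changes the structure and
# goal of those chats).

progression_grid <- function(grid_points) {
  stopifnot(grid_points >= 2)
  seq(0, 1, length.out = grid_points)
}

#' Visits eligible for trajectory analysis of one emotion
#'
#' A visit qualifies if the maximum available score over the focal user's
#' first `window` messages reaches `threshold` — chats are required to begin
#' with measurable distress so trajectories reflect an emotional concern,
#' not small talk. For the protective emotion (optimism) the threshold is
#' applied to the maximum over the four negative emotions instead (a low
#' optimism score cannot indicate distress); override via
#' `threshold_emotions`. Active-SI sessions are always excluded.
#'
#' @param corpus a [chat_corpus()].
#' @param emotion the emotion whose trajectory will be analysed.
#' @param threshold minimum qualifying score (default 5).
#' @param window number of initial focal-user messages inspected (default 3).
#' @param groups visit groups to consider (default: all except active SI).
#' @param threshold_emotions emotions the threshold is applied to; defaults
#'   to `emotion` itself, or the four negative emotions when
#'   `emotion == "optimism"`.
#' @return data.frame with columns `session_id`, `user_id`, `group`,
#'   `initial_intensity` (the qualifying maximum) and `topic`.
#' @export
eligible_sessions <- function(corpus, emotion, threshold = 5, window = 3,
                              groups = setdiff(VISIT_GROUPS, "active_si"),
                              threshold_emotions = NULL) {
  emotion <- match.arg(emotion, EMOTIONS)
  if (is.null(threshold_emotions)) {
    threshold_emotions <- if (emotion == "optimism") NEGATIVE_EMOTIONS else emotion
  }
  stopifnot(all(threshold_emotions %in% EMOTIONS))
  s <- corpus$sessions
  v <- corpus$visits
  keep_sid <- s$session_id[s$si_label != "active"]
  v <- v[v$group %in% groups & v$session_id %in% keep_sid, , drop = FALSE]
  if (!nrow(v)) {
    return(data.frame(session_id = character(0), user_id = character(0),
                      group = character(0), initial_intensity = numeric(0),
                      topic = character(0)))
  }
  m <- corpus$messages[corpus$messages$role == "participant", , drop = FALSE]
  m <- m[order(m$session_id, m$index), ]
  key <- paste(m$session_id, m$user_id)
  own <- stats::ave(seq_len(nrow(m)), key, FUN = seq_along)
  m <- m[own <= window, , drop = FALSE]
  key <- paste(m$session_id, m$user_id)
  sc <- as.matrix(m[, threshold_emotions, drop = FALSE])
  best <- suppressWarnings(
    tapply(do.call(pmax, c(as.data.frame(sc), na.rm = TRUE)), key, max, na.rm = TRUE))
  best[!is.finite(best)] <- NA_real_
  vkey <- paste(v$session_id, v$user_id)
  intensity <- as.numeric(best[vkey])
  ok <- !is.na(intensity) & intensity >= threshold
  out <- v[ok, c("session_id", "user_id", "group"), drop = FALSE]
  out$initial_intensity <- intensity[ok]
  out$topic <- s$topic[match(out$session_id, s$session_id)]
  rownames(out) <- NULL
  out
}

new_trajectory_curve <- function(emotion, grid, values, n, sd = NULL,
                                 session_id = NULL, user_id = NULL) {
  structure(list(emotion = emotion, grid = grid, values = values,
                 sd = sd, n = n, session_id = session_id, user_id = user_id),
            class = "trajectory_curve")
}

#' @export
print.trajectory_curve <- function(x, ...) {
  cat(sprintf("trajectory_curve [%s]: %d grid points, n = %d\n",
              x$emotion, length(x$grid), x$n))
  cat(sprintf("  begin %.3f -> end %.3f\n", x$values[1], x$values[length(x$values)]))
  invisible(x)
}

# m scored values -> piecewise-linear curve on the progression grid.
interp_values <- function(scores, grid) {
  m <- length(scores)
  knots <- (seq_len(m) - 1) / (m - 1)
  stats::approx(knots, scores, xout = grid, method = "linear",
                ties = "ordered")$y
}

#' Interpolate one user's emotion trajectory onto the progression grid
#'
#' The user's m scored messages (absent scores skipped) are placed at
#' progression i/(m-1), i = 0..m-1, and connected by straight lines; values
#' at the grid points are read off this piecewise-linear curve. Endpoints
#' equal the first and last scores exactly.
#'
#' @param corpus a [chat_corpus()].
#' @param session_id,user_id the visit whose trajectory is wanted.
#' @param emotion one of [EMOTIONS].
#' @param grid_points grid resolution (default 101: 0%, 1%, ..., 100%).
#' @return a `trajectory_curve` (n = 1), or `NULL` (with a message) when the
#'   user has fewer than 2 scored messages for the emotion.
#' @export
interpolate_trajectory <- function(corpus, session_id, user_id, emotion,
                                   grid_points = 101) {
  emotion <- match.arg(emotion, EMOTIONS)
  m <- corpus$messages
  m <- m[m$session_id == session_id & m$user_id == user_id &
           m$role == "participant", , drop = FALSE]
  m <- m[order(m$index), ]
  sc <- m[[emotion]][!is.na(m[[emotion]])]
  if (length(sc) < 2) {
    message(sprintf("visit %s/%s skipped: fewer than 2 scored %s messages",
                    session_id, user_id, emotion))
    return(NULL)
  }
  grid <- progression_grid(grid_points)
  new_trajectory_curve(emotion, grid, interp_values(sc, grid), n = 1L,
                       session_id = session_id, user_id = user_id)
}

# Bulk version: matrix of per-visit curves (rows = visits) for the visits in
# `who` (data.frame with session_id, user_id). Visits with < 2 scored
# messages are dropped; attribute "dropped" records how many.
trajectory_matrix <- function(corpus, who, emotion, grid_points = 101) {
  grid <- progression_grid(grid_points)
  m <- corpus$messages[corpus$messages$role == "participant", , drop = FALSE]
  key <- paste(m$session_id, m$user_id)
  wkey <- paste(who$session_id, who$user_id)
  m <- m[key %in% wkey & !is.na(m[[emotion]]), , drop = FALSE]
  m <- m[order(m$session_id, m$user_id, m$index), ]
  sc <- split(m[[emotion]], paste(m$session_id, m$user_id))
  sc <- sc[lengths(sc) >= 2]
  sc <- sc[intersect(wkey, names(sc))]
  out <- t(vapply(sc, interp_values, numeric(length(grid)), grid = grid))
  attr(out, "grid") <- grid
  attr(out, "dropped") <- length(wkey) - length(sc)
  attr(out, "keys") <- names(sc)
  out
}

#' Aggregate per-visit trajectory curves
#'
#' Pointwise mean and SD over curves sharing a grid.
#'
#' @param curves list of `trajectory_curve` objects (or a numeric matrix,
#'   one row per curve, with a `"grid"` attribute).
#' @return a `trajectory_curve` with pointwise `values` (means), `sd`, and
#'   `n` = number of curves.
#' @export
aggregate_trajectories <- function(curves) {
  if (is.matrix(curves)) {
    mat <- curves
    grid <- attr(mat, "grid")
    emotion <- attr(mat, "emotion")
    if (is.null(emotion)) emotion <- NA_character_
  } else {
    stopifnot(length(curves) >= 1)
    grid <- curves[[1]]$grid
    emotion <- curves[[1]]$emotion
    for (cv in curves) {
      if (length(cv$grid) != length(grid) || any(abs(cv$grid - grid) > 1e-12)) {
        stop("curves do not share a common grid", call. = FALSE)
      }
    }
    mat <- do.call(rbind, lapply(curves, `[[`, "values"))
  }
  new_trajectory_curve(
    emotion, grid,
    values = colMeans(mat),
    sd = apply(mat, 2, stats::sd),
    n = nrow(mat))
}

#' Begin-to-end percent change of a trajectory
#'
#' For the negative emotions the reported quantity is the reduction,
#' (begin - end)/begin x 100; for optimism it is the increase,
#' (end - begin)/begin x 100. Begin and end are the curve's endpoint values.
#'
#' @param curve a `trajectory_curve`.
#' @return signed percentage with attribute `"direction"` (`"reduction"` or
#'   `"increase"`).
#' @export
percent_change <- function(curve) {
  stopifnot(inherits(curve, "trajectory_curve"))
  begin <- curve$values[1]
  end <- curve$values[length(curve$values)]
  if (!is.finite(begin) || begin == 0) stop("begin value must be positive", call. = FALSE)
  if (identical(curve$emotion, "optimism")) {
    structure(100 * (end - begin) / begin, direction = "increase")
  } else {
    structure(100 * (begin - end) / begin, direction = "reduction")
  }
}

#' Aggregate trajectory of one visit group
#'
#' Convenience driver: eligibility filter, per-visit interpolation, and
#' pointwise aggregation for one emotion and group.
#'
#' @inheritParams eligible_sessions
#' @param group a single visit group.
#' @param grid_points grid resolution.
#' @return a `trajectory_curve`, or `NULL` when no visit qualifies.
#' @export
group_trajectory <- function(corpus, emotion, group, threshold = 5, window = 3,
                             grid_points = 101) {
  el <- eligible_sessions(corpus, emotion, threshold, window, groups = group)
  if (!nrow(el)) return(NULL)
  mat <- trajectory_matrix(corpus, el, emotion, grid_points)
  if (!nrow(mat)) return(NULL)
  attr(mat, "emotion") <- emotion
  aggregate_trajectories(mat)
}
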