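# Baseline group comparison (Mann-Whitney U) and trajectory-slope
# comparison (ANCOVA with a group-by-time interaction).

# Exact permutation distribution of the rank sum of sample A, conditional
# on the observed (mid)ranks. Doubled ranks are integers even under ties,
# so the distribution is built by integer convolution:
# f[k, s] = number of size-k subsets of the doubled ranks with total s.
ranksum_distribution <- function(ranks2, na) {
  total <- sum(ranks2)
  f <- matrix(0, nrow = na + 1, ncol = total + 1)  # [k+1, s+1]
  f[1, 1] <- 1
  for (r in ranks2) {
    for (k in rev(seq_len(na))) {
      shifted <- c(rep(0, r), f[k, seq_len(total + 1 - r)])
      f[k + 1, ] <- f[k + 1, ] + shifted
    }
  }
  f[na + 1, ]  # counts over s = 0..total (doubled rank-sum scale)
}

#' Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties (equivalently,
#' pair counting with half-credit for ties). When `n_a * n_b <= exact_limit`
#' the two-sided p-value comes from the exact permutation distribution of U
#' conditional on the observed ranks (valid under ties, where the classical
#' exact tables are not); otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used.
#'
#' @param sample_a,sample_b numeric score vectors (non-empty). Zero scores
#'   (no emotion detected) are expected to have been excluded upstream.
#' @param exact_limit exact enumeration is used when
#'   `length(sample_a) * length(sample_b)` is at most this (default 200).
#' @return object of class `mw_test`: `U` (for sample_a), `z` (NA in the
#'   exact branch), `p_value`, `method`, sample sizes.
#' @export
mann_whitney <- function(sample_a, sample_b, exact_limit = 200) {
  na <- length(sample_a); nb <- length(sample_b)
  if (!na || !nb) stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)  # midranks
  ra <- sum(r[seq_len(na)])
  U <- ra - na * (na + 1) / 2
  mu <- na * nb / 2
  if (na * nb <= exact_limit) {
    r2 <- as.integer(round(2 * r))
    dist <- ranksum_distribution(r2, na)
    s <- seq_along(dist) - 1          # doubled rank sums
    u_all <- s / 2 - na * (na + 1) / 2
    obs_dev <- abs(U - mu)
    p <- sum(dist[abs(u_all - mu) >= obs_dev - 1e-9]) / sum(dist)
    out <- list(U = U, z = NA_real_, p_value = min(p, 1),
                method = "exact permutation (tie-aware)", n_a = na, n_b = nb)
  } else {
    n <- na + nb
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    dev <- U - mu
    cc <- sign(dev) * 0.5  # continuity correction toward the mean
    z <- if (sigma2 > 0) (dev - cc) / sqrt(sigma2) else 0
    if (dev == 0) z <- 0
    p <- 2 * stats::pnorm(-abs(z))
    out <- list(U = U, z = z, p_value = min(p, 1),
                method = "normal approximation, tie-corrected, continuity-corrected",
                n_a = na, n_b = nb)
  }
  class(out) <- "mw_test"
  out
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s)\n", x$method))
  cat(sprintf("  U = %g (n_a = %d, n_b = %d)", x$U, x$n_a, x$n_b))
  if (!is.na(x$z)) cat(sprintf(", z = %.4f", x$z))
  cat(sprintf(", p = %.4g\n", x$p_value))
  invisible(x)
}

#' ANCOVA with a group-by-time interaction
#'
#' Ordinary least squares of score on normalized conversation progression
#' (`time` in \[0, 1\]), group, and their interaction:
#' `score ~ 1 + time + group + group:time`. The interaction coefficient is
#' the difference in emotional-change slope between groups; its two-sided
#' p-value uses the t distribution with n - 4 degrees of freedom. Points
#' are treated as independent (no session-level clustering), mirroring the
#' analysis design; fitted per-group slopes satisfy
#' slope(group 1) = slope(group 0) + interaction exactly.
#'
#' @param points data.frame with columns `group` (0/1, logical, or a
#'   2-level factor), `time` (in \[0, 1\]) and `score`; an optional
#'   `session_id` column is used only to report the session count.
#' @return object of class `ancova_result`.
#' @export
ancova_interaction <- function(points) {
  stopifnot(all(c("group", "time", "score") %in% names(points)))
  g <- points$group
  if (is.factor(g)) g <- as.integer(g) - 1L
  g <- as.numeric(g)
  if (length(unique(g)) != 2 || !all(g %in% c(0, 1))) {
    stop("group must take exactly the two values 0 and 1", call. = FALSE)
  }
  if (length(unique(points$time)) < 2) {
    stop("need at least 2 distinct time values", call. = FALSE)
  }
  df <- data.frame(score = points$score, time = points$time, group = g)
  fit <- stats::lm(score ~ time + group + time:group, data = df)
  qrr <- fit$qr$rank
  if (qrr < 4) stop("rank-deficient ANCOVA design", call. = FALSE)
  beta <- stats::coef(fit)
  n <- nrow(df)
  # standard errors computed directly from the QR factorization so that a
  # noiseless (perfect) fit is handled without special-casing
  sigma2 <- sum(stats::residuals(fit)^2) / (n - 4)
  xtx_inv <- chol2inv(qr.R(fit$qr))
  se <- stats::setNames(sqrt(pmax(diag(xtx_inv), 0) * sigma2), names(beta))
  tval <- beta[["time:group"]] / se[["time:group"]]
  p <- 2 * stats::pt(-abs(tval), df = n - 4)
  n_sessions <- if (!is.null(points$session_id)) {
    length(unique(points$session_id))
  } else NA_integer_
  structure(list(
    coefficients = beta, se = se,
    interaction = beta[["time:group"]],
    t = tval, p_value = p, df = n - 4,
    slopes = c(group0 = beta[["time"]],
               group1 = beta[["time"]] + beta[["time:group"]]),
    n_points = n, n_sessions = n_sessions, fit = fit),
    class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat("ANCOVA: score ~ time + group + time:group\n")
  cat(sprintf("  slopes: group0 %.4f, group1 %.4f\n",
              x$slopes[["group0"]], x$slopes[["group1"]]))
  cat(sprintf("  group-by-time interaction %.4f (t = %.3f, df = %d, p = %.4g)\n",
              x$interaction, x$t, x$df, x$p_value))
  cat(sprintf("  %d points", x$n_points))
  if (!is.na(x$n_sessions)) cat(sprintf(" from %d visits", x$n_sessions))
  cat("\n")
  invisible(x)
}

#' @export
coef.ancova_result <- function(object, ...) object$coefficients

# First/last available score of one emotion for each qualifying visit.
begin_end_scores <- function(corpus, emotion, group, min_messages = 5) {
  v <- corpus$visits[corpus$visits$group == group, , drop = FALSE]
  m <- corpus$messages[corpus$messages$role == "participant", , drop = FALSE]
  key <- paste(m$session_id, m$user_id)
  vkey <- paste(v$session_id, v$user_id)
  m <- m[key %in% vkey, , drop = FALSE]
  m <- m[order(m$session_id, m$user_id, m$index), ]
  key <- paste(m$session_id, m$user_id)
  cnt <- table(key)
  keep <- names(cnt)[cnt >= min_messages]
  m <- m[key %in% keep, , drop = FALSE]
  key <- key[key %in% keep]
  # begin = score carried by the user's FIRST message (excluded when not
  # scored); end symmetric, from the user's last message
  firsts <- m[[emotion]][!duplicated(key)]
  lasts <- m[[emotion]][!duplicated(key, fromLast = TRUE)]
  data.frame(key = unique(key), begin = firsts, end = lasts)
}

#' Baseline begin/end comparison between two visit groups
#'
#' Users are filtered to those who contributed at least `min_messages`
#' messages in the session. The baseline is the score carried by the
#' user's first message (visits whose first message has no detected score
#' for the emotion are excluded — zero scores never enter the analysis);
#' the ending level is taken from the last message symmetrically. Group
#' difference in baselines is tested with the Mann-Whitney U test.
#'
#' @param corpus a [chat_corpus()].
#' @param emotion one of [EMOTIONS].
#' @param groups length-2 character vector of visit groups (first = focus
#'   group, second = comparison group).
#' @param min_messages minimum messages per user per room (default 5).
#' @return object of class `baseline_comparison`: per-group begin/end
#'   means, SDs and n, plus the `mw_test` on baselines.
#' @export
baseline_comparison <- function(corpus, emotion,
                                groups = c("passive_si", "non_exposed_non_si"),
                                min_messages = 5) {
  emotion <- match.arg(emotion, EMOTIONS)
  stopifnot(length(groups) == 2)
  stat <- function(g) {
    be <- begin_end_scores(corpus, emotion, g, min_messages)
    begin <- be$begin[!is.na(be$begin)]
    end <- be$end[!is.na(be$end)]
    if (!length(begin)) {
      stop(sprintf("group '%s' is empty after the %d-message filter",
                   g, min_messages), call. = FALSE)
    }
    list(begin = begin, end = end,
         summary = data.frame(
           group = g,
           begin_mean = mean(begin), begin_sd = stats::sd(begin),
           end_mean = mean(end), end_sd = stats::sd(end),
           n_begin = length(begin), n_end = length(end)))
  }
  a <- stat(groups[1]); b <- stat(groups[2])
  structure(list(emotion = emotion,
                 table = rbind(a$summary, b$summary),
                 test = mann_whitney(a$begin, b$begin)),
            class = "baseline_comparison")
}

#' @export
print.baseline_comparison <- function(x, ...) {
  cat(sprintf("Baseline %s scores (begin/end, per group)\n", x$emotion))
  tb <- x$table
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("  %-20s %.2f/%.2f (SD = %.2f/%.2f), n = %d\n",
                tb$group[i], tb$begin_mean[i], tb$end_mean[i],
                tb$begin_sd[i], tb$end_sd[i], tb$n_begin[i]))
  }
  cat(sprintf("  baseline difference: Mann-Whitney p = %.4g\n", x$test$p_value))
  invisible(x)
}

#' Matched trajectory comparison between two visit groups
#'
#' End-to-end driver for one emotion: eligibility filtering of both arms,
#' propensity-score estimation (initial intensity + topic) on the eligible
#' visits, 1:1 caliper matching, per-visit trajectory interpolation of the
#' matched visits, pointwise aggregation, begin/end percent change, a
#' Mann-Whitney test on matched baseline (grid start) scores, and the
#' ANCOVA group-by-time interaction on the grid-resampled points.
#'
#' @param corpus a [chat_corpus()].
#' @param emotion one of [EMOTIONS].
#' @param treated_group,control_group visit groups being compared.
#' @param threshold,window eligibility rule (see [eligible_sessions()]).
#' @param grid_points trajectory grid resolution.
#' @param caliper logit-scale matching caliper.
#' @param match if `FALSE`, skip matching and use all eligible visits.
#' @param ridge optional ridge for [fit_propensity()].
#' @return object of class `trajectory_comparison`.
#' @export
trajectory_comparison <- function(corpus, emotion,
                                  treated_group = "passive_si",
                                  control_group = "non_exposed_non_si",
                                  threshold = 5, window = 3,
                                  grid_points = 101, caliper = 0.01,
                                  match = TRUE, ridge = 0) {
  emotion <- match.arg(emotion, EMOTIONS)
  el <- eligible_sessions(corpus, emotion, threshold, window,
                          groups = c(treated_group, control_group))
  el$id <- paste(el$session_id, el$user_id)
  el$treated <- el$group == treated_group
  if (!any(el$treated) || all(el$treated)) {
    stop("both comparison arms must have eligible visits", call. = FALSE)
  }
  records <- data.frame(id = el$id, treated = el$treated,
                        initial_intensity = el$initial_intensity,
                        topic = el$topic, stringsAsFactors = FALSE)
  if (match) {
    prop <- fit_propensity(records, ridge = ridge)
    mres <- match_pairs(records, prop$propensity, caliper = caliper)
    balance <- if (nrow(mres$pairs)) standardized_mean_diff(records, mres) else NULL
    keep_ids <- c(mres$pairs$treated_id, mres$pairs$control_id)
    el <- el[el$id %in% keep_ids, , drop = FALSE]
  } else {
    prop <- NULL; mres <- NULL; balance <- NULL
  }
  arms <- list()
  for (arm in c("treated", "control")) {
    who <- el[el$treated == (arm == "treated"), , drop = FALSE]
    mat <- trajectory_matrix(corpus, who, emotion, grid_points)
    if (!nrow(mat)) stop("no interpolable visits in the ", arm, " arm", call. = FALSE)
    attr(mat, "emotion") <- emotion
    arms[[arm]] <- mat
  }
  agg_t <- aggregate_trajectories(arms$treated)
  agg_c <- aggregate_trajectories(arms$control)
  grid <- attr(arms$treated, "grid")
  pts <- function(mat, g) {
    data.frame(session_id = rep(attr(mat, "keys"), each = length(grid)),
               group = g, time = rep(grid, nrow(mat)),
               score = as.vector(t(mat)))
  }
  anc <- ancova_interaction(rbind(pts(arms$treated, 1L), pts(arms$control, 0L)))
  structure(list(
    emotion = emotion,
    treated_group = treated_group, control_group = control_group,
    n_treated = nrow(arms$treated), n_control = nrow(arms$control),
    propensity = prop, match = mres, balance = balance,
    treated_curve = agg_t, control_curve = agg_c,
    percent_change = c(treated = as.numeric(percent_change(agg_t)),
                       control = as.numeric(percent_change(agg_c))),
    baseline_test = mann_whitney(arms$treated[, 1], arms$control[, 1]),
    ancova = anc),
    class = "trajectory_comparison")
}

#' @export
print.trajectory_comparison <- function(x, ...) {
  dir <- if (x$emotion == "optimism") "increase" else "reduction"
  cat(sprintf("%s trajectories: %s (n = %d) vs %s (n = %d)\n",
              x$emotion, x$treated_group, x$n_treated,
              x$control_group, x$n_control))
  cat(sprintf("  begin -> end: %.2f -> %.2f (treated), %.2f -> %.2f (control)\n",
              x$treated_curve$values[1], tail_value(x$treated_curve),
              x$control_curve$values[1], tail_value(x$control_curve)))
  cat(sprintf("  %s: %.1f%% (treated), %.1f%% (control)\n", dir,
              x$percent_change[["treated"]], x$percent_change[["control"]]))
  cat(sprintf("  ANCOVA group-by-time p = %.4g\n", x$ancova$p_value))
  invisible(x)
}

tail_value <- function(curve) curve$values[length(curve$values)]
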