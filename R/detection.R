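# Hybrid AI/moderator crisis-detection evaluation: confusion counts, the
# five agreement metrics, flag follow-up latency (T1/T2), referral
# timeliness, and SI prevalence summaries.
#
# Ground truth throughout is the moderator's initiation of the risk
# protocol (a protocol_question flag event), not the session's SI label:
# an AI-only flag is a false positive even in a session that carries an SI
# label, because the benchmark is the moderator's assessment.

#' Confusion counts of AI flags against the moderator benchmark
#'
#' Each session contributes exactly one cell: AI crisis flag and moderator
#' protocol question both present = TP; AI only = FP; moderator only = FN;
#' neither = TN. Order of the two events within the chat is irrelevant here
#' (it matters only for latency analysis); message content is never read.
#'
#' @param corpus a [chat_corpus()].
#' @return object of class `confusion_counts`: list with `tp`, `fp`, `fn`,
#'   `tn` and `n` (= tp+fp+fn+tn = number of evaluated sessions).
#' @export
confusion_counts <- function(corpus) {
  stopifnot(inherits(corpus, "chat_corpus"))
  f <- corpus$flags
  ai <- unique(f$session_id[f$source == "ai" & f$kind == "crisis_flag"])
  mod <- unique(f$session_id[f$source == "moderator" & f$kind == "protocol_question"])
  all_s <- corpus$sessions$session_id
  a <- all_s %in% ai
  m <- all_s %in% mod
  out <- list(tp = sum(a & m), fp = sum(a & !m), fn = sum(!a & m),
              tn = sum(!a & !m), n = length(all_s))
  class(out) <- "confusion_counts"
  out
}

#' Build confusion counts from raw cell values
#'
#' @param tp,fp,fn,tn non-negative integer cell counts.
#' @return a `confusion_counts` object.
#' @export
confusion_from_counts <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = tp + fp + fn + tn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("Confusion counts (moderator protocol = benchmark)\n")
  cat(sprintf("  TP %d | FP %d | FN %d | TN %d  (n = %d sessions)\n",
              x$tp, x$fp, x$fn, x$tn, x$n))
  invisible(x)
}

#' Detection metrics from confusion counts
#'
#' Sensitivity = TP/(TP+FN); specificity = TN/(TN+FP); precision =
#' TP/(TP+FP); negative predictive value = TN/(TN+FN); accuracy =
#' (TP+TN)/(TP+FP+FN+TN). Exact fractions are returned alongside
#' 2-decimal percentages (round-half-even) so rounding never compounds. A
#' metric whose denominator is zero is returned as `NA` and named in the
#' `undefined` field rather than silently reported as 0.
#'
#' @param counts a `confusion_counts` object (or compatible list).
#' @return object of class `detection_metrics` with `fraction`, `percent`
#'   (named vectors) and `undefined` (character).
#' @export
detection_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  if (tp + fp + fn + tn == 0) stop("all confusion counts are zero", call. = FALSE)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  frac <- c(sensitivity = ratio(tp, tp + fn),
            specificity = ratio(tn, tn + fp),
            precision = ratio(tp, tp + fp),
            npv = ratio(tn, tn + fn),
            accuracy = (tp + tn) / (tp + fp + fn + tn))
  structure(list(fraction = frac,
                 percent = as_percent(frac),
                 undefined = names(frac)[is.na(frac)],
                 counts = counts),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat("AI flag performance against the moderator benchmark\n")
  for (m in names(x$fraction)) {
    if (is.na(x$fraction[[m]])) {
      cat(sprintf("  %-12s undefined (zero denominator)\n", m))
    } else {
      cat(sprintf("  %-12s %6.2f%%\n", m, x$percent[[m]]))
    }
  }
  invisible(x)
}

new_latency_stats <- function(diffs, p_ai_first = NA_real_) {
  n <- length(diffs)
  structure(list(n = n,
                 mean = if (n) mean(diffs) else NA_real_,
                 sd = if (n > 1) stats::sd(diffs) else if (n == 1) 0 else NA_real_,
                 p_ai_first = p_ai_first,
                 diffs = diffs),
            class = "latency_stats")
}

#' @export
print.latency_stats <- function(x, ...) {
  if (!x$n) {
    cat("latency_stats: no qualifying sessions\n")
    return(invisible(x))
  }
  cat(sprintf("latency over %d sessions: mean %.2f s, sd %.2f s", x$n, x$mean, x$sd))
  if (!is.na(x$p_ai_first)) cat(sprintf(", AI first in %.2f%%", 100 * x$p_ai_first))
  cat("\n")
  invisible(x)
}

#' Moderator follow-up latency after the AI crisis flag
#'
#' Restricted to sessions of the requested SI class that carry both an AI
#' crisis flag (time T1) and a moderator protocol question (time T2).
#' Statistics describe the signed difference T2 - T1 over all such
#' sessions — negative values (moderator first) are included, exactly as a
#' signed latency histogram would show them. `p_ai_first` is the fraction
#' with T2 - T1 > 0.
#'
#' @param corpus a [chat_corpus()].
#' @param si_class `"passive"` or `"active"`.
#' @return a `latency_stats` object (`n = 0` when no session qualifies).
#' @export
flag_latency_stats <- function(corpus, si_class = c("active", "passive")) {
  si_class <- match.arg(si_class)
  s <- corpus$sessions
  f <- corpus$flags
  keep <- s$session_id[s$si_label == si_class]
  ai <- f[f$source == "ai" & f$kind == "crisis_flag" & f$session_id %in% keep, ]
  mod <- f[f$source == "moderator" & f$kind == "protocol_question" &
             f$session_id %in% keep, ]
  # first protocol question per session, first AI flag per session
  ai <- ai[order(ai$session_id, ai$t), ]
  ai <- ai[!duplicated(ai$session_id), ]
  mod <- mod[order(mod$session_id, mod$t), ]
  mod <- mod[!duplicated(mod$session_id), ]
  i <- match(ai$session_id, mod$session_id)
  ok <- !is.na(i)
  d <- mod$t[i[ok]] - ai$t[ok]
  new_latency_stats(d, p_ai_first = if (length(d)) mean(d > 0) else NA_real_)
}

#' Delay from the final crisis-determination question to the referral
#'
#' Over active-SI sessions holding both at least one protocol/safety
#' question and a referral event: time of the referral minus the time of
#' the last question before it was delivered.
#'
#' @param corpus a [chat_corpus()].
#' @return a `latency_stats` object (`p_ai_first` is `NA`; not applicable).
#' @export
referral_latency_stats <- function(corpus) {
  s <- corpus$sessions
  f <- corpus$flags
  keep <- s$session_id[s$si_label == "active"]
  q <- f[f$kind %in% c("protocol_question", "safety_question") &
           f$session_id %in% keep, ]
  r <- f[f$kind == "referral" & f$session_id %in% keep, ]
  if (!nrow(q) || !nrow(r)) return(new_latency_stats(numeric(0)))
  last_q <- tapply(q$t, q$session_id, max)
  r <- r[order(r$session_id, r$t), ]
  r <- r[!duplicated(r$session_id), ]
  i <- match(r$session_id, names(last_q))
  ok <- !is.na(i)
  new_latency_stats(r$t[ok] - as.numeric(last_q)[i[ok]])
}

#' SI prevalence and distribution summary
#'
#' Counts and rates of passive and active SI are reported against two
#' denominators — user visits and chat sessions — because both appear in
#' practice; they are labelled, never mixed. Also reports the
#' passive:active ratio, the exposure rate (fraction of visits occurring in
#' a session with an SI discloser, discloser included), and monthly counts
#' with each month's share of sessions.
#'
#' @param corpus a [chat_corpus()].
#' @return object of class `prevalence_summary`.
#' @export
prevalence_summary <- function(corpus) {
  s <- corpus$sessions
  v <- corpus$visits
  n_sessions <- nrow(s)
  n_visits <- nrow(v)
  n_passive <- sum(s$si_label == "passive")
  n_active <- sum(s$si_label == "active")
  si_sids <- s$session_id[s$si_label != "none"]
  n_exposed_visits <- sum(v$session_id %in% si_sids)
  monthly <- as.data.frame(table(
    month = factor(s$month, levels = 1:12),
    si_label = factor(s$si_label, levels = SI_LABELS)))
  names(monthly)[3] <- "n"
  monthly$month <- as.integer(as.character(monthly$month))
  tot_month <- table(factor(s$month, levels = 1:12))
  monthly$share_of_month <- ifelse(
    as.numeric(tot_month)[monthly$month] > 0,
    monthly$n / as.numeric(tot_month)[monthly$month], NA_real_)
  out <- list(
    n_sessions = n_sessions, n_visits = n_visits,
    counts = c(passive = n_passive, active = n_active),
    visit_rate = c(passive = if (n_visits) n_passive / n_visits else NA_real_,
                   active = if (n_visits) n_active / n_visits else NA_real_),
    session_rate = c(passive = if (n_sessions) n_passive / n_sessions else NA_real_,
                     active = if (n_sessions) n_active / n_sessions else NA_real_),
    exposure_rate = if (n_visits) n_exposed_visits / n_visits else NA_real_,
    n_exposed_visits = n_exposed_visits,
    ratio = if (n_active > 0) n_passive / n_active else NA_real_,
    monthly = monthly)
  out$ratio_label <- if (is.na(out$ratio)) NA_character_ else
    sprintf("%.1f:1", round(out$ratio, 1))
  class(out) <- "prevalence_summary"
  out
}

#' Prevalence arithmetic from raw counts
#'
#' The count-level companion of [prevalence_summary()] for published or
#' externally tabulated totals; returns the same rate/ratio quantities
#' without needing a corpus.
#'
#' @param n_passive,n_active SI visit counts by class.
#' @param n_visits total user visits (rate denominator).
#' @param n_exposed_visits visits occurring in chats with an SI discloser
#'   (discloser included); optional.
#' @return list with `visit_rate` (fractions), `visit_pct` (2-dp percent),
#'   `exposure_rate`/`exposure_pct`, `ratio` and `ratio_label`.
#' @export
prevalence_from_counts <- function(n_passive, n_active, n_visits,
                                   n_exposed_visits = NA) {
  rate <- c(passive = n_passive / n_visits, active = n_active / n_visits)
  exposure <- n_exposed_visits / n_visits
  ratio <- if (n_active > 0) n_passive / n_active else NA_real_
  list(visit_rate = rate, visit_pct = as_percent(rate),
       exposure_rate = exposure, exposure_pct = as_percent(exposure),
       ratio = ratio,
       ratio_label = if (is.na(ratio)) NA_character_ else
         sprintf("%.1f:1", round(ratio, 1)))
}

#' @export
print.prevalence_summary <- function(x, ...) {
  cat(sprintf("SI prevalence over %d visits in %d sessions\n",
              x$n_visits, x$n_sessions))
  cat(sprintf("  passive %d (%.2f%% of visits) | active %d (%.2f%% of visits)\n",
              x$counts[["passive"]], 100 * x$visit_rate[["passive"]],
              x$counts[["active"]], 100 * x$visit_rate[["active"]]))
  if (!is.na(x$ratio)) cat(sprintf("  passive:active ratio %s\n", x$ratio_label))
  cat(sprintf("  exposure: %d visits (%.2f%%) in chats with an SI discloser\n",
              x$n_exposed_visits, 100 * x$exposure_rate))
  invisible(x)
}
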