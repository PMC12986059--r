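# Transcript corpus container, validation, serialization and demographics.
#
# A corpus is columnar: four data frames (sessions, visits, messages, flags).
# Emotion scores live in one integer column per emotion on `messages`; NA
# encodes "no emotion detected" — a 0 score is never stored.

#' Emotion names scored on the 1-10 intensity scale
#' @export
EMOTIONS <- c("despair", "loneliness", "helplessness", "depression", "optimism")

#' Negative emotions (reductions are improvements); optimism is protective.
#' @export
NEGATIVE_EMOTIONS <- c("despair", "loneliness", "helplessness", "depression")

#' User-visit group labels
#' @export
VISIT_GROUPS <- c("passive_si", "active_si", "exposed_non_si", "non_exposed_non_si")

SI_LABELS <- c("none", "passive", "active")
FLAG_KINDS <- c("crisis_flag", "protocol_question", "safety_question", "referral")

#' Construct a chat-transcript corpus
#'
#' Bundles the four record tables of a transcript corpus. Columns beyond the
#' required ones are dropped; types are coerced where unambiguous. Use
#' [validate_corpus()] to check the domain invariants.
#'
#' @param sessions data.frame with columns `session_id`, `month` (1-12),
#'   `topic`, `si_label` (`"none"`, `"passive"`, `"active"`), `si_discloser`
#'   (user id, `NA` when `si_label == "none"`).
#' @param visits data.frame with `session_id`, `user_id`, `group` (one of
#'   [VISIT_GROUPS]) and optional self-reported `gender`, `race`, `age`
#'   (`NA` = not disclosed).
#' @param messages data.frame with `session_id`, `user_id`, `role`
#'   (`"participant"`/`"moderator"`), `index` (0-based order in session),
#'   `t` (seconds since session start), `text`, and one integer column per
#'   emotion in [EMOTIONS] (values 1-10 or `NA`).
#' @param flags data.frame with `session_id`, `source` (`"ai"`/`"moderator"`),
#'   `kind` (one of crisis_flag, protocol_question, safety_question,
#'   referral) and `t` (seconds).
#' @return an object of class `chat_corpus`.
#' @export
chat_corpus <- function(sessions, visits, messages, flags) {
  sessions <- as.data.frame(sessions)[, c("session_id", "month", "topic",
                                          "si_label", "si_discloser")]
  visits <- as.data.frame(visits)[, c("session_id", "user_id", "group",
                                      "gender", "race", "age")]
  messages <- as.data.frame(messages)[, c("session_id", "user_id", "role",
                                          "index", "t", "text", EMOTIONS)]
  flags <- as.data.frame(flags)[, c("session_id", "source", "kind", "t")]
  sessions$month <- as.integer(sessions$month)
  messages$index <- as.integer(messages$index)
  for (e in EMOTIONS) messages[[e]] <- as.integer(messages[[e]])
  visits$age <- as.numeric(visits$age)
  structure(list(sessions = sessions, visits = visits,
                 messages = messages, flags = flags),
            class = "chat_corpus")
}

empty_corpus <- function() {
  chr <- character(0); num <- numeric(0); int <- integer(0)
  msg <- data.frame(session_id = chr, user_id = chr, role = chr,
                    index = int, t = num, text = chr)
  for (e in EMOTIONS) msg[[e]] <- int
  chat_corpus(
    sessions = data.frame(session_id = chr, month = int, topic = chr,
                          si_label = chr, si_discloser = chr),
    visits = data.frame(session_id = chr, user_id = chr, group = chr,
                        gender = chr, race = chr, age = num),
    messages = msg,
    flags = data.frame(session_id = chr, source = chr, kind = chr, t = num))
}

#' @export
print.chat_corpus <- function(x, ...) {
  tab <- table(factor(x$sessions$si_label, levels = SI_LABELS))
  cat("<chat_corpus>\n")
  cat(sprintf("  sessions: %d (passive SI %d, active SI %d)\n",
              nrow(x$sessions), tab[["passive"]], tab[["active"]]))
  cat(sprintf("  user visits: %d | messages: %d | flag events: %d\n",
              nrow(x$visits), nrow(x$messages), nrow(x$flags)))
  invisible(x)
}

# Stable row orders used by write_corpus (byte-identical serialization).
sort_corpus <- function(corpus) {
  s <- corpus$sessions[order(corpus$sessions$session_id), , drop = FALSE]
  v <- corpus$visits[order(corpus$visits$session_id, corpus$visits$user_id), ,
                     drop = FALSE]
  f <- corpus$flags[order(corpus$flags$session_id, corpus$flags$t,
                          corpus$flags$kind, corpus$flags$source), ,
                    drop = FALSE]
  m <- corpus$messages[order(corpus$messages$session_id, corpus$messages$index), ,
                       drop = FALSE]
  rownames(s) <- rownames(v) <- rownames(f) <- rownames(m) <- NULL
  chat_corpus(s, v, m, f)
}

#' Validate a corpus against the domain invariants
#'
#' Reports (rather than raises) violations of the transcript-model
#' invariants: message ordering, score range, SI labelling consistency,
#' flag-event rules, referential integrity between tables, and the
#' analysis-inclusion rule that a session must contain at least
#' `min_messages` messages from some single participant.
#'
#' @param corpus a [chat_corpus()].
#' @param min_messages inclusion rule: minimum number of messages that at
#'   least one participant must have contributed (default 3).
#' @return character vector of human-readable violations; empty when valid.
#' @export
validate_corpus <- function(corpus, min_messages = 3) {
  stopifnot(inherits(corpus, "chat_corpus"))
  bad <- character(0)
  s <- corpus$sessions; v <- corpus$visits; m <- corpus$messages; f <- corpus$flags

  if (anyDuplicated(s$session_id)) {
    bad <- c(bad, "sessions: duplicated session_id")
  }
  if (any(!s$month %in% 1:12)) {
    bad <- c(bad, sprintf("session %s: month outside 1-12",
                          s$session_id[!s$month %in% 1:12]))
  }
  if (any(!s$si_label %in% SI_LABELS)) {
    bad <- c(bad, sprintf("session %s: unknown si_label",
                          s$session_id[!s$si_label %in% SI_LABELS]))
  }
  i <- s$si_label != "none" & is.na(s$si_discloser)
  if (any(i)) bad <- c(bad, sprintf("session %s: si_label set but si_discloser missing",
                                    s$session_id[i]))

  # messages: emotion scores are integers in [1,10]; 0 is never stored
  for (e in EMOTIONS) {
    out <- !is.na(m[[e]]) & (m[[e]] < 1 | m[[e]] > 10)
    if (any(out)) {
      bad <- c(bad, sprintf("session %s message %d: emotions[%s]=%d outside [1,10]",
                            m$session_id[out], m$index[out], e, m[[e]][out]))
    }
  }
  if (any(!m$role %in% c("participant", "moderator"))) {
    bad <- c(bad, "messages: role must be participant or moderator")
  }
  if (any(m$t < 0)) {
    bad <- c(bad, sprintf("session %s: negative message time",
                          unique(m$session_id[m$t < 0])))
  }
  # ordering: t non-decreasing with index within a session
  ord <- order(m$session_id, m$index)
  sid <- m$session_id[ord]; tt <- m$t[ord]; idx <- m$index[ord]
  same <- sid[-1] == sid[-length(sid)]
  if (length(sid) > 1) {
    viol <- same & (diff(tt) < 0)
    if (any(viol)) bad <- c(bad, sprintf("session %s: message times out of order",
                                         unique(sid[-1][viol])))
    gap <- same & (diff(idx) != 1L)
    first <- c(TRUE, !same) & idx != 0L
    if (any(gap) || any(first)) {
      bad <- c(bad, sprintf("session %s: message index not contiguous from 0",
                            unique(c(sid[-1][gap], sid[first]))))
    }
  }

  # inclusion rule: >= min_messages messages from at least one participant
  part <- m[m$role == "participant", c("session_id", "user_id")]
  if (nrow(part)) {
    per_user <- stats::aggregate(list(n = seq_len(nrow(part))), part, FUN = length)
    max_per_session <- tapply(per_user$n, per_user$session_id, max)
    low <- names(max_per_session)[max_per_session < min_messages]
  } else {
    low <- s$session_id
  }
  low <- union(low, setdiff(s$session_id, unique(part$session_id)))
  if (length(low)) {
    bad <- c(bad, sprintf(
      "session %s: no participant contributed at least %d messages (inclusion rule)",
      sort(low), min_messages))
  }

  # flags
  if (nrow(f)) {
    if (any(!f$kind %in% FLAG_KINDS)) bad <- c(bad, "flags: unknown kind")
    ai <- f[f$source == "ai" & f$kind == "crisis_flag", ]
    dup <- unique(ai$session_id[duplicated(ai$session_id)])
    if (length(dup)) bad <- c(bad, sprintf("session %s: more than one AI crisis_flag", dup))
    ref <- f$session_id[f$kind == "referral"]
    lab <- s$si_label[match(ref, s$session_id)]
    if (any(lab != "active", na.rm = TRUE) || anyNA(lab)) {
      bad <- c(bad, sprintf("session %s: referral outside an active-SI session",
                            unique(ref[is.na(lab) | lab != "active"])))
    }
  }

  # referential integrity
  orphan <- setdiff(v$session_id, s$session_id)
  if (length(orphan)) bad <- c(bad, sprintf("visit references unknown session %s", orphan))
  key <- paste(v$session_id, v$user_id)
  mm <- m[m$role == "participant", ]
  mkey <- paste(mm$session_id, mm$user_id)
  loose <- unique(mkey[!mkey %in% key])
  if (length(loose)) bad <- c(bad, sprintf("message user without visit record: %s", loose))
  if (any(!v$group %in% VISIT_GROUPS)) bad <- c(bad, "visits: unknown group label")

  # group-label consistency with the session's SI status
  lab <- s$si_label[match(v$session_id, s$session_id)]
  disc <- s$si_discloser[match(v$session_id, s$session_id)]
  is_disc <- !is.na(disc) & v$user_id == disc
  want <- ifelse(lab == "none", "non_exposed_non_si",
          ifelse(is_disc, ifelse(lab == "active", "active_si", "passive_si"),
                 "exposed_non_si"))
  mis <- which(!is.na(lab) & v$group != want)
  if (length(mis)) {
    bad <- c(bad, sprintf("visit %s/%s: group '%s' inconsistent with session SI status",
                          v$session_id[mis], v$user_id[mis], v$group[mis]))
  }
  bad
}

# ---------------------------------------------------------------------------
# Serialization: UTF-8 JSON-lines, one record per line, a "record" field
# naming the table. Deterministic sorted output (byte-identical for equal
# corpora). A CSV export (one row per message) is provided for interop.

#' Write a corpus to a JSON-lines file
#'
#' Serialization is deterministic: records are emitted in a canonical sort
#' order so equal corpora produce byte-identical files.
#'
#' @param corpus a valid [chat_corpus()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_corpus()] for the inverse; round-trips are exact.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "chat_corpus"))
  corpus <- sort_corpus(corpus)
  con <- file(path, open = "wb")
  on.exit(close(con))
  emit <- function(df, record) {
    if (!nrow(df)) return(invisible())
    df <- cbind(record = record, df)
    jsonlite::stream_out(df, con, digits = 8, verbose = FALSE)
  }
  emit(corpus$sessions, "session")
  emit(corpus$visits, "visit")
  emit(corpus$flags, "flag")
  emit(corpus$messages, "message")
  invisible(path)
}

#' Read a corpus from a JSON-lines file
#'
#' Parses a file written by [write_corpus()] (schema documented in the
#' README), validates it, and returns the corpus. A malformed line raises a
#' parse error naming the line number; invariant violations raise a
#' validation error listing the offending fields.
#'
#' @param path path to a JSON-lines corpus file.
#' @return a validated [chat_corpus()].
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_corpus())
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    recs[[i]] <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                          error = function(e) {
                            stop(sprintf("parse error on line %d of %s: %s",
                                         i, path, conditionMessage(e)),
                                 call. = FALSE)
                          })
    if (is.null(recs[[i]]$record)) {
      stop(sprintf("parse error on line %d of %s: missing 'record' field", i, path),
           call. = FALSE)
    }
  }
  kind <- vapply(recs, function(r) r$record, "")
  pick <- function(k, cols) {
    rows <- recs[kind == k]
    if (!length(rows)) return(NULL)
    out <- lapply(cols, function(cl) {
      vapply(rows, function(r) {
        val <- r[[cl]]
        if (is.null(val)) NA_character_ else as.character(val)
      }, "")
    })
    names(out) <- cols
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  num <- function(df, cols) {
    for (cl in cols) df[[cl]] <- as.numeric(df[[cl]])
    df
  }
  s <- pick("session", c("session_id", "month", "topic", "si_label", "si_discloser"))
  v <- pick("visit", c("session_id", "user_id", "group", "gender", "race", "age"))
  m <- pick("message", c("session_id", "user_id", "role", "index", "t", "text", EMOTIONS))
  f <- pick("flag", c("session_id", "source", "kind", "t"))
  base <- empty_corpus()
  if (is.null(s)) s <- base$sessions else s <- num(s, "month")
  if (is.null(v)) v <- base$visits else v <- num(v, "age")
  if (is.null(m)) m <- base$messages else m <- num(m, c("index", "t", EMOTIONS))
  if (is.null(f)) f <- base$flags else f <- num(f, "t")
  corpus <- chat_corpus(s, v, m, f)
  bad <- validate_corpus(corpus)
  if (length(bad)) {
    stop(sprintf("corpus validation failed (%d violations), e.g.: %s",
                 length(bad), paste(utils::head(bad, 5), collapse = "; ")),
         call. = FALSE)
  }
  sort_corpus(corpus)
}

#' Export a corpus as a flat CSV (one row per message)
#'
#' Session metadata is joined onto every message row; flag events are not
#' included. Intended for interoperability with spreadsheet tools.
#'
#' @inheritParams write_corpus
#' @export
write_corpus_csv <- function(corpus, path) {
  stopifnot(inherits(corpus, "chat_corpus"))
  corpus <- sort_corpus(corpus)
  m <- corpus$messages
  i <- match(m$session_id, corpus$sessions$session_id)
  out <- cbind(m, corpus$sessions[i, c("month", "topic", "si_label"), drop = FALSE])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Summarize self-reported demographics of user visits
#'
#' Category proportions are computed among disclosing visits only; the
#' non-disclosure rate is reported separately per attribute. Age summaries
#' use only visits with age present.
#'
#' @param visits the `visits` table of a corpus (or a compatible data.frame).
#' @param by_group if `TRUE`, return one summary per visit group.
#' @return a list with elements `gender`, `race` (data.frames of category,
#'   n, proportion), `age` (median/mean/sd/n) and `nondisclosure` (per
#'   attribute); or a named list of such summaries when `by_group = TRUE`.
#' @export
summarize_demographics <- function(visits, by_group = FALSE) {
  if (inherits(visits, "chat_corpus")) visits <- visits$visits
  if (by_group) {
    return(lapply(split(visits, visits$group), summarize_demographics))
  }
  cat_summary <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) {
      return(data.frame(category = character(0), n = integer(0),
                        proportion = numeric(0)))
    }
    tab <- sort(table(x), decreasing = TRUE)
    data.frame(category = names(tab), n = as.integer(tab),
               proportion = as.numeric(tab) / length(x), row.names = NULL)
  }
  age <- visits$age[!is.na(visits$age)]
  list(
    gender = cat_summary(visits$gender),
    race = cat_summary(visits$race),
    age = data.frame(median = if (length(age)) stats::median(age) else NA_real_,
                     mean = if (length(age)) mean(age) else NA_real_,
                     sd = if (length(age) > 1) stats::sd(age) else NA_real_,
                     n = length(age)),
    nondisclosure = c(
      gender = mean(is.na(visits$gender)),
      race = mean(is.na(visits$race)),
      age = mean(is.na(visits$age))),
    n_visits = nrow(visits)
  )
}
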