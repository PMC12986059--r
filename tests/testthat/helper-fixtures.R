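# Shared fixtures: a compact hand-built corpus constructor, brute-force
# oracles, and memoised generated corpora reused across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a corpus from a compact per-session spec. Each element of `specs`:
#   list(si_label =, discloser =, topic =, month =,
#        users = list(<uid> = list(t =, despair =, ..., text =)),
#        moderator_t = numeric(), flags = data.frame(source, kind, t))
# Message order (index) follows message time across users.
build_corpus <- function(specs) {
  sess <- list(); vis <- list(); msg <- list(); flg <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    sid <- names(specs)[i] %||% sprintf("S%03d", i)
    if (!nzchar(sid)) sid <- sprintf("S%03d", i)
    si <- sp$si_label %||% "none"
    disc <- sp$discloser %||% NA_character_
    sess[[i]] <- data.frame(session_id = sid, month = sp$month %||% 1L,
                            topic = sp$topic %||% "anxiety", si_label = si,
                            si_discloser = disc, stringsAsFactors = FALSE)
    rows <- list()
    for (uid in names(sp$users)) {
      u <- sp$users[[uid]]
      m <- length(u$t)
      r <- data.frame(session_id = sid, user_id = uid, role = "participant",
                      index = NA_integer_, t = u$t,
                      text = rep_len(u$text %||% "hello there friend", m),
                      stringsAsFactors = FALSE)
      for (e in EMOTIONS) {
        r[[e]] <- if (is.null(u[[e]])) rep(NA_integer_, m) else as.integer(u[[e]])
      }
      rows[[uid]] <- r
      grp <- if (si == "none") "non_exposed_non_si"
             else if (identical(uid, disc)) {
               if (si == "active") "active_si" else "passive_si"
             } else "exposed_non_si"
      vis[[paste(sid, uid)]] <- data.frame(
        session_id = sid, user_id = uid, group = grp,
        gender = sp$gender[[uid]] %||% NA_character_,
        race = NA_character_, age = sp$age[[uid]] %||% NA_real_,
        stringsAsFactors = FALSE)
    }
    if (!is.null(sp$moderator_t)) {
      r <- data.frame(session_id = sid, user_id = paste0(sid, "m"),
                      role = "moderator", index = NA_integer_,
                      t = sp$moderator_t, text = "thanks for sharing",
                      stringsAsFactors = FALSE)
      for (e in EMOTIONS) r[[e]] <- NA_integer_
      rows[["..mod"]] <- r
    }
    sm <- do.call(rbind, rows)
    sm <- sm[order(sm$t), , drop = FALSE]
    sm$index <- seq_len(nrow(sm)) - 1L
    msg[[i]] <- sm
    if (!is.null(sp$flags) && nrow(sp$flags)) {
      f <- sp$flags
      f$session_id <- sid
      flg[[i]] <- f[, c("session_id", "source", "kind", "t")]
    }
  }
  empty <- crisischat:::empty_corpus()
  chat_corpus(do.call(rbind, sess), do.call(rbind, vis), do.call(rbind, msg),
              if (length(flg)) do.call(rbind, flg) else empty$flags)
}

# Three scored messages for one solo participant (meets the inclusion rule).
solo_user <- function(t = c(10, 20, 30), ...) {
  c(list(t = t), list(...))
}

flag_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(source = r[[1]], kind = r[[2]], t = as.numeric(r[[3]]),
               stringsAsFactors = FALSE)
  }))
}

# Brute-force Mann-Whitney U by pair counting (ties get half credit).
brute_U <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
  s
}

# Exact two-sided p by full enumeration of group assignments (small N only).
brute_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  n <- length(pooled)
  idx <- utils::combn(n, na)
  mu <- na * length(b) / 2
  obs <- abs(brute_U(a, b) - mu)
  hits <- 0
  for (j in seq_len(ncol(idx))) {
    aa <- pooled[idx[, j]]
    bb <- pooled[-idx[, j]]
    if (abs(brute_U(aa, bb) - mu) >= obs - 1e-9) hits <- hits + 1
  }
  hits / ncol(idx)
}

# Reference greedy matcher: processes treated units in the given order,
# scanning all unused controls each time (ties -> lowest control id).
greedy_oracle <- function(treated_ids, treated_logit, control_ids,
                          control_logit, caliper, order_idx) {
  used <- rep(FALSE, length(control_ids))
  pairs <- list(); excluded <- character(0)
  for (i in order_idx) {
    free <- which(!used)
    if (!length(free)) { excluded <- c(excluded, treated_ids[i]); next }
    d <- abs(control_logit[free] - treated_logit[i])
    best <- free[order(d, control_ids[free])][1]
    if (abs(control_logit[best] - treated_logit[i]) > caliper) {
      excluded <- c(excluded, treated_ids[i])
    } else {
      used[best] <- TRUE
      pairs[[length(pairs) + 1]] <- c(treated_ids[i], control_ids[best])
    }
  }
  list(pairs = pairs, excluded = excluded)
}

# Memoised generated corpora (built once per test run).
.corpus_cache <- new.env(parent = emptyenv())

cached_corpus <- function(name, maker) {
  if (is.null(.corpus_cache[[name]])) .corpus_cache[[name]] <- maker()
  .corpus_cache[[name]]
}

# Moderate corpus at default rates (phrase mining, idf behaviour).
default_rate_corpus <- function() {
  cached_corpus("default_rate", function() {
    generate_corpus(generator_config(n_sessions = 3000, seed = 101))
  })
}

# SI-enriched multi-user corpus (trajectories, baselines, matching).
enriched_corpus <- function() {
  cached_corpus("enriched", function() {
    generate_corpus(generator_config(
      n_sessions = 3000, seed = 202,
      users_per_session = c("1" = 0.4, "2" = 0.3, "3" = 0.3),
      prevalence = list(passive = 0.25, active = 0.05)))
  })
}

# Large single-user corpus for latency/ordering parameter recovery.
latency_corpus <- function() {
  cached_corpus("latency", function() {
    generate_corpus(generator_config(
      n_sessions = 12000, seed = 303,
      users_per_session = c("1" = 1),
      prevalence = list(passive = 0.45, active = 0.45)))
  })
}
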