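# Synthetic transcript generator.
#
# Produces corpora carrying the statistical structure the downstream analyses
# assume: per-visit SI prevalence, AI/moderator flag agreement, signed flag
# follow-up latencies, referral delays, group-specific emotion trajectories,
# SI phrase lexicons, and partially disclosed demographics. Every draw is
# governed by the config seed, so identical config + seed means identical
# corpora.

# Default per-group, per-emotion begin/end levels of the latent trajectory
# (means and SDs of the starting and ending intensity on the 1-10 scale).
default_emotion_params <- function() {
  tab <- rbind(
    # group, emotion, begin_mean, begin_sd, end_mean, end_sd
    c("passive_si", "despair",      6.82, 1.39, 3.45, 2.26),
    c("passive_si", "loneliness",   7.14, 1.40, 4.34, 2.32),
    c("passive_si", "helplessness", 7.02, 1.40, 4.20, 2.28),
    c("passive_si", "depression",   6.74, 1.33, 3.74, 2.19),
    c("passive_si", "optimism",     2.12, 0.57, 4.09, 2.28),
    # active-SI trajectories are never analysed (crisis referral changes the
    # session's structure); levels mirror the passive group.
    c("active_si", "despair",      6.82, 1.39, 3.45, 2.26),
    c("active_si", "loneliness",   7.14, 1.40, 4.34, 2.32),
    c("active_si", "helplessness", 7.02, 1.40, 4.20, 2.28),
    c("active_si", "depression",   6.74, 1.33, 3.74, 2.19),
    c("active_si", "optimism",     2.12, 0.57, 4.09, 2.28),
    c("exposed_non_si", "despair",      6.63, 1.38, 3.15, 2.05),
    c("exposed_non_si", "loneliness",   7.02, 1.40, 4.02, 2.15),
    c("exposed_non_si", "helplessness", 6.89, 1.38, 3.91, 2.15),
    c("exposed_non_si", "depression",   6.57, 1.29, 3.27, 1.93),
    c("exposed_non_si", "optimism",     2.17, 0.55, 4.25, 2.32),
    c("non_exposed_non_si", "despair",      6.34, 1.23, 3.17, 1.99),
    c("non_exposed_non_si", "loneliness",   6.60, 1.26, 4.00, 2.11),
    c("non_exposed_non_si", "helplessness", 6.48, 1.22, 3.87, 2.06),
    c("non_exposed_non_si", "depression",   6.23, 1.17, 3.29, 1.92),
    c("non_exposed_non_si", "optimism",     2.17, 0.59, 4.02, 2.23))
  data.frame(group = tab[, 1], emotion = tab[, 2],
             begin_mean = as.numeric(tab[, 3]), begin_sd = as.numeric(tab[, 4]),
             end_mean = as.numeric(tab[, 5]), end_sd = as.numeric(tab[, 6]),
             stringsAsFactors = FALSE)
}

# Characteristic SI phrases with corpus frequencies used as sampling weights.
default_lexicons <- function() {
  list(
    active = data.frame(
      phrase = c("just wanna die", "feel like dying", "don't want life",
                 "want kill self", "feel like failure", "want end life",
                 "i'm better dead"),
      weight = c(261, 135, 91, 70, 64, 48, 29), stringsAsFactors = FALSE),
    passive = data.frame(
      phrase = c("just feel lonely", "just wanna disappear",
                 "feel like running away", "just feel worthless",
                 "i'm really scared", "just hate life",
                 "think autism social anxiety", "i'm said i'm ugly"),
      weight = c(428, 193, 186, 151, 137, 122, 83, 69),
      stringsAsFactors = FALSE))
}

# Neutral filler vocabulary. Deliberately large and disjoint from the SI
# lexicon tokens so that within a session individual filler words stay
# low-frequency while injected lexicon tokens recur, keeping the
# term-frequency ranker's task well posed.
filler_vocabulary <- function() {
  c("today", "morning", "evening", "week", "weekend", "month", "year",
    "school", "class", "homework", "teacher", "exam", "grade", "college",
    "work", "job", "boss", "shift", "office", "meeting", "project",
    "friend", "friends", "family", "mom", "dad", "sister", "brother",
    "roommate", "neighbor", "partner", "people", "everyone", "somebody",
    "house", "home", "room", "kitchen", "garden", "street", "town", "city",
    "music", "song", "movie", "show", "book", "story", "game", "phone",
    "computer", "internet", "video", "picture", "photo", "walk", "run",
    "gym", "exercise", "yoga", "sleep", "nap", "dream", "breakfast",
    "lunch", "dinner", "coffee", "tea", "water", "food", "cooking",
    "recipe", "shopping", "store", "market", "money", "budget", "bill",
    "rent", "car", "bus", "train", "trip", "travel", "vacation", "beach",
    "mountain", "park", "weather", "rain", "snow", "sun", "cloud", "wind",
    "season", "spring", "summer", "autumn", "winter", "holiday",
    "birthday", "party", "wedding", "dog", "cat", "pet", "bird", "fish",
    "plant", "tree", "flower", "talk", "talked", "talking", "chat",
    "call", "called", "text", "message", "wrote", "write", "read",
    "reading", "started", "finished", "tried", "trying", "learned",
    "learning", "practice", "playing", "played", "watch", "watched",
    "listen", "listened", "visit", "visited", "helped", "helping",
    "plan", "planning", "decide", "decided", "hoping", "waiting",
    "thinking", "wonder", "wondering", "maybe", "perhaps", "probably",
    "actually", "basically", "honestly", "mostly", "sometimes", "often",
    "always", "never", "yesterday", "tomorrow", "soon", "later", "early",
    "late", "busy", "quiet", "calm", "tired", "sleepy", "awake", "okay",
    "fine", "good", "great", "nice", "cool", "interesting", "boring",
    "funny", "weird", "strange", "normal", "usual", "different", "new",
    "old", "big", "small", "long", "short", "slow", "fast", "warm",
    "cold", "loud", "bright", "dark", "green", "blue", "red", "yellow",
    "lesson", "chapter", "page", "note", "list", "task", "chore",
    "laundry", "dishes", "cleaning", "garage", "closet", "desk", "chair",
    "table", "window", "door", "wall", "floor", "stairs", "garden",
    "bicycle", "skate", "swim", "soccer", "basketball", "tennis",
    "puzzle", "chess", "cards", "painting", "drawing", "craft", "sewing",
    "knitting", "guitar", "piano", "drum", "choir", "band", "concert",
    "ticket", "museum", "library", "cafe", "restaurant", "menu", "order",
    "package", "mail", "letter", "box", "bag", "jacket", "shoes", "hat")
}

default_demographics <- function() {
  list(
    p_disclose = 0.30,
    gender = list(
      active = c(female = 0.6310, male = 0.2758, nonbinary = 0.0931),
      passive = c(female = 0.6467, male = 0.2755, nonbinary = 0.0778),
      none = c(female = 0.6360, male = 0.2929, nonbinary = 0.0711)),
    race = list(
      active = c(white = 0.4793, asian = 0.1515, hispanic_latino = 0.1209,
                 black = 0.1178, amer_indian_ak_native = 0.0598,
                 mena = 0.0477, nh_pacific_islander = 0.0229),
      passive = c(white = 0.4856, asian = 0.1409, hispanic_latino = 0.1340,
                  black = 0.1026, amer_indian_ak_native = 0.0646,
                  mena = 0.0499, nh_pacific_islander = 0.0225),
      none = c(white = 0.4762, asian = 0.1453, hispanic_latino = 0.1348,
               black = 0.0995, amer_indian_ak_native = 0.0713,
               mena = 0.0492, nh_pacific_islander = 0.0237)),
    # age: min + lognormal moment-matched to (mean - min, sd)
    age = list(active = c(mean = 23.10, sd = 12.08),
               passive = c(mean = 24.42, sd = 12.74),
               none = c(mean = 23.90, sd = 11.94),
               min = 13))
}

#' Configuration of the synthetic corpus generator
#'
#' Returns the full generator configuration with every distribution and rate
#' the synthetic corpus is drawn from. Defaults encode the study conditions
#' the analyses are calibrated against: SI prevalence of 1.98% (passive) and
#' 1.21% (active) of user visits, AI flag sensitivity 12602/14401 against the
#' moderator-protocol benchmark with false-positive rate 14735/155401,
#' AI-first flag ordering of 81.26% (active) / 77.52% (passive), moderator
#' follow-up latencies with mean/SD 71.32/89.00 s (active) and
#' 79.87/95.71 s (passive), referral delay 245/557 s, per-group begin/end
#' emotion levels, SI phrase lexicons, and ~30% demographic disclosure.
#'
#' Any component can be overridden by passing a partial list; it is merged
#' into the defaults with [utils::modifyList()].
#'
#' @param n_sessions number of chat sessions to generate.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @param users_per_session named probability vector over session sizes 1-5.
#' @param messages_per_user_mean mean participant messages per visit
#'   (3 + Poisson(mean - 3); minimum 3 so every visit meets the inclusion rule).
#' @param moderator_messages_mean mean moderator messages per session.
#' @param gap_mean mean of the exponential inter-message gap, seconds.
#' @param prevalence list with `passive` and `active` fractions of visits.
#' @param flag_model list: `p_ai_flag_given_si`, `p_ai_flag_given_no_si`,
#'   `p_moderator_flag_given_si`.
#' @param ordering list: `p_ai_first_active`, `p_ai_first_passive`.
#' @param latency list of `c(mean, sd)` (seconds) for `active`, `passive`,
#'   `referral`, plus `moderator_lead` — the magnitude of the moderator's
#'   head start in the minority of sessions where the moderator flags first —
#'   and `safety_gap_mean`, the gap between the protocol and final safety
#'   question in active-SI sessions.
#' @param latency_family `"lognormal"` (moment-matched, default) or
#'   `"truncnorm"` (normal truncated at zero; an alternative shape).
#' @param emotion_params data.frame of per group x emotion begin/end
#'   means/SDs (see `default_emotion_params()`).
#' @param noise_sd per-message noise SD around the latent linear trajectory.
#' @param p_absent probability that a score is not detected (stored as `NA`).
#' @param topics named probability vector over conversation topics.
#' @param lexicons list with `active`/`passive` data.frames of
#'   `phrase`/`weight`, plus filler vocabulary under `filler`.
#' @param demographics disclosure probability and per-class category
#'   distributions (see `default_demographics()`).
#' @param disclosure_message_index the discloser's own-message index (1-based)
#'   at which SI language first appears; lexicon phrases are embedded from
#'   this message on.
#' @param month_weights probability vector over months 1-12.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_sessions = 1000,
                             seed = 1L,
                             users_per_session = c("1" = 0.15, "2" = 0.20,
                                                   "3" = 0.30, "4" = 0.20,
                                                   "5" = 0.15),
                             messages_per_user_mean = 8,
                             moderator_messages_mean = 4,
                             gap_mean = 30,
                             prevalence = list(),
                             flag_model = list(),
                             ordering = list(),
                             latency = list(),
                             latency_family = c("lognormal", "truncnorm"),
                             emotion_params = default_emotion_params(),
                             noise_sd = 0.6,
                             p_absent = 0.25,
                             topics = c(anxiety = 0.20, relationships = 0.18,
                                        family = 0.14, school = 0.12,
                                        work = 0.10, loneliness = 0.10,
                                        grief = 0.08, health = 0.08),
                             lexicons = list(),
                             demographics = list(),
                             disclosure_message_index = 3,
                             month_weights = rep(1 / 12, 12)) {
  prevalence <- utils::modifyList(list(passive = 0.0198, active = 0.0121),
                                  prevalence)
  flag_model <- utils::modifyList(
    list(p_ai_flag_given_si = 12602 / 14401,
         p_ai_flag_given_no_si = 14735 / 155401,
         p_moderator_flag_given_si = 1.0),
    flag_model)
  ordering <- utils::modifyList(
    list(p_ai_first_active = 0.8126, p_ai_first_passive = 0.7752), ordering)
  latency <- utils::modifyList(
    list(active = c(mean = 71.32, sd = 89.00),
         passive = c(mean = 79.87, sd = 95.71),
         referral = c(mean = 245, sd = 557),
         moderator_lead = c(mean = 30, sd = 30),
         safety_gap_mean = 60),
    latency)
  lexicons <- utils::modifyList(
    c(default_lexicons(),
      list(filler = filler_vocabulary(),
           moderator = c("welcome to the chat everyone",
                         "thanks for sharing that",
                         "how is everyone doing today",
                         "that sounds really tough",
                         "take your time there is no rush",
                         "what has helped you before",
                         "we are here with you"))),
    lexicons)
  demographics <- utils::modifyList(default_demographics(), demographics)
  cfg <- structure(list(
    n_sessions = as.integer(n_sessions), seed = as.integer(seed),
    users_per_session = users_per_session,
    messages_per_user_mean = messages_per_user_mean,
    moderator_messages_mean = moderator_messages_mean,
    gap_mean = gap_mean, prevalence = prevalence, flag_model = flag_model,
    ordering = ordering, latency = latency,
    latency_family = match.arg(latency_family),
    emotion_params = emotion_params, noise_sd = noise_sd,
    p_absent = p_absent, topics = topics, lexicons = lexicons,
    demographics = demographics,
    disclosure_message_index = as.integer(disclosure_message_index),
    month_weights = month_weights), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  sessions: %d | seed: %d | users/session: %s\n",
              x$n_sessions, x$seed,
              paste(names(x$users_per_session), collapse = "/")))
  cat(sprintf("  SI prevalence per visit: passive %.4f, active %.4f\n",
              x$prevalence$passive, x$prevalence$active))
  cat(sprintf("  AI flag: sens %.4f, FP rate %.4f | AI-first: %.4f active, %.4f passive\n",
              x$flag_model$p_ai_flag_given_si, x$flag_model$p_ai_flag_given_no_si,
              x$ordering$p_ai_first_active, x$ordering$p_ai_first_passive))
  cat(sprintf("  follow-up latency: active %.2f/%.2f s, passive %.2f/%.2f s; referral %.0f/%.0f s\n",
              x$latency$active[["mean"]], x$latency$active[["sd"]],
              x$latency$passive[["mean"]], x$latency$passive[["sd"]],
              x$latency$referral[["mean"]], x$latency$referral[["sd"]]))
  invisible(x)
}

validate_generator_config <- function(cfg) {
  err <- function(...) stop("invalid generator config: ", sprintf(...), call. = FALSE)
  probs <- c(unlist(cfg$prevalence), unlist(cfg$flag_model), unlist(cfg$ordering),
             cfg$p_absent, cfg$demographics$p_disclose)
  if (any(probs < 0 | probs > 1)) err("a probability lies outside [0, 1]")
  if (abs(sum(cfg$users_per_session) - 1) > 1e-8) err("users_per_session must sum to 1")
  sizes <- as.integer(names(cfg$users_per_session))
  if (any(is.na(sizes)) || any(sizes < 1 | sizes > 5)) {
    err("users_per_session sizes must be 1..5")
  }
  p_si <- cfg$prevalence$passive + cfg$prevalence$active
  if (max(sizes) * p_si > 1) {
    err("max session size x total SI prevalence exceeds 1 (cannot place disclosers)")
  }
  for (k in c("active", "passive", "referral", "moderator_lead")) {
    l <- cfg$latency[[k]]
    if (l[["mean"]] <= 0 || l[["sd"]] < 0) err("latency '%s' needs positive mean, sd >= 0", k)
  }
  ep <- cfg$emotion_params
  if (any(ep$begin_mean < 1 | ep$begin_mean > 10 | ep$end_mean < 1 | ep$end_mean > 10)) {
    err("emotion begin/end means must lie in [1, 10]")
  }
  if (cfg$messages_per_user_mean < 3) err("messages_per_user_mean must be >= 3")
  if (cfg$n_sessions < 0) err("n_sessions must be non-negative")
  # the signed flag-delta calibration must admit a positive-branch variance
  for (cl in c("active", "passive")) {
    fp <- flag_delta_params(cfg, cl)
    if (fp$s_pos2 < -1e-9) {
      err("flag-delta calibration infeasible for class '%s' (reduce moderator_lead)", cl)
    }
  }
  invisible(cfg)
}

# Positive-branch lognormal parameters of the signed flag follow-up delta.
# The overall signed difference T2 - T1 is a two-component mixture:
# +L_pos with probability p (AI first), -L_neg otherwise, calibrated so its
# overall mean and SD equal the configured printed moments.
flag_delta_params <- function(cfg, si_class) {
  p <- if (si_class == "active") cfg$ordering$p_ai_first_active
       else cfg$ordering$p_ai_first_passive
  ov <- cfg$latency[[si_class]]
  lead <- cfg$latency$moderator_lead
  m_neg <- lead[["mean"]]; s_neg <- lead[["sd"]]
  m_pos <- (ov[["mean"]] + (1 - p) * m_neg) / p
  s_pos2 <- (ov[["mean"]]^2 + ov[["sd"]]^2 - (1 - p) * (m_neg^2 + s_neg^2)) / p -
    m_pos^2
  list(p = p, m_pos = m_pos, s_pos2 = s_pos2, m_neg = m_neg, s_neg = s_neg)
}

rpositive <- function(n, mean, sd, family = "lognormal") {
  if (n == 0) return(numeric(0))
  if (sd <= 0) return(rep(mean, n))
  if (family == "lognormal") {
    lp <- lognormal_params(mean, sd)
    stats::rlnorm(n, lp$meanlog, lp$sdlog)
  } else {
    lo <- stats::pnorm(0, mean, sd)
    stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
  }
}

#' Draw latency values from the configured positive distribution
#'
#' Latencies are strictly positive draws from a lognormal whose parameters
#' are moment-matched to the configured arithmetic mean and SD (the printed
#' SDs exceed the means, which rules out an untruncated normal; a
#' zero-truncated normal family is available via `latency_family`).
#'
#' Uses R's global RNG; seed with [set.seed()] for reproducibility.
#'
#' @param kind `"active"`, `"passive"` or `"referral"`.
#' @param config a [generator_config()].
#' @param n number of draws.
#' @return numeric vector of `n` positive latencies in seconds.
#' @export
sample_latency <- function(kind, config, n = 1) {
  kind <- match.arg(kind, c("active", "passive", "referral", "moderator_lead"))
  l <- config$latency[[kind]]
  rpositive(n, l[["mean"]], l[["sd"]], config$latency_family)
}

# Signed follow-up difference T2 - T1 for sessions where both flags exist.
sample_flag_delta <- function(n, si_class, config) {
  fp <- flag_delta_params(config, si_class)
  ai_first <- stats::runif(n) < fp$p
  d <- numeric(n)
  d[ai_first] <- rpositive(sum(ai_first), fp$m_pos, sqrt(max(fp$s_pos2, 0)),
                           config$latency_family)
  d[!ai_first] <- -rpositive(sum(!ai_first), fp$m_neg, fp$s_neg,
                             config$latency_family)
  d
}

# Truncated-normal latent parameters memoised per (mean, sd) pair.
emotion_latent_params <- function(cfg) {
  ep <- cfg$emotion_params
  key <- unique(rbind(data.frame(mean = ep$begin_mean, sd = ep$begin_sd),
                      data.frame(mean = ep$end_mean, sd = ep$end_sd)))
  key$mu <- NA_real_; key$sigma <- NA_real_
  for (i in seq_len(nrow(key))) {
    pp <- truncnorm_params(key$mean[i], key$sd[i], 1, 10)
    key$mu[i] <- pp$mu; key$sigma[i] <- pp$sigma
  }
  key
}

lookup_latent <- function(tbl, mean, sd) {
  i <- match(paste(mean, sd), paste(tbl$mean, tbl$sd))
  list(mu = tbl$mu[i], sigma = tbl$sigma[i])
}

#' Simulate one user's emotion score series
#'
#' Reference (scalar) implementation of the emotion model used by
#' [generate_corpus()]: a latent level moves linearly from a sampled begin
#' level to a sampled end level across the user's messages; each message
#' score is the latent value plus Gaussian noise, rounded to an integer,
#' clamped to \[1, 10\], and dropped (NA) with probability `p_absent`. Begin
#' and end levels are drawn from \[1,10\]-truncated normals moment-matched to
#' the configured group means/SDs.
#'
#' Uses R's global RNG; seed with [set.seed()] for reproducibility.
#'
#' @param group one of [VISIT_GROUPS].
#' @param emotion one of [EMOTIONS].
#' @param m number of messages (>= 1).
#' @param config a [generator_config()].
#' @return integer vector of length `m` with `NA` for absent scores.
#' @export
simulate_emotion_series <- function(group, emotion, m, config) {
  stopifnot(m >= 1)
  group <- match.arg(group, VISIT_GROUPS)
  emotion <- match.arg(emotion, EMOTIONS)
  ep <- config$emotion_params
  row <- ep[ep$group == group & ep$emotion == emotion, ]
  if (!nrow(row)) stop("no emotion parameters for ", group, "/", emotion)
  tbl <- emotion_latent_params(config)
  b <- lookup_latent(tbl, row$begin_mean, row$begin_sd)
  e <- lookup_latent(tbl, row$end_mean, row$end_sd)
  begin <- rtruncnorm(1, b$mu, b$sigma)
  end <- rtruncnorm(1, e$mu, e$sigma)
  frac <- if (m == 1) 0 else (seq_len(m) - 1) / (m - 1)
  latent <- begin + (end - begin) * frac
  score <- as.integer(pmin(10, pmax(1, round(latent + stats::rnorm(m, 0, config$noise_sd)))))
  score[stats::runif(m) < config$p_absent] <- NA_integer_
  score
}

# Paste sampled filler tokens into one string per message.
filler_strings <- function(lengths, vocab) {
  n <- length(lengths)
  if (!n) return(character(0))
  tok <- sample(vocab, sum(lengths), replace = TRUE)
  grp <- factor(rep.int(seq_len(n), lengths), levels = seq_len(n))
  out <- vapply(split(tok, grp), paste, "", collapse = " ")
  names(out) <- NULL
  out
}

#' Generate a synthetic chat corpus
#'
#' Draws a complete corpus (sessions, visits, messages with emotion scores
#' and text, flag events) from a [generator_config()]. Deterministic given
#' the config seed; the caller's RNG state is left untouched.
#'
#' Construction notes: a session of size k is given an SI discloser with
#' probability k x (per-visit prevalence), with the discloser uniform among
#' its k users, so the expected per-visit SI rate equals the configured
#' prevalence exactly while each session has at most one discloser. The AI
#' crisis flag sits at the discloser's first SI-lexicon message; the
#' moderator protocol question follows at a signed offset whose sign honours
#' the configured AI-first probability and whose overall mean/SD equal the
#' configured follow-up latency moments. Active-SI sessions additionally
#' carry a final safety question and a crisis referral.
#'
#' @param config a [generator_config()].
#' @return a valid [chat_corpus()].
#' @export
generate_corpus <- function(config) {
  validate_generator_config(config)
  with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(cfg) {
  n <- cfg$n_sessions
  if (n == 0) return(empty_corpus())
  sizes <- as.integer(names(cfg$users_per_session))

  sid <- sprintf("S%06d", seq_len(n))
  k <- sample(sizes, n, replace = TRUE, prob = cfg$users_per_session)
  month <- sample.int(12, n, replace = TRUE, prob = cfg$month_weights)
  topic <- sample(names(cfg$topics), n, replace = TRUE, prob = cfg$topics)

  # session SI status: P(session passive) = k * per-visit passive prevalence
  u <- stats::runif(n)
  p_act <- k * cfg$prevalence$active
  p_pas <- k * cfg$prevalence$passive
  si <- ifelse(u < p_act, "active", ifelse(u < p_act + p_pas, "passive", "none"))
  disc_num <- ifelse(si == "none", NA_integer_, floor(stats::runif(n) * k) + 1)
  disc_uid <- ifelse(is.na(disc_num), NA_character_, paste0(sid, "u", disc_num))

  sessions <- data.frame(session_id = sid, month = month, topic = topic,
                         si_label = si, si_discloser = disc_uid,
                         stringsAsFactors = FALSE)

  # visits -----------------------------------------------------------------
  vis_sid <- rep(sid, k)
  vis_num <- sequence(k)
  vis_uid <- paste0(vis_sid, "u", vis_num)
  vis_si <- rep(si, k)
  is_disc <- !is.na(rep(disc_num, k)) & vis_num == rep(disc_num, k)
  vis_group <- ifelse(vis_si == "none", "non_exposed_non_si",
               ifelse(is_disc, ifelse(vis_si == "active", "active_si", "passive_si"),
                      "exposed_non_si"))
  nv <- length(vis_uid)

  # demographics (disclosure independent of group; category distributions
  # depend on the user's own SI class)
  demo_class <- ifelse(is_disc, vis_si, "none")
  disclose <- stats::runif(nv) < cfg$demographics$p_disclose
  gender <- race <- rep(NA_character_, nv)
  age <- rep(NA_real_, nv)
  for (cl in c("active", "passive", "none")) {
    i <- which(disclose & demo_class == cl)
    if (!length(i)) next
    gp <- cfg$demographics$gender[[cl]]
    rp <- cfg$demographics$race[[cl]]
    gender[i] <- sample(names(gp), length(i), replace = TRUE, prob = gp)
    race[i] <- sample(names(rp), length(i), replace = TRUE, prob = rp)
    ap <- cfg$demographics$age[[cl]]
    amin <- cfg$demographics$age$min
    age[i] <- amin + round(rpositive(length(i), ap[["mean"]] - amin, ap[["sd"]]))
  }
  visits <- data.frame(session_id = vis_sid, user_id = vis_uid,
                       group = vis_group, gender = gender, race = race,
                       age = age, stringsAsFactors = FALSE)

  # messages ---------------------------------------------------------------
  m_vis <- 3L + stats::rpois(nv, cfg$messages_per_user_mean - 3)
  m_mod <- 1L + stats::rpois(n, max(cfg$moderator_messages_mean - 1, 0))
  vis_of_msg <- c(rep.int(seq_len(nv), m_vis), rep(NA_integer_, sum(m_mod)))
  msg_sid <- c(rep.int(vis_sid, m_vis), rep.int(sid, m_mod))
  msg_uid <- c(rep.int(vis_uid, m_vis), rep.int(paste0(sid, "m"), m_mod))
  msg_role <- rep(c("participant", "moderator"), c(sum(m_vis), sum(m_mod)))
  total <- length(msg_sid)

  # random interleave within each session
  o <- order(msg_sid, stats::runif(total))
  vis_of_msg <- vis_of_msg[o]; msg_sid <- msg_sid[o]
  msg_uid <- msg_uid[o]; msg_role <- msg_role[o]

  idx <- as.integer(stats::ave(seq_len(total), msg_sid, FUN = seq_along)) - 1L
  t <- round(stats::ave(stats::rexp(total, 1 / cfg$gap_mean), msg_sid, FUN = cumsum), 3)
  own_idx <- as.integer(stats::ave(seq_len(total), paste(msg_sid, msg_uid),
                                   FUN = seq_along))

  # emotion scores per visit x emotion
  latent_tbl <- emotion_latent_params(cfg)
  part <- which(msg_role == "participant")
  vp <- vis_of_msg[part]
  frac <- ifelse(m_vis[vp] == 1L, 0, (own_idx[part] - 1) / (m_vis[vp] - 1))
  ep <- cfg$emotion_params
  scores <- list()
  for (e in EMOTIONS) {
    rows <- ep[ep$emotion == e, ]
    gi <- match(vis_group, rows$group)
    bp <- lookup_latent(latent_tbl, rows$begin_mean[gi], rows$begin_sd[gi])
    epar <- lookup_latent(latent_tbl, rows$end_mean[gi], rows$end_sd[gi])
    begin <- rtruncnorm(nv, bp$mu, bp$sigma)
    end <- rtruncnorm(nv, epar$mu, epar$sigma)
    latent <- begin[vp] + (end[vp] - begin[vp]) * frac
    sc <- as.integer(pmin(10, pmax(1, round(latent + stats::rnorm(length(part), 0, cfg$noise_sd)))))
    sc[stats::runif(length(part)) < cfg$p_absent] <- NA_integer_
    col <- rep(NA_integer_, total)
    col[part] <- sc
    scores[[e]] <- col
  }

  # text: filler for everyone; discloser messages from the disclosure index
  # on additionally embed one frequency-weighted lexicon phrase
  text <- rep(NA_character_, total)
  fl <- 4L + stats::rpois(length(part), 3)
  text[part] <- filler_strings(fl, cfg$lexicons$filler)
  mod_rows <- which(msg_role == "moderator")
  text[mod_rows] <- sample(cfg$lexicons$moderator, length(mod_rows), replace = TRUE)

  msg_si <- rep("none", total)
  msg_si[part] <- vis_si[vp]
  # discloser rows: user is the session's discloser
  sess_disc <- disc_uid[match(msg_sid, sid)]
  discl_row <- msg_role == "participant" & !is.na(sess_disc) &
    msg_uid == sess_disc
  si_row <- which(discl_row & own_idx >= cfg$disclosure_message_index)
  if (length(si_row)) {
    cl <- msg_si[si_row]
    phr <- character(length(si_row))
    for (lex_cl in c("active", "passive")) {
      j <- which(cl == lex_cl)
      if (!length(j)) next
      lx <- cfg$lexicons[[lex_cl]]
      phr[j] <- sample(lx$phrase, length(j), replace = TRUE, prob = lx$weight)
    }
    text[si_row] <- paste(text[si_row], phr)
  }

  messages <- data.frame(session_id = msg_sid, user_id = msg_uid,
                         role = msg_role, index = idx, t = t, text = text,
                         stringsAsFactors = FALSE)
  for (e in EMOTIONS) messages[[e]] <- scores[[e]]

  # flag events -------------------------------------------------------------
  flags <- generate_flags(cfg, sid, si, msg_sid, msg_uid, own_idx, t,
                          sess_disc, msg_role)

  chat_corpus(sessions, visits, messages, flags)
}

generate_flags <- function(cfg, sid, si, msg_sid, msg_uid, own_idx, t,
                           sess_disc, msg_role) {
  # disclosure time per SI session: the discloser's first lexicon message
  d_row <- which(msg_role == "participant" & !is.na(sess_disc) &
                   msg_uid == sess_disc & own_idx == cfg$disclosure_message_index)
  d_sid <- msg_sid[d_row]
  d_t <- t[d_row]
  cls <- si[match(d_sid, sid)]
  n_si <- length(d_row)

  out <- list()
  if (n_si) {
    has_ai <- stats::runif(n_si) < cfg$flag_model$p_ai_flag_given_si
    has_mod <- stats::runif(n_si) < cfg$flag_model$p_moderator_flag_given_si
    t2 <- rep(NA_real_, n_si)
    for (cl in c("active", "passive")) {
      i <- which(cls == cl & has_ai)
      if (length(i)) {
        d <- sample_flag_delta(length(i), cl, cfg)
        # the moderator's head start can never precede the session start
        redo <- which(d < 0 & d_t[i] + d <= 0.001)
        while (length(redo)) {
          fp <- flag_delta_params(cfg, cl)
          d[redo] <- -rpositive(length(redo), fp$m_neg, fp$s_neg,
                                cfg$latency_family)
          redo <- redo[d_t[i][redo] + d[redo] <= 0.001]
        }
        t2[i] <- d_t[i] + d
      }
      j <- which(cls == cl & !has_ai)
      if (length(j)) t2[j] <- d_t[j] + sample_latency(cl, cfg, length(j))
    }
    t2 <- round(t2, 3)
    if (any(has_ai)) {
      out$ai <- data.frame(session_id = d_sid[has_ai], source = "ai",
                           kind = "crisis_flag", t = d_t[has_ai],
                           stringsAsFactors = FALSE)
    }
    if (any(has_mod)) {
      out$protocol <- data.frame(session_id = d_sid[has_mod], source = "moderator",
                                 kind = "protocol_question", t = t2[has_mod],
                                 stringsAsFactors = FALSE)
    }
    act <- which(cls == "active" & has_mod)
    if (length(act)) {
      safety_t <- round(t2[act] + stats::rexp(length(act), 1 / cfg$latency$safety_gap_mean), 3)
      ref_t <- round(safety_t + sample_latency("referral", cfg, length(act)), 3)
      out$safety <- data.frame(session_id = d_sid[act], source = "moderator",
                               kind = "safety_question", t = safety_t,
                               stringsAsFactors = FALSE)
      out$ref <- data.frame(session_id = d_sid[act], source = "moderator",
                            kind = "referral", t = ref_t,
                            stringsAsFactors = FALSE)
    }
  }

  # false positives: AI flag in a session with no SI, at a random message
  none_sid <- sid[si == "none"]
  fp_sel <- none_sid[stats::runif(length(none_sid)) < cfg$flag_model$p_ai_flag_given_no_si]
  if (length(fp_sel)) {
    # pick a random message time within each selected session
    cnt <- table(msg_sid)
    starts <- cumsum(c(0, as.numeric(cnt)))  # msg rows are grouped by sorted sid
    names(starts) <- NULL
    sid_sorted <- names(cnt)
    pos <- match(fp_sel, sid_sorted)
    j <- starts[pos] + floor(stats::runif(length(fp_sel)) * as.numeric(cnt)[pos]) + 1
    out$fp <- data.frame(session_id = fp_sel, source = "ai",
                         kind = "crisis_flag", t = t[j],
                         stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(empty_corpus()$flags)
  }
  flags <- do.call(rbind, out)
  rownames(flags) <- NULL
  flags
}
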