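# N-gram phrase extraction, ranking and frequency tables characterizing
# active vs passive SI language.
#
# Tokenization: lowercase, strip punctuation except intra-word apostrophes
# ("don't" stays one token), split on whitespace. Candidates are contiguous
# token windows of 2-5 tokens. The shipped ranker scores a candidate by
# term-frequency cosine similarity to the session context; it is
# deterministic and dependency-free, and any scorer with the same signature
# (an embedding model, say) can be plugged in instead.

tokenize <- function(text) {
  x <- tolower(text)
  x <- gsub("[^a-z0-9' ]+", " ", x)
  x <- gsub("(^|\\s)'+|'+(\\s|$)", " ", x)  # strip quote-like apostrophes
  toks <- strsplit(trimws(gsub("\\s+", " ", x)), " ", fixed = TRUE)[[1]]
  toks[nzchar(toks)]
}

#' Candidate n-grams of a text
#'
#' Lowercased, punctuation-stripped token windows of `n_min` to `n_max`
#' tokens, in order of occurrence (all lengths starting at a position
#' before moving on).
#'
#' @param text a single character string.
#' @param n_min,n_max n-gram length bounds (defaults 2 and 5).
#' @return character vector of n-grams (possibly empty).
#' @export
candidate_ngrams <- function(text, n_min = 2, n_max = 5) {
  toks <- tokenize(text)
  nt <- length(toks)
  if (nt < n_min) return(character(0))
  out <- character(0)
  for (i in seq_len(nt - n_min + 1)) {
    for (n in n_min:min(n_max, nt - i + 1)) {
      out <- c(out, paste(toks[i:(i + n - 1)], collapse = " "))
    }
  }
  out
}

#' Term-frequency cosine ranker
#'
#' Returns a scoring function: `score(phrases, context_tf)` where
#' `context_tf` is a named token-count vector for the session context. A
#' phrase's score is the cosine between its token vector and the context
#' term-frequency vector, optionally with inverse-document-frequency token
#' weights: with `idf` supplied (see [corpus_idf()]), tokens that appear in
#' most sessions (greetings, small talk) are down-weighted and
#' session-distinctive tokens dominate — a dependency-free stand-in for the
#' semantic salience an embedding ranker would provide. Without `idf` the
#' score is the plain term-frequency cosine.
#'
#' @param idf optional named numeric vector of token weights; missing
#'   tokens get weight 1.
#' @return a function `(phrases, context_tf) -> numeric scores`.
#' @export
tf_cosine_ranker <- function(idf = NULL) {
  wt <- function(toks) {
    if (is.null(idf)) return(rep(1, length(toks)))
    w <- idf[toks]
    w[is.na(w)] <- 1
    as.numeric(w)
  }
  function(phrases, context_tf) {
    ctoks <- names(context_tf)
    cw <- wt(ctoks)
    cvec <- cw * as.numeric(context_tf)
    norm_c <- sqrt(sum(cvec^2))
    vapply(phrases, function(p) {
      toks <- unique(strsplit(p, " ", fixed = TRUE)[[1]])
      w <- wt(toks)
      hit <- context_tf[toks]
      hit[is.na(hit)] <- 0
      num <- sum(w^2 * as.numeric(hit))
      den <- sqrt(sum(w^2)) * norm_c
      if (den == 0) 0 else num / den
    }, numeric(1), USE.NAMES = FALSE)
  }
}

context_tf <- function(texts) {
  toks <- unlist(lapply(texts, tokenize), use.names = FALSE)
  if (!length(toks)) return(stats::setNames(integer(0), character(0)))
  table(toks)
}

#' Inverse document frequencies of corpus tokens
#'
#' Smoothed idf over sessions: `log((1 + N) / (1 + df)) + 1`, where `df` is
#' the number of sessions whose participant messages contain the token.
#' Feeding this into [tf_cosine_ranker()] makes phrase ranking favour
#' tokens that distinguish a session from the rest of the corpus.
#'
#' @param corpus a [chat_corpus()].
#' @return named numeric vector of idf weights.
#' @export
corpus_idf <- function(corpus) {
  m <- corpus$messages[corpus$messages$role == "participant", , drop = FALSE]
  toks <- lapply(m$text, function(tx) unique(tokenize(tx)))
  sess <- rep(m$session_id, lengths(toks))
  tok <- unlist(toks, use.names = FALSE)
  df <- table(tok[!duplicated(paste(sess, tok))])
  n <- length(unique(corpus$sessions$session_id))
  w <- log((1 + n) / (1 + as.numeric(df))) + 1
  stats::setNames(w, names(df))
}

#' Rank candidate phrases within each message of a session
#'
#' For every message, candidate 2-5-gram phrases are scored against the
#' session context by the ranker, case-insensitive duplicates are removed
#' (first occurrence kept), and the top `top_k` survive. Tied scores break
#' by first occurrence in the message, so ranking is deterministic given
#' the ranker.
#'
#' @param texts character vector: the messages to rank (e.g. one user's
#'   messages in a session).
#' @param context_texts messages defining the session context (defaults to
#'   `texts`).
#' @param ranker a scorer as returned by [tf_cosine_ranker()].
#' @param top_k phrases kept per message (default 3).
#' @param n_min,n_max candidate n-gram lengths.
#' @return list (one element per message) of ranked character vectors.
#' @export
rank_phrases <- function(texts, context_texts = texts,
                         ranker = tf_cosine_ranker(), top_k = 3,
                         n_min = 2, n_max = 5) {
  ctx <- context_tf(context_texts)
  lapply(texts, function(tx) {
    cand <- candidate_ngrams(tx, n_min, n_max)
    cand <- cand[!duplicated(tolower(cand))]
    if (!length(cand)) return(character(0))
    sc <- ranker(cand, ctx)
    # stable sort: ties keep first-occurrence order
    cand[order(-sc)][seq_len(min(top_k, length(cand)))]
  })
}

#' Phrase frequency table for one SI class
#'
#' Collects the ranked phrases of every SI-discloser message in sessions of
#' the given class, counts them across the corpus, and drops rows below
#' `min_freq` (default 2, i.e. frequency > 1). Rows are sorted by
#' descending frequency, ties alphabetical.
#'
#' @param corpus a [chat_corpus()].
#' @param si_class `"active"` or `"passive"`.
#' @param min_freq minimum count for a row to be kept.
#' @param ranker a phrase scorer; defaults to the idf-weighted
#'   term-frequency cosine ranker built from this corpus.
#' @param top_k,n_min,n_max passed to [rank_phrases()].
#' @return object of class `phrase_table`: data.frame of `phrase`,
#'   `frequency`, with the class in attribute `"si_class"`.
#' @export
phrase_frequency_table <- function(corpus, si_class = c("passive", "active"),
                                   min_freq = 2,
                                   ranker = tf_cosine_ranker(corpus_idf(corpus)),
                                   top_k = 3, n_min = 2, n_max = 5) {
  si_class <- match.arg(si_class)
  s <- corpus$sessions[corpus$sessions$si_label == si_class, , drop = FALSE]
  counts <- new.env(parent = emptyenv())
  m <- corpus$messages
  rows_by_session <- split(seq_len(nrow(m)), m$session_id)
  for (i in seq_len(nrow(s))) {
    sid <- s$session_id[i]
    disc <- s$si_discloser[i]
    sm <- m[rows_by_session[[sid]], , drop = FALSE]
    texts <- sm$text[sm$user_id == disc]
    if (!length(texts)) next
    ranked <- rank_phrases(texts, context_texts = sm$text[sm$role == "participant"],
                           ranker = ranker, top_k = top_k,
                           n_min = n_min, n_max = n_max)
    for (ph in unlist(ranked, use.names = FALSE)) {
      counts[[ph]] <- (if (is.null(counts[[ph]])) 0L else counts[[ph]]) + 1L
    }
  }
  phrases <- ls(counts)
  freq <- vapply(phrases, function(p) counts[[p]], integer(1), USE.NAMES = FALSE)
  keep <- freq >= min_freq
  tab <- data.frame(phrase = phrases[keep], frequency = freq[keep],
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$frequency, tab$phrase), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, si_class = si_class, class = c("phrase_table", "data.frame"))
}

#' @export
print.phrase_table <- function(x, ...) {
  cat(sprintf("Top %s-SI phrases (n-gram frequency analysis)\n",
              attr(x, "si_class")))
  NextMethod()
  invisible(x)
}
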