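#' Trace each message to the origin of its repost chain
#'
#' Follows `parent_id` links to the root post of every message.  Parent links
#' must form a forest; a cycle raises an error naming the ids involved.
#' Messages whose chain leaves the dataset resolve to `NA` (origin unknown).
#'
#' @param messages data.frame with columns `id` and `parent_id` (`NA` for
#'   original posts).
#' @return Character vector of origin message ids aligned with `messages`;
#'   `NA` where the chain dangles out of the dataset.
#' @export
trace_origin <- function(messages) {
  stopifnot(all(c("id", "parent_id") %in% names(messages)))
  id <- as.character(messages$id)
  par <- as.character(messages$parent_id)
  n <- length(id)
  cur <- seq_len(n)                      # current ancestor position per message
  for (step in seq_len(n + 1L)) {
    par_cur <- par[cur]
    nxt <- match(par_cur, id)
    advance <- !is.na(par_cur) & !is.na(nxt)
    if (!any(advance)) {
      # terminal: ancestor with no parent is the root; ancestor whose parent
      # id is absent from the dataset leaves the origin unknown
      return(ifelse(is.na(par_cur), id[cur], NA_character_))
    }
    cur[advance] <- nxt[advance]
  }
  # any chain still advancing after n hops revisits a message: a cycle
  stop_canx("repost chain contains a cycle involving message id(s): ",
            paste(utils::head(unique(id[cur]), 5L), collapse = ", "))
}

#' Label source credibility of messages
#'
#' A message is credible (1) iff the personal account at the origin of its
#' repost chain is platform-verified (institution-endorsed).  Messages whose
#' chain leaves the dataset get credibility 0 with a warning (origin
#' unknown).  Organizational accounts are excluded from communities upstream.
#'
#' @param messages data.frame with `id`, `user`, `parent_id`.
#' @param profiles data.frame with `user_id` and logical `is_verified`.
#' @return Integer vector of 0/1 credibility labels.
#' @export
source_credibility <- function(messages, profiles) {
  root <- trace_origin(messages)
  unknown <- is.na(root)
  if (any(unknown))
    warning(sum(unknown), " message(s) have repost chains leaving the ",
            "dataset; credibility set to 0", call. = FALSE)
  origin_user <- messages$user[match(root, as.character(messages$id))]
  ver <- profiles$is_verified[match(origin_user, profiles$user_id)]
  out <- as.integer(!is.na(ver) & ver)
  out[unknown] <- 0L
  out
}

#' Topic-text similarity of messages
#'
#' Cosine similarity between the mean embedding vector of a message's
#' keywords and the vector of the community topic label, clamped to
#' `[0, 1]`.  Messages with no embeddable tokens score 0 with a warning.
#'
#' @param texts character vector of message texts.
#' @param topic topic label (a word or short phrase).
#' @param embedding a `canx_embedding`.
#' @param stopwords stopword list.
#' @return Numeric vector of similarities in `[0, 1]`.
#' @export
topic_similarity <- function(texts, topic, embedding = hash_embedding(),
                             stopwords = default_stopwords()) {
  n <- length(texts)
  if (n == 0L) return(numeric(0))
  ttoks <- tokenize_text(topic)[[1L]]
  tv <- embed_tokens(embedding, ttoks)
  tv <- tv[!is.na(tv[, 1L]), , drop = FALSE]
  if (!nrow(tv)) stop_canx("embedding does not cover the topic label")
  tvec <- colMeans(tv)
  toks <- tokenize_text(texts)
  msg <- rep.int(seq_len(n), lengths(toks))
  flat <- unlist(toks, use.names = FALSE)
  keep <- !(flat %in% stopwords)
  msg <- msg[keep]; flat <- flat[keep]
  out <- numeric(n)
  if (!length(flat)) {
    warning("no embeddable tokens in any message; similarity 0", call. = FALSE)
    return(out)
  }
  vocab <- unique(flat)
  vm <- embed_tokens(embedding, vocab)
  vm[is.na(vm)] <- 0
  # mean token vector per message, then cosine against the topic vector
  tok_idx <- match(flat, vocab)
  sums <- rowsum(vm[tok_idx, , drop = FALSE], msg)
  rows <- as.integer(rownames(sums))
  cnts <- tabulate(msg, n)[rows]
  mv <- sums / cnts
  num <- as.numeric(mv %*% tvec)
  den <- sqrt(rowSums(mv^2)) * sqrt(sum(tvec^2))
  sim <- ifelse(den > 0, num / den, 0)
  out[rows] <- pmin(1, pmax(0, sim))
  empty <- setdiff(seq_len(n), rows)
  if (length(empty))
    warning(length(empty), " message(s) had no embeddable tokens; ",
            "similarity 0", call. = FALSE)
  out
}

#' Raw readability index
#'
#' The word-list readability formula
#' `4.53 + 0.01*dw - 0.86*ssr - 1.45*log_cwf + 0.02*pp`, applied exactly.
#' Higher values indicate harder text (a difficulty/grade-style index);
#' see [scale_readability()] for the direction used in the knowledge score.
#'
#' @param difficult_words count of tokens absent from the top-N frequency
#'   list.
#' @param simple_sentence_ratio fraction of sentences without a
#'   subordinate/coordinating marker, in `[0, 1]`.
#' @param log_content_word_freq mean log10 lexicon frequency of content
#'   words.
#' @param personal_pronouns count of pronoun-list hits.
#' @return Numeric vector of raw readability values.
#' @examples
#' readability_raw(20, 0.6, 2.0, 3)  # 1.374
#' @export
readability_raw <- function(difficult_words, simple_sentence_ratio,
                            log_content_word_freq, personal_pronouns) {
  stopifnot(all(difficult_words >= 0), all(personal_pronouns >= 0),
            all(simple_sentence_ratio >= 0 & simple_sentence_ratio <= 1))
  4.53 + 0.01 * difficult_words - 0.86 * simple_sentence_ratio -
    1.45 * log_content_word_freq + 0.02 * personal_pronouns
}

#' Extract readability features from message text
#'
#' Token-list approximation of the readability inputs: difficult words are
#' content tokens absent from the top-N entries of the frequency lexicon;
#' the simple-sentence ratio is the fraction of sentences containing no
#' marker from the marker list; content-word frequency is the mean log10
#' lexicon count of content tokens (absent tokens count as frequency 1,
#' i.e. log 0); personal pronouns are pronoun-list hits over raw tokens.
#'
#' @param texts character vector of message texts.
#' @param lexicons a [default_lexicons()] bundle (frequency lexicon, pronoun
#'   and marker lists, stopwords, `top_n`).
#' @return A data.frame with columns `difficult_words`,
#'   `simple_sentence_ratio`, `log_content_word_freq`, `personal_pronouns`.
#'   Empty texts yield all-zero rows (ratio undefined -> 0).
#' @export
readability_features <- function(texts, lexicons = default_lexicons()) {
  n <- length(texts)
  toks <- tokenize_text(texts)
  msg <- rep.int(seq_len(n), lengths(toks))
  flat <- unlist(toks, use.names = FALSE)

  pp <- tabulate(msg[flat %in% lexicons$pronouns], n)

  content <- !(flat %in% lexicons$stopwords)
  cm <- msg[content]; cf <- flat[content]
  topn <- utils::head(lexicons$freq, lexicons$top_n)
  hit <- match(cf, topn$token)
  dw <- tabulate(cm[is.na(hit)], n)
  lf <- log10(ifelse(is.na(hit), 1, topn$count[hit]))
  logcwf <- numeric(n)
  if (length(cm)) {
    s <- rowsum(lf, cm)
    rows <- as.integer(rownames(s))
    logcwf[rows] <- s[, 1L] / tabulate(cm, n)[rows]
  }

  sents <- split_sentences(texts)
  smsg <- rep.int(seq_len(n), lengths(sents))
  sflat <- unlist(sents, use.names = FALSE)
  ssr <- numeric(n)
  if (length(sflat)) {
    stoks <- tokenize_text(sflat)
    simple <- !vapply(stoks, function(v) any(v %in% lexicons$markers), logical(1))
    tot <- tabulate(smsg, n)
    simp <- tabulate(smsg[simple], n)
    ssr[tot > 0] <- simp[tot > 0] / tot[tot > 0]
  }

  data.frame(difficult_words = dw, simple_sentence_ratio = ssr,
             log_content_word_freq = logcwf, personal_pronouns = pp)
}

#' Scale raw readability for the knowledge score
#'
#' The raw index behaves like a difficulty grade, but the knowledge score
#' treats readable text as evidence of declarative knowledge, so before
#' entering the weighted sum the raw index is z-scored within the corpus and
#' negated: higher scaled readability = easier text.  This direction choice
#' is interpretive and deliberately isolated here.
#'
#' @param raw numeric vector of raw readability values.
#' @param center,scale optional fixed centering/scaling (defaults to the
#'   corpus mean and standard deviation of `raw`).
#' @return Scaled readability values (mean 0, higher = more readable).
#' @export
scale_readability <- function(raw, center = mean(raw), scale = stats::sd(raw)) {
  if (!is.finite(scale) || scale == 0) scale <- 1
  -(raw - center) / scale
}

#' Declarative knowledge of a message
#'
#' Weighted sum of the three knowledge components:
#' `DK(m) = a*credibility + b*similarity + c*readability`.
#'
#' @param credibility 0/1 source credibility.
#' @param similarity topic-text similarity in `[0, 1]`.
#' @param readability scaled readability (higher = more readable), see
#'   [scale_readability()].
#' @param weights non-negative weights `c(a, b, c)`; default equal thirds.
#' @return Numeric vector `DK(m)`.
#' @export
dk_message <- function(credibility, similarity, readability,
                       weights = c(1, 1, 1) / 3) {
  if (length(weights) != 3L || any(weights < 0) || any(is.na(weights)))
    stop_canx("weights must be three non-negative numbers (a, b, c)")
  weights[1L] * credibility + weights[2L] * similarity +
    weights[3L] * readability
}

#' Community declarative knowledge per day
#'
#' Cumulative daily sums of per-message knowledge scores: `DK(C, t)` is the
#' sum of `DK(m)` over all messages present in the community at time t
#' (cumulative snapshots matching the contagion series).
#'
#' @param dk numeric vector of per-message `DK(m)` values.
#' @param day integer day index (0-based) per message.
#' @param n_days length of the observation window.
#' @return A data.frame with columns `day` and `DK`.
#' @export
dk_community <- function(dk, day, n_days = max(day) + 1L) {
  stopifnot(length(dk) == length(day))
  if (length(dk) == 0L)
    return(data.frame(day = seq_len(n_days) - 1L, DK = numeric(n_days)))
  stopifnot(all(day >= 0), all(day < n_days))
  per_day <- group_sum(dk, as.integer(day) + 1L, n_days)
  data.frame(day = seq_len(n_days) - 1L, DK = cumsum(per_day))
}
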