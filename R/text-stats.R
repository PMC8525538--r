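# single-pass corpus text statistics
#
# The public operations (message_anchor_sim, readability_features,
# topic_similarity) each tokenize their input; on a corpus of 1e5+ messages
# that repeated scanning dominates the fit.  This internal engine tokenizes
# once, keeping sentence breaks as pseudo-tokens, and derives the anchor
# similarity, readability features, and topic similarity of every message in
# vectorized passes.  Tests assert its results match the public operations.

corpus_text_stats <- function(texts, topic_of_msg, lexicons, embedding) {
  n <- length(texts)
  x <- tolower(texts)
  x <- gsub("#[^#]*#", " ", x)
  x <- gsub("[.!?]+", " \u1f ", x)        # sentence break marker
  x <- gsub("[^a-z0-9'\u1f]+", " ", x)
  toks <- strsplit(trimws(x), " +")
  toks[!nzchar(trimws(x))] <- list(character(0))

  msg <- rep.int(seq_len(n), lengths(toks))
  flat <- unlist(toks, use.names = FALSE)
  is_break <- flat == "\u1f"
  word <- flat[!is_break]
  wmsg <- msg[!is_break]

  # sentence structure: id sentences by cumulative break count within the
  # stream; a sentence exists where it contains at least one word
  sent_id <- cumsum(c(TRUE, is_break[-length(is_break)] |
                        msg[-length(msg)] != msg[-1L]))
  wsent <- sent_id[!is_break]
  sent_msg <- wmsg[!duplicated(wsent)]
  sent_has_marker <- group_max(as.numeric(word %in% lexicons$markers),
                               match(wsent, unique(wsent)),
                               length(unique(wsent)), empty = 0)
  n_sent <- tabulate(sent_msg, n)
  n_simple <- tabulate(sent_msg[sent_has_marker == 0], n)
  ssr <- ifelse(n_sent > 0, n_simple / pmax(n_sent, 1L), 0)

  pp <- tabulate(wmsg[word %in% lexicons$pronouns], n)

  content <- !(word %in% lexicons$stopwords)
  cw <- word[content]; cm <- wmsg[content]
  topn <- utils::head(lexicons$freq, lexicons$top_n)
  hit <- match(cw, topn$token)
  dw <- tabulate(cm[is.na(hit)], n)
  logcwf <- numeric(n)
  if (length(cm)) {
    s <- rowsum(log10(ifelse(is.na(hit), 1, topn$count[hit])), cm)
    rows <- as.integer(rownames(s))
    logcwf[rows] <- s[, 1L] / tabulate(cm, n)[rows]
  }
  read_raw <- readability_raw(dw, ssr, logcwf, pp)

  # anchor similarity: max clamped cosine of any content token to any anchor
  anchor_sim <- numeric(n)
  if (length(cw)) {
    sim_tab <- token_anchor_sim(embedding, cw, lexicons$anchors)
    anchor_sim <- group_max(unname(sim_tab[cw]), cm, n, empty = 0)
  }

  # topic similarity: cosine of the mean content-token vector against each
  # message's community topic vector
  topic_sim <- numeric(n)
  if (length(cw)) {
    vocab <- unique(cw)
    vm <- embed_tokens(embedding, vocab)
    vm[is.na(vm)] <- 0
    sums <- rowsum(vm[match(cw, vocab), , drop = FALSE], cm)
    rows <- as.integer(rownames(sums))
    mv <- sums / tabulate(cm, n)[rows]
    topics <- unique(topic_of_msg)
    tvs <- t(vapply(topics, function(tp) {
      tt <- tokenize_text(tp)[[1L]]
      colMeans(embed_tokens(embedding, tt), na.rm = TRUE)
    }, numeric(ncol(vm))))
    tv <- tvs[match(topic_of_msg[rows], topics), , drop = FALSE]
    num <- rowSums(mv * tv)
    den <- sqrt(rowSums(mv^2)) * sqrt(rowSums(tv^2))
    topic_sim[rows] <- pmin(1, pmax(0, ifelse(den > 0, num / den, 0)))
  }

  list(anchor_sim = anchor_sim, topic_sim = topic_sim,
       features = data.frame(difficult_words = dw,
                             simple_sentence_ratio = ssr,
                             log_content_word_freq = logcwf,
                             personal_pronouns = pp),
       read_raw = read_raw)
}
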