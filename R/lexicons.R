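#' Anxiety anchor lexicon
#'
#' Anchor keywords derived from the wording of the Zung Self-Rating Anxiety
#' Scale items (e.g. "nervous", "afraid").  The topical factor scores a
#' message by the similarity of its keywords to these anchors.
#'
#' @param weights optional named numeric vector of per-word weights; defaults
#'   to 1 for every anchor.
#' @return A named numeric vector (names are the lowercased anchor words).
#' @export
anxiety_anchors <- function(weights = NULL) {
  words <- c("nervous", "afraid", "anxious", "worried", "panic", "tense",
             "uneasy", "fearful", "restless", "dread", "scared", "upset")
  w <- rep(1, length(words))
  names(w) <- words
  if (!is.null(weights)) {
    stopifnot(!is.null(names(weights)))
    w[names(weights)] <- weights
  }
  w
}

#' Default English stopword list
#'
#' Minimal function-word list used by [extract_keywords()] and the corpus
#' scoring path.  Pronouns are included: they carry no topical content, though
#' the readability extractor counts them separately from the raw tokens.
#'
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function() {
  c("a", "an", "the", "is", "are", "was", "were", "be", "been", "am",
    "i", "you", "he", "she", "it", "we", "they", "me", "him", "her",
    "us", "them", "my", "your", "our", "their", "its", "his", "hers",
    "of", "to", "in", "on", "at", "by", "for", "with", "and", "or",
    "but", "so", "if", "then", "than", "as", "that", "this", "these",
    "those", "have", "has", "had", "do", "does", "did", "not", "no",
    "too", "very", "s", "t", "ll", "d", "m", "re", "ve", "life", "it's",
    "life's")
}

#' Personal pronoun list
#'
#' Tokens counted as personal pronouns by the readability feature extractor.
#'
#' @return Character vector.
#' @export
pronoun_list <- function() {
  c("i", "you", "he", "she", "we", "they", "me", "him", "her", "us",
    "them", "my", "your", "our", "their")
}

#' Subordinate/coordinating marker list
#'
#' A sentence containing none of these markers counts as a "simple sentence"
#' for the simple-sentence ratio.  Crude by design: the readability index is a
#' token-list approximation, not a parse.
#'
#' @return Character vector.
#' @export
marker_list <- function() {
  c("because", "although", "though", "while", "since", "unless",
    "whereas", "but", "so", "if", "however", "therefore")
}

#' Default word-frequency lexicon
#'
#' Token -> count table used to decide "difficult words" (tokens absent from
#' the top-N entries) and the content-word log-frequency term of the
#' readability index.  Counts follow a Zipf-like profile over the package's
#' core vocabulary; the generator's "difficult" vocabulary is deliberately
#' absent.
#'
#' @return A data.frame with columns `token` and `count`, ordered by
#'   decreasing count.
#' @export
freq_lexicon <- function() {
  toks <- unique(c(default_stopwords(), pronoun_list(), marker_list(),
                   names(anxiety_anchors()), .canx_vocab$neutral,
                   unlist(.canx_vocab$topic, use.names = FALSE)))
  n <- length(toks)
  data.frame(token = toks,
             count = as.integer(round(1e6 / seq_len(n))),
             stringsAsFactors = FALSE)
}

#' Read a lexicon file
#'
#' One term per line; an optional tab-separated numeric second column is read
#' as a weight/count.
#'
#' @param path file path.
#' @return A named numeric vector if the file has weights, else a character
#'   vector of terms.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop_canx("lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (all(lengths(parts) >= 2L)) {
    w <- as.numeric(vapply(parts, `[[`, "", 2L))
    names(w) <- tolower(vapply(parts, `[[`, "", 1L))
    w
  } else {
    tolower(trimws(lines))
  }
}

#' Bundle the default lexicons
#'
#' Convenience constructor for the lexicon set consumed by [canx()]:
#' anchor weights, stopwords, frequency lexicon, pronouns, and markers.
#'
#' @param top_n how many of the most frequent lexicon entries count as
#'   non-difficult words (default 5000).
#' @return A list with class `canx_lexicons`.
#' @export
default_lexicons <- function(top_n = 5000L) {
  structure(list(anchors = anxiety_anchors(),
                 stopwords = default_stopwords(),
                 freq = freq_lexicon(),
                 pronouns = pronoun_list(),
                 markers = marker_list(),
                 top_n = as.integer(top_n)),
            class = "canx_lexicons")
}

# core vocabulary shared by the generator and the default frequency lexicon
.canx_vocab <- local({
  topic <- list(
    art = c("gallery", "painting", "sculpture", "exhibit", "canvas",
            "artist", "museum", "portrait"),
    education = c("school", "teacher", "exam", "student", "lecture",
                  "homework", "campus", "degree"),
    entertainment = c("concert", "celebrity", "show", "stage", "album",
                      "singer", "festival", "ticket"),
    movies = c("film", "director", "actor", "cinema", "trailer",
               "screen", "premiere", "sequel"),
    public_affairs = c("policy", "government", "citizen", "reform", "vote",
                       "council", "budget", "petition"),
    sports = c("match", "team", "coach", "league", "goal",
               "stadium", "season", "player"))
  neutral <- c("today", "weekend", "work", "home", "friend", "people",
               "time", "day", "news", "city", "food", "music", "photo",
               "weather", "travel", "good", "nice", "plan", "idea", "story",
               "morning", "evening", "online", "share", "read", "watch",
               "talk", "meet", "walk", "play", "enjoy", "start", "finish",
               "week", "month", "year", "thing", "place", "group", "topic")
  difficult <- c("abstruse", "recondite", "perspicacious", "obfuscatory",
                 "sesquipedalian", "tergiversation", "pusillanimous",
                 "grandiloquent", "circumlocution", "antediluvian",
                 "quixotic", "ineffable", "apocryphal", "soporific",
                 "lugubrious", "perfidious", "obstreperous", "truculent",
                 "insouciant", "mendacious")
  list(topic = topic, neutral = neutral, difficult = difficult)
})
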