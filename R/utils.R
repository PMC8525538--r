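# internal helpers shared across modules

clamp01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tokenize message text
#'
#' Lowercases, strips `#...#` hashtag spans and punctuation, and splits on
#' whitespace.  Used by the topical factor, keyword extraction, and the
#' readability feature extractor so that every text-consuming stage sees the
#' same tokens.
#'
#' @param text character vector of raw message texts.
#' @return A list of character vectors, one per input element.
#' @examples
#' tokenize_text("I feel terrible, have too much work to do! #today#")
#' @export
tokenize_text <- function(text) {
  stopifnot(is.character(text))
  x <- tolower(text)
  x <- gsub("#[^#]*#", " ", x)          # hashtag spans delimit topics, not content
  x <- gsub("[^a-z0-9']+", " ", x)
  x <- trimws(x)
  out <- strsplit(x, " +")
  out[x == ""] <- list(character(0))
  out
}

# split text into sentences on terminal punctuation
split_sentences <- function(text) {
  x <- trimws(gsub("#[^#]*#", " ", text))
  s <- strsplit(x, "[.!?]+")
  lapply(s, function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

# max of `x` within groups `g` (integer codes); fast sort-based group max,
# returns vector of length `ngroups` with `empty` where a group has no rows
group_max <- function(x, g, ngroups, empty = NA_real_) {
  out <- rep(empty, ngroups)
  if (length(x) == 0L) return(out)
  o <- order(g, x)                       # last element per group is the max
  g2 <- g[o]
  last <- !duplicated(g2, fromLast = TRUE)
  out[g2[last]] <- x[o][last]
  out
}

# sum/count of `x` within groups; wrapper kept for symmetry with group_max
group_sum <- function(x, g, ngroups) {
  out <- numeric(ngroups)
  if (length(x) == 0L) return(out)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

# evaluate expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# derive a bounded child seed from (seed, index); stays below 2^31
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483587)
}

stop_canx <- function(...) stop(..., call. = FALSE)
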