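#' Word embedding backends
#'
#' The topical factor and the declarative-knowledge similarity both compare
#' word vectors by cosine similarity.  Three interchangeable backends are
#' provided: a deterministic hashed embedding (any token maps to a
#' reproducible pseudo-random unit vector, so exact lexical matches score 1
#' and unrelated tokens score near 0), an explicit fixture embedding built
#' from a matrix, and a reader for the standard text word2vec format.
#'
#' @param dim embedding dimension for the hashed backend.
#' @return An object of class `canx_embedding`.
#' @seealso [read_word2vec()], [fixture_embedding()]
#' @export
hash_embedding <- function(dim = 64L) {
  dim <- as.integer(dim)
  stopifnot(dim >= 2L)
  structure(list(type = "hash", dim = dim, cache = new.env(parent = emptyenv())),
            class = "canx_embedding")
}

#' @rdname hash_embedding
#' @param vectors numeric matrix with one row per token; rownames are tokens.
#' @export
fixture_embedding <- function(vectors) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  rownames(vectors) <- tolower(rownames(vectors))
  structure(list(type = "fixture", dim = ncol(vectors), vectors = vectors),
            class = "canx_embedding")
}

#' Read word vectors in text word2vec format
#'
#' Expects a header line `"n dim"` followed by `token v1 v2 ...` lines.
#'
#' @param path file path.
#' @return An object of class `canx_embedding`.
#' @export
read_word2vec <- function(path) {
  if (!file.exists(path)) stop_canx("word-vector file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1L]), " +")[[1L]])
  if (length(hdr) != 2L || anyNA(hdr))
    stop_canx("malformed word2vec header in ", path)
  body <- strsplit(trimws(lines[-1L]), " +")
  body <- body[lengths(body) == hdr[2L] + 1L]
  if (length(body) != hdr[1L])
    stop_canx("word2vec body of ", path, " does not match header (",
              length(body), " vs ", hdr[1L], " rows)")
  toks <- vapply(body, `[[`, "", 1L)
  mat <- do.call(rbind, lapply(body, function(v) as.numeric(v[-1L])))
  rownames(mat) <- toks
  fixture_embedding(mat)
}

#' @export
print.canx_embedding <- function(x, ...) {
  n <- if (x$type == "fixture") nrow(x$vectors) else NA_integer_
  cat("<canx_embedding> type=", x$type, " dim=", x$dim,
      if (!is.na(n)) paste0(" tokens=", n), "\n", sep = "")
  invisible(x)
}

# deterministic unit vector for one token (hash backend); cached per object
hash_vector <- function(emb, token) {
  hit <- emb$cache[[token]]
  if (!is.null(hit)) return(hit)
  cs <- utf8ToInt(token)
  h1 <- sum(cs * 31^(seq_along(cs) %% 7)) %% 1048573
  h2 <- sum(cs * 131^(seq_along(cs) %% 5)) %% 2147483629
  v <- with_seed((h1 * 2039 + h2) %% 2147483587, stats::rnorm(emb$dim))
  v <- v / sqrt(sum(v^2))
  emb$cache[[token]] <- v
  v
}

#' Look up embedding vectors for tokens
#'
#' @param emb a `canx_embedding`.
#' @param tokens character vector.
#' @return A numeric matrix (one row per token); rows of unknown tokens are NA
#'   for fixture/word2vec backends.  The hashed backend covers every token.
#' @export
embed_tokens <- function(emb, tokens) {
  stopifnot(inherits(emb, "canx_embedding"))
  tokens <- tolower(tokens)
  if (emb$type == "hash") {
    out <- t(vapply(tokens, function(tk) hash_vector(emb, tk),
                    numeric(emb$dim)))
  } else {
    out <- matrix(NA_real_, length(tokens), emb$dim)
    hit <- match(tokens, rownames(emb$vectors))
    ok <- !is.na(hit)
    out[ok, ] <- emb$vectors[hit[ok], , drop = FALSE]
  }
  rownames(out) <- tokens
  out
}

#' Cosine similarity between two vectors
#'
#' @param a,b numeric vectors of equal length.
#' @return Cosine similarity in `[-1, 1]`; 0 if either vector is all-zero.
#' @export
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# for each token, max cosine similarity to any anchor word, clamped to [0,1];
# returns a named numeric vector over unique(tokens)
token_anchor_sim <- function(emb, tokens, anchors) {
  toks <- unique(tolower(tokens))
  if (length(toks) == 0L) return(numeric(0))
  tv <- embed_tokens(emb, toks)
  av <- embed_tokens(emb, names(anchors))
  keep <- !is.na(av[, 1L])
  if (!any(keep)) stop_canx("embedding covers none of the anchor words")
  av <- av[keep, , drop = FALSE]
  aw <- unname(anchors[keep])
  tn <- sqrt(rowSums(tv^2)); an <- sqrt(rowSums(av^2))
  cm <- tv %*% t(av) / outer(pmax(tn, 1e-12), pmax(an, 1e-12))
  cm[is.na(cm)] <- 0                      # unknown tokens contribute nothing
  cm <- sweep(cm, 2L, aw, `*`)
  out <- pmin(1, pmax(0, apply(cm, 1L, max)))
  names(out) <- toks
  out
}
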