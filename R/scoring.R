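#' SAS band levels
#'
#' Ordered severity levels of the Zung Self-Rating Anxiety Scale index:
#' no anxiety (25-49), slight (50-59), medium (60-69), extreme (70-100).
#'
#' @return Character vector of the four band labels, mildest first.
#' @export
sas_bands <- function() c("no", "slight", "medium", "extreme")

#' Band an SAS index score
#'
#' Maps SAS index scores to their severity band.  Bands are half-open on the
#' right, `[25,50) [50,60) [60,70) [70,100]`, so the function is total on
#' `[25, 100]` including non-integer scores.
#'
#' @param score numeric vector of SAS index scores in `[25, 100]`.
#' @return An ordered factor with levels [sas_bands()].
#' @examples
#' band_sas(c(25, 55, 70))
#' @export
band_sas <- function(score) {
  stopifnot(is.numeric(score))
  if (any(is.na(score)) || any(score < 25 | score > 100))
    stop_canx("SAS scores must lie in [25, 100]")
  cut(score, breaks = c(25, 50, 60, 70, 100), labels = sas_bands(),
      right = FALSE, include.lowest = TRUE, ordered_result = TRUE)
}

# encode profile rows into the numeric feature matrix the scorer consumes
profile_features <- function(profiles) {
  req <- c("gender", "age", "education_level", "occupation", "income_band")
  miss <- setdiff(req, names(profiles))
  if (length(miss))
    stop_canx("profile table is missing required feature(s): ",
              paste(miss, collapse = ", "))
  occ <- factor(profiles$occupation, levels = .canx_occupations)
  cbind(female = as.numeric(profiles$gender == "female"),
        age = as.numeric(profiles$age),
        education = as.numeric(profiles$education_level),
        income = as.numeric(profiles$income_band),
        stats::model.matrix(~ occ - 1))
}

.canx_occupations <- c("student", "service", "technical", "managerial",
                       "retired", "other")

#' Train the profile-factor anxiety scorer
#'
#' Fits a single-hidden-layer feed-forward regressor (with skip-layer
#' connections, so linear profile-to-score links are exactly representable)
#' mapping profile features to the SAS index score.  The trained scorer plays
#' the user-factor role: it predicts an SAS-scale anxiety score from a profile
#' without administering the questionnaire.
#'
#' @param profiles data.frame with columns `user_id`, `gender`, `age`,
#'   `education_level`, `occupation`, `income_band` (and optionally more).
#' @param sas data.frame with columns `user_id` and `score` (SAS index).
#' @param hidden hidden-layer width.
#' @param decay weight decay passed to [nnet::nnet()].
#' @param maxit optimizer iteration cap.
#' @param seed integer seed; training is deterministic given the seed.
#' @return An object of class `profile_scorer`.
#' @export
profile_scorer <- function(profiles, sas, hidden = 6L, decay = 1e-4,
                           maxit = 2000L, seed = 1L) {
  hit <- match(sas$user_id, profiles$user_id)
  if (anyNA(hit))
    stop_canx("SAS records reference unknown user ids: ",
              paste(utils::head(sas$user_id[is.na(hit)], 5L), collapse = ", "))
  if (nrow(sas) < 30L)
    stop_canx("need at least 30 linked SAS records to train a scorer")
  y <- as.numeric(sas$score)
  if (stats::sd(y) == 0)
    stop_canx("degenerate training target: all SAS scores identical")
  x <- profile_features(profiles[hit, , drop = FALSE])
  ctr <- colMeans(x)
  scl <- pmax(apply(x, 2L, stats::sd), 1e-8)
  xs <- scale(x, ctr, scl)
  fit <- with_seed(seed,
    nnet::nnet(xs, y / 100, size = hidden, linout = TRUE, skip = TRUE,
               decay = decay, maxit = maxit, trace = FALSE, MaxNWts = 5000L))
  structure(list(net = fit, center = ctr, scale = scl,
                 hidden = hidden, decay = decay, seed = seed,
                 n = nrow(sas)),
            class = "profile_scorer")
}

#' @export
print.profile_scorer <- function(x, ...) {
  cat("Profile anxiety scorer (feed-forward, ", x$hidden,
      " hidden units, skip links)\n", sep = "")
  cat("  trained on ", x$n, " SAS records; predicts SAS index in [25, 100]\n",
      sep = "")
  invisible(x)
}

#' Predict SAS-scale anxiety scores from profiles
#'
#' @param object a [profile_scorer()].
#' @param newdata profile data.frame.
#' @param ... unused.
#' @return Numeric vector of SAS index predictions, clamped to `[25, 100]`.
#' @export
predict.profile_scorer <- function(object, newdata, ...) {
  x <- profile_features(newdata)
  xs <- scale(x, object$center, object$scale)
  pmin(100, pmax(25, as.numeric(stats::predict(object$net, xs)) * 100))
}

#' Normalize an SAS index score onto the unit scale
#'
#' Fixed-bound min-max normalization of the SAS scale: 25 maps to 0,
#' 100 maps to 1.
#'
#' @param score numeric SAS index scores.
#' @return Scores on `[0, 1]`.
#' @export
normalize_sas <- function(score) clamp01((score - 25) / 75)

#' Profile-factor score p for community members
#'
#' Applies a trained scorer and normalizes the SAS-scale predictions by the
#' fixed scale bounds, giving the user-factor component `p` of the initial
#' anxiety score.
#'
#' @inheritParams predict.profile_scorer
#' @param scorer a [profile_scorer()].
#' @param profiles profile data.frame.
#' @return Numeric vector `p` in `[0, 1]`.
#' @export
score_profile <- function(scorer, profiles) {
  stopifnot(inherits(scorer, "profile_scorer"))
  normalize_sas(predict(scorer, profiles))
}

#' Cross-validate the profile scorer
#'
#' K-fold cross-validation: out-of-fold SAS predictions are pooled, banded
#' with [band_sas()], and scored against the observed bands with directional
#' precision/recall (a prediction in a more severe band than observed is a
#' false positive, less severe a false negative).
#'
#' @inheritParams profile_scorer
#' @param folds number of folds (default 3).
#' @param ... passed on to [profile_scorer()].
#' @return A `validation_counts` object (see [precision_recall()]).
#' @export
cv_scorer <- function(profiles, sas, folds = 3L, seed = 1L, ...) {
  folds <- as.integer(folds)
  n <- nrow(sas)
  if (folds < 2L) stop_canx("folds must be >= 2")
  if (folds > n) stop_canx("more folds (", folds, ") than records (", n, ")")
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    sc <- profile_scorer(profiles, sas[tr, , drop = FALSE],
                         seed = child_seed(seed, f), ...)
    hit <- match(sas$user_id[!tr], profiles$user_id)
    pred[!tr] <- predict(sc, profiles[hit, , drop = FALSE])
  }
  precision_recall(band_sas(pred), band_sas(sas$score))
}

#' Extract ranked keywords from a message
#'
#' Deterministic frequency-ranked keyword extraction: tokens are lowercased,
#' stopwords removed, remaining content words ranked by in-message term
#' frequency with ties broken by first occurrence.
#'
#' @param text a single message string.
#' @param k maximum number of keywords (default 5).
#' @param stopwords stopword list.
#' @return Character vector of at most `k` keywords (possibly empty).
#' @examples
#' extract_keywords("I feel terrible, have too much work to do! #today#")
#' @export
extract_keywords <- function(text, k = 5L, stopwords = default_stopwords()) {
  stopifnot(length(text) == 1L)
  toks <- tokenize_text(text)[[1L]]
  toks <- toks[!toks %in% stopwords]
  if (length(toks) == 0L) return(character(0))
  tab <- table(factor(toks, levels = unique(toks)))  # unique() keeps first-seen order
  ord <- order(-as.integer(tab), seq_along(tab))
  names(tab)[ord][seq_len(min(k, length(tab)))]
}

# vectorized per-message anchor similarity: for each text, the maximum
# clamped cosine between any content token and any anchor word.  `k` caps the
# keyword set per message; NULL uses all content tokens (the corpus default).
message_anchor_sim <- function(texts, anchors = anxiety_anchors(),
                               embedding = hash_embedding(),
                               stopwords = default_stopwords(), k = NULL) {
  n <- length(texts)
  if (n == 0L) return(numeric(0))
  if (is.null(k)) {
    toks <- tokenize_text(texts)
  } else {
    toks <- lapply(texts, extract_keywords, k = k, stopwords = stopwords)
  }
  msg <- rep.int(seq_len(n), lengths(toks))
  flat <- unlist(toks, use.names = FALSE)
  if (is.null(k) && length(flat)) {
    keep <- !(flat %in% stopwords)
    msg <- msg[keep]
    flat <- flat[keep]
  }
  if (length(flat) == 0L) return(numeric(n))
  sim <- token_anchor_sim(embedding, flat, anchors)
  group_max(unname(sim[flat]), msg, n, empty = 0)
}

#' Topical-factor anxiety score m
#'
#' Scores one member's messages against the anxiety anchor lexicon: per
#' message, the similarity is the maximum clamped cosine between any message
#' keyword and any anchor word; `m` is the mean of the per-message
#' similarities.  Higher similarity to the SAS-derived anchors means higher
#' topical anxiety.
#'
#' @param texts character vector of the member's messages (in-community).
#' @param anchors anchor lexicon, a named weight vector as from
#'   [anxiety_anchors()].
#' @param embedding a `canx_embedding`.
#' @param k keyword cap per message passed to [extract_keywords()]; `NULL`
#'   scores all content tokens.
#' @param stopwords stopword list.
#' @return `m` in `[0, 1]`, or `NA` if the member has no messages ("no
#'   topical evidence"; callers fall back to profile-only weighting).
#' @export
topical_anxiety <- function(texts, anchors = anxiety_anchors(),
                            embedding = hash_embedding(), k = NULL,
                            stopwords = default_stopwords()) {
  if (length(texts) == 0L) return(NA_real_)
  mean(message_anchor_sim(texts, anchors, embedding, stopwords, k = k))
}

#' Initial individual anxiety score
#'
#' Convex combination of the profile factor and the topical factor:
#' `a0 = lambda * p + (1 - lambda) * m`.  Both factors live on `[0, 1]`, so
#' `a0` is bounded by `min(p, m)` and `max(p, m)`.
#'
#' @param p profile-factor score(s) in `[0, 1]`.
#' @param m topical-factor score(s) in `[0, 1]`.
#' @param lambda weight of the profile factor, in `[0, 1]`.
#' @return Numeric vector `a0` in `[0, 1]`.
#' @examples
#' initial_anxiety(0.5, 0.9, lambda = 0.7)  # 0.62
#' @export
initial_anxiety <- function(p, m, lambda = 0.5) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop_canx("lambda must be a single value in [0, 1]")
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE),
            all(m >= 0 & m <= 1, na.rm = TRUE))
  lambda * p + (1 - lambda) * m
}
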