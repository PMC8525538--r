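#' Synthetic corpus configuration
#'
#' Parameters of the seeded community generator.  Defaults are the package's
#' reference study conditions: 100 communities of 50-500 members observed
#' over a 28-day window, a mean influencer share of 0.15, and wired effects
#' of -0.2 (topic proximity on mean latent anxiety), -0.5 (declarative
#' knowledge level on mean latent anxiety, per unit of the knowledge scale),
#' and -0.1 (influencer fraction on the day-to-day mood innovation scale).
#'
#' @param n_communities number of communities.
#' @param size_range integer pair, inclusive bounds on community size
#'   (minimum 3).
#' @param influencer_fraction mean influencer share; per-community shares are
#'   uniform on `[0, 2 * influencer_fraction]`.
#' @param messages_per_user_mean mean messages per member (each member posts
#'   at least one).
#' @param effect_proximity additive shift of community mean latent anxiety
#'   for proximate topics (expected negative).
#' @param effect_dk slope of mean latent anxiety on the community knowledge
#'   level (expected negative).
#' @param effect_influencer_sd slope of the daily mood innovation scale on
#'   the influencer fraction (expected negative).
#' @param noise_sd baseline daily mood innovation scale.
#' @param n_days observation window length (>= 2).
#' @param embedding_dim dimension of the hashed embedding the corpus is
#'   scored with.
#' @param seed integer seed; identical configurations generate byte-identical
#'   corpora.
#' @return A list of class `canx_sim_config`.
#' @export
sim_config <- function(n_communities = 100L, size_range = c(50L, 500L),
                       influencer_fraction = 0.15,
                       messages_per_user_mean = 5,
                       effect_proximity = -0.2, effect_dk = -0.5,
                       effect_influencer_sd = -0.3, noise_sd = 0.12,
                       n_days = 28L, embedding_dim = 64L, seed = 1L) {
  stopifnot(n_communities >= 1L, length(size_range) == 2L,
            size_range[1L] <= size_range[2L])
  if (size_range[1L] < 3L) stop_canx("size_range minimum must be >= 3")
  if (influencer_fraction < 0 || influencer_fraction > 1)
    stop_canx("influencer_fraction must lie in [0, 1]")
  if (messages_per_user_mean <= 0)
    stop_canx("messages_per_user_mean must be positive")
  if (noise_sd <= 0) stop_canx("noise_sd must be positive")
  if (n_days < 2L) stop_canx("n_days must be >= 2")
  structure(list(n_communities = as.integer(n_communities),
                 size_range = as.integer(size_range),
                 influencer_fraction = influencer_fraction,
                 messages_per_user_mean = messages_per_user_mean,
                 effect_proximity = effect_proximity,
                 effect_dk = effect_dk,
                 effect_influencer_sd = effect_influencer_sd,
                 noise_sd = noise_sd, n_days = as.integer(n_days),
                 embedding_dim = as.integer(embedding_dim),
                 seed = as.integer(seed)),
            class = "canx_sim_config")
}

# fixed linear link from profile features to the SAS index; chosen so the
# noiseless link range [27.5, 100] sits inside the instrument scale [25, 100]
sas_link <- function(profiles) {
  occ_coef <- c(student = 1.5, service = 0.5, technical = 0,
                managerial = -0.5, retired = -1, other = 0)
  119.5 +
    1.5 * (profiles$gender == "female") -
    3.5 * profiles$education_level -
    2.8 * profiles$income_band +
    unname(occ_coef[profiles$occupation]) -
    0.9 * profiles$age
}

.canx_locations <- c("north", "south", "east", "west", "coast", "inland",
                     "urban", "rural")

#' Simulate SAS training records
#'
#' Generates a volunteer panel of user profiles and their SAS questionnaire
#' results.  Scores follow a fixed, documented linear link on the profile
#' features (see the methods vignette) plus Gaussian noise; with
#' `noise_sd = 0` the scores are an exact linear function of the features, so
#' a correctly working scorer recovers them perfectly.
#'
#' @param n number of records (>= 30; cross-validation is undefined below
#'   that).
#' @param seed integer seed.
#' @param noise_sd measurement noise on the SAS index, in index points
#'   (default 2, roughly test-retest variability).
#' @return A list with `profiles` and `sas` data.frames (linked by
#'   `user_id`).
#' @export
simulate_sas <- function(n = 360L, seed = 1L, noise_sd = 2) {
  n <- as.integer(n)
  if (n < 30L) stop_canx("need n >= 30 SAS records")
  with_seed(seed, {
    profiles <- data.frame(
      user_id = sprintf("sas_u%04d", seq_len(n)),
      gender = sample(c("female", "male"), n, replace = TRUE),
      age = round(stats::runif(n, 18, 70), 1),
      education_level = sample.int(4L, n, replace = TRUE),
      occupation = sample(.canx_occupations, n, replace = TRUE),
      income_band = sample.int(5L, n, replace = TRUE),
      location = sample(.canx_locations, n, replace = TRUE),
      is_influencer = FALSE, is_verified = FALSE,
      is_organizational = FALSE,
      stringsAsFactors = FALSE)
    score <- sas_link(profiles)
    if (noise_sd > 0)
      score <- pmin(100, pmax(25, score + stats::rnorm(n, 0, noise_sd)))
    sas <- data.frame(user_id = profiles$user_id, score = score,
                      category = band_sas(score), stringsAsFactors = FALSE)
    list(profiles = profiles, sas = sas)
  })
}

# draw profile features consistent with a target latent anxiety: categorical
# features are free draws and age absorbs the residual of the linear link
profiles_from_latent <- function(ids, x, f_influencer) {
  n <- length(ids)
  target <- 25 + 75 * clamp01(x + stats::rnorm(n, 0, 0.08))
  gender <- sample(c("female", "male"), n, replace = TRUE)
  education_level <- sample.int(4L, n, replace = TRUE)
  occupation <- sample(.canx_occupations, n, replace = TRUE)
  income_band <- sample.int(5L, n, replace = TRUE)
  occ_coef <- c(student = 1.5, service = 0.5, technical = 0,
                managerial = -0.5, retired = -1, other = 0)
  rest <- 119.5 + 1.5 * (gender == "female") - 3.5 * education_level -
    2.8 * income_band + unname(occ_coef[occupation])
  age <- round(pmin(70, pmax(18, (rest - target) / 0.9)), 1)
  inf <- stats::runif(n) < f_influencer
  # institution-endorsed verification is a separate notion from the yellow-V
  # influencer flag and is drawn independently of it
  ver <- stats::runif(n) < 0.08
  data.frame(user_id = ids, gender = gender, age = age,
             education_level = education_level, occupation = occupation,
             income_band = income_band,
             location = sample(.canx_locations, n, replace = TRUE),
             is_influencer = inf, is_verified = ver,
             is_organizational = FALSE, stringsAsFactors = FALSE)
}

# directed follower graph: preferential attachment with an in-degree
# multiplier for influencer accounts ("volume of non-reciprocal follows")
pa_edges <- function(ids, is_influencer, m = 3L, boost = 4) {
  n <- length(ids)
  if (n < 2L) return(data.frame(src = character(0), dst = character(0)))
  ord <- sample.int(n)                    # arrival order decouples from id
  indeg <- numeric(n)
  src <- vector("list", n)
  for (t in 2:n) {
    k <- min(t - 1L, m)
    prev <- ord[seq_len(t - 1L)]
    w <- (indeg[prev] + 1) * (1 + boost * is_influencer[prev])
    tgt <- prev[sample.int(t - 1L, k, prob = w)]
    indeg[tgt] <- indeg[tgt] + 1
    src[[t]] <- tgt
  }
  dst <- unlist(src[-1L], use.names = FALSE)
  data.frame(src = rep(ids[ord[-1L]], times = lengths(src[-1L])),
             dst = ids[dst], stringsAsFactors = FALSE)
}

# message text assembly: token category by per-message anchor probability and
# community-level mixture weights; paste vectorized within (length, split)
gen_texts <- function(n_msg, p_anchor, topic_words, d_level) {
  vocab <- .canx_vocab
  anchors <- names(anxiety_anchors())
  pron <- pronoun_list(); mark <- marker_list()
  p_pron <- 0.10
  p_mark <- 0.25 * (0.55 - 0.4 * d_level)
  p_topic <- 0.15 + 0.40 * d_level
  p_diff <- 0.22 - 0.18 * d_level

  L <- sample(6:12, n_msg, replace = TRUE)
  two <- L >= 8 & stats::runif(n_msg) < 0.6
  msg_of <- rep.int(seq_len(n_msg), L)
  ntok <- length(msg_of)
  u1 <- stats::runif(ntok)
  is_anchor <- u1 < p_anchor[msg_of]
  u2 <- stats::runif(ntok)
  cat_idx <- 1L + (u2 >= p_pron) + (u2 >= p_pron + p_mark) +
    (u2 >= p_pron + p_mark + p_topic) +
    (u2 >= p_pron + p_mark + p_topic + p_diff)
  words <- character(ntok)
  pick <- function(set, k) set[sample.int(length(set), k, replace = TRUE)]
  words[is_anchor] <- pick(anchors, sum(is_anchor))
  for (ci in 1:5) {
    sel <- !is_anchor & cat_idx == ci
    if (!any(sel)) next
    set <- switch(ci, pron, mark, topic_words, vocab$difficult, vocab$neutral)
    words[sel] <- pick(set, sum(sel))
  }
  texts <- character(n_msg)
  for (len in unique(L)) {
    for (tw in c(FALSE, TRUE)) {
      rows <- which(L == len & two == tw)
      if (!length(rows)) next
      sel <- msg_of %in% rows
      wm <- matrix(words[sel], nrow = len)   # one column per message
      if (tw) {
        cut_at <- ceiling(len / 2)
        s1 <- do.call(paste, c(split(wm[seq_len(cut_at), , drop = FALSE],
                                     row(wm[seq_len(cut_at), , drop = FALSE])),
                               sep = " "))
        s2 <- do.call(paste, c(split(wm[(cut_at + 1):len, , drop = FALSE],
                                     row(wm[(cut_at + 1):len, , drop = FALSE])),
                               sep = " "))
        texts[rows] <- paste0(s1, ". ", s2, ".")
      } else {
        texts[rows] <- paste0(do.call(paste, c(split(wm, row(wm)), sep = " ")),
                              ".")
      }
    }
  }
  texts
}

#' Simulate one topic-based community
#'
#' Draws a community with known ground truth from the configured study
#' conditions: topic attributes, a latent community mean anxiety carrying the
#' wired proximity and knowledge effects, an AR(1) daily mood whose
#' innovation scale carries the influencer-fluctuation effect, member latent
#' anxiety, profiles consistent with the SAS link, a preferential-attachment
#' follower graph with influencer in-degree boost, and anchor-lexicon message
#' text whose anxiety-word density is logistic in latent anxiety.
#'
#' @param config a [sim_config()].
#' @param index community index (drives the per-community seed).
#' @return A list with `profiles`, `messages`, `edges`, `community` (one
#'   metadata row), and `truth` (one ground-truth row).
#' @export
simulate_community <- function(config, index) {
  stopifnot(inherits(config, "canx_sim_config"))
  cid <- sprintf("c%04d", as.integer(index))
  with_seed(child_seed(config$seed, index), {
    n <- if (config$size_range[1L] == config$size_range[2L])
      config$size_range[1L]
    else sample(seq(config$size_range[1L], config$size_range[2L]), 1L)
    field <- sample(names(.canx_vocab$topic), 1L)
    familiarity <- stats::rbinom(1L, 1L, 0.5)
    proximity <- stats::rbinom(1L, 1L, 0.5)
    d_level <- stats::runif(1L)
    f_inf <- stats::runif(1L, 0, min(1, 2 * config$influencer_fraction))
    mu <- min(0.98, max(0.02,
      0.45 + config$effect_proximity * proximity +
        config$effect_dk * (d_level - 0.5) + stats::rnorm(1L, 0, 0.05)))
    sigma <- max(0.02, config$noise_sd + config$effect_influencer_sd * f_inf)

    ids <- sprintf("%s_u%05d", cid, seq_len(n))
    x <- clamp01(mu + stats::rnorm(n, 0, 0.12))
    profiles <- profiles_from_latent(ids, x, f_inf)
    edges <- pa_edges(ids, profiles$is_influencer)

    # AR(1) daily mood; innovations scale with sigma (the wired H3 channel);
    # persistence lets the cumulative topical factor track the mood
    phi <- 0.8
    mood <- numeric(config$n_days)
    mood[1L] <- stats::rnorm(1L, 0, sigma / sqrt(1 - phi^2))
    for (t in seq_len(config$n_days - 1L))
      mood[t + 1L] <- phi * mood[t] + stats::rnorm(1L, 0, sigma)

    n_msg_u <- 1L + stats::rpois(n, max(0, config$messages_per_user_mean - 1))
    # hashtag communities are burst-triggered: every member engages at onset,
    # then posts through the window
    first_day <- rep(0L, n)
    user_of <- rep.int(seq_len(n), n_msg_u)
    day <- first_day[user_of] +
      floor(stats::runif(length(user_of)) *
              (config$n_days - first_day[user_of]))
    day[cumsum(n_msg_u) - n_msg_u + 1L] <- first_day  # first message fixes onset
    ord <- order(day, stats::runif(length(day)))      # arrival order
    user_of <- user_of[ord]; day <- day[ord]
    n_msg <- length(day)

    kind <- sample(c("post", "repost", "comment"), n_msg, replace = TRUE,
                   prob = c(0.55, 0.30, 0.15))
    kind[1L] <- "post"
    is_post <- kind == "post"
    # parents: earlier posts, preferring verified-authored ones in
    # knowledge-rich communities (the credibility-knowledge wiring)
    post_pos <- which(is_post)
    ver_post_pos <- post_pos[profiles$is_verified[user_of[post_pos]]]
    n_posts_before <- cumsum(is_post) - is_post
    n_ver_before <- cumsum(seq_len(n_msg) %in% ver_post_pos) -
      (seq_len(n_msg) %in% ver_post_pos)
    parent <- rep(NA_integer_, n_msg)
    need <- which(!is_post)
    if (length(need)) {
      q <- min(1, 0.15 + 0.6 * d_level)
      use_ver <- stats::runif(length(need)) < q & n_ver_before[need] > 0
      pick_any <- need[!use_ver & n_posts_before[need] > 0]
      pick_ver <- need[use_ver]
      parent[pick_ver] <- ver_post_pos[ceiling(stats::runif(length(pick_ver)) *
                                                 n_ver_before[pick_ver])]
      parent[pick_any] <- post_pos[ceiling(stats::runif(length(pick_any)) *
                                             n_posts_before[pick_any])]
      orphan <- need[is.na(parent[need])]
      kind[orphan] <- "post"             # nothing published yet to echo
    }

    p_anchor <- stats::plogis(-3.5 + 2.5 * (x[user_of] + mood[day + 1L]))
    texts <- gen_texts(n_msg, p_anchor, .canx_vocab$topic[[field]], d_level)
    msg_ids <- sprintf("%s_m%06d", cid, seq_len(n_msg))
    messages <- data.frame(
      id = msg_ids, user = ids[user_of], day = day, text = texts,
      hashtags = sprintf("#%s#", cid), kind = kind,
      parent = ifelse(is.na(parent), NA_character_, msg_ids[parent]),
      stringsAsFactors = FALSE)

    community <- data.frame(
      id = cid, field = field, familiarity = familiarity,
      proximity = proximity, topic = .canx_vocab$topic[[field]][1L],
      n_members = n, stringsAsFactors = FALSE)
    truth <- data.frame(
      community_id = cid, true_mean = mean(x),
      rating = as.character(rate_anxiety(mean(x))),
      dk_level_true = d_level, influencer_fraction = f_inf,
      mood_scale = sigma, stringsAsFactors = FALSE)
    list(profiles = profiles, messages = messages, edges = edges,
         community = community, truth = truth)
  })
}

#' Simulate a corpus of topic-based communities
#'
#' Generates `n_communities` seeded communities and bundles them with their
#' ground truth and a manifest echoing the configuration.  Identical
#' configurations yield byte-identical corpora.
#'
#' @param config a [sim_config()].
#' @return An object of class `canx_corpus`: a list with `profiles`,
#'   `messages`, `edges`, `communities`, `truth`, and `config`.  Users carry
#'   a `community` column linking them to their community.
#' @export
simulate_corpus <- function(config = sim_config()) {
  stopifnot(inherits(config, "canx_sim_config"))
  parts <- lapply(seq_len(config$n_communities),
                  function(i) simulate_community(config, i))
  bind <- function(field) do.call(rbind, lapply(parts, `[[`, field))
  profiles <- bind("profiles")
  communities <- bind("community")
  profiles$community <- rep(communities$id, communities$n_members)
  structure(list(profiles = profiles, messages = bind("messages"),
                 edges = bind("edges"), communities = communities,
                 truth = bind("truth"), config = config),
            class = "canx_corpus")
}

#' @export
print.canx_corpus <- function(x, ...) {
  cat("<canx_corpus> ", nrow(x$communities), " communities, ",
      nrow(x$profiles), " users, ", nrow(x$messages), " messages, ",
      x$config$n_days, "-day window (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}
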