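#' Fit the collective anxiety model to a community corpus
#'
#' Runs the full estimation pipeline on every community in the corpus:
#' initial individual anxiety scores (profile factor from a trained
#' [profile_scorer()], topical factor from anchor-lexicon similarity of
#' message text), daily cumulative cascades over the member relation matrix,
#' activation of the summed post-cascade scores into the daily collective
#' anxiety series, per-message declarative-knowledge scoring, and the
#' community features table feeding the hypothesis battery (see
#' [summary.canx()]).
#'
#' Without a scorer the profile factor is unavailable and the topical factor
#' alone is used (equivalent to `lambda = 0`); members without messages on a
#' given day have no topical evidence yet and enter the cascade only once
#' active.
#'
#' @param corpus a `canx_corpus` from [simulate_corpus()] or [read_corpus()].
#' @param scorer optional [profile_scorer()].
#' @param params a [contagion_params()]; `K = NULL` resolves per community to
#'   `min(diameter, 6)`.
#' @param dk_weights weights `c(a, b, c)` of credibility, similarity and
#'   readability in the knowledge score.
#' @param embedding a `canx_embedding`; defaults to a hashed embedding of the
#'   corpus-configured dimension.
#' @param lexicons a [default_lexicons()] bundle.
#' @param rating_bands rating breaks passed to [rate_anxiety()].
#' @return An object of class `canx` with components `features` (one row per
#'   community), `series` (named list of daily `canx_series`), `dk` (per-day
#'   community knowledge), `params`, and `truth` when the corpus carries
#'   ground truth.
#' @seealso [summary.canx()], [plot.canx()], [fitted.canx()]
#' @export
canx <- function(corpus, scorer = NULL, params = contagion_params(),
                 dk_weights = c(1, 1, 1) / 3, embedding = NULL,
                 lexicons = default_lexicons(),
                 rating_bands = c(0, 0.2, 0.4, 0.6, 0.8, 1)) {
  stopifnot(inherits(corpus, "canx_corpus"))
  if (is.null(embedding)) {
    dim <- if (!is.null(corpus$config)) corpus$config$embedding_dim else 64L
    embedding <- hash_embedding(dim)
  }
  profiles <- corpus$profiles
  keep <- !profiles$is_organizational
  profiles <- profiles[keep, , drop = FALSE]
  messages <- corpus$messages[corpus$messages$user %in% profiles$user_id, ,
                              drop = FALSE]
  names(messages)[names(messages) == "parent"] <- "parent_id"
  comm <- corpus$communities
  n_days <- if (!is.null(corpus$config)) corpus$config$n_days
            else max(messages$day) + 1L

  p_all <- if (!is.null(scorer)) score_profile(scorer, profiles) else NULL

  # corpus-wide per-message quantities, one text pass for the whole corpus
  msg_comm <- profiles$community[match(messages$user, profiles$user_id)]
  ts <- corpus_text_stats(messages$text,
                          comm$topic[match(msg_comm, comm$id)],
                          lexicons, embedding)
  anchor_sim <- ts$anchor_sim
  cred <- source_credibility(messages, profiles)
  read_scaled <- scale_readability(ts$read_raw)
  parent_user <- messages$user[match(messages$parent_id, messages$id)]
  edge_comm <- profiles$community[match(corpus$edges$src, profiles$user_id)]

  nbar <- mean(comm$n_members)
  series <- vector("list", nrow(comm))
  names(series) <- comm$id
  dk_series <- vector("list", nrow(comm))
  rows <- vector("list", nrow(comm))
  for (ci in seq_len(nrow(comm))) {
    cid <- comm$id[ci]
    mi <- which(msg_comm == cid)
    ui <- which(profiles$community == cid)
    members <- profiles$user_id[ui]
    medges <- corpus$edges[which(edge_comm == cid), , drop = FALSE]
    dk_msg <- dk_message(cred[mi], ts$topic_sim[mi], read_scaled[mi],
                         dk_weights)
    dk_series[[ci]] <- dk_community(dk_msg, messages$day[mi], n_days)

    pe <- data.frame(src = messages$user[mi], dst = parent_user[mi],
                     day = messages$day[mi], stringsAsFactors = FALSE)
    pe <- pe[!is.na(pe$dst), , drop = FALSE]
    all_edges <- rbind(medges, pe[c("src", "dst")])
    gm <- graph_metrics(members, all_edges)
    pr <- params
    if (is.null(pr$K)) pr$K <- min(gm$diameter, 6L)

    ser <- daily_series(members,
                        p = if (is.null(p_all)) NULL else p_all[ui],
                        msg_user = messages$user[mi],
                        msg_day = messages$day[mi],
                        msg_sim = anchor_sim[mi],
                        edges = medges, parent_edges = pe,
                        n_days = n_days, params = pr, nbar = nbar)
    series[[ci]] <- ser
    pol <- polarization(ser)
    rows[[ci]] <- data.frame(
      community_id = cid,
      familiarity = comm$familiarity[ci], proximity = comm$proximity[ci],
      dk_level = mean(dk_msg),
      influencer_ratio = influencer_ratio(profiles[ui, , drop = FALSE]),
      n_posts = sum(messages$kind[mi] == "post"),
      n_comments = sum(messages$kind[mi] == "comment"),
      n_members = length(members),
      interaction_frequency = interaction_frequency(messages$kind[mi],
                                                    length(members), n_days),
      edge_density = gm$edge_density, diameter = gm$diameter,
      avg_collective_anxiety = mean(ser$A),
      anxiety_sd = pol$fluctuation,
      trend_slope = pol$trend_slope, polarized = pol$polarized,
      stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, rows)
  features$rating <- rate_anxiety(features$avg_collective_anxiety,
                                  rating_bands)
  names(dk_series) <- comm$id
  structure(list(features = features, series = series, dk = dk_series,
                 params = params, dk_weights = dk_weights, nbar = nbar,
                 n_days = n_days, used_scorer = !is.null(scorer),
                 truth = corpus$truth, call = match.call()),
            class = "canx")
}

#' @export
print.canx <- function(x, ...) {
  cat("Collective anxiety fit: ", nrow(x$features), " communities, ",
      x$n_days, "-day window\n", sep = "")
  cat("  initial scores: ",
      if (x$used_scorer) "profile + topical factors" else
        "topical factor only (no profile scorer)", "\n", sep = "")
  cat("  mean A(C) = ", format(mean(x$features$avg_collective_anxiety),
                               digits = 4),
      ", polarized: ", sum(x$features$polarized, na.rm = TRUE), "/",
      nrow(x$features), " communities\n", sep = "")
  invisible(x)
}

#' Community features table of a fit
#'
#' @param object a `canx` fit.
#' @param ... unused.
#' @return The per-community features data.frame (topic attributes,
#'   knowledge level, influencer ratio, graph metrics, average collective
#'   anxiety, fluctuation, rating).
#' @export
fitted.canx <- function(object, ...) object$features

#' Hypothesis battery and validation for a collective anxiety fit
#'
#' Runs the analyses linking community traits to collective anxiety:
#' H1a/H1b Pearson correlations of average collective anxiety with topic
#' familiarity and proximity, H2 least-squares regression on the
#' declarative-knowledge level, H3 Spearman correlation of the influencer
#' ratio with anxiety fluctuation, and the ten-predictor regression.  When
#' the corpus carried ground truth, model ratings are validated against the
#' true ratings with directional precision/recall.
#'
#' @param object a `canx` fit.
#' @param ... unused.
#' @return An object of class `summary.canx`.
#' @export
summary.canx <- function(object, ...) {
  ft <- object$features
  out <- list(h1 = test_h1(ft), h2 = test_h2(ft), h3 = test_h3(ft),
              regression = anxiety_regression(ft),
              polarized_share = mean(ft$polarized, na.rm = TRUE),
              n_communities = nrow(ft))
  if (!is.null(object$truth)) {
    tr <- object$truth[match(ft$community_id, object$truth$community_id), ]
    out$validation <- precision_recall(
      ft$rating,
      factor(tr$rating, levels = anxiety_levels(), ordered = TRUE))
  }
  class(out) <- "summary.canx"
  out
}

#' @export
print.summary.canx <- function(x, ...) {
  cat("Hypothesis battery over", x$n_communities, "communities\n")
  f <- function(s, label) {
    if (is.na(s$estimate))
      cat(sprintf("  %-28s NA (%s)\n", label, s$note %||% "undefined"))
    else
      cat(sprintf("  %-28s %8.3f   p = %.4g\n", label, s$estimate, s$p))
  }
  f(x$h1$familiarity, "H1a familiarity (r)")
  f(x$h1$proximity, "H1b proximity (r)")
  f(x$h2, "H2 knowledge (slope)")
  if (!is.na(x$h2$estimate))
    cat(sprintf("  %-28s R^2 = %.3f, F = %.2f\n", "", x$h2$r_squared, x$h2$F))
  f(x$h3, "H3 influencer ratio (rho)")
  cat(sprintf("  polarized share: %.2f\n", x$polarized_share))
  cat("\nRegression of average collective anxiety:\n")
  reg <- x$regression
  for (i in seq_len(nrow(reg)))
    cat(sprintf("  %-24s beta = %10.3g  t = %7.2f  p = %.4g\n",
                reg$predictor[i], reg$beta[i], reg$t[i], reg$p[i]))
  if (!is.null(x$validation)) {
    cat("\nValidation against ground-truth ratings:\n")
    print(x$validation)
  }
  invisible(x)
}

#' Plot daily collective anxiety series
#'
#' Spaghetti plot of the daily `A(C)` series, one line per community.
#'
#' @param x a `canx` fit.
#' @param max_lines cap on the number of communities drawn.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.canx <- function(x, max_lines = 30L, ...) {
  ser <- x$series[seq_len(min(length(x$series), max_lines))]
  days <- seq_len(x$n_days) - 1L
  M <- vapply(ser, function(s) {
    v <- rep(NA_real_, x$n_days)
    v[s$day + 1L] <- s$A
    v
  }, numeric(x$n_days))
  graphics::matplot(days, M, type = "l", lty = 1,
                    col = grDevices::adjustcolor("steelblue", 0.5),
                    xlab = "day", ylab = "collective anxiety A(C)", ...)
  invisible(x)
}
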