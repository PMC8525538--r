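test_that("repost chains resolve to their origin post", {
  msgs <- data.frame(id = c("m1", "m2", "m3", "m4"),
                     parent_id = c(NA, "m1", "m2", NA),
                     stringsAsFactors = FALSE)
  expect_equal(trace_origin(msgs), c("m1", "m1", "m1", "m4"))
  # chain leaving the dataset: origin unknown
  dangling <- data.frame(id = c("m1", "m2"), parent_id = c("gone", "m1"))
  expect_equal(trace_origin(dangling), c(NA_character_, NA_character_))
  # cycle
  cyc <- data.frame(id = c("m1", "m2"), parent_id = c("m2", "m1"))
  expect_error(trace_origin(cyc), "cycle")
})

test_that("source credibility is the verification of the chain origin", {
  profs <- data.frame(user_id = c("ua", "ub"),
                      is_verified = c(TRUE, FALSE))
  msgs <- data.frame(id = c("m1", "m2", "m3"),
                     user = c("ua", "ub", "ub"),
                     parent_id = c(NA, "m1", NA),
                     stringsAsFactors = FALSE)
  expect_equal(source_credibility(msgs, profs), c(1L, 1L, 0L))
  # dangling chain: credibility 0 with a warning
  msgs2 <- data.frame(id = "m9", user = "ua", parent_id = "outside",
                      stringsAsFactors = FALSE)
  expect_warning(cr <- source_credibility(msgs2, profs), "leaving")
  expect_equal(cr, 0L)
})

test_that("topic similarity is the clamped cosine to the topic label", {
  emb <- fixture_embedding(rbind(alpha = c(1, 0, 0),
                                 beta = c(0, 1, 0),
                                 halfway = c(0.5, sqrt(0.75), 0)))
  expect_equal(topic_similarity("alpha alpha", "alpha", emb), 1)
  expect_equal(topic_similarity("beta", "alpha", emb), 0)
  expect_equal(topic_similarity("halfway", "alpha", emb), 0.5,
               tolerance = 1e-9)
  expect_warning(sim <- topic_similarity("the of", "alpha", emb), "token")
  expect_equal(sim, 0)
})

test_that("raw readability applies the printed formula exactly", {
  expect_equal(readability_raw(0, 0, 0, 0), 4.53)
  expect_equal(readability_raw(20, 0.6, 2.0, 3), 1.374, tolerance = 1e-12)
  # per-term linearity at the printed coefficients
  base <- readability_raw(5, 0.5, 1, 2)
  expect_equal(readability_raw(6, 0.5, 1, 2) - base, 0.01)
  expect_equal(readability_raw(5, 1, 1, 2) - base, -0.86 * 0.5)
  expect_equal(readability_raw(5, 0.5, 2, 2) - base, -1.45)
  expect_equal(readability_raw(5, 0.5, 1, 3) - base, 0.02)
})

test_that("readability features match a hand-counted fixture", {
  lex <- default_lexicons()
  # pronoun-only text, all in the frequency list
  f1 <- readability_features("i you we", lex)
  expect_equal(f1$difficult_words, 0)
  expect_equal(f1$personal_pronouns, 3)
  # one sentence without a marker is simple
  f2 <- readability_features("people walk home today", lex)
  expect_equal(f2$simple_sentence_ratio, 1)
  # hand-counted: sentence 1 has marker "because" + difficult "abstruse";
  # sentence 2 simple; content words: because(marker, in lexicon),
  # abstruse(absent), work, home
  f3 <- readability_features("work abstruse because. home!", lex)
  expect_equal(f3$difficult_words, 1)
  expect_equal(f3$simple_sentence_ratio, 0.5)
  expect_equal(f3$personal_pronouns, 0)
  freq <- lex$freq
  counts <- c(freq$count[freq$token == "because"], 1,
              freq$count[freq$token == "work"],
              freq$count[freq$token == "home"])
  expect_equal(f3$log_content_word_freq, mean(log10(counts)),
               tolerance = 1e-12)
  # empty text: zero features
  f4 <- readability_features("", lex)
  expect_equal(unlist(f4), c(difficult_words = 0, simple_sentence_ratio = 0,
                             log_content_word_freq = 0,
                             personal_pronouns = 0))
})

test_that("readability scaling flips the difficulty direction", {
  raw <- c(1, 3, 5)
  sc <- scale_readability(raw)
  expect_true(all(diff(sc) < 0))   # harder text -> lower scaled readability
  expect_equal(mean(sc), 0)
})

test_that("message knowledge is the weighted component sum", {
  expect_equal(dk_message(1, 0, 0, weights = c(1, 0, 0)), 1)
  expect_equal(dk_message(1, 0.6, 0.9), 0.8333333, tolerance = 1e-6)
  expect_equal(dk_message(0, 0, 0), 0)
  expect_error(dk_message(1, 1, 1, weights = c(-1, 1, 1)), "non-negative")
  base <- dk_message(0.5, 0.5, 0.5)
  expect_gt(dk_message(1, 0.5, 0.5), base)
  expect_gt(dk_message(0.5, 0.9, 0.5), base)
  expect_gt(dk_message(0.5, 0.5, 0.9), base)
})

test_that("community knowledge accumulates additively over days", {
  empty <- dk_community(numeric(0), integer(0), n_days = 3)
  expect_equal(empty$DK, c(0, 0, 0))
  two <- dk_community(c(0.2, 0.3), c(0, 0), n_days = 2)
  expect_equal(two$DK, c(0.5, 0.5))
  set.seed(3)
  dk <- runif(20); day <- sample(0:4, 20, replace = TRUE)
  split1 <- 1:8
  total <- dk_community(dk, day, 5)$DK
  parts <- dk_community(dk[split1], day[split1], 5)$DK +
    dk_community(dk[-split1], day[-split1], 5)$DK
  expect_equal(total, parts)
  expect_true(all(diff(total) >= 0))   # cumulative, non-negative scores
})

test_that("fast corpus text engine matches the public operations", {
  corp <- tiny_corpus(seed = 31, n_communities = 3, sizes = c(10, 15),
                      n_days = 5)
  msgs <- corp$messages
  lex <- default_lexicons()
  emb <- hash_embedding(32)
  topic_of <- corp$communities$topic[
    match(corp$profiles$community[match(msgs$user, corp$profiles$user_id)],
          corp$communities$id)]
  st <- canx:::corpus_text_stats(msgs$text, topic_of, lex, emb)

  expect_equal(st$anchor_sim,
               canx:::message_anchor_sim(msgs$text, lex$anchors, emb,
                                         lex$stopwords))
  expect_equal(st$features, readability_features(msgs$text, lex))
  for (tp in unique(topic_of)) {
    sel <- topic_of == tp
    expect_equal(st$topic_sim[sel],
                 topic_similarity(msgs$text[sel], tp, emb, lex$stopwords))
  }
})
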