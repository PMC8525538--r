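test_that("community rating uses half-open quintile bands", {
  expect_equal(as.character(rate_anxiety(0.05)), "no")
  expect_equal(as.character(rate_anxiety(0.95)), "extreme")
  # band edges map to the upper band; the top edge closes the last band
  expect_equal(as.character(rate_anxiety(c(0.2, 0.4, 0.6, 0.8, 1))),
               c("little", "medium", "high", "extreme", "extreme"))
  expect_equal(as.character(rate_anxiety(0)), "no")
  expect_error(rate_anxiety(1.2), "\\[0, 1\\]")
})

test_that("directional precision/recall partitions every rated case", {
  lv <- anxiety_levels()
  truth <- factor(c("medium", "medium", "high"), levels = lv, ordered = TRUE)
  model <- factor(c("medium", "high", "little"), levels = lv, ordered = TRUE)
  vc <- precision_recall(model, truth)
  expect_equal(c(vc$tp, vc$fp, vc$fn), c(1L, 1L, 1L))
  expect_equal(vc$precision, 0.5)
  expect_equal(vc$recall, 0.5)

  same <- precision_recall(truth, truth)
  expect_equal(same$precision, 1)
  expect_equal(same$recall, 1)

  # model uniformly one band above truth: no true positives, no misses below
  above <- precision_recall(pmin(as.integer(truth) + 1L, 5L), truth)
  expect_equal(above$precision, 0)
  expect_true(is.na(above$recall))

  expect_error(precision_recall(model[1:2], truth), "length")
})

test_that("precision/recall equals brute-force confusion counting", {
  set.seed(10)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    truth <- sample.int(5L, n, replace = TRUE)
    model <- sample.int(5L, n, replace = TRUE)
    vc <- precision_recall(model, truth)
    bc <- brute_confusion(model, truth)
    expect_equal(vc$tp, bc$tp)
    expect_equal(vc$fp, bc$fp)
    expect_equal(vc$fn, bc$fn)
    expect_equal(vc$tp + vc$fp + vc$fn, n)
  }
})

test_that("influencer ratio counts yellow-V accounts among personal ones", {
  profs <- data.frame(is_influencer = c(rep(TRUE, 2), rep(FALSE, 8)),
                      is_organizational = FALSE)
  expect_equal(influencer_ratio(profs), 0.2)
  profs$is_influencer <- FALSE
  expect_equal(influencer_ratio(profs), 0)
  profs$is_influencer <- TRUE
  expect_equal(influencer_ratio(profs), 1)
  # organizational accounts leave the denominator
  mixed <- data.frame(is_influencer = c(TRUE, FALSE, FALSE),
                      is_organizational = c(FALSE, FALSE, TRUE))
  expect_equal(influencer_ratio(mixed), 0.5)
  expect_error(influencer_ratio(data.frame(is_influencer = TRUE,
                                           is_organizational = TRUE)),
               "personal")
})

test_that("graph metrics match closed forms and a Floyd-Warshall oracle", {
  m4 <- paste0("u", 1:4)
  complete <- expand.grid(src = m4, dst = m4, stringsAsFactors = FALSE)
  complete <- complete[complete$src < complete$dst, ]
  gm <- graph_metrics(m4, complete)
  expect_equal(gm$edge_density, 1)
  expect_equal(gm$diameter, 1L)

  path <- data.frame(src = m4[1:3], dst = m4[2:4])
  gp <- graph_metrics(m4, path)
  expect_equal(gp$diameter, 3L)
  expect_equal(gp$edge_density, 2 * 3 / (4 * 3))

  set.seed(20)
  for (i in 1:15) {
    n <- sample(4:10, 1)
    adj <- random_relation(n, p = 0.35)
    if (sum(adj) == 0) next
    ids <- paste0("v", seq_len(n))
    idx <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
    ed <- data.frame(src = ids[idx[, 1]], dst = ids[idx[, 2]])
    expect_equal(graph_metrics(ids, ed)$diameter, fw_diameter(adj))
  }
})

test_that("interaction frequency is reposts+comments per member per day", {
  kind <- c("post", "repost", "comment", "repost", "post")
  expect_equal(interaction_frequency(kind, n_members = 3, n_days = 2), 0.5)
  expect_equal(interaction_frequency("post", 5, 7), 0)
})

make_features <- function(n, avg, dk = runif(n), fam = rbinom(n, 1, 0.5),
                          prox = rbinom(n, 1, 0.5)) {
  data.frame(community_id = paste0("c", seq_len(n)), familiarity = fam,
             proximity = prox, dk_level = dk,
             influencer_ratio = runif(n), n_posts = rpois(n, 50),
             n_comments = rpois(n, 20), n_members = sample(20:80, n, TRUE),
             interaction_frequency = runif(n), edge_density = runif(n),
             diameter = sample(2:6, n, TRUE),
             avg_collective_anxiety = avg, anxiety_sd = runif(n, 0.01, 0.1))
}

test_that("H1 Pearson tests recover constructed correlations", {
  set.seed(30)
  prox <- rep(c(0, 1), each = 10)
  ft <- make_features(20, avg = 0.8 - 0.3 * prox, prox = prox)
  # perfectly anticorrelated with proximity
  h1 <- test_h1(ft)
  expect_equal(h1$proximity$estimate, -1)
  expect_lt(h1$proximity$p, 1e-10)
  ft$familiarity <- 1
  expect_true(is.na(test_h1(ft)$familiarity$estimate))
})

test_that("H2 regression matches the closed-form slope", {
  set.seed(31)
  dk <- runif(25)
  ft <- make_features(25, avg = 1 - dk, dk = dk)
  h2 <- test_h2(ft)
  expect_equal(h2$estimate, -1, tolerance = 1e-10)
  expect_equal(h2$r_squared, 1, tolerance = 1e-10)

  dk2 <- runif(25)
  y2 <- 0.5 - 0.4 * dk2 + rnorm(25, 0, 0.05)
  ft2 <- make_features(25, avg = y2, dk = dk2)
  h22 <- test_h2(ft2)
  expect_equal(h22$estimate, cov(dk2, y2) / var(dk2), tolerance = 1e-10)

  ft$dk_level <- 0.5
  expect_true(is.na(test_h2(ft)$estimate))
})

test_that("H3 Spearman matches the brute-force rank oracle", {
  set.seed(32)
  inf <- runif(12)
  ft <- make_features(12, avg = runif(12))
  ft$influencer_ratio <- inf
  ft$anxiety_sd <- 1 - inf          # strictly monotone decreasing
  expect_equal(test_h3(ft)$estimate, -1)
  for (i in 1:10) {
    n <- sample(5:15, 1)
    ft2 <- make_features(n, avg = runif(n))
    expect_equal(test_h3(ft2)$estimate,
                 brute_spearman(ft2$influencer_ratio, ft2$anxiety_sd),
                 tolerance = 1e-10)
  }
  ft$anxiety_sd <- 0.5
  expect_true(is.na(test_h3(ft)$estimate))
})

test_that("the ten-predictor regression recovers a noiseless construction", {
  set.seed(33)
  n <- 40
  ft <- make_features(n, avg = 0)
  ft$avg_collective_anxiety <- 0.3 - 0.1 * ft$proximity - 0.2 * ft$dk_level +
    0.05 * ft$edge_density + 0.001 * ft$n_members
  reg <- anxiety_regression(ft)
  expect_s3_class(reg, "canx_regression")
  expect_equal(reg$beta[reg$predictor == "proximity"], -0.1,
               tolerance = 1e-8)
  expect_equal(reg$beta[reg$predictor == "dk_level"], -0.2,
               tolerance = 1e-8)
  expect_equal(reg$beta[reg$predictor == "n_members"], 0.001,
               tolerance = 1e-8)

  # constant predictor: NA row, never a silent estimate
  ft0 <- ft
  ft0$diameter <- 3
  reg0 <- anxiety_regression(ft0)
  expect_true(is.na(reg0$beta[reg0$predictor == "diameter"]))
  expect_false(anyNA(reg0$beta[reg0$predictor != "diameter"]))

  # perfect collinearity: error naming the offender
  ftc <- ft
  ftc$interaction_frequency <- 2 * ftc$edge_density
  expect_error(anxiety_regression(ftc), "collinear")

  expect_error(anxiety_regression(ft[1:5, ]), "at least")
})
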