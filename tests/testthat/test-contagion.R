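test_that("relation matrix symmetrizes directed links and stays hollow", {
  m <- c("u1", "u2", "u3")
  R <- relation_matrix(m, data.frame(src = "u1", dst = "u2"))
  expect_equal(R["u1", "u2"], 1)
  expect_equal(R["u2", "u1"], 1)
  expect_equal(sum(R), 2)
  expect_equal(relation_matrix(m, data.frame(src = character(0),
                                             dst = character(0))),
               matrix(0, 3, 3, dimnames = list(m, m)))
  Rs <- relation_matrix(m, data.frame(src = c("u1", "u2"),
                                      dst = c("u1", "u3")))
  expect_equal(diag(Rs), c(u1 = 0, u2 = 0, u3 = 0))
  expect_error(relation_matrix(m, data.frame(src = "u1", dst = "zz")), "zz")
})

test_that("propagation power follows the exponential law", {
  pr <- contagion_params(epsilon = 0.1, UB = 1)
  expect_equal(propagation_power(1, pr), 0.1)
  expect_equal(propagation_power(0, pr), 0.1 * exp(-1))
  x <- seq(0, 1, by = 0.05)
  d <- propagation_power(x, pr)
  expect_true(all(diff(d) > 0))
  expect_true(all(d > 0))
  pr2 <- contagion_params(epsilon = 0.03, UB = 2)
  expect_equal(propagation_power(2, pr2), 0.03)
})

test_that("one cascade iteration adds neighbor propagation power", {
  m <- c("a", "b")
  R <- relation_matrix(m, data.frame(src = "a", dst = "b"))
  pr <- contagion_params(epsilon = 0.1, UB = 1, clip_to_UB = TRUE)
  a1 <- iterate_anxiety(c(0, 1), R, pr)
  expect_equal(a1, c(0.1, 1.0))   # u1 gains delta(1)=0.1; u2 clips at UB
  expect_error(iterate_anxiety(c(0, 1, 0), R, pr), "dimension")
  # isolated member never changes
  R3 <- relation_matrix(c("a", "b", "c"), data.frame(src = "a", dst = "b"))
  aK <- run_cascade(c(0.2, 0.4, 0.7), R3,
                    contagion_params(epsilon = 0.1, K = 5))
  expect_equal(aK[3], 0.7)
})

test_that("unclipped cascade is monotone non-decreasing", {
  set.seed(42)
  pr <- contagion_params(epsilon = 0.05, clip_to_UB = FALSE, K = 1)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    R <- random_relation(n)
    a <- runif(n)
    expect_true(all(iterate_anxiety(a, R, pr) >= a))
  }
})

test_that("influence from a distance-d node first arrives at iteration d", {
  m <- c("u1", "u2", "u3")
  R <- relation_matrix(m, data.frame(src = c("u1", "u2"),
                                     dst = c("u2", "u3")))
  pr <- function(K) contagion_params(epsilon = 0.1, K = K,
                                     clip_to_UB = FALSE)
  expect_equal(run_cascade(c(0, 0, 1), R, pr(0)), c(0, 0, 1))
  # u3's anxiety is felt at u1 (distance 2) only from the second iteration:
  # until then u1's score is identical whether u3 is anxious or calm
  with_u3 <- run_cascade(c(0, 0, 1), R, pr(1))
  without <- run_cascade(c(0, 0, 0), R, pr(1))
  expect_equal(with_u3[1], without[1])
  expect_gt(with_u3[2], without[2])    # distance 1 already differs
  expect_gt(run_cascade(c(0, 0, 1), R, pr(2))[1],
            run_cascade(c(0, 0, 0), R, pr(2))[1])
})

test_that("matrix cascade equals the per-edge double-loop oracle", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    R <- random_relation(n)
    a0 <- runif(n)
    K <- sample(0:4, 1)
    clip <- i %% 2 == 0
    prm <- contagion_params(epsilon = 0.08, UB = 1, K = K, clip_to_UB = clip)
    expect_equal(run_cascade(a0, R, prm),
                 naive_cascade(a0, R, 0.08, 1, K, clip), tolerance = 1e-12)
  }
})

test_that("cascade is equivariant under member relabeling", {
  set.seed(11)
  n <- 8
  R <- random_relation(n)
  a0 <- runif(n)
  prm <- contagion_params(epsilon = 0.05, K = 3)
  perm <- sample(n)
  expect_equal(run_cascade(a0, R, prm)[perm],
               run_cascade(a0[perm], R[perm, perm], prm))
})

test_that("collective score activates the summed scores into [0,1]", {
  prs <- contagion_params(tau = 2)
  expect_equal(collective_score(0, prs, is_sum = TRUE), 0)
  expect_equal(collective_score(2, prs, is_sum = TRUE), 1 - exp(-1))
  prg <- contagion_params(norm = "global_max", n_max = 100)
  expect_equal(collective_score(0, prg, is_sum = TRUE), 0)
  expect_equal(collective_score(50, prg, is_sum = TRUE), 0.5)
  expect_error(collective_score(1, contagion_params(norm = "global_max"),
                                is_sum = TRUE), "n_max")
  # community size matters: equal mean anxiety, larger community scores higher
  prt <- contagion_params()
  nbar <- 500
  A_small <- collective_score(
    sum(rep(0.5, 10)),
    contagion_params(tau = canx:::community_tau(10, nbar, prt)),
    is_sum = TRUE)
  A_large <- collective_score(
    sum(rep(0.5, 1000)),
    contagion_params(tau = canx:::community_tau(1000, nbar, prt)),
    is_sum = TRUE)
  expect_gt(A_large, A_small)
  # strictly increasing in the summed score under both norms
  s <- seq(0, 10, by = 0.5)
  expect_true(all(diff(collective_score(s, prs, is_sum = TRUE)) > 0))
  expect_true(all(diff(collective_score(s, prg, is_sum = TRUE)) > 0))
})

test_that("daily series runs the cumulative pipeline day by day", {
  members <- c("u1", "u2", "u3")
  # members activate on successive days with identical message similarity
  ser <- daily_series(members, p = NULL,
                      msg_user = c("u1", "u2", "u3"),
                      msg_day = c(0, 1, 2),
                      msg_sim = c(0.5, 0.5, 0.5),
                      edges = data.frame(src = c("u1", "u2"),
                                         dst = c("u2", "u3")),
                      n_days = 4, params = contagion_params(K = 0))
  expect_s3_class(ser, "canx_series")
  expect_lte(nrow(ser), 4)
  expect_equal(ser$n_active, c(1, 2, 3, 3))
  expect_true(all(diff(ser$A) >= 0))   # growing community, non-decreasing A
  expect_true(all(ser$A >= 0 & ser$A <= 1))

  one <- daily_series("u1", p = NULL, msg_user = "u1", msg_day = 3,
                      msg_sim = 0.4, edges = NULL, n_days = 4,
                      params = contagion_params(K = 0))
  expect_equal(nrow(one), 1)           # series starts at the first active day
  expect_equal(polarization(one)$fluctuation, 0)
})

test_that("polarization reports trend, flag, and fluctuation honestly", {
  flat <- data.frame(day = 0:9, A = rep(0.4, 10))
  pf <- polarization(flat)
  expect_equal(pf$trend_slope, 0)
  expect_false(pf$polarized)
  expect_equal(pf$fluctuation, 0)

  lin <- data.frame(day = 0:9, A = 0.1 + 0.02 * (0:9))
  pl <- polarization(lin)
  expect_equal(pl$trend_slope, 0.02, tolerance = 1e-12)
  expect_true(pl$polarized)

  ser <- data.frame(day = 0:3, A = c(0.1, 0.3, 0.2, 0.4))
  mu <- mean(ser$A)
  hand_sd <- sqrt(sum((ser$A - mu)^2) / 3)
  expect_equal(polarization(ser)$fluctuation, hand_sd, tolerance = 1e-12)

  two <- data.frame(day = 0:1, A = c(0.2, 0.3))
  pt <- polarization(two)
  expect_true(is.na(pt$trend_slope))   # too few points for a trend
  expect_equal(pt$fluctuation, sd(c(0.2, 0.3)))
})
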