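# independent brute-force oracles; deliberately naive implementations that
# share no code with the package internals they check

# per-edge double-loop cascade (Eq. 2 done the slow way)
naive_cascade <- function(a0, R, epsilon, UB, K, clip = TRUE) {
  a <- a0
  n <- length(a0)
  for (k in seq_len(K)) {
    gain <- numeric(n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (R[i, j] > 0)
          gain[i] <- gain[i] + epsilon * exp((a[j] - UB) / UB)
      }
    }
    a <- a + gain
    if (clip) a <- pmin(UB, pmax(0, a))
  }
  a
}

# confusion counting by explicit loop
brute_confusion <- function(model, truth) {
  tp <- fp <- fn <- 0L
  for (i in seq_along(model)) {
    if (model[i] == truth[i]) tp <- tp + 1L
    else if (model[i] > truth[i]) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, fp = fp, fn = fn)
}

# Spearman rho as Pearson on hand-computed ranks (mean rank for ties)
brute_spearman <- function(x, y) {
  rk <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  stats::cor(rk(x), rk(y))
}

# all-pairs shortest paths by Floyd-Warshall; diameter of largest component
fw_diameter <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  finite <- d[is.finite(d)]
  max(finite)
}

# random symmetric binary matrix with zero diagonal
random_relation <- function(n, p = 0.3) {
  R <- matrix(0, n, n)
  up <- which(upper.tri(R))
  R[up] <- as.numeric(stats::runif(length(up)) < p)
  R + t(R)
}

# hand-built embedding for the worked w1/w2 example: "terrible" close to the
# anxiety anchors, "good" pointing away, plus orthogonal axes for fixtures
w1w2_embedding <- function() {
  v <- rbind(
    nervous  = c(1, 0, 0),
    afraid   = c(0.95, 0.31225, 0),
    terrible = c(0.9, 0.43589, 0),
    good     = c(-1, 0, 0),
    weekend  = c(0, 0, 1),
    work     = c(0, 1, 0),
    feel     = c(0, 0.70711, 0.70711),
    much     = c(0, -1, 0),
    orthog   = c(0, 0, -1))
  fixture_embedding(v)
}

# small wired corpus for pipeline tests
tiny_corpus <- function(seed = 1, n_communities = 5, sizes = c(25, 40),
                        n_days = 8, ...) {
  simulate_corpus(sim_config(n_communities = n_communities,
                             size_range = sizes, n_days = n_days,
                             messages_per_user_mean = 3, seed = seed, ...))
}

# one shared small scorer for pipeline tests (trained once per test run)
tiny_scorer <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- simulate_sas(120, seed = 42, noise_sd = 2)
      cache <<- profile_scorer(d$profiles, d$sas, seed = 42)
    }
    cache
  }
})
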