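#' Contagion parameters
#'
#' Tunable parameters of the anxiety cascade.  `epsilon` scales the
#' propagation power, `UB` is the maximum individual anxiety score on the
#' normalized scale, `K` the iteration depth (defaults to
#' `min(graph diameter, 6)` when `NULL`), and `clip_to_UB` keeps scores inside
#' `[0, UB]` after each iteration.  `norm` selects how the summed post-cascade
#' score is activated into `[0, 1]`: `"saturating"` uses `1 - exp(-s/tau)`,
#' `"global_max"` uses `s / (n_max * UB)`.  Under the saturating mode the
#' pipeline sizes `tau` per community as `UB * n^(1-gamma) * nbar^gamma`
#' (`nbar` = mean community size in the run): `gamma = 1` gives one shared
#' `tau = nbar * UB`, `gamma = 0` a fully per-community scale; the default
#' `gamma = 0.1` keeps collective anxiety increasing in community size at
#' equal member anxiety without letting size dominate the score.
#'
#' @param epsilon small positive propagation scale (default 5e-4, sized so a
#'   full cascade at typical degree perturbs member scores by a few percent:
#'   contagion redistributes and amplifies the initial scores rather than
#'   replacing them).
#' @param UB maximum individual anxiety score (default 1).
#' @param K iteration depth, or `NULL` for `min(diameter, 6)`.
#' @param clip_to_UB clip scores to `[0, UB]` each iteration (default TRUE).
#' @param norm `"saturating"` or `"global_max"`.
#' @param tau explicit saturation scale; `NULL` to size it from the run.
#' @param gamma size-tempering exponent in `[0, 1]` for the saturating mode.
#' @param n_max largest community size, required by `"global_max"` when no
#'   run context supplies it.
#' @param lambda profile/topical mixing weight shared with
#'   [initial_anxiety()].
#' @return A list of class `contagion_params`.
#' @export
contagion_params <- function(epsilon = 5e-4, UB = 1, K = NULL,
                             clip_to_UB = TRUE,
                             norm = c("saturating", "global_max"),
                             tau = NULL, gamma = 0.1, n_max = NULL,
                             lambda = 0.5) {
  norm <- match.arg(norm)
  if (epsilon <= 0) stop_canx("epsilon must be a small positive real")
  if (UB <= 0) stop_canx("UB must be positive")
  if (!is.null(K) && K < 0) stop_canx("K must be >= 0")
  if (!is.null(tau) && tau <= 0) stop_canx("tau must be positive")
  if (gamma < 0 || gamma > 1) stop_canx("gamma must lie in [0, 1]")
  if (lambda < 0 || lambda > 1) stop_canx("lambda must lie in [0, 1]")
  structure(list(epsilon = epsilon, UB = UB, K = K,
                 clip_to_UB = isTRUE(clip_to_UB), norm = norm, tau = tau,
                 gamma = gamma, n_max = n_max, lambda = lambda),
            class = "contagion_params")
}

#' Build the symmetric relation matrix of a community
#'
#' Realizes the binary member-connection matrix from directed edges
#' (follow/repost/comment links): any edge i->j sets both `r_ij` and `r_ji`.
#' Self-edges are dropped so the diagonal stays zero.
#'
#' @param members character vector of member ids (defines matrix order).
#' @param edges data.frame with columns `src` and `dst` (member ids).
#' @return An n x n symmetric binary matrix with `members` as dimnames.
#' @export
relation_matrix <- function(members, edges) {
  n <- length(members)
  R <- matrix(0, n, n, dimnames = list(members, members))
  if (nrow(edges)) {
    i <- match(edges$src, members)
    j <- match(edges$dst, members)
    bad <- is.na(i) | is.na(j)
    if (any(bad))
      stop_canx("edge endpoints outside the community: ",
                paste(utils::head(unique(c(edges$src[bad & is.na(i)],
                                           edges$dst[bad & is.na(j)])), 5L),
                      collapse = ", "))
    keep <- i != j
    R[cbind(i[keep], j[keep])] <- 1
    R[cbind(j[keep], i[keep])] <- 1
  }
  R
}

#' Propagation power function
#'
#' The per-iteration influence a member with anxiety `x` exerts on each
#' neighbor: `delta(x) = epsilon * exp((x - UB)/UB)`.  Strictly increasing in
#' `x`, always positive, and equal to `epsilon` at `x = UB`.
#'
#' @param x anxiety score(s), `>= 0`.
#' @param params a [contagion_params()] object (or anything with `epsilon`
#'   and `UB`).
#' @return `delta(x)`, same length as `x`.
#' @examples
#' propagation_power(0, contagion_params(epsilon = 0.1))  # 0.1 * exp(-1)
#' @export
propagation_power <- function(x, params = contagion_params()) {
  stopifnot(all(x >= 0))
  params$epsilon * exp((x - params$UB) / params$UB)
}

#' One cascade iteration
#'
#' Matrix form of the contagion update: `a_k = a_{k-1} + R %*% delta(a_{k-1})`
#' with `delta` applied elementwise, i.e. each member gains the summed
#' propagation power of its neighbors.  With `clip_to_UB` the result is
#' clipped to `[0, UB]`.
#'
#' @param a numeric vector of current anxiety scores.
#' @param R relation matrix from [relation_matrix()].
#' @param params a [contagion_params()].
#' @return Updated anxiety vector.
#' @export
iterate_anxiety <- function(a, R, params = contagion_params()) {
  if (length(a) != nrow(R) || nrow(R) != ncol(R))
    stop_canx("dimension mismatch: length(a)=", length(a),
              ", dim(R)=", nrow(R), "x", ncol(R))
  out <- a + as.numeric(R %*% propagation_power(a, params))
  if (params$clip_to_UB) out <- pmin(params$UB, pmax(0, out))
  out
}

#' Run the anxiety cascade
#'
#' Applies [iterate_anxiety()] `K` times; `K = 0` returns the initial vector
#' unchanged.  In the k-th iteration the influence of k-th-degree neighbors
#' reaches each member (one hop per iteration).
#'
#' @param a0 initial anxiety vector.
#' @param R relation matrix.
#' @param params a [contagion_params()]; `K = NULL` resolves to
#'   `min(diameter(R), 6)`.
#' @return Anxiety vector after `K` iterations.
#' @export
run_cascade <- function(a0, R, params = contagion_params()) {
  K <- params$K %||% min(graph_diameter_matrix(R), 6L)
  a <- a0
  for (k in seq_len(K)) a <- iterate_anxiety(a, R, params)
  a
}

# edge-list cascade: equivalent to the matrix form but O(E) per iteration;
# edges given as (i, j) index pairs of the symmetrized relation (both
# directions present).  Used by the daily-series pipeline.
cascade_edges <- function(a0, ei, ej, params, K) {
  a <- a0
  n <- length(a)
  for (k in seq_len(K)) {
    d <- params$epsilon * exp((a - params$UB) / params$UB)
    gain <- numeric(n)
    if (length(ei)) {
      s <- rowsum(d[ej], ei)
      gain[as.integer(rownames(s))] <- s[, 1L]
    }
    a <- a + gain
    if (params$clip_to_UB) a <- pmin(params$UB, pmax(0, a))
  }
  a
}

# diameter of the graph underlying a relation matrix (largest component)
graph_diameter_matrix <- function(R) {
  if (nrow(R) < 2L || sum(R) == 0) return(0L)
  g <- igraph::graph_from_adjacency_matrix(R > 0, mode = "undirected")
  as.integer(igraph::diameter(g, directed = FALSE, unconnected = TRUE))
}

#' Collective anxiety score A(C)
#'
#' Activates the summed post-cascade member scores into `[0, 1]`.  The sum
#' (not the average) enters deliberately: community size matters for
#' collective anxiety, so at equal mean member anxiety a larger community
#' scores higher.  `"saturating"` computes `1 - exp(-s/tau)`; `"global_max"`
#' computes `s / (n_max * UB)`.  Both are strictly increasing in `s`.
#'
#' @param a numeric vector of post-cascade anxiety scores (or a single
#'   pre-summed value with `is_sum = TRUE`).
#' @param params a [contagion_params()]; `tau` (saturating) or `n_max`
#'   (global_max) must be resolvable.
#' @param is_sum treat `a` as the already-summed score `s`.
#' @return `A(C)` in `[0, 1]`.
#' @examples
#' collective_score(c(0.2, 0.4), contagion_params(tau = 2))
#' @export
collective_score <- function(a, params = contagion_params(), is_sum = FALSE) {
  s <- if (is_sum) a else sum(a)
  if (params$norm == "saturating") {
    tau <- params$tau
    if (is.null(tau) && !is_sum) tau <- length(a) * params$UB
    if (is.null(tau) || tau <= 0)
      stop_canx("saturating norm needs a positive tau")
    1 - exp(-s / tau)
  } else {
    if (is.null(params$n_max) || params$n_max <= 0)
      stop_canx("global_max norm needs n_max (largest community size)")
    pmin(1, s / (params$n_max * params$UB))
  }
}

# per-community saturation scale: UB * n^(1-gamma) * nbar^gamma
community_tau <- function(n, nbar, params) {
  params$tau %||% (params$UB * n^(1 - params$gamma) * nbar^params$gamma)
}

#' Daily collective anxiety series for one community
#'
#' Evaluates the full pipeline day by day under cumulative snapshots:
#' for each day t the membership, messages, and relation edges active up to t
#' (half-open day indexing, day t includes days `0..t`) feed the cascade, and
#' the summed result is activated by the configured norm.  Members become
#' active with their first message; follow edges switch on once both
#' endpoints are active, repost/comment edges on the day of the child
#' message.
#'
#' @param members member ids.
#' @param p profile-factor scores aligned with `members` (may be `NULL` when
#'   no profile scorer is available, in which case the topical factor alone is
#'   used).
#' @param msg_user,msg_day,msg_sim per-message member id, day index (0-based)
#'   and anchor similarity.
#' @param edges data.frame of directed edges (`src`, `dst`) among members.
#' @param parent_edges optional data.frame (`src`, `dst`, `day`) of
#'   repost/comment interaction edges with their activation day.
#' @param n_days length of the observation window.
#' @param params a [contagion_params()].
#' @param nbar mean community size of the run (for the saturating `tau`);
#'   defaults to this community's size.
#' @return A data.frame of class `canx_series` with columns `day`, `A`,
#'   `n_active`.
#' @export
daily_series <- function(members, p, msg_user, msg_day, msg_sim, edges,
                         parent_edges = NULL, n_days,
                         params = contagion_params(), nbar = NULL) {
  n <- length(members)
  nbar <- nbar %||% n
  u <- match(msg_user, members)
  if (anyNA(u))
    stop_canx("messages reference users outside the community")
  stopifnot(all(msg_day >= 0), all(msg_day < n_days))

  # cumulative topical factor per member per day: running mean of similarities
  idx <- as.integer(msg_day) * n + u     # linear index into the n x n_days grid
  cnt <- matrix(0, n, n_days)
  sm <- matrix(0, n, n_days)
  tab <- rowsum(cbind(rep(1, length(idx)), msg_sim), idx)
  ii <- as.integer(rownames(tab))
  cnt[ii] <- tab[, 1L]
  sm[ii] <- tab[, 2L]
  U <- upper.tri(diag(n_days), diag = TRUE)  # column t = cumulative through t
  ccnt <- cnt %*% U
  csm <- sm %*% U
  m_mat <- ifelse(ccnt > 0, csm / pmax(ccnt, 1), NA_real_)
  first_day <- apply(cnt > 0, 1L, function(z) if (any(z)) which(z)[1L] - 1L else n_days)

  # edge activation days (symmetrized index pairs)
  ei <- integer(0); ej <- integer(0); eday <- integer(0)
  add_edges <- function(i, j, d) {
    keep <- !is.na(i) & !is.na(j) & i != j
    ei <<- c(ei, i[keep], j[keep])
    ej <<- c(ej, j[keep], i[keep])
    eday <<- c(eday, d[keep], d[keep])
  }
  if (!is.null(edges) && nrow(edges)) {
    i <- match(edges$src, members); j <- match(edges$dst, members)
    if (anyNA(i) || anyNA(j))
      stop_canx("edges reference users outside the community")
    add_edges(i, j, pmax(first_day[i], first_day[j]))
  }
  if (!is.null(parent_edges) && nrow(parent_edges)) {
    i <- match(parent_edges$src, members); j <- match(parent_edges$dst, members)
    add_edges(i, j, as.integer(parent_edges$day))
  }
  dup <- duplicated(cbind(ei, ej))          # keep the earliest activation
  if (any(dup)) {
    o <- order(eday)
    ei <- ei[o]; ej <- ej[o]; eday <- eday[o]
    dup <- duplicated(cbind(ei, ej))
    ei <- ei[!dup]; ej <- ej[!dup]; eday <- eday[!dup]
  }
  o <- order(eday)
  ei <- ei[o]; ej <- ej[o]; eday <- eday[o]

  K <- params$K
  if (is.null(K)) {
    Rfull <- matrix(0, n, n)
    if (length(ei)) Rfull[cbind(ei, ej)] <- 1
    K <- min(graph_diameter_matrix(Rfull), 6L)
  }
  tau <- community_tau(n, nbar, params)
  lam <- params$lambda

  days <- which(colSums(ccnt) > 0)[1L]  # first active day
  if (is.na(days)) stop_canx("community has no messages in the window")
  out_day <- integer(0); out_A <- numeric(0); out_n <- integer(0)
  for (t in (days - 1L):(n_days - 1L)) {
    act <- which(ccnt[, t + 1L] > 0)
    if (!length(act)) next
    m_t <- m_mat[act, t + 1L]
    if (is.null(p)) a0 <- m_t
    else a0 <- lam * p[act] + (1 - lam) * m_t
    ne <- sum(eday <= t)
    sub <- seq_len(ne)
    # reindex active members; edges among active only (guaranteed by
    # activation-day construction, but filtered defensively)
    map <- match(seq_len(n), act)
    i2 <- map[ei[sub]]; j2 <- map[ej[sub]]
    ok <- !is.na(i2) & !is.na(j2)
    aK <- cascade_edges(a0, i2[ok], j2[ok], params, K)
    pr <- params; pr$tau <- tau
    out_day <- c(out_day, t)
    out_A <- c(out_A, collective_score(sum(aK), pr, is_sum = TRUE))
    out_n <- c(out_n, length(act))
  }
  structure(data.frame(day = out_day, A = out_A, n_active = out_n),
            class = c("canx_series", "data.frame"))
}

#' Trend, polarization flag, and fluctuation of a collective anxiety series
#'
#' The trend slope is the least-squares slope of `A(C)` on the day index; the
#' community counts as affectively polarized when the slope is positive with
#' `p < 0.05` (collective anxiety accumulates over deliberation).
#' Fluctuation is the sample standard deviation of the daily scores, the
#' outcome variable of the influencer-ratio hypothesis.
#'
#' @param series a `canx_series` (or any data.frame with `day` and `A`).
#' @return A list with `trend_slope`, `trend_p`, `polarized`, `fluctuation`,
#'   and `n_days`.  With fewer than 3 points the trend fields are `NA`; with
#'   fewer than 2, fluctuation is `NA` (undefined, never fabricated).
#' @export
polarization <- function(series) {
  stopifnot(all(c("day", "A") %in% names(series)))
  n <- nrow(series)
  # a single observed day shows no variation; an empty series is undefined
  fl <- if (n >= 2L) stats::sd(series$A) else if (n == 1L) 0 else NA_real_
  if (n >= 3L && stats::var(series$day) > 0) {
    fit <- stats::lm(A ~ day, data = series)
    sl <- unname(stats::coef(fit)[2L])
    pv <- suppressWarnings(summary(fit))$coefficients[2L, 4L]
    # an exactly collinear series has a 0/0 test statistic: treat a nonzero
    # slope with zero residual as unambiguous, a flat series as no trend
    if (is.nan(pv)) pv <- if (abs(sl) > 1e-12) 0 else 1
    pol <- sl > 0 && pv < 0.05
  } else {
    sl <- NA_real_; pv <- NA_real_; pol <- NA
  }
  list(trend_slope = sl, trend_p = pv, polarized = pol,
       fluctuation = fl, n_days = n)
}
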