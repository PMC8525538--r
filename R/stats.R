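#' Community anxiety rating levels
#'
#' The five ordinal community-level anxiety ratings.
#'
#' @return Character vector, mildest first.
#' @export
anxiety_levels <- function() c("no", "little", "medium", "high", "extreme")

#' Rate a community's collective anxiety
#'
#' Maps `A(C)` in `[0, 1]` to the five ordinal anxiety levels.  Default bands
#' are equal quintiles; intervals are half-open `[lo, hi)` with the last
#' closed, so band edges map to the upper band.
#'
#' @param A numeric vector of collective anxiety scores in `[0, 1]`.
#' @param bands increasing break vector of length 6 spanning `[0, 1]`.
#' @return Ordered factor with levels [anxiety_levels()].
#' @examples
#' rate_anxiety(c(0.05, 0.2, 0.95))
#' @export
rate_anxiety <- function(A, bands = c(0, 0.2, 0.4, 0.6, 0.8, 1)) {
  stopifnot(length(bands) == 6L, !is.unsorted(bands))
  if (any(is.na(A)) || any(A < bands[1L] | A > bands[6L]))
    stop_canx("collective anxiety scores must lie in [",
              bands[1L], ", ", bands[6L], "]")
  cut(A, breaks = bands, labels = anxiety_levels(), right = FALSE,
      include.lowest = TRUE, ordered_result = TRUE)
}

#' Directional precision and recall for ordinal ratings
#'
#' Validation metric for ordinal anxiety ratings: a model rating equal to the
#' ground truth is a true positive, one more severe a false positive, one
#' less severe a false negative.  Every rated case is exactly one of the
#' three, so `tp + fp + fn` equals the number of cases.  `precision =
#' tp/(tp+fp)`, `recall = tp/(tp+fn)`; an empty denominator is reported as
#' `NA` (undefined), never fabricated.
#'
#' @param model,truth equal-length ordinal vectors (ordered factors on the
#'   same levels, or integer codes).
#' @return An object of class `validation_counts`: a list with `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `n`.
#' @export
precision_recall <- function(model, truth) {
  if (length(model) != length(truth))
    stop_canx("model and truth ratings differ in length (",
              length(model), " vs ", length(truth), ")")
  if (is.factor(model)) model <- as.integer(model)
  if (is.factor(truth)) truth <- as.integer(truth)
  tp <- sum(model == truth)
  fp <- sum(model > truth)
  fn <- sum(model < truth)
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 n = length(model)),
            class = "validation_counts")
}

#' @export
print.validation_counts <- function(x, ...) {
  cat("Directional validation counts (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  tp = %d  fp = %d  fn = %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  precision = %s  recall = %s\n",
              format(x$precision, digits = 4),
              format(x$recall, digits = 4)))
  invisible(x)
}

#' Influencer ratio of a community
#'
#' Ratio of influencer ("yellow-V") personal accounts to all personal
#' accounts.  Organizational accounts are excluded from the denominator.
#'
#' @param profiles data.frame with logical columns `is_influencer` and
#'   `is_organizational`.
#' @return A single ratio in `[0, 1]`.
#' @export
influencer_ratio <- function(profiles) {
  personal <- !profiles$is_organizational
  if (!any(personal)) stop_canx("community has no personal accounts")
  mean(profiles$is_influencer[personal])
}

#' Structural metrics of a community graph
#'
#' Edge density `2|E| / (n(n-1))` over unique undirected member pairs, and
#' the diameter (longest shortest path) of the largest connected component.
#'
#' @param members member ids.
#' @param edges data.frame of edges (`src`, `dst`); direction and duplicates
#'   are ignored.
#' @return A list with `edge_density` (NA when `n < 2`) and `diameter`.
#' @export
graph_metrics <- function(members, edges) {
  n <- length(members)
  i <- match(edges$src, members); j <- match(edges$dst, members)
  keep <- !is.na(i) & !is.na(j) & i != j
  pair <- unique(cbind(pmin(i[keep], j[keep]), pmax(i[keep], j[keep])))
  e <- nrow(pair)
  dens <- if (n >= 2L) 2 * e / (n * (n - 1)) else NA_real_
  if (e == 0L) {
    diam <- 0L
  } else {
    g <- igraph::graph_from_edgelist(pair, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    diam <- as.integer(igraph::diameter(g, directed = FALSE,
                                        unconnected = TRUE))
  }
  list(edge_density = dens, diameter = diam)
}

#' Interaction frequency of a community
#'
#' Reposts plus comments per member per day over the observation window.
#'
#' @param kind character vector of message kinds (`post`, `repost`,
#'   `comment`).
#' @param n_members community size.
#' @param n_days window length in days.
#' @return A single non-negative rate.
#' @export
interaction_frequency <- function(kind, n_members, n_days) {
  stopifnot(n_members > 0, n_days > 0)
  sum(kind %in% c("repost", "comment")) / n_members / n_days
}

new_stat <- function(estimate, p, n, method, ...) {
  structure(c(list(estimate = estimate, p = p, n = n, method = method),
              list(...)),
            class = "canx_stat")
}

#' @export
print.canx_stat <- function(x, ...) {
  cat(x$method, ": estimate = ", format(x$estimate, digits = 4),
      ", p = ", format(x$p, digits = 4), ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Topic-attribute correlations with collective anxiety (H1)
#'
#' Pearson correlations of average collective anxiety with topic familiarity
#' (H1a) and topic proximity (H1b), both coded 0/1.
#'
#' @param features community features table (see [fitted.canx()]), needing
#'   columns `avg_collective_anxiety`, `familiarity`, `proximity`.
#' @return A list with `familiarity` and `proximity`, each a `canx_stat`
#'   (estimate = Pearson r).  Zero variance in either variable yields an
#'   `NA` estimate with the reason in `$note`.
#' @export
test_h1 <- function(features) {
  one <- function(xname) {
    x <- as.numeric(features[[xname]])
    y <- features$avg_collective_anxiety
    if (length(x) < 3L)
      return(new_stat(NA_real_, NA_real_, length(x), "Pearson correlation",
                      note = "fewer than 3 communities"))
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(new_stat(NA_real_, NA_real_, length(x), "Pearson correlation",
                      note = paste0("zero variance in ",
                                    if (stats::sd(x) == 0) xname else
                                      "collective anxiety")))
    ct <- stats::cor.test(x, y, method = "pearson")
    new_stat(unname(ct$estimate), ct$p.value, length(x),
             "Pearson correlation")
  }
  list(familiarity = one("familiarity"), proximity = one("proximity"))
}

#' Declarative knowledge vs collective anxiety (H2)
#'
#' Simple least-squares regression of average collective anxiety on the
#' community declarative-knowledge level; reports the slope, R-squared, the
#' model F statistic and its p-value.
#'
#' @param features community features table with `avg_collective_anxiety`
#'   and `dk_level`.
#' @return A `canx_stat` with `estimate` (slope), `r_squared`, `F`, `p`.
#' @export
test_h2 <- function(features) {
  x <- features$dk_level
  y <- features$avg_collective_anxiety
  if (length(x) < 3L || stats::sd(x) == 0 || is.na(stats::sd(x)))
    return(new_stat(NA_real_, NA_real_, length(x), "OLS regression",
                    note = "degenerate predictor"))
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate inputs
  fstat <- unname(sm$fstatistic)
  new_stat(unname(stats::coef(fit)[2L]),
           stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE),
           length(x), "OLS regression",
           r_squared = sm$r.squared, F = fstat[1L],
           beta_std = unname(stats::coef(fit)[2L]) * stats::sd(x) / stats::sd(y))
}

#' Influencer ratio vs anxiety fluctuation (H3)
#'
#' Spearman rank correlation between the influencer ratio and the standard
#' deviation of the daily collective anxiety series.
#'
#' @param features community features table with `influencer_ratio` and
#'   `anxiety_sd`.
#' @return A `canx_stat` (estimate = Spearman rho).
#' @export
test_h3 <- function(features) {
  x <- features$influencer_ratio
  y <- features$anxiety_sd
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(new_stat(NA_real_, NA_real_, length(x), "Spearman correlation",
                    note = "ties-only or degenerate data"))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  new_stat(unname(ct$estimate), ct$p.value, length(x), "Spearman correlation")
}

#' Multi-predictor regression of collective anxiety
#'
#' Ordinary least squares of average collective anxiety on the ten community
#' predictors: topic familiarity, topic proximity, declarative knowledge,
#' influencer ratio, numbers of posts, comments and members, interaction
#' frequency, edge density, and diameter.
#'
#' @param features community features table with all predictor columns.
#' @return A data.frame (class `canx_regression`) with one row per
#'   predictor: `beta`, `sd`, `t`, `p`.  Constant (zero-variance) predictors
#'   are reported with `NA` rows; perfectly collinear predictors raise an
#'   error naming the offending columns.
#' @export
anxiety_regression <- function(features) {
  preds <- c("familiarity", "proximity", "dk_level", "influencer_ratio",
             "n_posts", "n_comments", "n_members", "interaction_frequency",
             "edge_density", "diameter")
  miss <- setdiff(c(preds, "avg_collective_anxiety"), names(features))
  if (length(miss))
    stop_canx("features table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(features) < length(preds) + 2L)
    stop_canx("need at least ", length(preds) + 2L, " communities for the ",
              length(preds), "-predictor regression")
  X <- as.data.frame(lapply(features[preds], as.numeric))
  const <- vapply(X, function(v) stats::sd(v) == 0, logical(1))
  use <- preds[!const]
  fit <- stats::lm(stats::reformulate(use, response = "avg_collective_anxiety"),
                   data = cbind(X, avg_collective_anxiety =
                                     features$avg_collective_anxiety))
  alias <- is.na(stats::coef(fit))[-1L]
  if (any(alias))
    stop_canx("perfectly collinear predictor(s): ",
              paste(use[alias], collapse = ", "))
  cf <- suppressWarnings(summary(fit))$coefficients[-1L, , drop = FALSE]
  out <- data.frame(predictor = preds, beta = NA_real_, sd = NA_real_,
                    t = NA_real_, p = NA_real_)
  hit <- match(use, preds)
  out$beta[hit] <- cf[, 1L]; out$sd[hit] <- cf[, 2L]
  out$t[hit] <- cf[, 3L]; out$p[hit] <- cf[, 4L]
  attr(out, "r_squared") <- suppressWarnings(summary(fit))$r.squared
  class(out) <- c("canx_regression", "data.frame")
  out
}
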