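# format doubles so CSV round-trips are exact to the bit
precise_df <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]]))
      df[[nm]] <- ifelse(is.na(df[[nm]]), NA_character_,
                         sprintf("%.17g", df[[nm]]))
  }
  df
}

#' Write a corpus to a directory
#'
#' Writes the declared plain-text formats: `profiles.csv`, `messages.jsonl`
#' (one JSON record per line), `edges.tsv`, `communities.csv`, `truth.csv`,
#' and `manifest.json` echoing the generator configuration.  Output is
#' deterministic: identical corpora produce byte-identical files.
#'
#' @param corpus a `canx_corpus`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "canx_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(precise_df(corpus$profiles),
                   file.path(dir, "profiles.csv"), row.names = FALSE)
  con <- file(file.path(dir, "messages.jsonl"), open = "wb")
  jsonlite::stream_out(corpus$messages, con, verbose = FALSE, digits = NA)
  close(con)
  utils::write.table(corpus$edges, file.path(dir, "edges.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(precise_df(corpus$communities),
                   file.path(dir, "communities.csv"), row.names = FALSE)
  utils::write.csv(precise_df(corpus$truth), file.path(dir, "truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(c(format = "canx_corpus/1",
                         unclass(corpus$config)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a corpus from a directory
#'
#' Reads the formats written by [write_corpus()] and validates
#' cross-references; all referential errors (messages or edges pointing at
#' unknown users, truth rows without communities) are collected and reported
#' together.
#'
#' @param dir corpus directory.
#' @return A `canx_corpus`.
#' @export
read_corpus <- function(dir) {
  need <- c("profiles.csv", "messages.jsonl", "edges.tsv",
            "communities.csv", "truth.csv")
  missing_files <- need[!file.exists(file.path(dir, need))]
  if (length(missing_files))
    stop_canx("corpus directory ", dir, " is missing: ",
              paste(missing_files, collapse = ", "))
  profiles <- utils::read.csv(file.path(dir, "profiles.csv"),
                              stringsAsFactors = FALSE)
  con <- file(file.path(dir, "messages.jsonl"), open = "rb")
  messages <- jsonlite::stream_in(con, verbose = FALSE)
  close(con)
  if (!"parent" %in% names(messages)) messages$parent <- NA_character_
  edges <- utils::read.table(file.path(dir, "edges.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  communities <- utils::read.csv(file.path(dir, "communities.csv"),
                                 stringsAsFactors = FALSE)
  truth <- utils::read.csv(file.path(dir, "truth.csv"),
                           stringsAsFactors = FALSE)
  config <- NULL
  if (file.exists(file.path(dir, "manifest.json"))) {
    man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                               simplifyVector = TRUE)
    man$format <- NULL
    man$size_range <- as.integer(man$size_range)
    config <- do.call(sim_config, man)
  }
  errs <- character(0)
  bad_msg <- setdiff(messages$user, profiles$user_id)
  if (length(bad_msg))
    errs <- c(errs, paste0("messages reference unknown user(s): ",
                           paste(utils::head(bad_msg, 5L), collapse = ", ")))
  bad_edge <- setdiff(c(edges$src, edges$dst), profiles$user_id)
  if (length(bad_edge))
    errs <- c(errs, paste0("edges reference unknown user(s): ",
                           paste(utils::head(bad_edge, 5L), collapse = ", ")))
  bad_truth <- setdiff(truth$community_id, communities$id)
  if (length(bad_truth))
    errs <- c(errs, paste0("truth rows without community: ",
                           paste(utils::head(bad_truth, 5L), collapse = ", ")))
  if (length(errs))
    stop_canx("invalid corpus in ", dir, ":\n  ",
              paste(errs, collapse = "\n  "))
  structure(list(profiles = profiles, messages = messages, edges = edges,
                 communities = communities, truth = truth, config = config),
            class = "canx_corpus")
}

#' Write the hypothesis report as JSON
#'
#' Serializes a [summary.canx()] object: per-test estimate, p-value, n and
#' method, the multi-predictor regression table, and (when ground truth is
#' available) the directional validation counts.
#'
#' @param x a `summary.canx` object.
#' @param path output file; `NULL` returns the report list without writing.
#' @return The report list, invisibly.
#' @export
hypothesis_report <- function(x, path = NULL) {
  stopifnot(inherits(x, "summary.canx"))
  stat_entry <- function(s)
    list(estimate = s$estimate, p = s$p, n = s$n, method = s$method)
  rep <- list(
    h1a_familiarity = stat_entry(x$h1$familiarity),
    h1b_proximity = stat_entry(x$h1$proximity),
    h2_knowledge = c(stat_entry(x$h2),
                     list(r_squared = x$h2$r_squared, F = x$h2$F)),
    h3_influencer = stat_entry(x$h3),
    regression = as.list(as.data.frame(x$regression)),
    polarized_share = x$polarized_share)
  if (!is.null(x$validation))
    rep$validation <- x$validation[c("tp", "fp", "fn", "precision", "recall")]
  if (!is.null(path))
    jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, na = "null")
  invisible(rep)
}
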