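# Collection hygiene: keyword pruning by median weekly retrieval count,
# streaming tweet-id deduplication (retweet-aware), and JSON-lines corpus
# I/O with per-line validation.

corpus_columns <- c("tweet_id", "text", "label", "true_topic",
                    "is_retweet", "original_tweet_id", "source_keyword")

#' Prune keywords whose median weekly retrieval count is zero
#'
#' A keyword is retained iff the median of its weekly tweet counts is
#' strictly greater than zero; an all-but-dead keyword (median 0) is no
#' longer relevant to the discourse and is dropped. The median of an
#' even-length count vector is the mean of the two middle order statistics,
#' so a keyword with counts `c(0, 0, 1, 5)` (median 0.5) is retained.
#'
#' @param logs Either a named list mapping keyword to a numeric vector of
#'   weekly counts, or a data frame with columns `keyword`, `week`,
#'   `count` (as read by [read_keyword_log()]).
#' @return Character vector of retained keywords, in input order.
#' @export
prune_keywords <- function(logs) {
  if (is.data.frame(logs)) {
    if (!all(c("keyword", "count") %in% names(logs)))
      stopf("keyword log needs columns keyword, week, count")
    kws <- unique(as.character(logs$keyword))
    logs <- lapply(stats::setNames(kws, kws),
                   function(k) logs$count[logs$keyword == k])
  }
  if (!is.list(logs) || is.null(names(logs)))
    stopf("logs must be a named list of weekly counts or a keyword-log data frame")
  for (k in names(logs)) {
    counts <- logs[[k]]
    if (length(counts) == 0L)
      stopf("keyword '%s' has empty weekly_counts", k)
    if (any(!is.finite(counts)) || any(counts < 0))
      stopf("keyword '%s' has invalid weekly counts", k)
  }
  keep <- vapply(logs, function(counts) stats::median(counts) > 0, logical(1))
  names(logs)[keep]
}

#' Read a keyword retrieval log
#'
#' @param path CSV file with columns `keyword`, `week`, `count`.
#' @return Tibble with those columns.
#' @export
read_keyword_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("keyword", "week", "count") %in% names(df)))
    stopf("keyword log %s needs columns keyword, week, count", path)
  tibble::as_tibble(df)
}

#' Deduplicate a tweet stream by tweet id
#'
#' Streams through the records keeping the first occurrence of each
#' `tweet_id`. For a retweet the embedded original's id is what decides
#' redundancy: if the original was already collected the retweet is
#' dropped; otherwise both the retweet's and the original's ids are
#' registered and the retweet is kept. Output preserves first-seen order.
#'
#' @param records Data frame of tweet records with at least `tweet_id`,
#'   and optionally `is_retweet` / `original_tweet_id`.
#' @return List with `unique` (deduplicated records) and `n_dropped`.
#' @export
deduplicate <- function(records) {
  if (!is.data.frame(records)) stopf("records must be a data frame")
  if (!"tweet_id" %in% names(records)) stopf("records need a tweet_id column")
  ids <- as.character(records$tweet_id)
  if (any(is.na(ids) | !nzchar(ids)))
    stopf("record %d has an empty tweet_id",
          which(is.na(ids) | !nzchar(ids))[1L])
  is_rt <- if ("is_retweet" %in% names(records))
    records$is_retweet %in% TRUE else rep(FALSE, nrow(records))
  orig <- if ("original_tweet_id" %in% names(records))
    as.character(records$original_tweet_id) else rep(NA_character_, nrow(records))

  seen <- new.env(parent = emptyenv(), hash = TRUE)
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    id <- ids[i]
    if (is_rt[i] && !is.na(orig[i]) && nzchar(orig[i])) {
      if (!is.null(seen[[orig[i]]]) || !is.null(seen[[id]])) next
      seen[[orig[i]]] <- TRUE
      seen[[id]] <- TRUE
      keep[i] <- TRUE
    } else {
      if (!is.null(seen[[id]])) next
      seen[[id]] <- TRUE
      keep[i] <- TRUE
    }
  }
  list(unique = records[keep, , drop = FALSE],
       n_dropped = sum(!keep))
}

#' Write a corpus as JSON lines
#'
#' One JSON object per line with fields `tweet_id`, `text`, `label`,
#' `true_topic`, `is_retweet`, `original_tweet_id`, `source_keyword`;
#' `NA` fields are omitted from the line. [read_corpus()] inverts this
#' exactly.
#'
#' @param records Data frame with at least `tweet_id` and `text`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(records, path) {
  if (!is.data.frame(records)) stopf("records must be a data frame")
  records <- as.data.frame(records)
  for (col in corpus_columns)
    if (!col %in% names(records)) records[[col]] <- NA
  lines <- vapply(seq_len(nrow(records)), function(i) {
    row <- lapply(records[i, corpus_columns], identity)
    row <- row[!vapply(row, function(v) is.na(v), logical(1))]
    jsonlite::toJSON(row, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a JSON-lines corpus
#'
#' @param path JSON-lines file written by [write_corpus()] (or compatible:
#'   one object per line with at least a non-empty `tweet_id`).
#' @return Tibble with the canonical corpus columns; missing optional
#'   fields come back as `NA`.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  out <- list(
    tweet_id = character(n), text = character(n), label = character(n),
    true_topic = integer(n), is_retweet = logical(n),
    original_tweet_id = character(n), source_keyword = character(n))
  for (i in seq_len(n)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stopf(
                      "malformed corpus line %d in %s: %s", i, path,
                      conditionMessage(e)))
    if (is.null(rec$tweet_id) || !nzchar(as.character(rec$tweet_id)))
      stopf("corpus line %d in %s: missing or empty tweet_id", i, path)
    out$tweet_id[i] <- as.character(rec$tweet_id)
    out$text[i] <- if (is.null(rec$text)) NA_character_ else as.character(rec$text)
    out$label[i] <- if (is.null(rec$label)) NA_character_ else as.character(rec$label)
    out$true_topic[i] <- if (is.null(rec$true_topic)) NA_integer_ else
      as.integer(rec$true_topic)
    out$is_retweet[i] <- if (is.null(rec$is_retweet)) FALSE else
      isTRUE(rec$is_retweet)
    out$original_tweet_id[i] <- if (is.null(rec$original_tweet_id))
      NA_character_ else as.character(rec$original_tweet_id)
    out$source_keyword[i] <- if (is.null(rec$source_keyword))
      NA_character_ else as.character(rec$source_keyword)
  }
  tibble::as_tibble(out)
}
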