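#' Rank topics by prevalence and keep the major prefix
#'
#' Topics are sorted by assigned tweet count, descending (count ties broken
#' toward the lower topic id).  Under the default cumulative rule the
#' retained set is the minimal prefix whose cumulative share reaches at
#' least 75% of all assigned tweets — i.e. the minor tail that is discarded
#' holds less than 25% plus whatever mass the boundary topic carries.  The
#' alternative `"per_topic"` rule instead keeps every topic whose own share
#' is at least 25%.
#'
#' @param assignments data.frame with columns `id` and `topic` (NA topics,
#'   from empty documents, are excluded from the shares).
#' @param threshold Retained cumulative mass (default 0.75).
#' @param rule `"cumulative"` (default) or `"per_topic"`.
#' @return data.frame of class `topic_ranking` with `topic_id`,
#'   `tweet_count`, `share`, `cum_share`, `major`; rows sorted descending,
#'   all topics present, `major` marking the retained prefix.
#' @export
rank_and_filter_topics <- function(assignments, threshold = 0.75,
                                   rule = c("cumulative", "per_topic")) {
  rule <- match.arg(rule)
  topics <- assignments$topic[!is.na(assignments$topic)]
  if (!length(topics)) stop("no topic assignments to rank")
  tab <- table(topics)
  df <- data.frame(topic_id = as.integer(names(tab)),
                   tweet_count = as.integer(tab))
  df <- df[order(-df$tweet_count, df$topic_id), , drop = FALSE]
  df$share <- df$tweet_count / sum(df$tweet_count)
  df$cum_share <- cumsum(df$share)
  df$major <- if (rule == "cumulative") {
    # minimal prefix with cumulative share >= threshold
    seq_len(nrow(df)) <= match(TRUE, df$cum_share >= threshold - 1e-12)
  } else {
    df$share >= (1 - threshold)
  }
  rownames(df) <- NULL
  class(df) <- c("topic_ranking", "data.frame")
  df
}

#' Write annotation bundles for human topic labeling
#'
#' For each major topic, writes two UTF-8 TSV files into `out_dir`: the up-to
#' `n_tweets` most-retweeted tweets assigned to the topic (ties on retweet
#' count broken by earlier timestamp, then id) and the top `n_words` highest
#' probability words from the topic-word distribution.  Ordering is
#' deterministic so re-runs produce identical bundles.
#'
#' @param ranking A [rank_and_filter_topics()] result (only `major` rows are
#'   bundled).
#' @param assignments data.frame `id`, `topic`.
#' @param records The `tweet_records` store the ids refer to.
#' @param model The fitted `lda_model` for the phase.
#' @param out_dir Output directory (created if needed).
#' @param n_tweets,n_words Caps (defaults 1000 and 30).
#' @return Invisibly, a data.frame listing the files written.
#' @export
annotation_bundle <- function(ranking, assignments, records, model, out_dir,
                              n_tweets = 1000L, n_words = 30L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  major_ids <- ranking$topic_id[ranking$major]
  files <- list()
  for (tid in major_ids) {
    ids <- assignments$id[!is.na(assignments$topic) & assignments$topic == tid]
    sub <- records[records$id %in% ids, , drop = FALSE]
    ord <- order(-sub$retweet_count, sub$timestamp, sub$id)
    sub <- sub[ord, , drop = FALSE][seq_len(min(n_tweets, nrow(sub))), ,
                                    drop = FALSE]
    tw_path <- file.path(out_dir, sprintf("topic%03d_tweets.tsv", tid))
    utils::write.table(sub[, c("id", "timestamp", "retweet_count", "text")],
                       tw_path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    phi <- model$topic_word[tid + 1L, ]
    top <- order(-phi, seq_along(phi))[seq_len(min(n_words, length(phi)))]
    words <- data.frame(token = model$vocab$token[match(top - 1L, model$vocab$id)],
                        probability = phi[top])
    w_path <- file.path(out_dir, sprintf("topic%03d_words.tsv", tid))
    utils::write.table(words, w_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    files[[length(files) + 1L]] <- data.frame(topic_id = tid,
                                              tweets = tw_path, words = w_path)
  }
  invisible(do.call(rbind, files))
}

#' Daily theme-weight table from a topic label map
#'
#' Converts per-tweet topic assignments into daily theme trends.  A topic
#' carrying one theme label contributes weight 1 per tweet to that theme's
#' cell for the tweet's day; a topic carrying two labels contributes 0.5 to
#' each, so each labeled tweet always contributes total weight 1 and the
#' per-day row sums equal the day's labeled tweet count exactly.
#'
#' @param assignments data.frame with `id`, `topic`, and `date` (class Date)
#'   per record.
#' @param label_map Named list: topic id (as character) -> character vector
#'   of 1 or 2 theme labels.  Topics missing from the map count under
#'   `"unlabeled"`.
#' @return data.frame, one row per day in the assignment date range, first
#'   column `date`, remaining columns one per theme.
#' @export
apply_theme_labels <- function(assignments, label_map) {
  if (!"date" %in% names(assignments)) {
    stop("assignments must carry a 'date' column")
  }
  n_labels <- lengths(label_map)
  if (any(n_labels > 2L)) {
    stop("a topic may carry at most 2 theme labels; offending topic(s): ",
         paste(names(label_map)[n_labels > 2L], collapse = ", "))
  }
  ok <- !is.na(assignments$topic)
  asg <- assignments[ok, , drop = FALSE]
  key <- as.character(asg$topic)
  themes_per <- lapply(key, function(k) label_map[[k]] %||% "unlabeled")
  all_themes <- sort(unique(unlist(c(themes_per, list(character())))))
  days <- seq(min(asg$date), max(asg$date), by = "day")
  out <- matrix(0, nrow = length(days), ncol = length(all_themes),
                dimnames = list(NULL, all_themes))
  di <- match(asg$date, days)
  for (i in seq_len(nrow(asg))) {
    th <- themes_per[[i]]
    out[di[i], th] <- out[di[i], th] + 1 / length(th)
  }
  cbind(data.frame(date = days), as.data.frame(out))
}

#' Cohen's kappa for intercoder agreement
#'
#' `kappa = (p_o - p_e) / (1 - p_e)`, with observed agreement `p_o` and
#' chance agreement `p_e` from the product of the two coders' marginal label
#' frequencies.  When `p_e = 1` (both coders constant), kappa is 1 if they
#' agree and 0 otherwise.
#'
#' @param labels_a,labels_b Equal-length label vectors (at least 2 items).
#' @return Scalar kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label sequences differ in length")
  }
  if (length(labels_a) < 2L) stop("need at least 2 items")
  levs <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(as.character(labels_a), levels = levs)
  b <- factor(as.character(labels_b), levels = levs)
  p_o <- mean(a == b)
  p_e <- sum((table(a) / length(a)) * (table(b) / length(b)))
  if (abs(1 - p_e) < 1e-12) return(if (p_o == 1) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

#' Read a theme label map from JSON
#'
#' Expected form: `{"0": ["news_confirmed"], "1": ["news_hate",
#' "news_economy"], ...}` — topic ids as keys, 1 or 2 theme labels as values.
#'
#' @param path JSON file path.
#' @return Named list suitable for [apply_theme_labels()].
#' @export
read_label_map <- function(path) {
  m <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(m, function(v) unlist(v, use.names = FALSE))
}
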