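# Shared fixture builders: everything is generated in code at test time.

write_jsonl_fixture <- function(rows, path = tempfile(fileext = ".jsonl")) {
  writeLines(vapply(rows, function(r) {
    jsonlite::toJSON(r, auto_unbox = TRUE)
  }, character(1)), path, useBytes = TRUE)
  path
}

write_csv_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Minimal in-memory record table.
make_records <- function(texts,
                         dates = rep(as.Date("2020-01-01"), length(texts)),
                         is_retweet = rep(FALSE, length(texts)),
                         retweet_count = rep(0L, length(texts)),
                         user_id = sprintf("u%03d", seq_along(texts)),
                         id = sprintf("t%03d", seq_along(texts))) {
  ts <- if (length(texts)) {
    as.POSIXct(paste(dates, "12:00:00"), tz = "UTC")
  } else as.POSIXct(character(), tz = "UTC")
  out <- data.frame(
    id = id,
    timestamp = ts,
    text = texts, user_id = user_id, is_retweet = is_retweet,
    retweet_count = retweet_count,
    country_tag = rep("test", length(texts)),
    stringsAsFactors = FALSE)
  class(out) <- c("tweet_records", "data.frame")
  out
}

# Hand-checkable series fixture for threshold learning / start detection:
# flat, small jump, big jump.  With the identity smoother all derivatives
# are exact integer differences.
detection_fixture <- function() {
  daily_series(as.Date("2020-01-01"), c(10, 10, 12, 20, 21, 22, 30, 50, 55))
}

# Corpus of balanced, sharply separated synthetic topics (flat stream, no
# retweets, no mentions), as a list of token vectors plus generation truth.
make_separable_corpus <- function(seed, k_true = 3, days = 20,
                                  baseline = 100) {
  cfg <- generator_config(
    window = as.Date("2020-01-01") + c(0, days - 1),
    baseline_rate = baseline, surges = list(), retweet_prob = 0,
    mention_prob = numeric(), k_true = k_true,
    phase_mix = rep(1, k_true), seed = seed)
  st <- generate_stream(cfg)
  list(docs = strsplit(st$records$text, " ", fixed = TRUE),
       ids = st$records$id, truth = st$truth)
}
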