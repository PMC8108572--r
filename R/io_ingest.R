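#' Read tweet-like records from JSONL or CSV
#'
#' Parses timestamped short-text records into the canonical record table used
#' throughout the package.  Field names are resolved through `field_map`, a
#' named list mapping canonical names (`id`, `timestamp`, `text`, `user_id`,
#' `is_retweet`, `retweet_count`) to the names used in the file; the default
#' map accepts the common crawler-style column names (`id`/`tweet_id`,
#' `date`/`created_at`/`timestamp`, `tweet`/`text`, `user_id`/`username`,
#' `retweet`/`is_retweet`, `retweets_count`/`retweet_count`).
#'
#' Rows with a missing/empty `text`, an unparseable timestamp, or a missing
#' `id` are skipped; duplicate ids keep the first occurrence.  Skip counts are
#' attached as attributes `n_skipped` and `n_duplicates`.  When no explicit
#' retweet flag is present, a leading `"RT @"` in the text marks a retweet.
#'
#' @param path Path to the input file.
#' @param format `"jsonl"` (one JSON object per line, UTF-8) or `"csv"`
#'   (RFC 4180, header row).
#' @param field_map Named list overriding the default field-name resolution.
#' @param country_tag Short code recorded on every row (stream identity).
#' @param tz Timezone used to parse timestamps lacking an offset.
#' @return A `data.frame` of class `tweet_records` with columns `id`, `timestamp`
#'   (POSIXct), `text`, `user_id`, `is_retweet`, `retweet_count`, `country_tag`.
#' @export
read_tweets <- function(path, format = c("jsonl", "csv"), field_map = NULL,
                        country_tag = NA_character_, tz = "UTC") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read tweet file: ", path)

  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    rows <- vector("list", length(lines))
    bad <- 0L
    for (i in seq_along(lines)) {
      obj <- tryCatch(jsonlite::fromJSON(lines[[i]]), error = function(e) NULL)
      if (is.null(obj) || !is.list(obj)) bad <- bad + 1L else rows[[i]] <- obj
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", encoding = "UTF-8")
    rows <- lapply(seq_len(nrow(raw)), function(i) as.list(raw[i, , drop = FALSE]))
    bad <- 0L
  }

  fm <- .resolve_field_map(field_map)
  pick <- function(row, keys) {
    for (k in keys) if (!is.null(row[[k]]) && !is.na(row[[k]][1])) return(row[[k]][1])
    NULL
  }

  out <- vector("list", length(rows))
  skipped <- bad
  for (i in seq_along(rows)) {
    row <- rows[[i]]
    id <- pick(row, fm$id)
    text <- pick(row, fm$text)
    ts_raw <- pick(row, fm$timestamp)
    if (is.null(id) || is.null(text) || !nzchar(trimws(as.character(text))) ||
        is.null(ts_raw)) {
      skipped <- skipped + 1L
      next
    }
    ts <- .parse_timestamp(as.character(ts_raw), tz)
    if (is.na(ts)) { skipped <- skipped + 1L; next }
    rt_flag <- pick(row, fm$is_retweet)
    text <- as.character(text)
    is_rt <- if (!is.null(rt_flag)) {
      tolower(as.character(rt_flag)) %in% c("true", "t", "1", "yes")
    } else {
      startsWith(text, "RT @")
    }
    rtc <- pick(row, fm$retweet_count)
    rtc <- if (is.null(rtc)) 0L else suppressWarnings(as.integer(rtc))
    if (is.na(rtc) || rtc < 0L) rtc <- 0L
    uid <- pick(row, fm$user_id)
    out[[i]] <- data.frame(
      id = as.character(id), timestamp = ts, text = text,
      user_id = if (is.null(uid)) NA_character_ else as.character(uid),
      is_retweet = is_rt, retweet_count = rtc,
      country_tag = country_tag, stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  recs <- if (length(out)) do.call(rbind, out) else .empty_records(country_tag)

  dup <- duplicated(recs$id)
  n_dup <- sum(dup)
  recs <- recs[!dup, , drop = FALSE]
  rownames(recs) <- NULL
  attr(recs, "n_skipped") <- skipped
  attr(recs, "n_duplicates") <- n_dup
  class(recs) <- c("tweet_records", "data.frame")
  recs
}

.empty_records <- function(country_tag = NA_character_) {
  data.frame(id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
             text = character(), user_id = character(), is_retweet = logical(),
             retweet_count = integer(), country_tag = character(),
             stringsAsFactors = FALSE)
}

.resolve_field_map <- function(field_map) {
  default <- list(
    id = c("id", "tweet_id", "status_id"),
    timestamp = c("timestamp", "date", "created_at"),
    text = c("text", "tweet", "full_text"),
    user_id = c("user_id", "username", "user"),
    is_retweet = c("is_retweet", "retweet"),
    retweet_count = c("retweet_count", "retweets_count", "nretweets")
  )
  if (is.null(field_map)) return(default)
  for (nm in names(field_map)) default[[nm]] <- c(field_map[[nm]], default[[nm]])
  default
}

.parse_timestamp <- function(x, tz = "UTC") {
  ts <- suppressWarnings(as.POSIXct(x, tz = tz,
                                    tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                                   "%Y-%m-%d %H:%M:%S",
                                                   "%Y-%m-%d")))
  ts
}

#' Keep records whose text matches any collection keyword
#'
#' Matching is case-insensitive substring matching, so off-topic uses of a
#' keyword are deliberately retained (a record only has to contain the
#' keyword, not be about it).  A leading `#` on a keyword is ignored, so
#' hashtag keywords match the bare word and vice versa.
#'
#' @param records A `tweet_records` table.
#' @param keywords Character vector of collection keywords (non-empty).
#' @return The matching subset, same class and column layout.
#' @export
filter_by_keywords <- function(records, keywords) {
  keywords <- unique(sub("^#", "", keywords))
  keywords <- keywords[nzchar(keywords)]
  if (!length(keywords)) stop("keyword set must be non-empty")
  txt <- tolower(records$text)
  keep <- rep(FALSE, length(txt))
  for (kw in tolower(keywords)) keep <- keep | grepl(kw, txt, fixed = TRUE)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Define a language-specific tokenizer
#'
#' Bundles the stopword list and the ordered cleaning rules applied before
#' whitespace tokenization.  Applying the resulting tokenizer to its own
#' re-joined output is a no-op (idempotence), which keeps preprocessing safe
#' to re-run.
#'
#' Available rules, applied in the order given: `"urls"` (strip http(s)/t.co
#' links), `"mentions"` (strip `@user` handles and `RT` markers), `"emoji"`
#' (strip non-letter symbols outside the basic multilingual letters),
#' `"nonletters"` (strip digits/punctuation; `#` is removed so hashtags fold
#' into plain words), `"lowercase"`.
#'
#' @param language Language identifier (informational; declared per stream).
#' @param stopwords Character vector of stopwords (removed post-tokenization).
#' @param rules Ordered character vector of cleaning rules.
#' @return A `tokenizer_spec` object.
#' @export
tokenizer_spec <- function(language = "en", stopwords = character(),
                           rules = c("urls", "mentions", "emoji",
                                     "nonletters", "lowercase")) {
  known <- c("urls", "mentions", "emoji", "nonletters", "lowercase")
  bad <- setdiff(rules, known)
  if (length(bad)) stop("unknown cleaning rule(s): ", paste(bad, collapse = ", "))
  structure(list(language = language, stopwords = tolower(stopwords),
                 rules = rules),
            class = "tokenizer_spec")
}

#' Clean and tokenize text
#'
#' Applies the spec's cleaning rules, splits on whitespace, and removes
#' stopwords and tokens with no letters.  Token order is preserved.
#'
#' @param text Character vector of raw texts.
#' @param spec A [tokenizer_spec()].
#' @return For a single input string, a character vector of tokens; for a
#'   longer input, a list of such vectors (one per element).
#' @export
preprocess_text <- function(text, spec) {
  if (!inherits(spec, "tokenizer_spec")) {
    stop("no tokenizer defined; supply a tokenizer_spec (language: ",
         if (is.character(spec)) spec else "unknown", ")")
  }
  toks <- lapply(as.character(text), .tokenize_one, spec = spec)
  if (length(toks) == 1L) toks[[1]] else toks
}

.tokenize_one <- function(x, spec) {
  if (is.na(x) || !nzchar(x)) return(character())
  for (rule in spec$rules) {
    x <- switch(rule,
      urls = gsub("(https?://\\S+)|(t\\.co/\\S+)", " ", x, perl = TRUE),
      mentions = gsub("(^|\\s)RT(\\s|$)", " ", gsub("@\\S+", " ", x), perl = TRUE),
      emoji = gsub("[^\\p{L}\\p{M}\\p{N}\\p{P}\\s]", " ", x, perl = TRUE),
      nonletters = gsub("[^\\p{L}\\p{M}\\s]", " ", x, perl = TRUE),
      lowercase = tolower(x)
    )
  }
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  toks <- toks[grepl("\\p{L}", toks, perl = TRUE)]
  toks[!(tolower(toks) %in% spec$stopwords)]
}

#' Aggregate records to a daily count series
#'
#' Bins records by local calendar date over a closed date window.  Days with
#' no records carry a zero; records outside the window are excluded and their
#' count attached as attribute `n_outside`.
#'
#' @param records A `tweet_records` table.
#' @param window Length-2 `Date` vector (first day, last day), inclusive.
#' @param tz Timezone used to localize timestamps before taking the date.
#' @return A `daily_series` object: list with `start_date`, `dates`, `counts`.
#' @export
build_daily_series <- function(records, window, tz = "UTC") {
  window <- as.Date(window)
  if (length(window) != 2L || is.na(window[1]) || is.na(window[2]) ||
      window[2] < window[1]) {
    stop("window must be two ordered dates")
  }
  days <- seq(window[1], window[2], by = "day")
  dates <- as.Date(format(records$timestamp, tz = tz, format = "%Y-%m-%d"))
  inside <- dates >= window[1] & dates <= window[2]
  tab <- table(factor(as.character(dates[inside]), levels = as.character(days)))
  s <- daily_series(window[1], as.integer(tab))
  attr(s, "n_outside") <- sum(!inside)
  s
}

#' Construct a daily series from counts
#'
#' @param start_date First calendar day.
#' @param counts Non-negative numeric vector, one value per consecutive day.
#' @return A `daily_series` object.
#' @export
daily_series <- function(start_date, counts) {
  start_date <- as.Date(start_date)
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative and non-missing")
  }
  structure(list(start_date = start_date,
                 dates = seq(start_date, by = "day", length.out = length(counts)),
                 counts = counts),
            class = "daily_series")
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series> %d days from %s, total %s\n",
              length(x$counts), format(x$start_date), format(sum(x$counts))))
  invisible(x)
}

#' @export
as.data.frame.daily_series <- function(x, ...) {
  data.frame(date = x$dates, count = x$counts)
}

#' Read a one-entry-per-line plain-text list (keywords, stopwords)
#'
#' Blank lines and lines starting with `#` followed by a space are kept as-is
#' except blank; the file is read as UTF-8.
#'
#' @param path File path.
#' @return Character vector.
#' @export
read_word_list <- function(path) {
  x <- readLines(path, warn = FALSE, encoding = "UTF-8")
  trimws(x[nzchar(trimws(x))])
}
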