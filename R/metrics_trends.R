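#' Tweet depth: retweets per original
#'
#' The ratio of the average number of retweets per day to the average number
#' of original tweets per day within a phase — a standardized cascade-depth
#' measure (higher means each original travels further).  Reported rounded
#' half-up to 2 decimals; 0 when there are no originals.
#'
#' @param avg_retweets_per_day,avg_original_per_day Non-negative reals.
#' @param digits Reporting precision (default 2; `NULL` for unrounded).
#' @return Scalar depth.
#' @export
tweet_depth <- function(avg_retweets_per_day, avg_original_per_day,
                        digits = 2L) {
  if (any(avg_retweets_per_day < 0) || any(avg_original_per_day < 0)) {
    stop("per-day averages must be non-negative")
  }
  depth <- ifelse(avg_original_per_day > 0,
                  avg_retweets_per_day / avg_original_per_day, 0)
  if (is.null(digits)) depth else round_half_up(depth, digits)
}

#' Round half away from zero
#'
#' Fixed-decimal rounding where a residue of exactly 5 always rounds up in
#' magnitude, matching how the reported tables are formatted (base `round()`
#' rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-phase summary statistics
#'
#' For each phase of a segmentation computes the total tweet count, average
#' distinct users per day, average original tweets and retweets per day
#' (totals divided by the number of calendar days in the phase, both ends
#' inclusive), and tweet depth.  Optional topic metadata (topic counts per
#' phase) is joined on `phase_id` when supplied.
#'
#' @param records A `tweet_records` table.
#' @param segmentation A `phase_segmentation`.
#' @param topic_meta Optional data.frame with `phase_id` plus columns such as
#'   `n_topics_perplexity`, `n_major_topics`, `n_final_topics`.
#' @param tz Timezone used to date the records.
#' @return data.frame, one row per phase, with the statistics above (depth
#'   rounded to 2 decimals, averages to 2 decimals).
#' @export
phase_stats <- function(records, segmentation, topic_meta = NULL, tz = "UTC") {
  dates <- as.Date(format(records$timestamp, tz = tz, format = "%Y-%m-%d"))
  rows <- lapply(seq_len(nrow(segmentation)), function(i) {
    lo <- segmentation$start[i]; hi <- segmentation$end[i]
    n_days <- as.integer(hi - lo) + 1L
    inph <- which(dates >= lo & dates <= hi)
    sub <- records[inph, , drop = FALSE]
    n_orig <- sum(!sub$is_retweet)
    n_rt <- sum(sub$is_retweet)
    users_per_day <- if (nrow(sub)) {
      mean(tapply(sub$user_id, factor(as.character(dates[inph]),
                                      levels = as.character(seq(lo, hi, by = "day"))),
                  function(u) length(unique(u[!is.na(u)])), default = 0L))
    } else 0
    avg_orig <- n_orig / n_days
    avg_rt <- n_rt / n_days
    data.frame(phase_id = segmentation$phase_id[i], start = lo, end = hi,
               n_days = n_days, total_tweets = nrow(sub),
               avg_users_per_day = round_half_up(users_per_day, 2L),
               avg_original_per_day = round_half_up(avg_orig, 2L),
               avg_retweets_per_day = round_half_up(avg_rt, 2L),
               tweet_depth = tweet_depth(avg_rt, avg_orig))
  })
  out <- do.call(rbind, rows)
  if (!is.null(topic_meta)) {
    out <- merge(out, topic_meta, by = "phase_id", all.x = TRUE, sort = TRUE)
  }
  class(out) <- c("phase_stats", "data.frame")
  out
}

#' Daily country-mention series
#'
#' Counts, per day and per country, the tweets whose text mentions any of the
#' country's name variants (case-insensitive substring).  A tweet counts at
#' most once per country regardless of how many times or in how many variants
#' the name appears, and can count toward several countries.
#'
#' @param records A `tweet_records` table.
#' @param name_dict Named list: country -> character vector of name variants
#'   (local language and/or English).
#' @param tz Timezone used to date the records.
#' @return data.frame `date` x one column per country with daily counts,
#'   covering the full record date range.
#' @export
country_mentions <- function(records, name_dict, tz = "UTC") {
  if (!length(name_dict)) stop("name dictionary must be non-empty")
  dates <- as.Date(format(records$timestamp, tz = tz, format = "%Y-%m-%d"))
  days <- seq(min(dates), max(dates), by = "day")
  txt <- tolower(records$text)
  out <- data.frame(date = days)
  for (country in names(name_dict)) {
    hit <- rep(FALSE, length(txt))
    for (v in tolower(name_dict[[country]])) {
      hit <- hit | grepl(v, txt, fixed = TRUE)
    }
    out[[country]] <- as.integer(
      table(factor(as.character(dates[hit]), levels = as.character(days))))
  }
  out
}

#' Daily topic diversity from theme weights
#'
#' Two per-day measures over a daily theme-weight table (see
#' [apply_theme_labels()]): the number of themes with positive weight, and
#' the Shannon entropy of the theme-weight distribution normalized by
#' `log(number of themes in the catalog)` so that 1 means all themes equally
#' active and 0 a single active theme.  Days with zero total weight have no
#' defined diversity and are emitted as `NA`.
#'
#' @param theme_weights data.frame: `date` column plus one numeric column per
#'   theme.
#' @return data.frame `date`, `total_weight`, `n_themes`, `entropy`.
#' @export
topic_diversity <- function(theme_weights) {
  w <- as.matrix(theme_weights[, setdiff(names(theme_weights), "date"),
                               drop = FALSE])
  n_cat <- ncol(w)
  total <- rowSums(w)
  n_active <- rowSums(w > 0)
  entropy <- vapply(seq_len(nrow(w)), function(i) {
    if (total[i] <= 0) return(NA_real_)
    p <- w[i, ] / total[i]
    p <- p[p > 0]
    if (n_cat < 2L) return(0)
    -sum(p * log(p)) / log(n_cat)
  }, numeric(1))
  data.frame(date = theme_weights$date, total_weight = total,
             n_themes = ifelse(total > 0, n_active, NA_integer_),
             entropy = entropy)
}
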