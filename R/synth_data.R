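#' Describe one volume surge
#'
#' A surge models a triggering event (e.g. a national spike in confirmed
#' cases): the expected daily rate rises log-linearly from baseline to
#' `peak_multiplier` times baseline over `rise_days`, then decays
#' log-linearly back over `decay_days`.
#'
#' @param onset Onset date (last day at baseline before the rise).
#' @param peak_multiplier Peak rate relative to baseline, > 1.
#' @param rise_days,decay_days Positive integers.
#' @return A `surge_event` object.
#' @export
surge_event <- function(onset, peak_multiplier = 10, rise_days = 5L,
                        decay_days = 10L) {
  if (peak_multiplier <= 1) stop("invalid surge field: peak_multiplier must be > 1")
  if (rise_days < 1L) stop("invalid surge field: rise_days must be >= 1")
  if (decay_days < 1L) stop("invalid surge field: decay_days must be >= 1")
  structure(list(onset = as.Date(onset), peak_multiplier = peak_multiplier,
                 rise_days = as.integer(rise_days),
                 decay_days = as.integer(decay_days)),
            class = "surge_event")
}

#' Configuration for the synthetic tweet-stream generator
#'
#' Defaults emulate one country stream over the first quarter of 2020 (the
#' kind of window the phase pipeline is built for): a modest baseline, a
#' first long gradual surge triggered by the first confirmed case, two later
#' sharper surges (later triggering events hit an already-primed audience
#' and attention rises faster), a small synthetic vocabulary with a few
#' well-separated topics, phase-dependent retweet rates, and occasional
#' country-name mentions.
#'
#' The ground-truth anchor date (`gt_date` in the emitted truth) models the
#' official first-case announcement, which trails the earliest rise of
#' chatter by `gt_lag` days: thresholds are therefore calibrated a few days
#' into the first climb, where velocity is already substantial while
#' acceleration is still moderate.  With the default shapes the later,
#' steeper onsets then satisfy the detection condition (velocity below, and
#' acceleration above, the calibrated thresholds) on the day before each
#' onset — verified on the noiseless rate curve, so every onset is
#' detectable in principle and recovery failures can be attributed to
#' sampling noise.
#'
#' @param window Length-2 date vector, inclusive.
#' @param baseline_rate Expected tweets/day away from surges.
#' @param surges List of [surge_event()]s, all inside the window (may be
#'   empty for a flat stream, e.g. when only the topic machinery is needed).
#' @param gt_lag Days between the first surge onset and the ground-truth
#'   announcement date (default 4).
#' @param vocab_size Number of synthetic word types (letter-only tokens
#'   `tokaaa`, `tokbaa`, ..., at most 17576).
#' @param k_true Number of generating topics.
#' @param topic_word_concentration Symmetric Dirichlet parameter for each
#'   topic's word distribution (small = sharply separated topics).
#' @param doc_topic_concentration Per-phase Dirichlet scale for per-document
#'   topic mixtures (scalar recycled, or one value per phase; small = nearly
#'   single-topic documents).
#' @param tokens_per_doc Mean document length in tokens.
#' @param tokens_dispersion Negative-binomial size parameter for document
#'   length (`Inf` = Poisson lengths).
#' @param phase_mix Optional matrix (phases x `k_true`) of mean topic-mixture
#'   weights per phase, rows summing to 1.  `NULL` (default) draws each
#'   phase's mixture from a flat Dirichlet, so phases emphasize different
#'   topics; pass a balanced matrix for corpora where all topics should be
#'   equally represented.
#' @param retweet_prob Probability a record is a retweet, per phase
#'   (recycled across phases).  The default rises sharply in the first surge
#'   phase and relaxes afterwards, so tweet depth peaks when public
#'   attention soars.
#' @param mention_prob Named vector: probability that an original tweet
#'   mentions each country by name.
#' @param n_users User pool size.
#' @param seed Integer seed; the whole stream is a pure function of the
#'   config including this seed.
#' @return A validated `generator_config` object.
#' @export
generator_config <- function(window = as.Date(c("2020-01-01", "2020-03-31")),
                             baseline_rate = 150,
                             surges = list(
                               surge_event("2020-01-20", peak_multiplier = 30,
                                           rise_days = 12, decay_days = 10),
                               surge_event("2020-02-19", peak_multiplier = 20,
                                           rise_days = 3, decay_days = 10),
                               surge_event("2020-03-10", peak_multiplier = 20,
                                           rise_days = 3, decay_days = 10)),
                             gt_lag = 4L,
                             vocab_size = 500L,
                             k_true = 3L,
                             topic_word_concentration = 0.05,
                             doc_topic_concentration = 0.1,
                             tokens_per_doc = 12,
                             tokens_dispersion = Inf,
                             phase_mix = NULL,
                             retweet_prob = c(0.3, 0.75, 0.65, 0.55),
                             mention_prob = c(china = 0.05, usa = 0.03,
                                              italy = 0.02),
                             n_users = 500L,
                             seed = 1L) {
  window <- as.Date(window)
  if (baseline_rate < 0) stop("invalid config field: baseline_rate must be >= 0")
  if (vocab_size < 2L || vocab_size > 17576L) {
    stop("invalid config field: vocab_size must be in [2, 17576]")
  }
  if (k_true < 1L) stop("invalid config field: k_true must be >= 1")
  if (topic_word_concentration <= 0 || any(doc_topic_concentration <= 0)) {
    stop("invalid config field: concentrations must be positive")
  }
  if (any(retweet_prob < 0 | retweet_prob > 1)) {
    stop("invalid config field: retweet_prob must be in [0, 1]")
  }
  if (length(mention_prob) && (is.null(names(mention_prob)) ||
                               any(mention_prob < 0 | mention_prob > 1))) {
    stop("invalid config field: mention_prob must be a named vector in [0, 1]")
  }
  for (s in surges) {
    if (!inherits(s, "surge_event")) stop("invalid config field: surges must be surge_event objects")
    if (s$onset < window[1] || s$onset + s$rise_days + s$decay_days > window[2]) {
      stop("invalid config field: surge at ", format(s$onset),
           " does not fit inside the window")
    }
  }
  if (gt_lag < 0) stop("invalid config field: gt_lag must be >= 0")
  structure(list(window = window, baseline_rate = baseline_rate,
                 surges = surges, gt_lag = as.integer(gt_lag),
                 vocab_size = as.integer(vocab_size),
                 k_true = as.integer(k_true),
                 topic_word_concentration = topic_word_concentration,
                 doc_topic_concentration = doc_topic_concentration,
                 tokens_per_doc = tokens_per_doc,
                 tokens_dispersion = tokens_dispersion,
                 phase_mix = phase_mix,
                 retweet_prob = retweet_prob, mention_prob = mention_prob,
                 n_users = as.integer(n_users), seed = as.integer(seed)),
            class = "generator_config")
}

# Deterministic expected-rate curve implied by a config.
.rate_curve <- function(config) {
  days <- seq(config$window[1], config$window[2], by = "day")
  log_mult <- rep(0, length(days))
  for (s in config$surges) {
    j <- as.numeric(days - s$onset)
    up <- j >= 0 & j <= s$rise_days
    down <- j > s$rise_days & j <= s$rise_days + s$decay_days
    log_mult[up] <- log_mult[up] +
      (j[up] / s$rise_days) * log(s$peak_multiplier)
    log_mult[down] <- log_mult[down] +
      (1 - (j[down] - s$rise_days) / s$decay_days) * log(s$peak_multiplier)
  }
  data.frame(date = days, rate = config$baseline_rate * exp(log_mult))
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  x / rowSums(x)
}

#' Generate a seeded synthetic tweet stream with ground truth
#'
#' Daily record counts are Poisson draws around the config's rate curve.
#' Each original document draws a per-document topic mixture from the
#' phase's Dirichlet, then tokens from the corresponding topic-word
#' distributions; country names are appended with the configured mention
#' probabilities.  Retweets copy the text of a uniformly chosen earlier
#' original (same stream) and increment its retweet count.  The same config
#' (including seed) always yields the identical stream.
#'
#' @param config A [generator_config()].
#' @return List with `records` (a `tweet_records` data.frame) and `truth`:
#'   `onsets` (surge onset dates), `rate` (per-day expected rate),
#'   `topic_word` (k_true x vocab matrix, columns named by token),
#'   `doc_topics` (data.frame `id`, `topic` for originals), `phase_of_day`,
#'   `daily_counts`.
#' @export
generate_stream <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  rc <- .rate_curve(config)
  n_days <- nrow(rc)
  onsets <- as.Date(vapply(config$surges, function(s) format(s$onset),
                           character(1)))
  phase_of_day <- findInterval(as.numeric(rc$date), as.numeric(sort(onsets)))
  n_phases <- length(onsets) + 1L
  dconc <- rep_len(config$doc_topic_concentration, n_phases)
  rt_prob <- rep_len(config$retweet_prob, n_phases)

  # letter-only synthetic word types so streams survive the standard
  # cleaning rules unchanged
  g <- expand.grid(a = letters, b = letters, c = letters,
                   stringsAsFactors = FALSE)
  vocab_tokens <- paste0("tok", g$a, g$b, g$c)[seq_len(config$vocab_size)]
  topic_word <- .rdirichlet(config$k_true,
                            rep(config$topic_word_concentration,
                                config$vocab_size))
  colnames(topic_word) <- vocab_tokens
  # per-phase mean topic mixture (phases emphasize different topics)
  phase_mix <- if (is.null(config$phase_mix)) {
    .rdirichlet(n_phases, rep(1, config$k_true))
  } else {
    m <- matrix(config$phase_mix, ncol = config$k_true)
    m <- m / rowSums(m)
    m[rep_len(seq_len(nrow(m)), n_phases), , drop = FALSE]
  }

  daily_counts <- stats::rpois(n_days, rc$rate)
  n_total <- sum(daily_counts)
  users <- sprintf("u%04d", seq_len(config$n_users))
  countries <- names(config$mention_prob)

  day_of_rec <- rep(seq_len(n_days), daily_counts)
  ph_of_rec <- phase_of_day[day_of_rec] + 1L
  secs <- floor(stats::runif(n_total, 0, 86400))
  secs <- unlist(lapply(split(secs, day_of_rec), sort), use.names = FALSE)
  stamps <- as.numeric(as.POSIXct(paste(rc$date[day_of_rec], "00:00:00"),
                                  tz = "UTC")) + secs
  ids <- sprintf("t%07d", seq_len(n_total))
  uid <- users[sample.int(config$n_users, n_total, replace = TRUE)]

  # retweet flags; the first record is always an original so a source pool
  # exists for every later retweet
  is_rt <- stats::runif(n_total) < rt_prob[ph_of_rec]
  if (n_total) is_rt[1] <- FALSE
  orig_idx <- which(!is_rt)
  n_orig <- length(orig_idx)

  # original documents: lengths, mixtures, topics, tokens
  n_tok <- if (is.finite(config$tokens_dispersion)) {
    stats::rnbinom(n_orig, size = config$tokens_dispersion,
                   mu = config$tokens_per_doc)
  } else stats::rpois(n_orig, config$tokens_per_doc)
  n_tok <- pmax(2L, n_tok)
  theta <- matrix(0, n_orig, config$k_true)
  for (ph in unique(ph_of_rec[orig_idx])) {
    at <- which(ph_of_rec[orig_idx] == ph)
    theta[at, ] <- .rdirichlet(length(at),
                               dconc[ph] * config$k_true * phase_mix[ph, ])
  }
  doc_of_tok <- rep(seq_len(n_orig), n_tok)
  cum_theta <- theta %*% upper.tri(diag(config$k_true), diag = TRUE)
  u <- stats::runif(length(doc_of_tok))
  z <- 1L + rowSums(u > cum_theta[doc_of_tok, , drop = FALSE])
  words <- character(length(z))
  for (k in unique(z)) {
    at <- z == k
    words[at] <- vocab_tokens[sample.int(config$vocab_size, sum(at),
                                         replace = TRUE,
                                         prob = topic_word[k, ])]
  }
  doc_text <- vapply(split(words, doc_of_tok), paste, character(1),
                     collapse = " ")
  if (length(countries)) {
    hit <- matrix(stats::runif(n_orig * length(countries)), n_orig) <
      matrix(config$mention_prob, n_orig, length(countries), byrow = TRUE)
    extra <- vapply(seq_len(n_orig), function(i) {
      if (any(hit[i, ])) paste(c("", countries[hit[i, ]]), collapse = " ") else ""
    }, character(1))
    doc_text <- paste0(doc_text, extra)
  }

  texts <- character(n_total)
  true_topic <- integer(n_total)
  texts[orig_idx] <- doc_text
  true_topic[orig_idx] <- max.col(theta, ties.method = "first")

  # retweets copy a uniformly chosen earlier original
  rt_count <- integer(n_total)
  rt_idx <- which(is_rt)
  if (length(rt_idx)) {
    n_pool <- cumsum(!is_rt)[rt_idx]   # originals strictly before each retweet
    src <- orig_idx[ceiling(stats::runif(length(rt_idx)) * n_pool)]
    texts[rt_idx] <- texts[src]
    true_topic[rt_idx] <- true_topic[src]
    rt_count <- tabulate(src, nbins = n_total)
  }

  records <- data.frame(
    id = ids, timestamp = as.POSIXct(stamps, origin = "1970-01-01", tz = "UTC"),
    text = texts, user_id = uid, is_retweet = is_rt,
    retweet_count = rt_count, country_tag = "synthetic",
    stringsAsFactors = FALSE)
  class(records) <- c("tweet_records", "data.frame")

  surge_onsets <- sort(onsets)
  gt_date <- if (length(surge_onsets)) surge_onsets[1] + config$gt_lag else NULL
  phase_starts <- if (length(surge_onsets)) {
    c(gt_date, surge_onsets[-1])
  } else as.Date(character())

  list(records = records,
       truth = list(onsets = phase_starts,
                    surge_onsets = surge_onsets,
                    gt_date = gt_date,
                    rate = rc,
                    topic_word = topic_word,
                    phase_mix = phase_mix,
                    doc_topics = data.frame(id = ids, topic = true_topic - 1L,
                                            is_retweet = is_rt,
                                            stringsAsFactors = FALSE),
                    phase_of_day = data.frame(date = rc$date,
                                              phase = phase_of_day),
                    daily_counts = daily_series(config$window[1],
                                                daily_counts)))
}

# Greedy one-to-one matching of fitted topic rows to true rows by cosine.
.match_topics <- function(fitted, truth) {
  cos <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  sim <- outer(seq_len(nrow(fitted)), seq_len(nrow(truth)),
               Vectorize(function(i, j) cos(fitted[i, ], truth[j, ])))
  pairs <- list()
  while (any(is.finite(sim))) {
    ij <- arrayInd(which.max(sim), dim(sim))
    pairs[[length(pairs) + 1L]] <- c(fitted = ij[1], truth = ij[2],
                                     cosine = sim[ij[1], ij[2]])
    sim[ij[1], ] <- -Inf
    sim[, ij[2]] <- -Inf
  }
  do.call(rbind, pairs)
}

#' Score pipeline recovery against generator ground truth
#'
#' Matches detected phase starts to true surge onsets greedily by date
#' distance and reports the recall within a +/- 1 day tolerance.  When a
#' fitted model is supplied, fitted topics are matched one-to-one to the
#' generating topics greedily by cosine similarity (on the shared
#' vocabulary) and the mean matched cosine reported; when per-record
#' assignments are supplied as well, assignment accuracy after that topic
#' alignment is reported.
#'
#' @param truth The `truth` component of [generate_stream()].
#' @param detected_starts Dates from [detect_phase_starts()].
#' @param model Optional fitted `lda_model`.
#' @param assignments Optional data.frame `id`, `topic` (fitted topics).
#' @param tolerance_days Match tolerance for onsets (default 1).
#' @return List with `onset_recall`, and when available `topic_cosine`
#'   (mean matched cosine), `assignment_accuracy`, and the `topic_map`.
#' @export
evaluate_recovery <- function(truth, detected_starts, model = NULL,
                              assignments = NULL, tolerance_days = 1) {
  onsets <- sort(truth$onsets)
  det <- sort(unique(as.Date(detected_starts)))
  matched <- 0L
  avail <- det
  for (o in seq_along(onsets)) {
    if (!length(avail)) break
    dist <- abs(as.numeric(avail - onsets[o]))
    i <- which.min(dist)
    if (dist[i] <= tolerance_days) {
      matched <- matched + 1L
      avail <- avail[-i]
    }
  }
  out <- list(onset_recall = matched / length(onsets))

  if (!is.null(model)) {
    shared <- intersect(model$vocab$token, colnames(truth$topic_word))
    fitted <- model$topic_word[, match(shared, model$vocab$token) ,
                               drop = FALSE]
    true_tw <- truth$topic_word[, shared, drop = FALSE]
    m <- .match_topics(fitted, true_tw)
    out$topic_cosine <- mean(m[, "cosine"])
    out$topic_map <- m
    if (!is.null(assignments)) {
      map <- stats::setNames(as.integer(m[, "truth"]) - 1L,
                             as.integer(m[, "fitted"]) - 1L)
      joined <- merge(assignments, truth$doc_topics, by = "id",
                      suffixes = c("_fit", "_true"))
      joined <- joined[!is.na(joined$topic_fit), , drop = FALSE]
      pred <- map[as.character(joined$topic_fit)]
      out$assignment_accuracy <- mean(pred == joined$topic_true)
    }
  }
  out
}
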