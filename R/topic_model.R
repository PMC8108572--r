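#' Build a phase vocabulary with a minimum-frequency floor
#'
#' Counts token occurrences across the phase corpus and keeps every token
#' occurring at least `min_count` times (the boundary is inclusive: a token
#' seen exactly `min_count` times is kept).  Integer ids are dense, starting
#' at 0, assigned in order of first occurrence in the corpus.
#'
#' @param docs List of character vectors, one per document.
#' @param min_count Minimum total corpus frequency for a token to enter the
#'   vocabulary (default 20).
#' @return A `lda_vocabulary`: data.frame with `token`, `id`, `count`.
#' @export
build_vocabulary <- function(docs, min_count = 20L) {
  if (!length(docs)) stop("corpus is empty")
  all_tokens <- unlist(docs, use.names = FALSE)
  if (!length(all_tokens)) stop("corpus has no tokens")
  first_seen <- !duplicated(all_tokens)
  order_tokens <- all_tokens[first_seen]
  counts <- table(factor(all_tokens, levels = order_tokens))
  keep <- counts >= min_count
  if (!any(keep)) {
    stop("vocabulary is empty after the min_count = ", min_count,
         " filter; consider a lower min_count")
  }
  vocab <- data.frame(token = names(counts)[keep],
                      id = seq_len(sum(keep)) - 1L,
                      count = as.integer(counts[keep]),
                      stringsAsFactors = FALSE)
  class(vocab) <- c("lda_vocabulary", "data.frame")
  attr(vocab, "min_count") <- as.integer(min_count)
  vocab
}

# Encode docs as 0-based id vectors against a vocabulary; out-of-vocabulary
# tokens are dropped.
.encode_docs <- function(docs, vocab) {
  lookup <- stats::setNames(vocab$id, vocab$token)
  lapply(docs, function(d) {
    ids <- unname(lookup[d])
    as.integer(ids[!is.na(ids)])
  })
}

#' Fit a latent Dirichlet allocation model by collapsed Gibbs sampling
#'
#' Runs `epochs` full Gibbs sweeps over the token-topic assignments and
#' returns point estimates of the topic-word matrix (K rows summing to 1)
#' and per-document topic distributions (rows summing to 1), smoothed by the
#' symmetric priors.  Documents left empty by vocabulary filtering are
#' excluded from sampling and carry a uniform `doc_topic` row flagged in
#' `empty_docs`.
#'
#' Identical `seed`, corpus and parameters reproduce the fit bit for bit.
#'
#' @param docs List of character vectors (tokenized documents).
#' @param vocab A [build_vocabulary()] result.
#' @param K Number of topics, `2 <= K <= length(docs)`.
#' @param epochs Gibbs sweeps (default 100).
#' @param seed Integer RNG seed.
#' @param alpha Symmetric document-topic prior (default `1/K`).
#' @param beta Symmetric topic-word prior (default 0.01).
#' @param doc_ids Optional record ids aligned with `docs`.
#' @return An `lda_model`: list with `K`, `topic_word` (K x V), `doc_topic`
#'   (N x K), `vocab`, `doc_ids`, `empty_docs`, and the fitting parameters.
#' @export
fit_lda <- function(docs, vocab, K, epochs = 100L, seed = 1L,
                    alpha = 1 / K, beta = 0.01, doc_ids = NULL) {
  n_docs <- length(docs)
  if (K < 2L || K > n_docs) {
    stop("K must satisfy 2 <= K <= number of documents (", n_docs, ")")
  }
  enc <- .encode_docs(docs, vocab)
  lens <- lengths(enc)
  nonempty <- which(lens > 0L)
  if (!length(nonempty)) stop("all documents are empty after vocabulary filtering")
  tokens <- unlist(enc[nonempty], use.names = FALSE)
  doc_index <- rep(seq_along(nonempty) - 1L, lens[nonempty])
  V <- nrow(vocab)

  set.seed(seed)
  fit <- .lda_gibbs(tokens, doc_index, length(nonempty), V, as.integer(K),
                    as.integer(epochs), alpha, beta)

  doc_topic <- matrix(1 / K, nrow = n_docs, ncol = K)
  doc_topic[nonempty, ] <- fit$doc_topic
  structure(list(K = as.integer(K), topic_word = fit$topic_word,
                 doc_topic = doc_topic, vocab = vocab,
                 doc_ids = doc_ids, empty_docs = which(lens == 0L),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 alpha = alpha, beta = beta),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> K = %d, V = %d, %d docs, %d epochs, seed %d\n",
              x$K, ncol(x$topic_word), nrow(x$doc_topic), x$epochs, x$seed))
  invisible(x)
}

#' Perplexity of a model on a corpus
#'
#' `exp(-L/N)` where `L` is the total log-likelihood of the corpus tokens
#' under the per-document mixtures (`p(w | d) = sum_k theta_dk * phi_kw`)
#' and `N` the total token count.  Lower is better; a uniform model over a
#' vocabulary of size V scores exactly V.
#'
#' @param model An `lda_model` (or compatible list with `topic_word`,
#'   `doc_topic`, `vocab`).
#' @param docs Corpus as a list of character vectors; out-of-vocabulary
#'   tokens are ignored.
#' @return Positive scalar perplexity.
#' @export
compute_perplexity <- function(model, docs) {
  if (!length(docs)) stop("corpus is empty")
  enc <- .encode_docs(docs, model$vocab)
  lens <- lengths(enc)
  use <- which(lens > 0L)
  if (!length(use)) stop("no in-vocabulary tokens in the corpus")
  loglik <- 0
  n_tokens <- 0
  for (d in use) {
    theta <- model$doc_topic[d, , drop = TRUE]
    pw <- as.numeric(theta %*% model$topic_word)   # length V
    loglik <- loglik + sum(log(pw[enc[[d]] + 1L]))
    n_tokens <- n_tokens + lens[d]
  }
  exp(-loglik / n_tokens)
}

#' Select the topic count by minimum perplexity
#'
#' Fits one model per candidate K on a grid and returns the K with the
#' smallest perplexity (ties broken toward the smaller K) together with the
#' full perplexity curve for audit.  By default perplexity is measured on
#' the training corpus; set `holdout` to a fraction in (0, 1) to score on a
#' held-out document split instead.
#'
#' @param docs List of tokenized documents.
#' @param vocab A [build_vocabulary()] result.
#' @param k_min,k_max Grid bounds (defaults 2 and 50).
#' @param k_step Grid step (default 1).
#' @param epochs,seed,alpha,beta Passed to [fit_lda()]; `alpha = NULL` means
#'   `1/K` for each candidate.
#' @param holdout Fraction of documents held out for scoring (0 = none).
#' @return List with `K_star`, `curve` (data.frame `K`, `perplexity`), and
#'   `model` (the refitted winner).
#' @export
select_topic_count <- function(docs, vocab, k_min = 2L, k_max = 50L,
                               k_step = 1L, epochs = 100L, seed = 1L,
                               alpha = NULL, beta = 0.01, holdout = 0) {
  if (k_min < 2L) stop("k_min must be at least 2")
  if (k_max < k_min) stop("k_max must be >= k_min")
  if (length(docs) < k_min) stop("fewer documents than k_min topics")
  grid <- seq(as.integer(k_min), as.integer(k_max), by = as.integer(k_step))
  grid <- grid[grid <= length(docs)]

  train_idx <- seq_along(docs)
  score_docs <- docs
  if (holdout > 0) {
    set.seed(seed)
    n_hold <- max(1L, floor(holdout * length(docs)))
    hold_idx <- sample(seq_along(docs), n_hold)
    train_idx <- setdiff(seq_along(docs), hold_idx)
    score_docs <- docs[hold_idx]
  }

  perp <- vapply(grid, function(K) {
    m <- fit_lda(docs[train_idx], vocab, K, epochs = epochs, seed = seed,
                 alpha = if (is.null(alpha)) 1 / K else alpha, beta = beta)
    if (holdout > 0) .holdout_perplexity(m, score_docs) else
      compute_perplexity(m, score_docs)
  }, numeric(1))

  K_star <- grid[which.min(perp)]   # which.min takes the first minimum, so
                                    # ties break toward the smaller K
  best <- fit_lda(docs, vocab, K_star, epochs = epochs, seed = seed,
                  alpha = if (is.null(alpha)) 1 / K_star else alpha,
                  beta = beta)
  list(K_star = K_star,
       curve = data.frame(K = grid, perplexity = perp),
       model = best)
}

# Held-out perplexity by document completion: each held-out document's
# topic mixture is estimated (EM under the fitted topic-word matrix) from
# the odd-position tokens only, and the even-position tokens are scored
# under that mixture.  Estimating theta on the same tokens that are scored
# would reward extra topics unconditionally; completion makes surplus
# topics pay on the unseen half.
.holdout_perplexity <- function(model, docs) {
  enc <- .encode_docs(docs, model$vocab)
  enc <- enc[lengths(enc) >= 2L]
  if (!length(enc)) stop("no scorable held-out documents (need >= 2 in-vocabulary tokens)")
  K <- model$K
  loglik <- 0
  n_tokens <- 0
  for (ids in enc) {
    est <- ids[seq_along(ids) %% 2L == 1L]
    score <- ids[seq_along(ids) %% 2L == 0L]
    phi_est <- model$topic_word[, est + 1L, drop = FALSE]   # K x n_est
    theta <- rep(1 / K, K)
    for (it in 1:25) {
      resp <- phi_est * theta
      resp <- sweep(resp, 2, colSums(resp), "/")
      theta_new <- (rowSums(resp) + model$alpha) /
        (ncol(resp) + K * model$alpha)
      if (max(abs(theta_new - theta)) < 1e-8) { theta <- theta_new; break }
      theta <- theta_new
    }
    loglik <- loglik + sum(log(as.numeric(
      theta %*% model$topic_word[, score + 1L, drop = FALSE])))
    n_tokens <- n_tokens + length(score)
  }
  exp(-loglik / n_tokens)
}

#' Dominant topic per document
#'
#' The argmax of each document-topic distribution; ties go to the lowest
#' topic id.  Documents that were empty after vocabulary filtering get `NA`.
#'
#' @param model An `lda_model`.
#' @param doc_ids Optional ids to attach (defaults to the ids stored at fit
#'   time, else the document index).
#' @return data.frame with `id` and `topic` (0-based topic ids).
#' @export
assign_topics <- function(model, doc_ids = NULL) {
  topics <- max.col(model$doc_topic, ties.method = "first") - 1L
  if (length(model$empty_docs)) topics[model$empty_docs] <- NA_integer_
  ids <- doc_ids %||% model$doc_ids %||% seq_len(nrow(model$doc_topic))
  data.frame(id = ids, topic = topics, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split tokenized records into per-phase corpora
#'
#' @param records A `tweet_records` table.
#' @param tokens List of token vectors aligned with `records` rows (e.g. from
#'   [preprocess_text()]).
#' @param segmentation A `phase_segmentation`.
#' @param tz Timezone used to date the records.
#' @param dedup_retweets If `TRUE`, retweet records are dropped before corpus
#'   construction so duplicated texts do not dominate the topics.
#' @return Named list (one element per phase id) of `phase_corpus` objects:
#'   lists with `phase_id`, `docs`, `ids`.
#' @export
build_phase_corpora <- function(records, tokens, segmentation, tz = "UTC",
                                dedup_retweets = FALSE) {
  stopifnot(length(tokens) == nrow(records))
  dates <- as.Date(format(records$timestamp, tz = tz, format = "%Y-%m-%d"))
  keep <- rep(TRUE, nrow(records))
  if (dedup_retweets) keep <- !records$is_retweet
  lapply(stats::setNames(seq_len(nrow(segmentation)), segmentation$phase_id),
         function(i) {
    inph <- keep & dates >= segmentation$start[i] & dates <= segmentation$end[i]
    structure(list(phase_id = segmentation$phase_id[i],
                   docs = tokens[inph], ids = records$id[inph]),
              class = "phase_corpus")
  })
}
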