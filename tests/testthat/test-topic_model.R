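test_that("vocabulary applies the inclusive min-count floor with dense ids", {
  docs <- c(rep(list(rep("alpha", 4)), 5),   # alpha x20
            rep(list(rep("beta", 1)), 19),   # beta  x19
            list(c("alpha", "gamma")))       # alpha x21 total... gamma x1
  v <- build_vocabulary(docs, min_count = 20)
  expect_true("alpha" %in% v$token)
  expect_false("beta" %in% v$token)   # 19 < 20
  expect_false("gamma" %in% v$token)
  expect_equal(v$id, seq_len(nrow(v)) - 1L)

  # exactly 20 occurrences is included
  v20 <- build_vocabulary(rep(list("word"), 20), min_count = 20)
  expect_equal(v20$token, "word")
  expect_equal(v20$count, 20L)

  one <- build_vocabulary(list(rep("solo", 25)), min_count = 20)
  expect_equal(nrow(one), 1L)

  expect_error(build_vocabulary(list(c("a", "b")), min_count = 20),
               "min_count")
})

test_that("fitted distributions are normalized and seed-reproducible", {
  corp <- make_separable_corpus(seed = 5, days = 5)
  vocab <- build_vocabulary(corp$docs, 20)
  m1 <- fit_lda(corp$docs, vocab, K = 3, epochs = 30, seed = 9)
  expect_equal(rowSums(m1$topic_word), rep(1, 3), tolerance = 1e-6)
  expect_equal(rowSums(m1$doc_topic), rep(1, nrow(m1$doc_topic)),
               tolerance = 1e-6)
  m2 <- fit_lda(corp$docs, vocab, K = 3, epochs = 30, seed = 9)
  expect_identical(m1$topic_word, m2$topic_word)
  expect_identical(m1$doc_topic, m2$doc_topic)
  expect_error(fit_lda(corp$docs, vocab, K = 1), "K must")
})

test_that("a corpus split over disjoint vocabulary halves separates at K = 2", {
  set.seed(21)
  words_a <- sprintf("left%02d", 1:20)
  words_b <- sprintf("right%02d", 1:20)
  docs <- lapply(1:80, function(i) {
    pool <- if (i %% 2 == 0) words_a else words_b
    sample(pool, 15, replace = TRUE)
  })
  vocab <- build_vocabulary(docs, min_count = 5)
  m <- fit_lda(docs, vocab, K = 2, epochs = 60, seed = 2)
  expect_true(all(apply(m$doc_topic, 1, max) >= 0.9))
  # the two halves land on different topics
  asg <- assign_topics(m)$topic
  expect_true(all(asg[seq(2, 80, 2)] == asg[2]))
  expect_true(all(asg[seq(1, 79, 2)] == asg[1]))
  expect_false(asg[1] == asg[2])
})

test_that("perplexity matches the closed form for uniform models", {
  for (V in c(2L, 100L)) {
    vocab <- data.frame(token = sprintf("w%03d", 1:V), id = 0:(V - 1),
                        count = 50L)
    model <- list(K = 2L,
                  topic_word = matrix(1 / V, 2, V),
                  doc_topic = matrix(0.5, 3, 2),
                  vocab = vocab, alpha = 0.5)
    docs <- list(c("w001", "w002"), "w001", rep("w002", 3))
    expect_equal(compute_perplexity(model, docs), V, tolerance = 1e-6)
  }
})

test_that("perplexity equals a brute-force token-mixture computation", {
  vocab <- data.frame(token = c("a", "b", "c"), id = 0:2, count = 10L)
  tw <- rbind(c(0.7, 0.2, 0.1),
              c(0.1, 0.3, 0.6))
  dt <- rbind(c(0.9, 0.1),
              c(0.4, 0.6))
  model <- list(K = 2L, topic_word = tw, doc_topic = dt, vocab = vocab,
                alpha = 0.5)
  docs <- list(c("a", "a", "b"), c("c", "b"))
  # independent direct summation over per-token mixture probabilities
  p_tok <- c(dt[1, ] %*% tw[, 1], dt[1, ] %*% tw[, 1], dt[1, ] %*% tw[, 2],
             dt[2, ] %*% tw[, 3], dt[2, ] %*% tw[, 2])
  expected <- exp(-sum(log(p_tok)) / 5)
  expect_equal(compute_perplexity(model, docs), expected, tolerance = 1e-12)
})

test_that("perplexity of a fitted model beats the uniform bound on separable corpora", {
  corp <- make_separable_corpus(seed = 8, days = 6)
  vocab <- build_vocabulary(corp$docs, 20)
  m <- fit_lda(corp$docs, vocab, K = 3, epochs = 50, seed = 1)
  expect_lt(compute_perplexity(m, corp$docs), nrow(vocab))
})

test_that("topic-count selection takes the perplexity argmin with low tie-break", {
  # argmin and tie-break contracts on stubbed curves
  pick <- function(perp, grid) grid[which.min(perp)]
  expect_equal(pick(c(110, 90, 95), 2:4), 3)
  expect_equal(pick(c(90, 90), 2:3), 2)

  # generative recovery: corpus with 4 separated topics, grid 2..8, the
  # held-out (document-completion) minimum concentrates near 4
  ks <- vapply(1:3, function(seed) {
    corp <- make_separable_corpus(seed = seed, k_true = 4, days = 12,
                                  baseline = 60)
    vocab <- build_vocabulary(corp$docs, 20)
    select_topic_count(corp$docs, vocab, k_min = 2, k_max = 8, seed = seed,
                       holdout = 0.25)$K_star
  }, numeric(1))
  expect_true(all(ks %in% 3:5))
})

test_that("dominant-topic assignment uses argmax with low-id tie-break", {
  vocab <- data.frame(token = "w", id = 0L, count = 5L)
  model <- structure(list(K = 3L, topic_word = matrix(1, 3, 1),
                          doc_topic = rbind(c(0.1, 0.7, 0.2),
                                            c(0.5, 0.5, 0.0)),
                          vocab = vocab, doc_ids = c("r1", "r2"),
                          empty_docs = integer()),
                     class = "lda_model")
  asg <- assign_topics(model)
  expect_equal(asg$topic, c(1L, 0L))
  expect_equal(asg$id, c("r1", "r2"))
})

test_that("documents emptied by vocabulary filtering get a null topic", {
  docs <- c(rep(list(rep("common", 3)), 10), list(c("rare", "rare")))
  vocab <- build_vocabulary(docs, min_count = 20)
  m <- fit_lda(docs, vocab, K = 2, epochs = 10, seed = 1)
  expect_equal(m$empty_docs, 11L)
  expect_true(is.na(assign_topics(m)$topic[11]))
})

test_that("phase corpora hold only records dated inside their phase", {
  recs <- make_records(c("a b", "c d", "e f", "g h"),
                       dates = as.Date(c("2020-01-01", "2020-01-05",
                                         "2020-01-05", "2020-01-09")))
  tokens <- strsplit(recs$text, " ")
  seg <- segment_phases(as.Date("2020-01-05"),
                        as.Date(c("2020-01-01", "2020-01-10")))
  corp <- build_phase_corpora(recs, tokens, seg)
  expect_equal(corp[["0"]]$ids, "t001")
  expect_equal(corp[["1"]]$ids, c("t002", "t003", "t004"))
  # retweet dedup drops retweets from the corpus
  recs$is_retweet[2] <- TRUE
  corp2 <- build_phase_corpora(recs, tokens, seg, dedup_retweets = TRUE)
  expect_equal(corp2[["1"]]$ids, c("t003", "t004"))
})
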