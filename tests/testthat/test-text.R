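# Linguistic feature extraction

test_that("identity tagging reproduces generator part-of-speech truth", {
  lex <- build_synthetic_lexicon()
  p <- fast_profile("BP", 1, words_per_subject = dist_spec("point", 400))
  set.seed(51)
  tr <- synthesize_transcript(p, lex)
  tagged <- tag_transcript(tr$text, lookup_tagger(lex$tagmap))
  expect_equal(tagged$word_count, tr$truth$word_count)
  freqs <- pos_frequencies(tagged, lex$negations)
  n <- tagged$word_count
  for (cat in c("adjectives", "adverbs", "nouns", "verbs", "time",
                "pronouns_first", "pronouns_second", "pronouns_third")) {
    expect_equal(unname(freqs[cat]) * n, unname(tr$truth$pos_counts[cat]),
                 tolerance = 1e-9, label = cat)
  }
  expect_equal(unname(freqs["negations"]) * n, tr$truth$negation_count,
               tolerance = 1e-9)
})

test_that("empty text yields an empty transcript flagged downstream", {
  lex <- build_synthetic_lexicon()
  tagged <- tag_transcript("", lookup_tagger(lex$tagmap))
  expect_equal(tagged$word_count, 0)
  expect_error(pos_frequencies(tagged, lex$negations), "undefined-feature")
})

test_that("unmapped tokens stay out of every category but count as words", {
  lex <- build_synthetic_lexicon()
  tagged <- tag_transcript("zzz_unknown w.nouns.plain.1",
                           lookup_tagger(lex$tagmap))
  expect_equal(tagged$word_count, 2)
  freqs <- pos_frequencies(tagged, lex$negations)
  mapped <- sum(freqs[setdiff(names(freqs),
                              c("pronouns_first", "pronouns_second",
                                "pronouns_third"))]) * 2
  expect_lte(mapped, 2)
  expect_equal(unname(freqs["nouns"]), 0.5)
})

test_that("category frequencies divide counts by total word count", {
  toks <- c(rep("w.adverbs.plain.1", 22), rep("w.nouns.plain.1", 78))
  lex <- build_synthetic_lexicon()
  tagged <- tag_transcript(paste(toks, collapse = " "),
                           lookup_tagger(lex$tagmap))
  freqs <- pos_frequencies(tagged, lex$negations)
  expect_equal(unname(freqs["adverbs"]), 0.22)
  expect_equal(unname(freqs["negations"]), 0)
})

test_that("generator category probabilities are recovered in the mean", {
  lex <- build_synthetic_lexicon()
  pos <- default_pos_probs()
  p <- fast_profile("BP", 1, words_per_subject = dist_spec("point", 250),
                    negation_prob = 0, stopword_prob = 0,
                    keyword_probs = c(work = 0),
                    sentiment_mix = c(positive = 0, negative = 0, neutral = 0,
                                      non_opinionated = 0, not_a_word = 0,
                                      emotion = 0))
  set.seed(52)
  n_sub <- 60
  freqs <- vapply(seq_len(n_sub), function(i) {
    tr <- synthesize_transcript(p, lex)
    tagged <- tag_transcript(tr$text, lookup_tagger(lex$tagmap))
    unname(pos_frequencies(tagged, lex$negations)["adverbs"])
  }, numeric(1))
  p0 <- pos["adverbs"]
  se <- sqrt(p0 * (1 - p0) / (250 * n_sub))
  expect_lt(abs(mean(freqs) - p0), 3 * se)
})

test_that("stop-word counting filters without modifying the source", {
  toks <- c("stopw01", "a", "stopw02", "b")
  lex <- build_synthetic_lexicon()
  r <- count_stopwords(toks, lex$stopwords)
  expect_equal(r$count, 2)
  expect_equal(r$filtered, c("a", "b"))
  r0 <- count_stopwords(toks, character(0))
  expect_equal(r0$count, 0)
  expect_identical(r0$filtered, toks)
  rall <- count_stopwords(c("stopw01", "stopw01"), lex$stopwords)
  expect_length(rall$filtered, 0)
})

test_that("disjoint two-document corpora zero out foreign terms", {
  corpus <- list(c("apple", "apple"), c("banana"))
  m <- fit_tfidf(corpus, k = 2, k_bounds = c(1, 500))
  expect_setequal(m$vocabulary, c("apple", "banana"))
  f <- tfidf_features(m, corpus[[2]], word_count = 1)
  expect_equal(unname(f$vector["apple"]), 0)
  expect_gt(unname(f$vector["banana"]), 0)
})

test_that("tf-idf values equal hand-computed products on a tiny corpus", {
  corpus <- list(c("sun", "sun", "moon"), c("moon", "star"), c("star", "sun"))
  m <- fit_tfidf(corpus, k = 3, k_bounds = c(1, 500))
  # straight-line recomputation of the smoothed variant
  N <- 3
  df <- c(moon = 2, star = 2, sun = 2)
  idf <- log((1 + N) / (1 + df)) + 1
  f1 <- tfidf_features(m, corpus[[1]], word_count = 3)
  expect_equal(unname(f1$vector["sun"]), (2 / 3) * idf[["sun"]])
  expect_equal(unname(f1$vector["moon"]), (1 / 3) * idf[["moon"]])
  expect_equal(unname(f1$vector["star"]), 0)
  expect_equal(f1$top_word_sum, sum(f1$vector))
  expect_equal(f1$top_word_sum_per_word, f1$top_word_sum / 3)
  # unsmoothed variant
  mu <- fit_tfidf(corpus, k = 3, k_bounds = c(1, 500), smooth_idf = FALSE)
  fu <- tfidf_features(mu, corpus[[1]], word_count = 3)
  expect_equal(unname(fu$vector["sun"]), (2 / 3) * log(3 / 2))
})

test_that("default keyword extraction selects 75 terms on a synthetic corpus", {
  lex <- build_synthetic_lexicon()
  p <- fast_profile("BP", 1, words_per_subject = dist_spec("point", 150))
  set.seed(53)
  corpus <- lapply(seq_len(40), function(i) {
    toks <- synthesize_transcript(p, lex)$tokens
    count_stopwords(toks, lex$stopwords)$filtered
  })
  m <- fit_tfidf(corpus)
  expect_equal(m$k, 75)
  expect_length(m$vocabulary, 75)
})

test_that("vocabulary selection is deterministic and duplication-invariant", {
  corpus <- list(c("a", "b", "b"), c("b", "c"), c("a", "c", "d"))
  m1 <- fit_tfidf(corpus, k = 4, k_bounds = c(1, 500))
  m2 <- fit_tfidf(corpus, k = 4, k_bounds = c(1, 500))
  expect_identical(m1$vocabulary, m2$vocabulary)
  expect_identical(m1$idf, m2$idf)
  # duplicating every document preserves the IDF ranking
  m3 <- fit_tfidf(c(corpus, corpus), k = 4, k_bounds = c(1, 500))
  expect_identical(order(m1$idf[m1$vocabulary]),
                   order(m3$idf[m1$vocabulary]))
})

test_that("requesting more terms than exist keeps all terms with a warning", {
  corpus <- list(c("a", "b"), c("c"))
  expect_warning(m <- fit_tfidf(corpus, k = 50), "k reduced")
  expect_equal(m$k, 3)
})

test_that("tf-idf features of an empty or degenerate document behave", {
  corpus <- list(c("a", "b"), c("b", "c"))
  m <- fit_tfidf(corpus, k = 3, k_bounds = c(1, 500))
  f <- tfidf_features(m, character(0), word_count = 5)
  expect_true(all(f$vector == 0))
  expect_equal(f$top_word_sum, 0)
  f1 <- tfidf_features(m, c("b", "b", "b"), word_count = 3)
  expect_true(f1$vector[["b"]] > 0)
  expect_true(all(f1$vector[setdiff(names(f1$vector), "b")] == 0))
  expect_error(tfidf_features(m, c("a"), word_count = 0), "undefined-feature")
})

test_that("speaking rate is an exact quotient with guarded duration", {
  expect_equal(speaking_rate(120, 60), 2)
  expect_equal(speaking_rate(0, 60), 0)
  expect_error(speaking_rate(100, 0), "undefined-feature")
})
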