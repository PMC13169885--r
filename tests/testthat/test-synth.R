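# Synthetic cohort generator

test_that("cohort generation respects group sizes and labels", {
  cfg <- list(BP = fast_profile("BP", 4), MDD = fast_profile("MDD", 7))
  co <- generate_cohort(cfg, seed = 11)
  expect_length(co$subjects, 11)
  expect_equal(sum(vapply(co$subjects, `[[`, "", "label") == "BP"), 4)
  expect_equal(sum(vapply(co$subjects, `[[`, "", "label") == "MDD"), 7)
  expect_error(bp_profile(n_subjects = 0), "positive integer")
})

test_that("generation is reproducible for a fixed (config, seed)", {
  cfg <- list(BP = fast_profile("BP", 2))
  a <- generate_cohort(cfg, seed = 5)
  b <- generate_cohort(cfg, seed = 5)
  expect_identical(a$subjects[[1]]$samples, b$subjects[[1]]$samples)
  expect_identical(a$subjects[[2]]$tokens, b$subjects[[2]]$tokens)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(cfg, seed = 6)
  expect_false(identical(a$subjects[[1]]$samples, c2$subjects[[1]]$samples))
})

test_that("point-mass pause fraction is reproduced exactly in the truth log", {
  cfg <- list(G = fast_profile("BP", 20, dur = 10,
                               pause_fraction = dist_spec("point", 0.30)))
  co <- generate_cohort(cfg, seed = 3, keep_audio = FALSE)
  ratios <- vapply(co$truth, function(t) t$pause_total_s / t$duration_s,
                   numeric(1))
  expect_equal(mean(ratios), 0.30, tolerance = 1e-12)
  expect_true(all(abs(ratios - 0.30) < 1e-12))
})

test_that("zero pause fraction yields no inserted silences", {
  p <- fast_profile("BP", 1, dur = 6, pause_fraction = dist_spec("point", 0))
  set.seed(1)
  u <- synthesize_utterance(p)
  expect_equal(nrow(u$truth$silences), 0)
  expect_equal(u$truth$pause_total_s, 0)
})

test_that("truth silence total lands within one pause length of target", {
  p <- fast_profile("BP", 1, dur = 60,
                    pause_fraction = dist_spec("point", 0.25),
                    pause_length_ms = dist_spec("uniform", min = 250, max = 450))
  set.seed(7)
  u <- synthesize_utterance(p)
  expect_equal(u$truth$pause_total_s, 15, tolerance = 1e-9)
  expect_equal(sum(u$truth$silences$end_s - u$truth$silences$start_s),
               u$truth$pause_total_s, tolerance = 1e-9)
})

test_that("point-mass voiced amplitude bounds the waveform maximum", {
  p <- fast_profile("BP", 1, dur = 4,
                    pause_fraction = dist_spec("point", 0),
                    voiced_amplitude = dist_spec("point", 0.5))
  set.seed(2)
  u <- synthesize_utterance(p)
  expect_equal(max(abs(u$samples)), 0.5, tolerance = 1e-6)
})

test_that("infeasible pause fractions raise a generation error", {
  p <- fast_profile("BP", 1, dur = 2,
                    pause_fraction = dist_spec("point", 0.9))
  set.seed(1)
  expect_error(synthesize_utterance(p), "infeasible pause_fraction")
})

test_that("truth is internally consistent across a random cohort", {
  cfg <- list(BP = fast_profile("BP", 6), MDD = fast_profile("MDD", 6))
  co <- generate_cohort(cfg, seed = 9)
  for (id in names(co$subjects)) {
    t <- co$truth[[id]]
    expect_gte(t$pause_total_s, 0)
    expect_lte(t$pause_total_s, t$duration_s)
    expect_equal(t$word_count, length(co$subjects[[id]]$tokens))
    expect_equal(length(co$subjects[[id]]$samples) /
                   co$subjects[[id]]$sample_rate,
                 t$duration_s, tolerance = 1e-6)
  }
})

test_that("all-neutral sentiment mix with no negation produces zero counts", {
  mix <- c(positive = 0, negative = 0, neutral = 0.5, non_opinionated = 0,
           not_a_word = 0, emotion = 0)
  p <- fast_profile("BP", 1, sentiment_mix = mix, negation_prob = 0,
                    keyword_probs = c(work = 0), stopword_prob = 0)
  lex <- build_synthetic_lexicon()
  set.seed(4)
  tr <- synthesize_transcript(p, lex)
  expect_equal(unname(tr$truth$annotation_counts["Positive"]), 0L)
  expect_equal(tr$truth$negation_count, 0L)
  expect_gt(tr$truth$annotation_counts["Neutral"], 0)
})

test_that("negation insertion matches the binomial model", {
  p <- fast_profile("BP", 1, words_per_subject = dist_spec("point", 100),
                    negation_prob = 0.1)
  lex <- build_synthetic_lexicon()
  set.seed(12)
  total <- sum(vapply(seq_len(200), function(i)
    synthesize_transcript(p, lex)$truth$negation_count, integer(1)))
  # 200 subjects x Binomial(100, 0.1): two-sided 99% interval for the total
  lo <- qbinom(0.005, 200 * 100, 0.1)
  hi <- qbinom(0.995, 200 * 100, 0.1)
  expect_gte(total, lo)
  expect_lte(total, hi)
})

test_that("keyword emission frequency tracks its configured probability", {
  p <- fast_profile("BP", 1, words_per_subject = dist_spec("point", 10000),
                    negation_prob = 0, keyword_probs = c(work = 0.05))
  lex <- build_synthetic_lexicon()
  set.seed(21)
  tr <- synthesize_transcript(p, lex)
  freq <- sum(tr$tokens == "work") / length(tr$tokens)
  expect_lt(abs(freq - 0.05), 0.01)
})

test_that("empty vocabulary and invalid configs raise configuration errors", {
  lex <- build_synthetic_lexicon()
  lex$vocab <- lex$vocab[0, ]
  p <- fast_profile("BP", 1)
  set.seed(1)
  expect_error(synthesize_transcript(p, lex), "empty vocabulary")
  expect_error(group_profile("X", 2, pause_fraction = dist_spec("point", 0.99)),
               "pause_fraction")
  bad_mix <- c(positive = 0.7, negative = 0.7, neutral = 0,
               non_opinionated = 0, not_a_word = 0, emotion = 0)
  expect_error(group_profile("X", 2, sentiment_mix = bad_mix), "exceed 1")
})

test_that("written cohorts round-trip through WAV and manifest", {
  dir <- withr::local_tempdir()
  cfg <- list(BP = fast_profile("BP", 2, dur = 4))
  co <- generate_cohort(cfg, seed = 8)
  write_cohort(co, dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 2)
  w <- read_wav(man$wav[1])
  expect_equal(w$sample_rate, 16000)
  expect_lt(max(abs(w$samples - co$subjects[[1]]$samples)), 1e-4)
  txt <- readLines(man$transcript[1], warn = FALSE)
  expect_identical(strsplit(txt, " ")[[1]], co$subjects[[1]]$tokens)
})
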