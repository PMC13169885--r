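#' Generator profile for one diagnostic group
#'
#' A `GroupProfile` collects every distributional parameter the synthetic
#' cohort generator needs for one diagnostic group: how long the subjects
#' speak, how much of that time is pause, how loud the voiced segments are,
#' how many words they produce, and the lexical composition (keyword,
#' sentiment-class, part-of-speech and negation probabilities) of their
#' transcripts. Demographic categoricals are sampled from per-variable
#' probability tables.
#'
#' @param label Group label, e.g. `"BP"` or `"MDD"`.
#' @param n_subjects Number of subjects (>= 1).
#' @param speech_duration_s [dist_spec()] for total recording duration (s).
#' @param pause_fraction [dist_spec()] for the fraction of the recording that
#'   is true inserted silence; support must lie in \[0, 0.95\].
#' @param pause_length_ms [dist_spec()] for individual silence lengths (ms).
#' @param voiced_amplitude [dist_spec()] for per-segment envelope peak
#'   amplitude, full-scale units in \[0, 1\].
#' @param words_per_subject [dist_spec()] for transcript word counts.
#' @param keyword_probs Named numeric vector: per-token emission probability
#'   of dedicated keyword tokens.
#' @param sentiment_mix Named probabilities of drawing a content token from
#'   each polarity-lexicon annotation class (`positive`, `negative`,
#'   `neutral`, `non_opinionated`, `not_a_word`) or from the emotion lexicon
#'   (`emotion`); the remaining mass produces plain out-of-lexicon tokens.
#' @param negation_prob Probability that a content token is preceded by a
#'   negation token.
#' @param stopword_prob Probability that a content token is a stop word.
#' @param pos_probs Named probabilities over part-of-speech categories for
#'   plain content tokens (see [pos_categories()]); remaining mass is tagged
#'   `other`.
#' @param demographics A named list of probability tables (and distribution
#'   specs for the numeric variables), as produced by
#'   [default_demographics()].
#' @param sample_rate Audio sampling rate in Hz (>= 8000).
#' @return An object of class `vm_profile`.
#' @seealso [bp_profile()], [mdd_profile()], [generate_cohort()]
#' @export
group_profile <- function(label,
                          n_subjects,
                          speech_duration_s = dist_spec("normal", 60, 6, min = 40, max = 80),
                          pause_fraction    = dist_spec("normal", 0.25, 0.07, min = 0.05, max = 0.6),
                          pause_length_ms   = dist_spec("uniform", min = 250, max = 450),
                          voiced_amplitude  = dist_spec("normal", 0.3, 0.1, min = 0.02, max = 0.95),
                          words_per_subject = dist_spec("normal", 160, 40, min = 30, max = 400),
                          keyword_probs     = default_keyword_probs(),
                          sentiment_mix     = default_sentiment_mix(),
                          negation_prob     = 0.018,
                          stopword_prob     = 0.10,
                          pos_probs         = default_pos_probs(),
                          demographics      = default_demographics(),
                          sample_rate       = 16000) {
  if (!is.numeric(n_subjects) || n_subjects < 1 || n_subjects != round(n_subjects))
    stop("configuration error: 'n_subjects' must be a positive integer")
  if (sample_rate < 8000)
    stop("configuration error: 'sample_rate' must be >= 8000 Hz")
  for (nm in c("speech_duration_s", "pause_fraction", "pause_length_ms",
               "voiced_amplitude", "words_per_subject")) {
    if (!inherits(get(nm), "vm_dist"))
      stop("configuration error: '", nm, "' must be a dist_spec")
  }
  pf_hi <- if (pause_fraction$dist == "point") pause_fraction$mean else pause_fraction$max
  if (!is.finite(pf_hi) || pf_hi > 0.95 ||
      (is.finite(pause_fraction$min) && pause_fraction$min < 0) ||
      (pause_fraction$dist == "point" && pause_fraction$mean < 0))
    stop("configuration error: 'pause_fraction' support must lie in [0, 0.95]")
  check_probs(keyword_probs, "keyword_probs")
  check_probs(sentiment_mix, "sentiment_mix")
  check_probs(c(negation_prob, stopword_prob), "negation_prob/stopword_prob")
  check_probs(pos_probs, "pos_probs")
  if (sum(sentiment_mix) + sum(keyword_probs) + stopword_prob > 1)
    stop("configuration error: sentiment_mix + keyword_probs + stopword_prob exceed 1")
  miss <- setdiff(c("positive", "negative", "neutral", "non_opinionated",
                    "not_a_word", "emotion"), names(sentiment_mix))
  if (length(miss))
    stop("configuration error: sentiment_mix missing classes: ",
         paste(miss, collapse = ", "))
  for (nm in names(demographics)) {
    d <- demographics[[nm]]
    if (is.numeric(d) && !inherits(d, "vm_dist") && nm != "n_illnesses")
      check_probs(d, paste0("demographics$", nm), must_sum = length(d) > 1)
  }
  structure(list(label = label, n_subjects = as.integer(n_subjects),
                 speech_duration_s = speech_duration_s,
                 pause_fraction = pause_fraction,
                 pause_length_ms = pause_length_ms,
                 voiced_amplitude = voiced_amplitude,
                 words_per_subject = words_per_subject,
                 keyword_probs = keyword_probs,
                 sentiment_mix = sentiment_mix,
                 negation_prob = negation_prob,
                 stopword_prob = stopword_prob,
                 pos_probs = pos_probs,
                 demographics = demographics,
                 sample_rate = sample_rate),
            class = "vm_profile")
}

#' Part-of-speech categories of the linguistic feature block
#'
#' The thirteen canonical categories reported by the pipeline: negations are
#' counted by dictionary membership rather than by tag, and person-pronoun
#' splits are counted by membership in configured pronoun lists.
#'
#' @return Character vector of 13 category names.
#' @export
pos_categories <- function() {
  c("adjectives", "conjunctions", "adverbs", "nouns", "verbs",
    "measure_words", "prepositions", "pronouns", "time", "negations",
    "pronouns_first", "pronouns_second", "pronouns_third")
}

# taggable categories drawn by the generator for plain tokens (negations are
# inserted separately; person pronouns are drawn as pronoun subtypes)
.pos_draw_categories <- c("adjectives", "conjunctions", "adverbs", "nouns",
                          "verbs", "measure_words", "prepositions", "pronouns",
                          "time", "pronouns_first", "pronouns_second",
                          "pronouns_third")

#' @rdname group_profile
#' @export
default_pos_probs <- function() {
  c(adjectives = 0.032, conjunctions = 0.003, adverbs = 0.220, nouns = 0.125,
    verbs = 0.060, measure_words = 0.027, prepositions = 0.032,
    pronouns = 0.032, time = 0.044, pronouns_first = 0.002,
    pronouns_second = 0.037, pronouns_third = 0.008)
}

#' @rdname group_profile
#' @export
default_sentiment_mix <- function() {
  c(positive = 0.110, negative = 0.066, neutral = 0.012,
    non_opinionated = 0.006, not_a_word = 0.002, emotion = 0.170)
}

#' @rdname group_profile
#' @export
default_keyword_probs <- function() {
  c(work = 0.010, sleep = 0.010, doctor = 0.006, body = 0.006, stress = 0.006,
    family = 0.005, mood = 0.005, night = 0.004, tired = 0.004, worry = 0.004)
}

#' Demographic sampling tables
#'
#' Categorical probability tables and numeric distribution specs for the ten
#' demographic variables carried by each subject: sex, age, education level,
#' occupation, marital status, suicide history, psychiatric hospitalization
#' history, residential status, alcohol consumption pattern, and number of
#' physical illnesses. Defaults correspond to a predominantly female adult
#' outpatient cohort; group-specific overrides are set in [bp_profile()] and
#' [mdd_profile()].
#'
#' @param sex `P(male)`.
#' @param age [dist_spec()] for age in years.
#' @param education Probabilities over elementary / junior high / senior
#'   high / college-or-higher.
#' @param occupation `P(employed)`.
#' @param marriage Probabilities over unmarried / married / divorced.
#' @param suicide_history `P(positive history)`.
#' @param hospitalization Probabilities over never / within past year /
#'   more than a year ago.
#' @param residential `P(living alone)`.
#' @param alcohol `P(three or more times per week)`.
#' @param n_illnesses [dist_spec()] or Poisson mean for the count of physical
#'   illnesses.
#' @return Named list consumed by [group_profile()].
#' @export
default_demographics <- function(sex = 0.26,
                                 age = dist_spec("normal", 42, 13, min = 18, max = 85),
                                 education = c(elementary = 0.05, junior_high = 0.09,
                                               senior_high = 0.34, college = 0.52),
                                 occupation = 0.50,
                                 marriage = c(unmarried = 0.50, married = 0.41,
                                              divorced = 0.09),
                                 suicide_history = 0.36,
                                 hospitalization = c(never = 0.69, past_year = 0.10,
                                                     earlier = 0.21),
                                 residential = 0.19,
                                 alcohol = 0.05,
                                 n_illnesses = 0.48) {
  list(sex = sex, age = age, education = education, occupation = occupation,
       marriage = marriage, suicide_history = suicide_history,
       hospitalization = hospitalization, residential = residential,
       alcohol = alcohol, n_illnesses = n_illnesses)
}

#' Default bipolar-disorder group profile
#'
#' Calibrated defaults for the bipolar group: 41 subjects, shorter pauses
#' (pause fraction centred at 0.19), higher verbal output (about 200 words
#' per minute of monologue), and lower, less variable voiced amplitude than
#' the depressive group.
#'
#' @param n_subjects Number of subjects.
#' @param ... Overrides passed to [group_profile()].
#' @return A `vm_profile`.
#' @export
bp_profile <- function(n_subjects = 41, ...) {
  defaults <- list(
    label = "BP", n_subjects = n_subjects,
    pause_fraction    = dist_spec("normal", 0.19, 0.055, min = 0.04, max = 0.50),
    voiced_amplitude  = dist_spec("normal", 0.16, 0.05, min = 0.02, max = 0.90),
    words_per_subject = dist_spec("normal", 201, 45, min = 40, max = 400),
    sentiment_mix     = c(positive = 0.112, negative = 0.064, neutral = 0.012,
                          non_opinionated = 0.004, not_a_word = 0.002,
                          emotion = 0.170),
    negation_prob     = 0.015,
    keyword_probs     = c(work = 0.014, sleep = 0.007, doctor = 0.006,
                          body = 0.005, stress = 0.009, family = 0.005,
                          mood = 0.006, night = 0.003, tired = 0.003,
                          worry = 0.003),
    demographics      = default_demographics(
      sex = 0.2927,
      age = dist_spec("normal", 39.9, 11.2, min = 18, max = 85),
      education = c(elementary = 0.0001, junior_high = 0.1219,
                    senior_high = 0.3659, college = 0.5121),
      occupation = 0.5854,
      marriage = c(unmarried = 0.5366, married = 0.3415, divorced = 0.1219),
      suicide_history = 0.4146,
      hospitalization = c(never = 0.4878, past_year = 0.0488, earlier = 0.4634),
      residential = 0.1463,
      alcohol = 0.0732,
      n_illnesses = 0.68))
  args <- utils::modifyList(defaults, list(...))
  do.call(group_profile, args)
}

#' Default major-depressive-disorder group profile
#'
#' Calibrated defaults for the depressive group: 150 subjects, longer pauses
#' (pause fraction centred at 0.30), lower verbal output (about 146 words),
#' and higher, more variable voiced amplitude.
#'
#' @inheritParams bp_profile
#' @return A `vm_profile`.
#' @export
mdd_profile <- function(n_subjects = 150, ...) {
  defaults <- list(
    label = "MDD", n_subjects = n_subjects,
    pause_fraction    = dist_spec("normal", 0.30, 0.085, min = 0.05, max = 0.60),
    voiced_amplitude  = dist_spec("normal", 0.40, 0.18, min = 0.02, max = 0.95),
    words_per_subject = dist_spec("normal", 146, 40, min = 30, max = 400),
    sentiment_mix     = c(positive = 0.106, negative = 0.070, neutral = 0.013,
                          non_opinionated = 0.008, not_a_word = 0.002,
                          emotion = 0.175),
    negation_prob     = 0.019,
    keyword_probs     = c(work = 0.006, sleep = 0.013, doctor = 0.006,
                          body = 0.008, stress = 0.004, family = 0.005,
                          mood = 0.004, night = 0.006, tired = 0.006,
                          worry = 0.005),
    demographics      = default_demographics(
      sex = 0.2533,
      age = dist_spec("normal", 42.5, 12.9, min = 18, max = 85),
      education = c(elementary = 0.06, junior_high = 0.0867,
                    senior_high = 0.3333, college = 0.52),
      occupation = 0.4867,
      marriage = c(unmarried = 0.4867, married = 0.4333, divorced = 0.08),
      suicide_history = 0.3467,
      hospitalization = c(never = 0.7467, past_year = 0.1133, earlier = 0.14),
      residential = 0.2067,
      alcohol = 0.04,
      n_illnesses = 0.42))
  args <- utils::modifyList(defaults, list(...))
  do.call(group_profile, args)
}

#' Default two-group study configuration
#'
#' @return List of two profiles: 41 BP and 150 MDD subjects.
#' @export
default_cohort_config <- function() {
  list(BP = bp_profile(), MDD = mdd_profile())
}
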