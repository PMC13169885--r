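# Feature extraction orchestration and assembly ------------------------------

.demographic_cols <- c("dem_sex", "dem_age", "dem_education", "dem_occupation",
                       "dem_marriage", "dem_suicide_history",
                       "dem_hospitalization", "dem_residential",
                       "dem_alcohol", "dem_n_illnesses")

# single-column numeric encodings; ordered categories get ordinal codes,
# the remaining multi-level variable (marriage) gets documented integer codes
encode_demographics <- function(dem) {
  data.frame(
    dem_sex = as.numeric(dem$sex == "male"),
    dem_age = as.numeric(dem$age),
    dem_education = match(dem$education,
                          c("elementary", "junior_high", "senior_high", "college")),
    dem_occupation = as.numeric(dem$occupation == "employed"),
    dem_marriage = match(dem$marriage, c("unmarried", "married", "divorced")) - 1,
    dem_suicide_history = as.numeric(dem$suicide_history == "yes"),
    dem_hospitalization = match(dem$hospitalization,
                                c("never", "earlier", "past_year")) - 1,
    dem_residential = as.numeric(dem$residential == "alone"),
    dem_alcohol = as.numeric(dem$alcohol == "three_plus_weekly"),
    dem_n_illnesses = as.numeric(dem$n_illnesses)
  )
}

#' Extract text, sentiment and assemble features for a set of subjects
#'
#' Takes per-subject records that already carry audio features, tokens and
#' demographics; computes the corpus-level TF-IDF model and all per-subject
#' linguistic and sentiment features; and assembles the canonical feature
#' matrix of 118 columns (10 demographic + 13 part-of-speech + 75 TF-IDF +
#' 14 sentiment + 6 acoustic). With `extended = TRUE` five additional
#' textual variables (total word count, speaking rate, stop-word count and
#' the two TF-IDF top-word-sum metrics) are appended.
#'
#' @param records List of per-subject lists with elements `id`, `label`,
#'   `tokens`, `demographics`, `audio` (from [extract_audio_features()]).
#' @param lexicon A `vm_lexicon` (tag map, lexica, stop words).
#' @param k Number of TF-IDF keywords (default 75).
#' @param extended Include the five extra textual variables.
#' @param scope Negation scope for sentiment scoring.
#' @return A tibble of class `vm_features` with `subject_id`, `label` and
#'   the feature columns; attributes `family` (named character: column ->
#'   feature family) and `categorical` (demographic columns compared by
#'   chi-squared test).
#' @export
assemble_features <- function(records, lexicon, k = 75, extended = FALSE,
                              scope = 1) {
  for (r in records) {
    miss <- setdiff(c("id", "label", "tokens", "demographics", "audio"),
                    names(r))
    if (length(miss))
      stop("assembly error: subject ", r$id %||% "?", " missing block(s): ",
           paste(miss, collapse = ", "))
    if (!length(r$tokens))
      stop("assembly error: subject ", r$id, " has an empty transcript")
  }
  tagger <- lookup_tagger(lexicon$tagmap)
  tagged <- lapply(records, function(r)
    tag_transcript(paste(r$tokens, collapse = " "), tagger))
  filtered <- lapply(records, function(r)
    count_stopwords(r$tokens, lexicon$stopwords))
  model <- fit_tfidf(lapply(filtered, `[[`, "filtered"), k = k)

  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    wc <- tagged[[i]]$word_count
    pos <- pos_frequencies(tagged[[i]], lexicon$negations)
    tf <- tfidf_features(model, filtered[[i]]$filtered, wc)
    sent <- extract_sentiment_features(r$tokens, lexicon$polarity,
                                       lexicon$emotions, lexicon$negations,
                                       scope)
    audio <- r$audio
    base <- cbind(
      data.frame(subject_id = r$id, label = r$label,
                 stringsAsFactors = FALSE),
      encode_demographics(r$demographics),
      stats::setNames(as.data.frame(as.list(pos)),
                      paste0("pos_", names(pos))),
      stats::setNames(as.data.frame(as.list(tf$vector)),
                      paste0("tfidf_", names(tf$vector))),
      as.data.frame(sent, stringsAsFactors = FALSE),
      data.frame(pause_per_duration = audio$pause_per_duration,
                 pause_per_word = audio$pause_per_word,
                 peak_amplitude = audio$peak_amplitude,
                 max_peak_amplitude = audio$max_peak_amplitude,
                 min_peak_amplitude = audio$min_peak_amplitude,
                 average_peak_amplitude = audio$average_peak_amplitude)
    )
    if (extended) {
      base <- cbind(base, data.frame(
        total_word_count = wc,
        speaking_rate = speaking_rate(wc, audio$total_duration_s),
        stop_word_count = filtered[[i]]$count,
        tfidf_top_word_sum = tf$top_word_sum,
        tfidf_top_word_sum_per_word = tf$top_word_sum_per_word))
    }
    base
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  pos_cols <- paste0("pos_", pos_categories())
  tfidf_cols <- paste0("tfidf_", model$vocabulary)
  sent_cols <- c("copeopi_score",
                 paste0("ann_", c("positive", "neutral", "negative",
                                  "non_opinionated", "not_a_word")),
                 paste0("emo_", emotion_categories()))
  audio_cols <- c("pause_per_duration", "pause_per_word", "peak_amplitude",
                  "max_peak_amplitude", "min_peak_amplitude",
                  "average_peak_amplitude")
  fam <- c(stats::setNames(rep("Demographic", 10), .demographic_cols),
           stats::setNames(rep("Linguistic", length(pos_cols)), pos_cols),
           stats::setNames(rep("Linguistic", length(tfidf_cols)), tfidf_cols),
           stats::setNames(rep("Sentiment", length(sent_cols)), sent_cols),
           stats::setNames(rep("Acoustic", length(audio_cols)), audio_cols))
  if (extended) {
    ext_cols <- c("total_word_count", "speaking_rate", "stop_word_count",
                  "tfidf_top_word_sum", "tfidf_top_word_sum_per_word")
    fam <- c(fam, stats::setNames(rep("Linguistic", 5), ext_cols))
  }
  attr(out, "family") <- fam
  attr(out, "categorical") <- c("dem_sex", "dem_education", "dem_occupation",
                                "dem_marriage", "dem_suicide_history",
                                "dem_hospitalization", "dem_residential",
                                "dem_alcohol")
  attr(out, "tfidf_model") <- model
  class(out) <- c("vm_features", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a cohort and extract its feature matrix in one pass
#'
#' Generates each subject, extracts the acoustic features immediately and
#' discards the waveform, then runs the corpus-level text and sentiment
#' stages. Identical sub-seeding to [generate_cohort()], so the features
#' equal those extracted from a stored cohort with the same configuration
#' and seed.
#'
#' @param config Named list of [group_profile()]s.
#' @param seed Integer root seed.
#' @param k TF-IDF keyword count.
#' @param extended Include the five extra textual variables.
#' @param threshold_db,min_ms,max_ms Pause detector settings.
#' @param noise_profile_s Noise-reduction profile length (0 = off).
#' @return A `vm_features` tibble (see [assemble_features()]) with the
#'   per-subject ground truth attached as attribute `truth`.
#' @export
simulate_feature_matrix <- function(config = default_cohort_config(),
                                    seed = 1, k = 75, extended = FALSE,
                                    threshold_db = 35, min_ms = 200,
                                    max_ms = 500, noise_profile_s = 0) {
  lexicon <- build_synthetic_lexicon()
  n_total <- sum(vapply(config, function(p) p$n_subjects, integer(1)))
  seeds <- split_seed(seed, n_total)
  records <- vector("list", n_total)
  truth <- vector("list", n_total)
  idx <- 0
  for (p in config) {
    for (j in seq_len(p$n_subjects)) {
      idx <- idx + 1
      set.seed(seeds[idx])
      utt <- synthesize_utterance(p)
      tr <- synthesize_transcript(p, lexicon)
      dem <- sample_demographics(p)
      audio <- extract_audio_features(
        utt$samples, utt$sample_rate, word_count = length(tr$tokens),
        threshold_db = threshold_db, min_ms = min_ms, max_ms = max_ms,
        noise_profile_s = noise_profile_s)
      records[[idx]] <- list(id = sprintf("S%03d", idx), label = p$label,
                             tokens = tr$tokens, demographics = dem,
                             audio = audio)
      truth[[idx]] <- c(utt$truth, tr$truth)
    }
  }
  names(truth) <- vapply(records, `[[`, "", "id")
  fm <- assemble_features(records, lexicon, k = k, extended = extended)
  attr(fm, "truth") <- truth
  fm
}
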