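# Negation-aware lexicon sentiment scoring -----------------------------------
#
# Per-word polarity follows the sign-flip rule: the score of a word is its
# lexicon orientation, negated when a negation word occurs within the scope
# window immediately before it. A word absent from the lexicon scores 0.

#' Score tokens against a polarity lexicon with negation handling
#'
#' For each token, `score = Negation x Orientation(w)` where `Negation` is
#' -1 if any of the preceding `scope` tokens is in the negation dictionary
#' (a presence test: double negation within one window still flips once)
#' and +1 otherwise; `Orientation(w)` is 0 for out-of-lexicon tokens.
#'
#' @param tokens Character vector.
#' @param lexicon Polarity lexicon data frame (`token`, `orientation`,
#'   `annotation`), e.g. from [read_polarity_lexicon()] or
#'   [build_synthetic_lexicon()]`$polarity`.
#' @param negations Character vector of negation words.
#' @param scope Number of preceding tokens inspected for negation
#'   (default 1: exactly the immediately preceding token).
#' @return Numeric vector of per-token signed scores.
#' @export
score_tokens <- function(tokens, lexicon, negations, scope = 1) {
  if (!length(tokens)) return(numeric(0))
  orient <- lexicon$orientation[match(tokens, lexicon$token)]
  orient[is.na(orient)] <- 0
  is_neg <- tokens %in% negations
  negated <- rep(FALSE, length(tokens))
  for (d in seq_len(scope)) {
    shifted <- c(rep(FALSE, d), is_neg[seq_len(length(tokens) - d)])
    negated <- negated | shifted
  }
  ifelse(negated, -orient, orient)
}

#' @rdname score_tokens
#' @param token A single token.
#' @param preceding Its preceding token (or `NA`).
#' @export
score_word <- function(token, preceding, lexicon, negations) {
  pre <- if (is.na(preceding)) character(0) else preceding
  score_tokens(c(pre, token), lexicon, negations)[length(pre) + 1]
}

#' Aggregate polarity score of a text
#'
#' The mean of per-word signed scores over all tokens; bounded by the
#' largest per-word orientation magnitude and therefore within \[-1, 1\].
#'
#' @inheritParams score_tokens
#' @return Scalar in \[-1, 1\].
#' @export
copeopi_score <- function(tokens, lexicon, negations, scope = 1) {
  if (!length(tokens)) stop("undefined-feature error: empty transcript")
  mean(score_tokens(tokens, lexicon, negations, scope))
}

#' Annotation-class frequencies
#'
#' Lexicon-hit counts per annotation class (Positive, Neutral, Negative,
#' Non-opinionated, Not-a-word), normalized by the total word count.
#'
#' @inheritParams score_tokens
#' @return Named numeric vector over the five annotation classes.
#' @export
annotation_frequencies <- function(tokens, lexicon) {
  if (!length(tokens)) stop("undefined-feature error: empty transcript")
  ann <- lexicon$annotation[match(tokens, lexicon$token)]
  counts <- table(factor(ann, levels = .annotation_levels))
  stats::setNames(as.numeric(counts) / length(tokens), .annotation_levels)
}

#' Emotion frequencies with negation weighting
#'
#' Counts tokens per emotion category, normalized by the total word count.
#' Under the weighted-multiplication rule a negated emotion token carries
#' weight -1, floored at 0 per token, so it drops out of the reported
#' frequency (negating one of three Joy tokens in a 100-word text yields
#' 0.02 rather than 0.03). `signed = FALSE` switches to plain absolute
#' counts that ignore negation.
#'
#' @param tokens Character vector.
#' @param emotion_lexicon Data frame `token`, `emotion` (one row per
#'   word-emotion pair).
#' @param negations Character vector of negation words.
#' @param scope Negation scope window (tokens).
#' @param signed Apply the negation-weighting rule (default `TRUE`).
#' @return Named numeric vector over [emotion_categories()].
#' @export
emotion_frequencies <- function(tokens, emotion_lexicon, negations,
                                scope = 1, signed = TRUE) {
  if (!length(tokens)) stop("undefined-feature error: empty transcript")
  is_neg <- tokens %in% negations
  negated <- rep(FALSE, length(tokens))
  for (d in seq_len(scope)) {
    shifted <- c(rep(FALSE, d), is_neg[seq_len(length(tokens) - d)])
    negated <- negated | shifted
  }
  out <- stats::setNames(numeric(8), emotion_categories())
  idx <- which(tokens %in% emotion_lexicon$token)
  for (i in idx) {
    emos <- emotion_lexicon$emotion[emotion_lexicon$token == tokens[i]]
    w <- if (signed && negated[i]) -1 else 1
    out[emos] <- out[emos] + max(w, 0)
  }
  out / length(tokens)
}

#' Extract the sentiment feature block for one transcript
#'
#' @param tokens Token vector of the full transcript.
#' @param lexicon Polarity lexicon data frame.
#' @param emotion_lexicon Emotion lexicon data frame.
#' @param negations Negation dictionary.
#' @param scope Negation scope window.
#' @return Named list of 14 features: `copeopi_score`, five
#'   `ann_*` annotation frequencies, eight `emo_*` emotion frequencies.
#' @export
extract_sentiment_features <- function(tokens, lexicon, emotion_lexicon,
                                       negations, scope = 1) {
  ann <- annotation_frequencies(tokens, lexicon)
  emo <- emotion_frequencies(tokens, emotion_lexicon, negations, scope)
  c(list(copeopi_score = copeopi_score(tokens, lexicon, negations, scope)),
    stats::setNames(as.list(ann),
                    paste0("ann_", c("positive", "neutral", "negative",
                                     "non_opinionated", "not_a_word"))),
    stats::setNames(as.list(emo), paste0("emo_", emotion_categories())))
}
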