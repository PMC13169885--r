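# Synthetic vocabulary and lexica -------------------------------------------
#
# The generator emits whitespace-delimited pseudo-words. Every content token
# carries two independent attributes: a part-of-speech category (drawn from
# the profile's pos_probs) and a lexicon class (drawn from sentiment_mix).
# The vocabulary is therefore a crossing of tag x class with a few surface
# forms per cell, plus dedicated keyword, stop-word and negation tokens.
# Chinese segmentation is not emulated; the identity tagger looks tokens up
# in this table.

.annotation_levels <- c("Positive", "Neutral", "Negative",
                        "Non-opinionated", "Not-a-word")

#' Emotion categories of the emotion lexicon
#' @return Character vector of the eight emotion names.
#' @export
emotion_categories <- function() {
  c("anger", "anticipation", "disgust", "fear", "joy",
    "sadness", "surprise", "trust")
}

#' Build the synthetic vocabulary table
#'
#' Deterministically constructs the pseudo-word vocabulary used by the
#' synthetic cohort generator, together with its polarity lexicon, emotion
#' lexicon, negation dictionary and stop-word list. Surface forms encode
#' nothing the extractors use; all lookups go through the returned tables.
#'
#' @param forms_per_cell Surface forms per (tag, class) cell.
#' @param keywords Character vector of dedicated keyword tokens.
#' @return A list of class `vm_lexicon` with elements `vocab` (data frame:
#'   token, tag, class, orientation, annotation, emotion), `polarity`
#'   (token, orientation, annotation), `emotions` (token, emotion),
#'   `negations`, `stopwords`, and `tagmap` (token -> tag lookup).
#' @export
build_synthetic_lexicon <- function(forms_per_cell = 2,
                                    keywords = names(default_keyword_probs())) {
  tags <- c(.pos_draw_categories, "other")
  classes <- c("plain", "positive", "negative", "neutral",
               "non_opinionated", "not_a_word",
               paste0("emotion_", emotion_categories()))
  grid <- expand.grid(tag = tags, class = classes,
                      form = seq_len(forms_per_cell),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$tag, grid$class, grid$form), ]
  token <- sprintf("w.%s.%s.%d", grid$tag, grid$class, grid$form)
  # orientations alternate in magnitude so the lexicon is not a point mass
  orient <- numeric(nrow(grid))
  orient[grid$class == "positive"] <- ifelse(grid$form[grid$class == "positive"] %% 2 == 1, 0.9, 0.6)
  orient[grid$class == "negative"] <- ifelse(grid$form[grid$class == "negative"] %% 2 == 1, -0.9, -0.6)
  annotation <- rep(NA_character_, nrow(grid))
  annotation[grid$class == "positive"] <- "Positive"
  annotation[grid$class == "negative"] <- "Negative"
  annotation[grid$class == "neutral"] <- "Neutral"
  annotation[grid$class == "non_opinionated"] <- "Non-opinionated"
  annotation[grid$class == "not_a_word"] <- "Not-a-word"
  emotion <- rep(NA_character_, nrow(grid))
  is_emo <- startsWith(grid$class, "emotion_")
  emotion[is_emo] <- sub("^emotion_", "", grid$class[is_emo])

  vocab <- data.frame(token = token, tag = grid$tag, class = grid$class,
                      orientation = orient, annotation = annotation,
                      emotion = emotion, stringsAsFactors = FALSE)
  if (length(keywords)) {
    vocab <- rbind(vocab, data.frame(
      token = keywords, tag = "nouns", class = "keyword",
      orientation = 0, annotation = NA_character_,
      emotion = NA_character_, stringsAsFactors = FALSE))
  }
  negations <- c("not", "no", "never", "without", "none")
  stopwords <- sprintf("stopw%02d", seq_len(20))
  vocab <- rbind(vocab,
    data.frame(token = negations, tag = "other", class = "negation",
               orientation = 0, annotation = NA_character_,
               emotion = NA_character_, stringsAsFactors = FALSE),
    data.frame(token = stopwords, tag = "other", class = "stopword",
               orientation = 0, annotation = NA_character_,
               emotion = NA_character_, stringsAsFactors = FALSE))
  pol <- vocab[!is.na(vocab$annotation), c("token", "orientation", "annotation")]
  emo <- vocab[!is.na(vocab$emotion), c("token", "emotion")]
  tagmap <- stats::setNames(vocab$tag, vocab$token)
  structure(list(vocab = vocab, polarity = pol, emotions = emo,
                 negations = negations, stopwords = stopwords,
                 tagmap = tagmap),
            class = "vm_lexicon")
}

#' Write lexicon resources as plain-text files
#'
#' Emits the polarity lexicon (`polarity.tsv`: word, orientation,
#' annotation), emotion lexicon (`emotions.tsv`: word, emotion — one row per
#' word-emotion pair), negation dictionary (`negations.txt`), stop-word list
#' (`stopwords.txt`) and tag map (`tagmap.tsv`) into a directory.
#'
#' @param lexicon A `vm_lexicon`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_lexicon <- function(lexicon, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(lexicon$polarity, file.path(dir, "polarity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(lexicon$emotions, file.path(dir, "emotions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(lexicon$negations, file.path(dir, "negations.txt"))
  writeLines(lexicon$stopwords, file.path(dir, "stopwords.txt"))
  utils::write.table(
    data.frame(token = names(lexicon$tagmap), tag = unname(lexicon$tagmap)),
    file.path(dir, "tagmap.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a polarity lexicon from TSV
#'
#' Expects columns word/token, orientation, annotation. Validates that
#' orientation signs are consistent with annotations and that magnitudes do
#' not exceed 1.
#'
#' @param path TSV path.
#' @return Data frame with columns `token`, `orientation`, `annotation`.
#' @export
read_polarity_lexicon <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(d)[1] <- "token"
  if (!all(c("token", "orientation", "annotation") %in% names(d)))
    stop("input error: polarity lexicon needs token/orientation/annotation columns")
  if (any(abs(d$orientation) > 1))
    stop("input error: polarity orientations must have |orientation| <= 1")
  if (any(d$annotation == "Positive" & d$orientation <= 0) ||
      any(d$annotation == "Negative" & d$orientation >= 0))
    stop("input error: orientation sign inconsistent with annotation")
  d
}

#' Read an emotion lexicon from TSV (one word-emotion pair per row)
#' @param path TSV path.
#' @return Data frame with columns `token`, `emotion`.
#' @export
read_emotion_lexicon <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(d)[1:2] <- c("token", "emotion")
  d$emotion <- tolower(d$emotion)
  bad <- setdiff(unique(d$emotion), emotion_categories())
  if (length(bad))
    stop("input error: unknown emotion categories: ", paste(bad, collapse = ", "))
  d
}

#' Read a one-word-per-line dictionary (negations, stop words)
#' @param path File path.
#' @return Character vector.
#' @export
read_wordlist <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x[nzchar(trimws(x))]
}
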