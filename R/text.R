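# Linguistic feature extraction ----------------------------------------------

#' Whitespace tokenizer and pluggable taggers
#'
#' A tagger is any function mapping a text string to a data frame with
#' columns `token` and `tag`. `lookup_tagger()` builds one from a
#' token-to-tag lookup (the identity tagger for the synthetic vocabulary);
#' unknown tokens receive tag `"other"`. Adapters for external segmenters
#' plug in through the same interface.
#'
#' @param tagmap Named character vector, token -> raw tag.
#' @return A tagger function.
#' @export
lookup_tagger <- function(tagmap) {
  force(tagmap)
  function(text) {
    toks <- tokenize(text)
    tags <- unname(tagmap[toks])
    tags[is.na(tags)] <- "other"
    data.frame(token = toks, tag = tags, stringsAsFactors = FALSE)
  }
}

#' @rdname lookup_tagger
#' @param text A character scalar.
#' @export
tokenize <- function(text) {
  if (!nzchar(trimws(text))) return(character(0))
  strsplit(trimws(text), "\\s+")[[1]]
}

#' Tag a transcript
#'
#' Runs the tagger and maps its raw tagset onto the canonical categories via
#' `mapping` (raw tag -> canonical tag); raw tags without a mapping become
#' `"other"`. With the identity mapping (default) the tagger's tags are used
#' directly.
#'
#' @param text Character scalar (UTF-8).
#' @param tagger A tagger function (see [lookup_tagger()]).
#' @param mapping Optional named character vector, raw tag -> canonical tag.
#' @return A `TaggedTranscript`: list with `tokens` (data frame token, tag)
#'   and `word_count`.
#' @export
tag_transcript <- function(text, tagger, mapping = NULL) {
  tt <- tagger(text)
  stopifnot(is.data.frame(tt), all(c("token", "tag") %in% names(tt)))
  if (!is.null(mapping)) {
    mapped <- unname(mapping[tt$tag])
    mapped[is.na(mapped)] <- "other"
    tt$tag <- mapped
  }
  list(tokens = tt, word_count = nrow(tt))
}

#' Part-of-speech frequencies
#'
#' Computes the thirteen canonical category frequencies (category count
#' divided by total word count). Negations are counted by membership in the
#' negation dictionary, not by tag; first/second/third-person pronoun splits
#' are counted by membership in the configured pronoun lists.
#'
#' @param tagged A [tag_transcript()] result.
#' @param negation_dict Character vector of negation words.
#' @param pronoun_lists Optional list with elements `first`, `second`,
#'   `third` (character vectors of person-pronoun surface forms). When
#'   `NULL`, person splits are derived from tags `pronouns_first/second/third`
#'   if the tagger emits them.
#' @return Named numeric vector over [pos_categories()].
#' @export
pos_frequencies <- function(tagged, negation_dict, pronoun_lists = NULL) {
  n <- tagged$word_count
  if (n == 0) stop("undefined-feature error: empty transcript")
  toks <- tagged$tokens$token
  tags <- tagged$tokens$tag
  count_tag <- function(cat, extra = character(0))
    sum(tags %in% c(cat, extra))
  person <- function(which) {
    if (!is.null(pronoun_lists)) sum(toks %in% pronoun_lists[[which]])
    else sum(tags == paste0("pronouns_", which))
  }
  counts <- c(
    adjectives = count_tag("adjectives"),
    conjunctions = count_tag("conjunctions"),
    adverbs = count_tag("adverbs"),
    nouns = count_tag("nouns"),
    verbs = count_tag("verbs"),
    measure_words = count_tag("measure_words"),
    prepositions = count_tag("prepositions"),
    pronouns = count_tag("pronouns", paste0("pronouns_", c("first", "second", "third"))),
    time = count_tag("time"),
    negations = sum(toks %in% negation_dict),
    pronouns_first = person("first"),
    pronouns_second = person("second"),
    pronouns_third = person("third")
  )
  counts / n
}

#' Stop-word counting and removal
#'
#' Counts stop-list matches and returns the filtered token sequence; the
#' input transcript is left unmodified.
#'
#' @param tokens Character vector of tokens.
#' @param stoplist Character vector of stop words.
#' @return List with `count` and `filtered` (tokens with stop words removed).
#' @export
count_stopwords <- function(tokens, stoplist) {
  hit <- tokens %in% stoplist
  list(count = sum(hit), filtered = tokens[!hit])
}

#' Fit a TF-IDF keyword model
#'
#' Term frequency is the raw within-document count divided by document
#' length; inverse document frequency is the smoothed
#' `log((1 + N) / (1 + df)) + 1` (switchable to the unsmoothed
#' `log(N / df)`). The keyword vocabulary is the top `k` terms ranked by
#' corpus-summed TF-IDF mass, ties broken lexicographically. If fewer than
#' `k` distinct terms exist, all terms are kept with a warning.
#'
#' @param corpus List of token vectors (stop words already removed).
#' @param k Vocabulary size; the supported sweep range is
#'   `k_bounds[1]`..`k_bounds[2]` (default 50..500), default `k = 75`.
#' @param smooth_idf Use the smoothed IDF variant (default `TRUE`).
#' @param k_bounds Allowed range for `k`.
#' @return A `TfidfModel`: list with `vocabulary`, `idf` (named, over
#'   vocabulary), `df`, `n_docs`, `k`, `smooth_idf`.
#' @export
fit_tfidf <- function(corpus, k = 75, smooth_idf = TRUE,
                      k_bounds = c(50, 500)) {
  stopifnot(length(corpus) >= 2)
  if (k < k_bounds[1] || k > k_bounds[2])
    stop("configuration error: k must lie in [", k_bounds[1], ", ",
         k_bounds[2], "]")
  n_docs <- length(corpus)
  terms <- sort(unique(unlist(corpus)))
  if (!length(terms)) stop("configuration error: empty corpus")
  df <- numeric(length(terms))
  names(df) <- terms
  mass <- numeric(length(terms))
  names(mass) <- terms
  for (doc in corpus) {
    if (!length(doc)) next
    tab <- table(doc)
    tf <- as.numeric(tab) / length(doc)
    df[names(tab)] <- df[names(tab)] + 1
    mass[names(tab)] <- mass[names(tab)] + tf
  }
  idf_all <- if (smooth_idf) log((1 + n_docs) / (1 + df)) + 1 else {
    out <- log(n_docs / pmax(df, 1))
    out[df == 0] <- 0
    out
  }
  score <- mass * idf_all
  ord <- order(-score, terms)  # ties broken lexicographically
  k_eff <- min(k, length(terms))
  if (k_eff < k)
    warning("fit_tfidf: only ", length(terms), " distinct terms; k reduced")
  vocab <- sort(terms[ord[seq_len(k_eff)]])
  list(vocabulary = vocab, idf = idf_all[vocab], df = df[vocab],
       n_docs = n_docs, k = k_eff, smooth_idf = smooth_idf)
}

#' TF-IDF features for one document
#'
#' Projects a (stop-word-filtered) document onto the fitted keyword
#' vocabulary and computes the cumulative keyword score (top-word sum) and
#' its per-word normalization.
#'
#' @param model A [fit_tfidf()] model.
#' @param tokens Filtered token vector for the document.
#' @param word_count Total word count of the transcript (pre-filtering),
#'   > 0; denominators of the per-word metric.
#' @return List with `vector` (named, length `k`), `top_word_sum`,
#'   `top_word_sum_per_word`.
#' @export
tfidf_features <- function(model, tokens, word_count) {
  if (!isTRUE(word_count > 0))
    stop("undefined-feature error: word_count must be > 0")
  v <- numeric(length(model$vocabulary))
  names(v) <- model$vocabulary
  if (length(tokens)) {
    tab <- table(tokens)
    hit <- intersect(names(tab), model$vocabulary)
    v[hit] <- as.numeric(tab[hit]) / length(tokens) * model$idf[hit]
  }
  s <- sum(v)
  list(vector = v, top_word_sum = s, top_word_sum_per_word = s / word_count)
}

#' Speaking rate
#'
#' Words per second over the original (pause-intact) recording duration.
#'
#' @param word_count Words spoken.
#' @param total_duration_s Recording duration (s), > 0.
#' @return Words per second.
#' @export
speaking_rate <- function(word_count, total_duration_s) {
  if (!isTRUE(total_duration_s > 0))
    stop("undefined-feature error: total_duration_s must be > 0")
  word_count / total_duration_s
}
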