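# Synthetic cohort generator -------------------------------------------------

#' Synthesize one utterance waveform with known pause ground truth
#'
#' Builds a waveform that alternates voiced segments (band-limited harmonic
#' bursts: a fundamental drawn in 120-220 Hz plus two overtones, with a
#' per-segment peak amplitude drawn from the profile's `voiced_amplitude`)
#' and true silences at a -80 dBFS noise floor. Silence lengths are drawn
#' from `pause_length_ms` until the target pause fraction is met; the last
#' silence is truncated so that total silence hits the target exactly. All
#' segment boundaries are aligned to a 5 ms grid. Uses the current RNG
#' state.
#'
#' @param profile A [group_profile()].
#' @return List with `samples`, `sample_rate`, and `truth` — a list holding
#'   `duration_s`, `pause_total_s`, `pause_fraction`, a data frame `silences`
#'   (start_s, end_s), and the per-segment voiced amplitudes.
#' @export
synthesize_utterance <- function(profile) {
  sr <- profile$sample_rate
  duration <- round_to_grid_s(draw_dist(profile$speech_duration_s))
  frac <- draw_dist(profile$pause_fraction)
  target <- round_to_grid_s(duration * frac)

  pause_lens <- numeric(0)
  if (target > 0) {
    repeat {
      len <- round_to_grid_s(draw_dist(profile$pause_length_ms) / 1000)
      if (sum(pause_lens) + len >= target) {
        pause_lens <- c(pause_lens, target - sum(pause_lens))
        break
      }
      pause_lens <- c(pause_lens, len)
    }
    pause_lens <- pause_lens[pause_lens > 0]
  }
  n_pause <- length(pause_lens)
  voiced_total <- duration - sum(pause_lens)
  # voiced segments target >= 300 ms but shrink when many pauses must fit;
  # below a 50 ms floor the pause fraction cannot be realized
  min_voiced <- min(0.30, round_to_grid_s(0.9 * voiced_total / (n_pause + 1)))
  if (min_voiced < 0.05)
    stop("generation error: infeasible pause_fraction ", signif(frac, 3),
         " for duration ", duration, " s with the configured pause lengths")

  # split voiced time into n_pause+1 grid-aligned segments, each >= min_voiced
  n_seg <- n_pause + 1
  w <- stats::runif(n_seg, 0.5, 1.5)
  seg <- min_voiced + (voiced_total - n_seg * min_voiced) * w / sum(w)
  seg <- round_to_grid_s(seg)
  seg[n_seg] <- seg[n_seg] + (voiced_total - sum(seg))  # fix rounding on last

  amps <- draw_dist(profile$voiced_amplitude, n_seg)
  f0 <- stats::runif(n_seg, 120, 220)

  pieces <- vector("list", n_seg + n_pause)
  silences <- matrix(numeric(0), ncol = 2)
  t_cursor <- 0
  k <- 1
  for (i in seq_len(n_seg)) {
    n_smp <- round(seg[i] * sr)
    tt <- seq_len(n_smp) / sr
    h <- sin(2 * pi * f0[i] * tt) +
      0.5 * sin(2 * pi * 2 * f0[i] * tt) +
      0.25 * sin(2 * pi * 3 * f0[i] * tt)
    h <- h / max(abs(h)) * amps[i]
    ramp_n <- min(round(0.005 * sr), n_smp %/% 2)
    if (ramp_n > 0) {
      r <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
      h[seq_len(ramp_n)] <- h[seq_len(ramp_n)] * r
      h[n_smp - ramp_n + seq_len(ramp_n)] <- h[n_smp - ramp_n + seq_len(ramp_n)] * rev(r)
    }
    pieces[[k]] <- h
    k <- k + 1
    t_cursor <- t_cursor + seg[i]
    if (i <= n_pause) {
      n_sil <- round(pause_lens[i] * sr)
      pieces[[k]] <- stats::rnorm(n_sil) * 1e-4  # -80 dBFS floor
      silences <- rbind(silences, c(t_cursor, t_cursor + pause_lens[i]))
      t_cursor <- t_cursor + pause_lens[i]
      k <- k + 1
    }
  }
  samples <- unlist(pieces)
  truth <- list(
    duration_s = duration,
    pause_total_s = sum(pause_lens),
    pause_fraction = if (duration > 0) sum(pause_lens) / duration else 0,
    silences = data.frame(start_s = silences[, 1], end_s = silences[, 2]),
    voiced_amplitudes = amps
  )
  list(samples = samples, sample_rate = sr, truth = truth)
}

#' Synthesize one transcript with known per-class token counts
#'
#' Draws a target number of content tokens from `words_per_subject`. Each
#' content token is a keyword (per `keyword_probs`), a stop word (per
#' `stopword_prob`), or an ordinary token whose part-of-speech category and
#' lexicon class are drawn independently from `pos_probs` and
#' `sentiment_mix`. With probability `negation_prob` a negation token is
#' inserted before a content token; the reported word count is the total
#' token count including negations. Uses the current RNG state.
#'
#' @param profile A [group_profile()].
#' @param lexicon A [build_synthetic_lexicon()] result.
#' @return List with `tokens` (character vector), `text` (space-joined), and
#'   `truth`: word_count, content_count, negation_count, stopword_count,
#'   keyword_counts, pos_counts (per tag), annotation_counts (per polarity
#'   class), emotion_counts and negated_emotion_counts (per emotion).
#' @export
synthesize_transcript <- function(profile, lexicon) {
  vocab <- lexicon$vocab
  if (nrow(vocab) == 0) stop("configuration error: empty vocabulary")
  n_content <- max(1L, round(draw_dist(profile$words_per_subject)))

  kw <- profile$keyword_probs
  p_kw <- sum(kw)
  p_stop <- profile$stopword_prob
  mix <- profile$sentiment_mix
  classes <- c(names(mix), "plain")
  class_p <- c(mix, plain = 1 - sum(mix))

  # resolve the emotion class into one of the eight emotions uniformly
  by_cell <- split(vocab$token, paste(vocab$tag, vocab$class, sep = "\r"))
  pick_token <- function(tag, class) {
    cands <- by_cell[[paste(tag, class, sep = "\r")]]
    cands[sample.int(length(cands), 1L)]
  }

  pos_p <- profile$pos_probs[.pos_draw_categories]
  pos_p[is.na(pos_p)] <- 0
  tag_levels <- c(.pos_draw_categories, "other")
  tag_p <- c(pos_p, other = 1 - sum(pos_p))

  u <- stats::runif(n_content)
  kind <- character(n_content)
  kind[u < p_kw] <- "keyword"
  kind[u >= p_kw & u < p_kw + p_stop] <- "stopword"
  kind[u >= p_kw + p_stop] <- "ordinary"

  n_ord <- sum(kind == "ordinary")
  ord_tag <- tag_levels[sample.int(length(tag_levels), n_ord, replace = TRUE, prob = tag_p)]
  ord_class <- classes[sample.int(length(classes), n_ord, replace = TRUE, prob = class_p)]
  ord_class[ord_class == "emotion"] <-
    paste0("emotion_", emotion_categories()[sample.int(8L, sum(ord_class == "emotion"), replace = TRUE)])

  content <- character(n_content)
  if (any(kind == "keyword"))
    content[kind == "keyword"] <-
      names(kw)[sample.int(length(kw), sum(kind == "keyword"), replace = TRUE, prob = kw / p_kw)]
  if (any(kind == "stopword"))
    content[kind == "stopword"] <-
      lexicon$stopwords[sample.int(length(lexicon$stopwords), sum(kind == "stopword"), replace = TRUE)]
  if (n_ord)
    content[kind == "ordinary"] <-
      mapply(pick_token, ord_tag, ord_class, USE.NAMES = FALSE)

  negate <- stats::runif(n_content) < profile$negation_prob
  neg_tokens <- lexicon$negations[sample.int(length(lexicon$negations), sum(negate), replace = TRUE)]

  tokens <- vector("list", n_content)
  j <- 1
  for (i in seq_len(n_content)) {
    if (negate[i]) {
      tokens[[i]] <- c(neg_tokens[j], content[i])
      j <- j + 1
    } else tokens[[i]] <- content[i]
  }
  tokens <- unlist(tokens)

  row <- match(content, vocab$token)
  tag_of <- vocab$tag[row]
  ann_of <- vocab$annotation[row]
  emo_of <- vocab$emotion[row]

  pos_counts <- table(factor(tag_of, levels = tag_levels))
  ann_counts <- table(factor(ann_of, levels = .annotation_levels))
  emo_counts <- table(factor(emo_of, levels = emotion_categories()))
  neg_emo <- table(factor(emo_of[negate], levels = emotion_categories()))
  kw_counts <- table(factor(content[kind == "keyword"], levels = names(kw)))

  truth <- list(
    word_count = length(tokens),
    content_count = n_content,
    negation_count = sum(negate),
    stopword_count = sum(kind == "stopword"),
    keyword_counts = as.vector(kw_counts, mode = "integer") |> stats::setNames(names(kw)),
    pos_counts = as.vector(pos_counts, mode = "integer") |> stats::setNames(tag_levels),
    annotation_counts = as.vector(ann_counts, mode = "integer") |> stats::setNames(.annotation_levels),
    emotion_counts = as.vector(emo_counts, mode = "integer") |> stats::setNames(emotion_categories()),
    negated_emotion_counts = as.vector(neg_emo, mode = "integer") |> stats::setNames(emotion_categories())
  )
  list(tokens = tokens, text = paste(tokens, collapse = " "), truth = truth)
}

#' Sample one demographic record
#'
#' Draws the ten demographic variables from the profile's per-variable
#' probability tables. Demographics never feed back into the audio or text
#' generation process.
#'
#' @param profile A [group_profile()].
#' @return One-row data frame with the ten demographic columns.
#' @export
sample_demographics <- function(profile) {
  d <- profile$demographics
  draw_cat <- function(p) names(p)[sample.int(length(p), 1L, prob = p)]
  age_spec <- if (inherits(d$age, "vm_dist")) d$age else dist_spec("point", d$age)
  ill <- if (inherits(d$n_illnesses, "vm_dist")) round(draw_dist(d$n_illnesses))
         else stats::rpois(1L, d$n_illnesses)
  data.frame(
    sex = ifelse(stats::runif(1) < d$sex, "male", "female"),
    age = round(draw_dist(age_spec)),
    education = draw_cat(d$education),
    occupation = ifelse(stats::runif(1) < d$occupation, "employed", "unemployed"),
    marriage = draw_cat(d$marriage),
    suicide_history = ifelse(stats::runif(1) < d$suicide_history, "yes", "no"),
    hospitalization = draw_cat(d$hospitalization),
    residential = ifelse(stats::runif(1) < d$residential, "alone", "with_others"),
    alcohol = ifelse(stats::runif(1) < d$alcohol, "three_plus_weekly", "less_than_three"),
    n_illnesses = ill,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic cohort
#'
#' Generates `sum(n_subjects)` subjects across the configured groups, each
#' with a waveform, a transcript, a demographic record and a ground-truth
#' log. Deterministic for fixed `(config, seed)`: every subject draws from
#' an independent sub-seed derived from the root seed.
#'
#' @param config Named list of [group_profile()]s (default:
#'   [default_cohort_config()], 41 BP + 150 MDD).
#' @param seed Integer root seed.
#' @param lexicon Shared [build_synthetic_lexicon()]; built on the fly if
#'   `NULL`.
#' @param keep_audio If `FALSE`, waveforms are dropped after synthesis
#'   (callers that extract features subject-by-subject should use
#'   [simulate_feature_matrix()] instead).
#' @return A list of class `vm_cohort`: `subjects` (list of per-subject
#'   records with `id`, `label`, `samples`, `sample_rate`, `tokens`, `text`,
#'   `demographics`), `truth` (per-subject ground-truth list), `lexicon`,
#'   `seed`.
#' @export
generate_cohort <- function(config = default_cohort_config(), seed = 1,
                            lexicon = NULL, keep_audio = TRUE) {
  stopifnot(length(config) >= 1)
  for (p in config) {
    if (!inherits(p, "vm_profile")) stop("configuration error: config entries must be group_profile objects")
    if (p$n_subjects < 1) stop("configuration error: n_subjects must be >= 1 in group ", p$label)
  }
  if (is.null(lexicon)) lexicon <- build_synthetic_lexicon()
  n_total <- sum(vapply(config, function(p) p$n_subjects, integer(1)))
  seeds <- split_seed(seed, n_total)
  subjects <- vector("list", n_total)
  truth <- vector("list", n_total)
  idx <- 0
  for (p in config) {
    for (j in seq_len(p$n_subjects)) {
      idx <- idx + 1
      set.seed(seeds[idx])
      utt <- synthesize_utterance(p)
      tr <- synthesize_transcript(p, lexicon)
      dem <- sample_demographics(p)
      subjects[[idx]] <- list(
        id = sprintf("S%03d", idx), label = p$label,
        samples = if (keep_audio) utt$samples else NULL,
        sample_rate = utt$sample_rate,
        tokens = tr$tokens, text = tr$text, demographics = dem)
      truth[[idx]] <- c(utt$truth, tr$truth)
    }
  }
  names(subjects) <- names(truth) <- vapply(subjects, `[[`, "", "id")
  structure(list(subjects = subjects, truth = truth, lexicon = lexicon,
                 seed = seed),
            class = "vm_cohort")
}

#' Write a cohort to disk
#'
#' Writes per-subject WAV files (PCM 16-bit mono) and UTF-8 transcripts, a
#' cohort manifest CSV (subject id, label, demographics, file paths), a
#' ground-truth CSV, and the lexicon resources.
#'
#' @param cohort A `vm_cohort` generated with `keep_audio = TRUE`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vm_cohort"))
  dir.create(file.path(dir, "wav"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "transcripts"), showWarnings = FALSE)
  rows <- lapply(cohort$subjects, function(s) {
    if (is.null(s$samples)) stop("write_cohort needs keep_audio = TRUE")
    wav_path <- file.path(dir, "wav", paste0(s$id, ".wav"))
    txt_path <- file.path(dir, "transcripts", paste0(s$id, ".txt"))
    write_wav(s$samples, s$sample_rate, wav_path)
    writeLines(s$text, txt_path, useBytes = TRUE)
    cbind(data.frame(subject_id = s$id, label = s$label,
                     stringsAsFactors = FALSE),
          s$demographics,
          data.frame(wav = wav_path, transcript = txt_path,
                     stringsAsFactors = FALSE))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  tr <- do.call(rbind, lapply(names(cohort$truth), function(id) {
    t <- cohort$truth[[id]]
    data.frame(subject_id = id, duration_s = t$duration_s,
               pause_total_s = t$pause_total_s, word_count = t$word_count,
               negation_count = t$negation_count,
               stopword_count = t$stopword_count)
  }))
  utils::write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE)
  write_lexicon(cohort$lexicon, file.path(dir, "lexicon"))
  invisible(dir)
}
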