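# Shared fixtures and independent oracles ------------------------------------

# pure tone burst at full control of amplitude/duration
tone_burst <- function(dur_s, amp = 0.3, f0 = 150, sr = 16000) {
  t <- seq_len(round(dur_s * sr)) / sr
  amp * sin(2 * pi * f0 * t)
}

# near-silent floor segment (-80 dBFS)
floor_seg <- function(dur_s, sr = 16000) rnorm(round(dur_s * sr)) * 1e-4

# tone-silence-tone probe with a single gap of d_ms
gap_probe <- function(d_ms, sr = 16000) {
  c(tone_burst(1, sr = sr), floor_seg(d_ms / 1000, sr), tone_burst(1, sr = sr))
}

# signal with a given set of silence durations separated by voiced bursts
silences_signal <- function(sil_ms, sr = 16000, amp = 0.3) {
  parts <- list(tone_burst(0.8, amp, sr = sr))
  for (d in sil_ms) {
    parts <- c(parts, list(floor_seg(d / 1000, sr)),
               list(tone_burst(0.8, amp, sr = sr)))
  }
  unlist(parts)
}

# brute-force per-window envelope scan: independent of the package's
# vectorized implementation (explicit window loop + manual run scan)
oracle_pauses <- function(samples, sr, threshold_db = 35, min_ms = 200,
                          max_ms = 500, win_ms = 10, hop_ms = 5) {
  win <- round(win_ms / 1000 * sr)
  hop <- round(hop_ms / 1000 * sr)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      counted_s = numeric(0))
  if (length(samples) < win) return(empty)
  starts <- seq(1L, length(samples) - win + 1L, by = hop)
  env <- vapply(starts, function(s) sqrt(mean(samples[s:(s + win - 1L)]^2)),
                numeric(1))
  thr <- max(env) * 10^(-threshold_db / 20)
  below <- env <= thr
  res <- list()
  i <- 1L
  while (i <= length(below)) {
    if (below[i]) {
      j <- i
      while (j < length(below) && below[j + 1L]) j <- j + 1L
      st <- (starts[i] - 1L) / sr
      en <- (starts[j] - 1L + win) / sr
      if (en - st >= min_ms / 1000 - 1e-9)
        res[[length(res) + 1L]] <- data.frame(
          start_s = st, end_s = en, counted_s = min(en - st, max_ms / 1000))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(res)) return(empty)
  do.call(rbind, res)
}

# straight-line reimplementation of the negation sign-flip scoring rule
oracle_scores <- function(tokens, lexicon, negations) {
  out <- numeric(length(tokens))
  for (i in seq_along(tokens)) {
    row <- which(lexicon$token == tokens[i])
    o <- if (length(row)) lexicon$orientation[row[1]] else 0
    neg <- i > 1 && tokens[i - 1] %in% negations
    out[i] <- if (neg) -o else o
  }
  out
}

# tiny polarity lexicon for hand-arithmetic sentiment tests
mini_lexicon <- function() {
  data.frame(
    token = c("good", "great", "bad", "awful", "table", "hmm"),
    orientation = c(0.5, 1.0, -0.5, -1.0, 0, 0),
    annotation = c("Positive", "Positive", "Negative", "Negative",
                   "Neutral", "Not-a-word"),
    stringsAsFactors = FALSE)
}

mini_emotions <- function() {
  data.frame(token = c("happy", "happy", "angry", "scared"),
             emotion = c("joy", "trust", "anger", "fear"),
             stringsAsFactors = FALSE)
}

# small fast profiles for cohort-level tests
fast_profile <- function(label = "BP", n = 5, dur = 8, ...) {
  f <- if (label == "BP") bp_profile else mdd_profile
  f(n_subjects = n, speech_duration_s = dist_spec("point", dur), ...)
}
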