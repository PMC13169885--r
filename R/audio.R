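# Acoustic feature extraction ------------------------------------------------

#' Short-window RMS envelope
#'
#' Computes the RMS level of consecutive analysis windows (default 10 ms
#' windows at a 5 ms hop). Only complete windows are evaluated; trailing
#' samples shorter than one window are ignored.
#'
#' @param samples Numeric waveform in \[-1, 1\].
#' @param sample_rate Hz.
#' @param win_ms,hop_ms Window length and hop in milliseconds.
#' @return List with `rms` (per-window RMS), `start_s` (window start times),
#'   `win_s`, `hop_s`.
#' @export
rms_envelope <- function(samples, sample_rate, win_ms = 10, hop_ms = 5) {
  if (any(!is.finite(samples))) stop("input error: non-finite samples")
  win <- round(win_ms / 1000 * sample_rate)
  hop <- round(hop_ms / 1000 * sample_rate)
  n <- length(samples)
  if (n < win)
    return(list(rms = numeric(0), start_s = numeric(0),
                win_s = win / sample_rate, hop_s = hop / sample_rate))
  starts <- seq(1L, n - win + 1L, by = hop)
  cs <- cumsum(c(0, samples^2))
  sums <- cs[starts + win] - cs[starts]
  list(rms = sqrt(sums / win), start_s = (starts - 1L) / sample_rate,
       win_s = win / sample_rate, hop_s = hop / sample_rate)
}

#' Detect pauses by dB-gated envelope scanning
#'
#' A pause is a maximal run of analysis windows whose RMS level sits at
#' least `threshold_db` below the recording's reference level (the maximum
#' short-window RMS), lasting at least `min_ms`. Each pause's credited
#' duration (`counted_s`) is capped at `max_ms`, emulating silence deletion
#' with a maximum deletion length; intervals themselves are reported
#' uncapped.
#'
#' @param samples Numeric waveform.
#' @param sample_rate Hz.
#' @param threshold_db Gate depth in dB below the reference level (> 0).
#' @param min_ms Minimum pause duration (ms).
#' @param max_ms Maximum credited pause duration (ms).
#' @param win_ms,hop_ms Envelope analysis parameters.
#' @return Data frame with columns `start_s`, `end_s`, `counted_s`, sorted
#'   and non-overlapping; zero rows if no pause qualifies or the waveform is
#'   shorter than one analysis window.
#' @export
detect_pauses <- function(samples, sample_rate, threshold_db = 35,
                          min_ms = 200, max_ms = 500,
                          win_ms = 10, hop_ms = 5) {
  stopifnot(threshold_db > 0, min_ms < max_ms)
  env <- rms_envelope(samples, sample_rate, win_ms, hop_ms)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      counted_s = numeric(0))
  if (!length(env$rms)) return(empty)
  ref <- max(env$rms)
  thr <- ref * 10^(-threshold_db / 20)
  sub <- env$rms <= thr
  if (!any(sub)) return(empty)
  r <- rle(sub)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  keep <- r$values
  starts_idx <- starts_idx[keep]
  ends_idx <- ends_idx[keep]
  start_s <- env$start_s[starts_idx]
  end_s <- env$start_s[ends_idx] + env$win_s
  dur <- end_s - start_s
  ok <- dur >= min_ms / 1000 - 1e-9
  out <- data.frame(start_s = start_s[ok], end_s = end_s[ok],
                    counted_s = pmin(dur[ok], max_ms / 1000))
  out[order(out$start_s), , drop = FALSE]
}

#' Cumulative credited pause duration
#'
#' Sums the credited durations of detected pauses. Under the
#' silence-deletion emulation this equals the original recording length
#' minus the silence-deleted length.
#'
#' @param pauses Data frame from [detect_pauses()].
#' @return Total credited pause time in seconds.
#' @export
cumulative_pause <- function(pauses) {
  if (is.null(pauses) || nrow(pauses) == 0) return(0)
  stopifnot(all(pauses$end_s > pauses$start_s),
            all(pauses$counted_s >= 0),
            all(pauses$counted_s <= pauses$end_s - pauses$start_s + 1e-9))
  sum(pauses$counted_s)
}

#' Pause ratios
#'
#' `pause_per_duration` divides the cumulative pause by the total speaking
#' time (the original, pause-intact recording duration);
#' `pause_per_word` divides it by the number of words spoken.
#'
#' @param pause_total_s Cumulative pause (s).
#' @param total_duration_s Recording duration (s), > 0.
#' @param word_count Words spoken, > 0.
#' @return Named list `pause_per_duration`, `pause_per_word`.
#' @export
pause_ratios <- function(pause_total_s, total_duration_s, word_count) {
  if (!isTRUE(total_duration_s > 0))
    stop("undefined-feature error: total_duration_s must be > 0")
  if (!isTRUE(word_count > 0))
    stop("undefined-feature error: word_count must be > 0")
  list(pause_per_duration = pause_total_s / total_duration_s,
       pause_per_word = pause_total_s / word_count)
}

#' Amplitude statistics
#'
#' Reports the signal's extreme excursions and RMS-derived average peak:
#' `max_peak = max(samples)`, `min_peak = min(samples)`,
#' `peak = max(|samples|)`, and `average_peak = RMS x 1.414` (for a
#' sinusoid the true peak is 1.414 times the RMS level).
#'
#' @param samples Numeric waveform.
#' @return Named list `peak`, `max_peak`, `min_peak`, `average_peak`.
#' @export
amplitude_stats <- function(samples) {
  stopifnot(length(samples) > 0)
  if (any(!is.finite(samples))) stop("input error: non-finite samples")
  rms <- sqrt(mean(samples^2))
  list(peak = max(abs(samples)), max_peak = max(samples),
       min_peak = min(samples), average_peak = rms * 1.414)
}

#' Spectral-gate noise reduction
#'
#' Estimates a noise magnitude profile from the lowest-energy `profile_s`
#' seconds of the recording (by STFT frame energy) and subtracts it from
#' every frame's magnitude spectrum, flooring at a small fraction of the
#' original magnitude. Frames are 20 ms with a 5 ms hop (Hann window,
#' normalized overlap-add), so frame boundaries align with the pause
#' detector's envelope grid. `profile_s = 0` returns the input unchanged.
#' Output length equals input length.
#'
#' @param samples Numeric waveform.
#' @param sample_rate Hz.
#' @param profile_s Seconds of lowest-energy audio used as noise profile.
#' @param floor_frac Minimum retained fraction of each magnitude bin.
#' @return Denoised waveform (numeric, same length).
#' @export
reduce_noise <- function(samples, sample_rate, profile_s = 0.5,
                         floor_frac = 0.02) {
  stopifnot(profile_s >= 0)
  if (profile_s == 0) return(samples)
  if (any(!is.finite(samples))) stop("input error: non-finite samples")
  frame <- round(0.020 * sample_rate)
  hop <- round(0.005 * sample_rate)
  n <- length(samples)
  if (n < frame) return(samples)
  starts <- seq(1L, n - frame + 1L, by = hop)
  win <- 0.5 * (1 - cos(2 * pi * (seq_len(frame) - 1) / (frame - 1)))
  frames <- vapply(starts, function(s) samples[s:(s + frame - 1L)] * win,
                   numeric(frame))
  spec <- stats::mvfft(frames)
  mag <- Mod(spec)
  energy <- colSums(mag^2)
  n_prof <- max(1L, min(length(starts), round(profile_s / 0.005)))
  prof_idx <- order(energy)[seq_len(n_prof)]
  noise_mag <- rowMeans(mag[, prof_idx, drop = FALSE])
  new_mag <- pmax(mag - noise_mag, floor_frac * mag)
  scale <- ifelse(mag > 0, new_mag / mag, 0)
  rec <- Re(stats::mvfft(spec * scale, inverse = TRUE)) / frame
  out <- numeric(n)
  norm <- numeric(n)
  for (j in seq_along(starts)) {
    idx <- starts[j]:(starts[j] + frame - 1L)
    out[idx] <- out[idx] + rec[, j] * win
    norm[idx] <- norm[idx] + win^2
  }
  covered <- norm > 1e-12
  out[covered] <- out[covered] / norm[covered]
  out[!covered] <- samples[!covered]
  out
}

#' Extract the acoustic feature block from one waveform
#'
#' Runs optional noise reduction, pause detection and amplitude statistics,
#' returning the six acoustic variables plus duration bookkeeping. Amplitude
#' statistics are computed on the (optionally noise-reduced) pause-intact
#' signal.
#'
#' @param samples,sample_rate Waveform.
#' @param word_count Words spoken (for `pause_per_word`).
#' @param threshold_db,min_ms,max_ms Pause detector settings.
#' @param noise_profile_s Seconds of noise profile for [reduce_noise()];
#'   0 (default) disables the stage.
#' @return Named list: `total_duration_s`, `pause_total_s`,
#'   `pause_per_duration`, `pause_per_word`, `peak_amplitude`,
#'   `max_peak_amplitude`, `min_peak_amplitude`, `average_peak_amplitude`.
#' @export
extract_audio_features <- function(samples, sample_rate, word_count,
                                   threshold_db = 35, min_ms = 200,
                                   max_ms = 500, noise_profile_s = 0) {
  x <- reduce_noise(samples, sample_rate, noise_profile_s)
  duration <- length(x) / sample_rate
  pauses <- detect_pauses(x, sample_rate, threshold_db, min_ms, max_ms)
  total <- cumulative_pause(pauses)
  ratios <- pause_ratios(total, duration, word_count)
  amp <- amplitude_stats(x)
  list(total_duration_s = duration,
       pause_total_s = total,
       pause_per_duration = ratios$pause_per_duration,
       pause_per_word = ratios$pause_per_word,
       peak_amplitude = amp$peak,
       max_peak_amplitude = amp$max_peak,
       min_peak_amplitude = amp$min_peak,
       average_peak_amplitude = amp$average_peak)
}
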