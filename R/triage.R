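# Input triage: signal-to-noise gating of the recording environment and
# vocal-range estimation/transposition, the two quality-control steps run
# before any singing is scored.

#' Signal-to-noise ratio of a recording environment
#'
#' `SNR = 20 * log10(RMS_signal / RMS_noise)` in dB, where each RMS is the
#' root mean square of the respective sample vector (a sung tone vs. a
#' silent-room recording). pYIN-style transcription degrades substantially
#' below about 14 dB, so the default gate requires `snr_db >= 14`; a gate of
#' 0 (any signal louder than the room) reproduces the earlier, laxer
#' screening mode.
#'
#' @param signal numeric vector of signal samples (or RMS amplitudes).
#' @param noise numeric vector of background-noise samples.
#' @param threshold pass threshold in dB (default 14).
#' @return an object of class `"snr_result"`: a list with `rms_signal`,
#'   `rms_noise`, `snr_db` and `passes`. A silent noise recording yields
#'   `snr_db = NA` and `passes = NA` (undefined, distinct from failure).
#' @examples
#' compute_snr(rep(1, 100), rep(0.1, 100))  # 20 dB, passes
#' @export
compute_snr <- function(signal, noise, threshold = 14) {
  if (!length(signal) || !length(noise)) {
    stop("compute_snr(): signal and noise must be non-empty", call. = FALSE)
  }
  rms <- function(x) sqrt(mean(x^2))
  rs <- rms(signal); rn <- rms(noise)
  if (rn == 0) {
    warning("compute_snr(): silent noise recording; SNR undefined")
    snr <- NA_real_; passes <- NA
  } else {
    snr <- 20 * log10(rs / rn)
    passes <- snr >= threshold
  }
  structure(list(rms_signal = rs, rms_noise = rn, snr_db = snr,
                 passes = passes, threshold = threshold),
            class = "snr_result")
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf("<snr_result: %.2f dB (threshold %.1f) -> %s>\n",
              x$snr_db, x$threshold,
              if (is.na(x$passes)) "undefined" else if (x$passes) "pass" else "fail"))
  invisible(x)
}

#' Construct a vocal range
#'
#' @param low_midi,high_midi integer MIDI bounds, `low_midi < high_midi`.
#' @return an object of class `"vocal_range"` with `low_midi`, `high_midi`
#'   and `mean_midi = (low + high) / 2`.
#' @export
vocal_range <- function(low_midi, high_midi) {
  if (low_midi >= high_midi) {
    stop("vocal_range(): low note must be below high note", call. = FALSE)
  }
  structure(list(low_midi = as.integer(low_midi),
                 high_midi = as.integer(high_midi),
                 mean_midi = (low_midi + high_midi) / 2),
            class = "vocal_range")
}

#' @export
print.vocal_range <- function(x, ...) {
  cat(sprintf("<vocal_range: MIDI %d-%d, mean %.1f>\n",
              x$low_midi, x$high_midi, x$mean_midi))
  invisible(x)
}

#' Estimate a vocal range from a sung low and high note
#'
#' Each bound is the rounded median MIDI pitch of the voiced frames of the
#' corresponding pitch track; the median is robust to isolated octave-error
#' frames. An inverted range (the "high" note sung at or below the "low"
#' note) is an error.
#'
#' @param low_track,high_track [pitch_track()]s with at least `min_voiced`
#'   voiced frames each.
#' @param min_voiced minimum voiced frames per track.
#' @return a [vocal_range()].
#' @export
estimate_range <- function(low_track, high_track, min_voiced = 10) {
  med_midi <- function(track, which) {
    v <- voiced_frames(track)
    if (nrow(v) < min_voiced) {
      stop("estimate_range(): ", which, " track has only ", nrow(v),
           " voiced frames (need >= ", min_voiced, ")", call. = FALSE)
    }
    round_half_away(stats::median(hz_to_midi(v$freq)))
  }
  lo <- med_midi(low_track, "low")
  hi <- med_midi(high_track, "high")
  if (lo >= hi) {
    stop("estimate_range(): high note (MIDI ", hi,
         ") is not above low note (MIDI ", lo, ")", call. = FALSE)
  }
  vocal_range(lo, hi)
}

#' Transpose a melody into a vocal range
#'
#' Shifts all pitches by the integer number of semitones that best matches
#' the melody's mean pitch to the range's mean note (rounding half away from
#' zero, so up- and down-shifts are treated symmetrically). Intervals are
#' preserved exactly, and applying the transposition twice for the same
#' range is idempotent.
#'
#' @param m a [melody()].
#' @param range a [vocal_range()].
#' @return the transposed [melody()].
#' @export
transpose_to_range <- function(m, range) {
  k <- round_half_away(range$mean_midi - mean(note_pitches(m)))
  transpose_melody(m, k)
}
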