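#' @keywords internal
"_PACKAGE"

#' Round half away from zero
#'
#' Deterministic rounding used wherever real-valued MIDI numbers are compared
#' to integer target pitches. `round()` in R rounds half to even, which makes
#' "correct note" membership depend on parity; half-away-from-zero does not.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Convert frequency in Hz to a real-valued MIDI number
#'
#' Standard 12-tone equal temperament mapping with A4 = MIDI 69 = 440 Hz.
#' Rounding to the nearest integer pitch is a separate, explicit step
#' (see [round_half_away()]).
#'
#' @param f0 numeric vector of frequencies in Hz, all > 0.
#' @return real-valued MIDI numbers.
#' @examples
#' hz_to_midi(440)   # 69
#' hz_to_midi(880)   # 81
#' @export
hz_to_midi <- function(f0) {
  if (any(!is.finite(f0) | f0 <= 0)) {
    stop("hz_to_midi(): all frequencies must be finite and > 0", call. = FALSE)
  }
  69 + 12 * log2(f0 / 440)
}

#' Convert a MIDI number to frequency in Hz
#'
#' @param midi numeric vector of (possibly real-valued) MIDI numbers.
#' @return frequencies in Hz.
#' @export
midi_to_hz <- function(midi) {
  440 * 2^((midi - 69) / 12)
}

#' Signed deviation of a frequency from a target pitch, in cents
#'
#' One cent is 1/100 of an equal-tempered semitone; +100 means one semitone
#' sharp of the target.
#'
#' @param f0 frequencies in Hz, > 0.
#' @param target_midi integer MIDI number of the target pitch.
#' @return signed deviations in cents.
#' @examples
#' cents_deviation(440, 69)  # 0
#' cents_deviation(440, 68)  # +100
#' @export
cents_deviation <- function(f0, target_midi) {
  100 * (hz_to_midi(f0) - target_midi)
}

#' Construct a melody
#'
#' A melody is an ordered sequence of note events, each with an onset (s),
#' a duration (s) and a (possibly real-valued) MIDI pitch. Arhythmic melodies
#' are those presented with every note fixed to the same duration (250 ms in
#' the default test protocol); they carry `is_rhythmic = FALSE`.
#'
#' @param pitch numeric vector of MIDI pitches in \[0, 127\].
#' @param onset numeric vector of onsets in seconds, non-decreasing. Defaults
#'   to notes butted end-to-end from 0 using `duration`.
#' @param duration numeric vector of note durations in seconds, > 0.
#'   Defaults to 0.5 s per note.
#' @param id optional label.
#' @param is_rhythmic logical flag; `FALSE` marks an arhythmic (uniform
#'   duration) melody.
#' @return an object of class `"melody"`: a data frame with columns
#'   `onset`, `duration`, `pitch`.
#' @export
melody <- function(pitch, onset = NULL, duration = NULL, id = NULL,
                   is_rhythmic = TRUE) {
  if (length(pitch) < 1) stop("melody(): at least one note required", call. = FALSE)
  if (is.null(duration)) duration <- rep(0.5, length(pitch))
  if (length(duration) == 1) duration <- rep(duration, length(pitch))
  if (is.null(onset)) onset <- cumsum(c(0, duration[-length(duration)]))
  stopifnot(length(onset) == length(pitch), length(duration) == length(pitch))
  if (any(duration <= 0)) stop("melody(): durations must be > 0", call. = FALSE)
  if (any(pitch < 0 | pitch > 127)) {
    stop("melody(): pitches must lie in [0, 127]", call. = FALSE)
  }
  if (is.unsorted(onset)) stop("melody(): onsets must be non-decreasing", call. = FALSE)
  if (!is_rhythmic && length(unique(round(duration, 9))) != 1) {
    stop("melody(): arhythmic melodies must have uniform durations", call. = FALSE)
  }
  structure(
    data.frame(onset = as.numeric(onset), duration = as.numeric(duration),
               pitch = as.numeric(pitch)),
    id = id, is_rhythmic = is_rhythmic,
    class = c("melody", "data.frame")
  )
}

#' Construct an arhythmic melody with uniform note durations
#'
#' @param pitch MIDI pitches.
#' @param note_duration duration of every note in seconds (default 0.25 s,
#'   the protocol's arhythmic note length).
#' @param id optional label.
#' @return a `"melody"` with `is_rhythmic = FALSE`.
#' @export
arhythmic_melody <- function(pitch, note_duration = 0.25, id = NULL) {
  melody(pitch, duration = rep(note_duration, length(pitch)),
         id = id, is_rhythmic = FALSE)
}

#' @export
print.melody <- function(x, ...) {
  id <- attr(x, "id")
  cat(sprintf("<melody%s: %d notes, %s>\n",
              if (!is.null(id)) paste0(" '", id, "'") else "",
              nrow(x),
              if (isTRUE(attr(x, "is_rhythmic"))) "rhythmic" else "arhythmic"))
  print.data.frame(x, ...)
  invisible(x)
}

#' Number of notes in a melody
#' @param m a `"melody"`.
#' @return integer note count.
#' @export
n_notes <- function(m) nrow(m)

#' Note pitches, onsets and durations of a melody
#' @param m a `"melody"`.
#' @return numeric vector.
#' @export
note_pitches <- function(m) m$pitch

#' @rdname note_pitches
#' @export
note_onsets <- function(m) m$onset

#' @rdname note_pitches
#' @export
note_durations <- function(m) m$duration

#' Successive pitch intervals of a melody, in semitones
#'
#' Signed differences between successive pitches after rounding each to the
#' nearest integer MIDI number (half away from zero). Length is one less than
#' the number of notes.
#'
#' @param m a `"melody"` with at least 2 notes.
#' @return integer vector of signed semitone intervals.
#' @export
melody_intervals <- function(m) {
  if (n_notes(m) < 2) {
    stop("melody_intervals(): melody must have at least 2 notes", call. = FALSE)
  }
  diff(round_half_away(note_pitches(m)))
}

#' Transpose a melody by an integer number of semitones
#' @param m a `"melody"`.
#' @param semitones signed integer shift.
#' @return transposed `"melody"`.
#' @export
transpose_melody <- function(m, semitones) {
  p <- note_pitches(m) + semitones
  if (any(p < 0 | p > 127)) {
    stop("transpose_melody(): transposition leaves MIDI range [0, 127]", call. = FALSE)
  }
  melody(p, onset = note_onsets(m), duration = note_durations(m),
         id = attr(m, "id"), is_rhythmic = attr(m, "is_rhythmic"))
}

#' All contiguous n-grams of a sequence
#'
#' @param seq a vector.
#' @param n window length, >= 1.
#' @return a list of length `max(0, length(seq) - n + 1)` of contiguous
#'   windows, in order.
#' @examples
#' extract_ngrams(c(2, 2, -1), 2)
#' @export
extract_ngrams <- function(seq, n) {
  if (length(n) != 1 || is.na(n) || n < 1) {
    stop("extract_ngrams(): n must be a positive integer", call. = FALSE)
  }
  L <- length(seq)
  if (L < n) return(list())
  lapply(seq_len(L - n + 1), function(i) seq[i:(i + n - 1)])
}

#' Construct a frame-level pitch track
#'
#' A pitch track is a series of (time, f0) frames, as produced by a pYIN-style
#' fundamental frequency tracker. Unvoiced frames (f0 absent or <= 0) are kept
#' as `NA` rather than dropped, so that gaps do not bias variance or
#' autocorrelation statistics computed downstream.
#'
#' @param time frame times in seconds, strictly increasing.
#' @param freq fundamental frequency per frame in Hz; `NA` or <= 0 marks an
#'   unvoiced frame.
#' @return an object of class `"pitch_track"`: a data frame with columns
#'   `time`, `freq` (`NA` where unvoiced).
#' @export
pitch_track <- function(time, freq) {
  stopifnot(length(time) == length(freq))
  if (length(time) < 1) stop("pitch_track(): at least one frame required", call. = FALSE)
  if (any(diff(time) <= 0)) {
    stop("pitch_track(): frame times must be strictly increasing", call. = FALSE)
  }
  freq <- as.numeric(freq)
  freq[!is.na(freq) & freq <= 0] <- NA_real_
  structure(data.frame(time = as.numeric(time), freq = freq),
            class = c("pitch_track", "data.frame"))
}

#' @export
print.pitch_track <- function(x, ...) {
  cat(sprintf("<pitch_track: %d frames, %d voiced, %.2f-%.2f s>\n",
              nrow(x), sum(!is.na(x$freq)), min(x$time), max(x$time)))
  invisible(x)
}

#' Voiced frames of a pitch track
#' @param track a `"pitch_track"`.
#' @return the subset of frames with a defined f0.
#' @export
voiced_frames <- function(track) {
  track[!is.na(track$freq), , drop = FALSE]
}
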