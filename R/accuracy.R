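# Low-level singing accuracy/precision measures (Pfordresher-style) and the
# rehearsal-paradigm dependent variable. Deviations are expressed in cents
# (scale-free), and note alignment is positional: these measures deliberately
# do not use edit-based alignment, which belongs to the similarity family.

#' Proportion of correct note events
#'
#' The rehearsal-paradigm outcome: the proportion of sung notes whose
#' rounded MIDI pitch is contained in the set of rounded target pitches.
#' Order-insensitive by construction; incidental (out-of-target) singing
#' lowers the score.
#'
#' @param target target [melody()].
#' @param sung sung recall [melody()], non-empty.
#' @param octave_equivalent if `TRUE`, membership is judged on pitch class
#'   (mod 12) rather than absolute MIDI. Off by default because stimuli are
#'   transposed into the singer's range before presentation.
#' @return proportion in \[0, 1\].
#' @examples
#' t <- melody(c(60, 62, 64)); s <- melody(c(60, 61, 62, 64, 64))
#' proportion_of_correct_note_events(t, s)  # 0.8
#' @export
proportion_of_correct_note_events <- function(target, sung,
                                              octave_equivalent = FALSE) {
  if (n_notes(sung) < 1) {
    stop("proportion_of_correct_note_events(): sung melody is empty", call. = FALSE)
  }
  tp <- round_half_away(note_pitches(target))
  sp <- round_half_away(note_pitches(sung))
  if (octave_equivalent) {
    tp <- tp %% 12; sp <- sp %% 12
  }
  mean(sp %in% tp)
}

# Accuracy = mean absolute deviation (cents) over positionally aligned pairs.
# Precision = mean, over distinct target values occurring >= 2 times among the
# aligned pairs, of the SD (cents) of the sung values produced for that target.
.acc_prec <- function(target_vals, sung_vals) {
  k <- min(length(target_vals), length(sung_vals))
  if (k < 1) stop("no aligned pairs", call. = FALSE)
  tv <- target_vals[seq_len(k)]; sv <- sung_vals[seq_len(k)]
  accuracy <- mean(abs(sv - tv)) * 100
  key <- round_half_away(tv)
  groups <- split(sv, key)
  sds <- vapply(groups[lengths(groups) >= 2],
                function(g) stats::sd(g) * 100, numeric(1))
  precision <- if (length(sds)) mean(sds) else NA_real_
  c(accuracy = accuracy, precision = precision)
}

#' Note accuracy and precision
#'
#' Accuracy: mean absolute deviation (in cents) of each sung pitch from its
#' positionally aligned target pitch. Precision: the consistency with which
#' the singer reproduces a given target pitch across its repeated
#' occurrences -- the mean SD (cents) of sung pitches grouped by target
#' pitch, over targets occurring at least twice; `NA` when no target pitch
#' recurs.
#'
#' @param target,sung melodies; aligned index-by-index up to the shorter
#'   length.
#' @return named numeric vector `c(accuracy, precision)` in cents.
#' @export
note_measures <- function(target, sung) {
  .acc_prec(note_pitches(target), note_pitches(sung))
}

#' Interval accuracy and precision
#'
#' The note measures applied to the successive (unrounded) interval
#' sequences of both melodies, in cents. A constant transposition error on
#' every note leaves interval accuracy at 0.
#'
#' @param target,sung melodies with at least 2 notes each.
#' @return named numeric vector `c(accuracy, precision)` in cents.
#' @export
interval_measures <- function(target, sung) {
  if (n_notes(target) < 2 || n_notes(sung) < 2) {
    stop("interval_measures(): both melodies need at least 2 notes", call. = FALSE)
  }
  .acc_prec(diff(note_pitches(target)), diff(note_pitches(sung)))
}

#' All five accuracy measures for a sung recall
#'
#' @param target,sung melodies.
#' @param octave_equivalent see [proportion_of_correct_note_events()].
#' @return a one-row data frame with columns `melody_note_accuracy`,
#'   `melody_note_precision`, `interval_accuracy`, `interval_precision`
#'   (all cents) and `proportion_of_correct_note_events`.
#' @export
accuracy_measures <- function(target, sung, octave_equivalent = FALSE) {
  nm <- note_measures(target, sung)
  im <- if (n_notes(target) >= 2 && n_notes(sung) >= 2) {
    interval_measures(target, sung)
  } else {
    c(accuracy = NA_real_, precision = NA_real_)
  }
  data.frame(
    melody_note_accuracy = unname(nm["accuracy"]),
    melody_note_precision = unname(nm["precision"]),
    interval_accuracy = unname(im["accuracy"]),
    interval_precision = unname(im["precision"]),
    proportion_of_correct_note_events =
      proportion_of_correct_note_events(target, sung, octave_equivalent)
  )
}
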