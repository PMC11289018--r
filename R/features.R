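# Melodic features used as fixed effects in the explanatory item response
# models: interval entropy, duration-class entropy, tonalness, local step
# contour variation, and corpus n-gram log frequency.

.entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Interval entropy of a melody
#'
#' Normalized Shannon entropy (log2) of the empirical distribution of
#' successive semitone intervals, clamped to \[-12, +12\] (25 classes, the
#' bounded alphabet convention of the FANTASTIC feature set). 0 for a
#' constant-interval melody, 1 for uniform use of all 25 classes.
#'
#' @param m a [melody()] with at least 2 notes.
#' @return entropy in \[0, 1\].
#' @export
i_entropy <- function(m) {
  iv <- pmin(pmax(melody_intervals(m), -12), 12)
  .entropy_bits(table(iv)) / log2(25)
}

#' Duration-class entropy of a melody
#'
#' Normalized entropy of the fuzzified duration-class distribution (5
#' classes, see [fuzzify_durations()]); the normalizer is log2(5). 0 for an
#' arhythmic (uniform-duration) melody.
#'
#' @param m a [melody()].
#' @return entropy in \[0, 1\].
#' @export
d_entropy <- function(m) {
  cls <- fuzzify_durations(note_durations(m))
  .entropy_bits(table(cls)) / log2(5)
}

#' Tonalness of a melody
#'
#' How strongly the melody correlates with a single key center: the maximum
#' over the 24 Krumhansl-Kessler key-profile correlations of the melody's
#' duration-weighted pitch-class profile. Transposition shifts the key label
#' but leaves the value unchanged.
#'
#' @param m a [melody()] whose duration-weighted pitch-class profile is not
#'   perfectly uniform (a flat profile -- e.g. a chromatic scale in equal
#'   durations -- has zero variance and no defined correlation).
#' @return a list with `tonalness` (in \[-1, 1\]) and `key` (the best key
#'   label, e.g. `"C major"`).
#' @export
tonalness <- function(m) {
  prof <- .pc_profile(note_pitches(m), note_durations(m))
  if (stats::sd(prof) == 0) {
    stop("tonalness(): pitch-class profile has zero variance ",
         "(perfectly uniform profile)", call. = FALSE)
  }
  r <- .key_correlations(prof)
  k <- .best_key(prof)
  list(tonalness = r[k], key = .key_labels[k])
}

#' Local variation of the step contour
#'
#' The melody is rendered as a duration-weighted step function of MIDI pitch
#' over its total duration and sampled at `samples` equidistant points
#' (64 by convention); the feature is the mean absolute difference between
#' adjacent samples, in semitones. Invariant to uniform tempo scaling.
#'
#' @param m a [melody()] with at least 2 notes.
#' @param samples number of equidistant contour samples.
#' @return mean absolute adjacent-sample step, in semitones.
#' @export
step_cont_loc_var <- function(m, samples = 64) {
  if (n_notes(m) < 2) {
    stop("step_cont_loc_var(): melody must have at least 2 notes", call. = FALSE)
  }
  t0 <- note_onsets(m)[1]
  t_end <- max(note_onsets(m) + note_durations(m))
  ts <- seq(t0, t_end, length.out = samples)
  idx <- findInterval(ts, note_onsets(m))
  idx[idx < 1L] <- 1L
  c_i <- note_pitches(m)[idx]
  mean(abs(diff(c_i)))
}

#' Corpus n-gram count tables
#'
#' Builds, per n-gram length, the frequency table of interval sequences over
#' all contiguous n-grams (before deduplication) of the corpus. Interval
#' identity makes the table transposition-invariant, matching the
#' deduplication basis of the item bank.
#'
#' @param corpus list of [melody()] objects.
#' @param n_min,n_max n-gram length range.
#' @return a list, one element per length, each with `counts` (named integer
#'   vector keyed by comma-separated interval strings) and `total`.
#' @export
corpus_ngram_counts <- function(corpus, n_min = 3, n_max = 15) {
  out <- list()
  for (n in n_min:n_max) {
    toks <- unlist(lapply(corpus, function(m) {
      if (n_notes(m) < n) return(character(0))
      .ngram_tokens(melody_intervals(m), n - 1L)
    }))
    if (length(toks)) {
      tab <- table(toks)
      out[[as.character(n)]] <- list(counts = stats::setNames(as.integer(tab),
                                                              names(tab)),
                                     total = length(toks))
    }
  }
  out
}

#' Log relative frequency of an item's interval sequence in a corpus
#'
#' Natural log of the item's interval-sequence count among all corpus
#' n-grams of the same length, divided by the total count of such n-grams.
#' Unseen items receive a 0.5-count smoothing: `log(0.5 / total)`.
#'
#' @param m the item [melody()].
#' @param counts a table from [corpus_ngram_counts()].
#' @return natural-log relative frequency (<= 0 in practice).
#' @export
ngram_log_freq <- function(m, counts) {
  n <- n_notes(m)
  entry <- counts[[as.character(n)]]
  if (is.null(entry) || entry$total == 0) {
    stop("ngram_log_freq(): no corpus counts for length ", n, call. = FALSE)
  }
  key <- paste(melody_intervals(m), collapse = ",")
  cnt <- entry$counts[key]
  cnt <- if (is.na(cnt)) 0.5 else as.numeric(cnt)
  log(cnt / entry$total)
}

#' All item features for a melody
#'
#' @param m a [melody()].
#' @param counts optional [corpus_ngram_counts()] table for `log_freq`
#'   (`NA` when absent).
#' @param contour_samples samples for [step_cont_loc_var()].
#' @return one-row data frame with columns `N`, `i_entropy`, `d_entropy`,
#'   `tonalness`, `step_cont_loc_var`, `log_freq`.
#' @export
item_features <- function(m, counts = NULL, contour_samples = 64) {
  ton <- tryCatch(tonalness(m)$tonalness, error = function(e) NA_real_)
  data.frame(
    N = n_notes(m),
    i_entropy = if (n_notes(m) >= 2) i_entropy(m) else NA_real_,
    d_entropy = d_entropy(m),
    tonalness = ton,
    step_cont_loc_var = if (n_notes(m) >= 2) step_cont_loc_var(m, contour_samples)
                        else NA_real_,
    log_freq = if (!is.null(counts)) ngram_log_freq(m, counts) else NA_real_
  )
}
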