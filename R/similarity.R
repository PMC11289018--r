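# Melodic similarity: the opti3 hybrid score and its three components.
#
# opti3 = 3.027 * ngrukkon + 2.502 * rhythfuzz + 1.439 * harmcore
#
# Each component lies in [0, 1] (1 = identity) and is length-normalized by the
# longer melody. The raw weighted sum exceeds 1 for identical melodies; by
# default it is divided by the weight sum so the combined score is also on
# [0, 1], the scale on which sung-recall outcomes are modelled.

#' opti3 component weights
#'
#' The published weights of the three similarity components, derived from
#' perceptual similarity ratings: 3.027 (interval n-grams), 2.502 (fuzzified
#' rhythm), 1.439 (implied harmony).
#'
#' @param w_ngrukkon,w_rhythfuzz,w_harmcore positive component weights.
#' @param normalize divide the weighted sum by the weight total so the
#'   combined score lies in \[0, 1\] (default `TRUE`).
#' @return an object of class `"similarity_weights"`.
#' @export
similarity_weights <- function(w_ngrukkon = 3.027, w_rhythfuzz = 2.502,
                               w_harmcore = 1.439, normalize = TRUE) {
  stopifnot(w_ngrukkon > 0, w_rhythfuzz > 0, w_harmcore > 0)
  structure(list(w_ngrukkon = w_ngrukkon, w_rhythfuzz = w_rhythfuzz,
                 w_harmcore = w_harmcore, normalize = isTRUE(normalize)),
            class = "similarity_weights")
}

#' Levenshtein edit distance between two sequences
#'
#' Number of insertions, deletions and substitutions (unit costs) needed to
#' transform one sequence into the other. Elements are compared for equality;
#' any atomic type works. Empty sequences are allowed: `d(empty, b) =
#' length(b)`.
#'
#' @param a,b vectors.
#' @return non-negative integer distance.
#' @examples
#' edit_distance(strsplit("kitten", "")[[1]], strsplit("sitting", "")[[1]])  # 3
#' @export
edit_distance <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    for (j in seq_len(m)) {
      cost <- if (a[i] == b[j]) 0L else 1L
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L, prev[j] + cost)
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Length-normalized edit similarity
#'
#' `1 - edit_distance(a, b) / max(length(a), length(b))`; 1 for identical
#' sequences, 0 for maximally different ones.
#'
#' @param a,b vectors; at least one non-empty.
#' @return similarity in \[0, 1\].
#' @export
edit_sim <- function(a, b) {
  L <- max(length(a), length(b))
  if (L == 0L) stop("edit_sim(): both sequences are empty", call. = FALSE)
  1 - edit_distance(a, b) / L
}

.ngram_tokens <- function(x, n) {
  vapply(extract_ngrams(x, n), paste, character(1), collapse = ",")
}

#' Interval n-gram similarity (Ukkonen measure)
#'
#' Compares the occurrence-frequency profiles of contiguous interval n-grams
#' of the two melodies: `1 - sum |f_a - f_b| / (N_a + N_b)` over all n-gram
#' types, where `N_x` is the number of n-gram tokens of melody `x`. Identical
#' melodies score 1; melodies sharing no n-gram score 0. Transposition
#' invariant (intervals, not pitches, are compared).
#'
#' When either melody is too short for the requested `n`, `n` falls back to
#' the shorter melody's interval count so 2-3-note items remain scorable.
#'
#' @param a,b melodies with at least 2 notes each.
#' @param n n-gram length (default 3).
#' @return similarity in \[0, 1\].
#' @export
ngrukkon <- function(a, b, n = 3) {
  if (n_notes(a) < 2 || n_notes(b) < 2) {
    stop("ngrukkon(): both melodies need at least 2 notes", call. = FALSE)
  }
  ia <- melody_intervals(a); ib <- melody_intervals(b)
  n_eff <- min(n, length(ia), length(ib))
  ta <- .ngram_tokens(ia, n_eff); tb <- .ngram_tokens(ib, n_eff)
  types <- union(ta, tb)
  fa <- tabulate(match(ta, types), nbins = length(types))
  fb <- tabulate(match(tb, types), nbins = length(types))
  1 - sum(abs(fa - fb)) / (length(ta) + length(tb))
}

#' Fuzzify note durations into five coarse classes
#'
#' Classes \{very short, short, medium, long, very long\} assigned by the
#' log2 ratio of each duration to the melody's median duration, with class
#' boundaries at -1.5, -0.5, +0.5, +1.5. Median-relative, so uniformly
#' scaling all durations (a tempo change) leaves the classes unchanged.
#'
#' @param durations positive durations in seconds.
#' @return integer class codes 1..5 with a `"labels"` attribute.
#' @export
fuzzify_durations <- function(durations) {
  if (length(durations) == 0) stop("fuzzify_durations(): empty input", call. = FALSE)
  if (any(durations <= 0)) stop("fuzzify_durations(): durations must be > 0", call. = FALSE)
  r <- log2(durations / stats::median(durations))
  cls <- findInterval(r, c(-1.5, -0.5, 0.5, 1.5)) + 1L
  structure(cls, labels = c("very short", "short", "medium", "long", "very long"))
}

#' Rhythmic similarity over fuzzified durations
#'
#' Edit similarity between the two melodies' duration-class sequences.
#' Two arhythmic melodies of equal length always score 1 (all durations map
#' to the "medium" class).
#'
#' @param a,b melodies.
#' @return similarity in \[0, 1\].
#' @export
rhythfuzz <- function(a, b) {
  edit_sim(as.integer(fuzzify_durations(note_durations(a))),
           as.integer(fuzzify_durations(note_durations(b))))
}

# Krumhansl-Kessler probe-tone key profiles (major, minor), indexed from C.
.kk_major <- c(6.35, 2.23, 3.48, 2.33, 4.38, 4.09, 2.52, 5.19, 2.39, 3.66, 2.29, 2.88)
.kk_minor <- c(6.33, 2.68, 3.52, 5.38, 2.60, 3.53, 2.54, 4.75, 3.98, 2.69, 3.34, 3.17)
.pc_names <- c("C", "C#", "D", "D#", "E", "F", "F#", "G", "G#", "A", "A#", "B")

# 24 x 12 matrix of rotated profiles; rows 1..12 major keys C..B, 13..24 minor.
.key_profiles <- local({
  rot <- function(p, k) p[((0:11 - k) %% 12) + 1]
  rbind(t(sapply(0:11, function(k) rot(.kk_major, k))),
        t(sapply(0:11, function(k) rot(.kk_minor, k))))
})
.key_labels <- c(paste(.pc_names, "major"), paste(.pc_names, "minor"))

# Duration-weighted pitch-class profile (length 12, indexed from C).
.pc_profile <- function(pitch, duration) {
  pc <- round_half_away(pitch) %% 12
  as.numeric(tapply(duration, factor(pc, levels = 0:11), sum, default = 0))
}

# Correlate a pitch-class profile with all 24 key profiles. Returns the
# correlation vector; NA profile variance raises an error upstream.
.key_correlations <- function(profile) {
  as.numeric(stats::cor(profile, t(.key_profiles)))
}

# Deterministic argmax over key correlations: ties broken major before minor,
# then lowest pitch class.
.best_key <- function(profile) {
  r <- .key_correlations(profile)
  ord <- order(-r, rep(c(1, 2), each = 12), rep(0:11, 2))
  ord[1]
}

#' Implied harmony of a melody (Krumhansl-Schmuckler)
#'
#' The melody is split into contiguous time windows of `segment_dur` seconds
#' (the last may be shorter). Within each window the duration-weighted
#' pitch-class profile is correlated with all 24 rotated Krumhansl-Kessler
#' key profiles and the best-matching key label emitted, ties broken
#' deterministically (major before minor, then lowest pitch class). Windows
#' containing no note onset are skipped.
#'
#' The default window of 2 s corresponds to two beats at the test's nominal
#' tempo and to eight notes of an arhythmic (250 ms/note) item.
#'
#' @param m a [melody()].
#' @param segment_dur window length in seconds (default 2).
#' @return character vector of key labels (e.g. `"C major"`), one per
#'   non-empty segment.
#' @examples
#' implied_harmony(melody(c(60, 64, 67)))  # "C major"
#' @export
implied_harmony <- function(m, segment_dur = 2.0) {
  on <- note_onsets(m) - note_onsets(m)[1]
  seg <- floor(on / segment_dur)
  labs <- vapply(split(seq_len(n_notes(m)), seg), function(idx) {
    prof <- .pc_profile(note_pitches(m)[idx], note_durations(m)[idx])
    .key_labels[.best_key(prof)]
  }, character(1))
  unname(labs)
}

#' Harmonic similarity (harmcore)
#'
#' Edit similarity between the implied-harmony label sequences of the two
#' melodies. Invariant to transposing both melodies by the same amount
#' (labels rotate together).
#'
#' @param a,b melodies.
#' @param segment_dur harmony window in seconds, see [implied_harmony()].
#' @return similarity in \[0, 1\].
#' @export
harmcore <- function(a, b, segment_dur = 2.0) {
  edit_sim(implied_harmony(a, segment_dur), implied_harmony(b, segment_dur))
}

#' opti3 melodic similarity
#'
#' Weighted combination of [ngrukkon()], [rhythfuzz()] and [harmcore()].
#' With `normalize = TRUE` (default) the weighted sum is divided by the
#' weight total, so identical melodies score exactly 1 and the result lies
#' on the \[0, 1\] scale on which sung-recall outcomes are modelled; with
#' `normalize = FALSE` the raw weighted sum is returned (6.968 at identity).
#'
#' @param a,b melodies with at least 2 notes each.
#' @param weights a [similarity_weights()].
#' @param n n-gram length for the interval component.
#' @param segment_dur harmony window in seconds.
#' @param average_ngram_n if `TRUE`, the interval component is averaged over
#'   n-gram lengths 3..8 (where the melodies are long enough) instead of
#'   using the single length `n`.
#' @return an object of class `"similarity_result"`: a one-row data frame
#'   with columns `ngrukkon`, `rhythfuzz`, `harmcore`, `opti3`.
#' @examples
#' m <- melody(c(60, 62, 64, 65, 67))
#' opti3(m, m)$opti3  # 1
#' @export
opti3 <- function(a, b, weights = similarity_weights(), n = 3,
                  segment_dur = 2.0, average_ngram_n = FALSE) {
  v_ngr <- if (average_ngram_n) {
    ns <- 3:8
    mean(vapply(ns, function(k) ngrukkon(a, b, n = k), numeric(1)))
  } else {
    ngrukkon(a, b, n = n)
  }
  v_rhy <- rhythfuzz(a, b)
  v_har <- harmcore(a, b, segment_dur)
  w <- c(weights$w_ngrukkon, weights$w_rhythfuzz, weights$w_harmcore)
  total <- sum(w * c(v_ngr, v_rhy, v_har))
  structure(
    data.frame(ngrukkon = v_ngr, rhythfuzz = v_rhy, harmcore = v_har,
               opti3 = if (weights$normalize) total / sum(w) else total),
    class = c("similarity_result", "data.frame")
  )
}
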