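# Shared fixtures and independent oracles.

# Random test melody: integer-ish pitches in a singable range, durations drawn
# from common note values. Caller controls the RNG seed.
random_melody <- function(n = NULL, rhythmic = TRUE) {
  if (is.null(n)) n <- sample(3:12, 1)
  pitch <- sample(48:79, n, replace = TRUE)
  if (rhythmic) {
    melody(pitch, duration = sample(c(0.25, 0.5, 0.75, 1, 2), n, replace = TRUE))
  } else {
    arhythmic_melody(pitch)
  }
}

# Brute-force recursive Levenshtein oracle (no memoization, no DP).
brute_edit <- function(a, b) {
  if (!length(a)) return(length(b))
  if (!length(b)) return(length(a))
  cost <- if (a[1] == b[1]) 0L else 1L
  min(brute_edit(a[-1], b) + 1L,
      brute_edit(a, b[-1]) + 1L,
      brute_edit(a[-1], b[-1]) + cost)
}

# All sequences of length 0..maxlen over an alphabet, as a list of vectors.
all_seqs <- function(alphabet, maxlen) {
  out <- list(character(0))
  for (len in seq_len(maxlen)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), len), stringsAsFactors = FALSE))
    out <- c(out, lapply(seq_len(nrow(grid)), function(i) {
      unlist(grid[i, ], use.names = FALSE)
    }))
  }
  out
}

# Independent Krumhansl oracle: explicit loop over the 24 keys using the
# published probe-tone vectors, duration-weighted pitch-class counting done
# from scratch.
oracle_key_fit <- function(pitches, durations) {
  maj <- c(6.35, 2.23, 3.48, 2.33, 4.38, 4.09, 2.52, 5.19, 2.39, 3.66, 2.29, 2.88)
  mnr <- c(6.33, 2.68, 3.52, 5.38, 2.60, 3.53, 2.54, 4.75, 3.98, 2.69, 3.34, 3.17)
  prof <- rep(0, 12)
  for (i in seq_along(pitches)) {
    pc <- (sign(pitches[i]) * floor(abs(pitches[i]) + 0.5)) %% 12
    prof[pc + 1] <- prof[pc + 1] + durations[i]
  }
  best_r <- -Inf; best_label <- NA_character_; rs <- numeric(0)
  pcn <- c("C", "C#", "D", "D#", "E", "F", "F#", "G", "G#", "A", "A#", "B")
  for (mode in c("major", "minor")) {
    base <- if (mode == "major") maj else mnr
    for (k in 0:11) {
      rotated <- base[((0:11 - k) %% 12) + 1]
      r <- stats::cor(prof, rotated)
      rs <- c(rs, r)
      if (r > best_r + 1e-12) {  # first-found wins ties: major first, low pc first
        best_r <- r
        best_label <- paste(pcn[k + 1], mode)
      }
    }
  }
  list(tonalness = best_r, key = best_label, correlations = rs)
}

# Exhaustive single-split least-squares changepoint oracle.
oracle_single_split <- function(x, min_seg = 2L) {
  n <- length(x)
  best <- Inf; best_tau <- NA_integer_
  for (tau in min_seg:(n - min_seg)) {
    sse <- sum((x[1:tau] - mean(x[1:tau]))^2) +
      sum((x[(tau + 1):n] - mean(x[(tau + 1):n]))^2)
    if (sse < best) { best <- sse; best_tau <- tau }
  }
  best_tau
}
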