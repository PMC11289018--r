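# Corpus tokenization into a feature-annotated n-gram item bank with
# model-predicted difficulty, in the role the Berkowitz sight-singing corpus
# plays for the deployed test: every contiguous sub-melody of 3..15 notes,
# deduplicated on interval identity (plus duration classes for rhythmic
# banks), annotated with features and a predicted score per trial type.

#' Default difficulty models
#'
#' Fixed-effect coefficient sets of the published explanatory item response
#' models regressing the sung-recall outcome onto melodic features:
#' * `arhythmic`: intercept 0.74, N -0.01, step_cont_loc_var -0.32,
#'   tonalness +0.13, log_freq +0.02;
#' * `rhythmic`: intercept 0.37, N -0.01, step_cont_loc_var -0.50,
#'   log_freq -0.02, d_entropy -0.26, i_entropy -0.19;
#' * `combined` (both trial types in one model; the rhythmic indicator and
#'   its interaction with d_entropy as extra terms): intercept 0.64,
#'   N -0.01, step_cont_loc_var -0.38, tonalness +0.10, log_freq +0.01,
#'   melody_type_rhythmic -0.15, arhythmic x d_entropy -0.08,
#'   rhythmic x d_entropy -0.28.
#'
#' A lower predicted score means a harder item.
#'
#' @return an object of class `"difficulty_model"`: a named list of
#'   coefficient vectors.
#' @export
difficulty_model <- function() {
  structure(list(
    arhythmic = c(intercept = 0.74, N = -0.01, step_cont_loc_var = -0.32,
                  tonalness = 0.13, log_freq = 0.02),
    rhythmic = c(intercept = 0.37, N = -0.01, step_cont_loc_var = -0.50,
                 log_freq = -0.02, d_entropy = -0.26, i_entropy = -0.19),
    combined = c(intercept = 0.64, N = -0.01, step_cont_loc_var = -0.38,
                 tonalness = 0.10, log_freq = 0.01,
                 melody_type_rhythmic = -0.15,
                 arhythmic_x_d_entropy = -0.08, rhythmic_x_d_entropy = -0.28)
  ), class = "difficulty_model")
}

#' Predict an item's score from its features
#'
#' The linear predictor of the chosen trial-type model -- intercept plus the
#' coefficient-weighted features -- clipped to \[0, 1\]. Lower predicted
#' scores indicate harder items.
#'
#' @param features a one-row data frame from [item_features()].
#' @param model a [difficulty_model()].
#' @param trial_type `"arhythmic"` or `"rhythmic"`.
#' @return predicted score in \[0, 1\].
#' @export
predict_item_score <- function(features, model = difficulty_model(),
                               trial_type = c("arhythmic", "rhythmic")) {
  trial_type <- match.arg(trial_type)
  beta <- model[[trial_type]]
  terms <- setdiff(names(beta), "intercept")
  vals <- vapply(terms, function(nm) {
    v <- features[[nm]]
    if (is.null(v) || is.na(v)) {
      stop("predict_item_score(): missing feature '", nm, "'", call. = FALSE)
    }
    as.numeric(v)
  }, numeric(1))
  pred <- unname(beta["intercept"] + sum(beta[terms] * vals))
  min(max(pred, 0), 1)
}

.sub_melody <- function(m, start, len) {
  idx <- start:(start + len - 1L)
  melody(note_pitches(m)[idx], onset = note_onsets(m)[idx],
         duration = note_durations(m)[idx],
         is_rhythmic = attr(m, "is_rhythmic"))
}

#' Tokenize a melody corpus into n-gram items
#'
#' Emits every contiguous sub-melody of `n_min..n_max` notes of every corpus
#' melody, in deterministic order (source, start index, length), then removes
#' duplicates. The deduplication key is the interval sequence (transposition
#' robust, matching range-based transposition at test time); rhythmic banks
#' additionally require an identical duration-class sequence. The first
#' occurrence is kept.
#'
#' @param corpus list of monophonic [melody()] objects; names are used as
#'   source ids when present.
#' @param n_min,n_max item length range in notes; `n_min` must be >= 2.
#' @param rhythmic include duration classes in the deduplication key.
#' @param dedup remove duplicates (disable to count raw windows).
#' @return a data frame with columns `item_id`, `source_melody_id`,
#'   `start_index`, `N` and a list column `melody`.
#' @export
tokenize_corpus <- function(corpus, n_min = 3, n_max = 15, rhythmic = FALSE,
                            dedup = TRUE) {
  if (n_min < 2) stop("tokenize_corpus(): n_min must be >= 2", call. = FALSE)
  ids <- names(corpus)
  if (is.null(ids)) ids <- sprintf("melody%03d", seq_along(corpus))
  rows <- list()
  for (s in seq_along(corpus)) {
    m <- corpus[[s]]
    L <- n_notes(m)
    for (len in n_min:n_max) {
      if (L < len) next
      for (start in seq_len(L - len + 1L)) {
        rows[[length(rows) + 1L]] <- list(source = ids[s], start = start,
                                          len = len,
                                          melody = .sub_melody(m, start, len))
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(item_id = character(0), source_melody_id = character(0),
                      start_index = integer(0), N = integer(0)))
  }
  # deterministic ordering: source position, start, length
  ord <- order(match(vapply(rows, `[[`, character(1), "source"), ids),
               vapply(rows, `[[`, numeric(1), "start"),
               vapply(rows, `[[`, numeric(1), "len"))
  rows <- rows[ord]
  key <- vapply(rows, function(r) {
    k <- paste(melody_intervals(r$melody), collapse = ",")
    if (rhythmic) {
      k <- paste(k, paste(as.integer(fuzzify_durations(note_durations(r$melody))),
                          collapse = ","), sep = "|")
    }
    k
  }, character(1))
  if (dedup) rows <- rows[!duplicated(key)]
  out <- data.frame(
    item_id = sprintf("item%06d", seq_along(rows)),
    source_melody_id = vapply(rows, `[[`, character(1), "source"),
    start_index = vapply(rows, function(r) as.integer(r$start), integer(1)),
    N = vapply(rows, function(r) as.integer(r$len), integer(1)),
    stringsAsFactors = FALSE
  )
  out$melody <- lapply(rows, `[[`, "melody")
  out
}

#' Build a feature-annotated item bank from a corpus
#'
#' Tokenizes the corpus ([tokenize_corpus()]), builds corpus-wide n-gram
#' frequency tables ([corpus_ngram_counts()]), annotates every item with its
#' features and predicts a score for both trial types using
#' [difficulty_model()].
#'
#' @param corpus list of [melody()] objects.
#' @param n_min,n_max item length range in notes.
#' @param rhythmic deduplication mode, see [tokenize_corpus()].
#' @param model a [difficulty_model()].
#' @return an object of class `"item_bank"`: the tokenized data frame plus
#'   the six feature columns and `predicted_score_arhythmic` /
#'   `predicted_score_rhythmic`.
#' @export
build_item_bank <- function(corpus, n_min = 3, n_max = 15, rhythmic = FALSE,
                            model = difficulty_model()) {
  bank <- tokenize_corpus(corpus, n_min, n_max, rhythmic = rhythmic)
  counts <- corpus_ngram_counts(corpus, n_min, n_max)
  feats <- do.call(rbind, lapply(bank$melody, item_features, counts = counts))
  bank <- cbind(bank, feats)
  bank$predicted_score_arhythmic <- vapply(seq_len(nrow(bank)), function(i) {
    # single-pitch-class items have no defined tonalness; leave those NA
    tryCatch(predict_item_score(bank[i, ], model, "arhythmic"),
             error = function(e) NA_real_)
  }, numeric(1))
  bank$predicted_score_rhythmic <- vapply(seq_len(nrow(bank)), function(i) {
    f <- bank[i, ]
    # arhythmic corpora have zero rhythmic-entropy features by construction
    if (is.na(f$d_entropy)) f$d_entropy <- 0
    predict_item_score(f, model, "rhythmic")
  }, numeric(1))
  class(bank) <- c("item_bank", "data.frame")
  bank
}

#' Write an item bank as a tab-separated table
#'
#' One item per row: ids, position, length, comma-separated pitch and
#' duration lists, the six feature columns and the two predicted scores.
#' Rebuilding and rewriting the same bank is byte-identical.
#'
#' @param bank an `"item_bank"` from [build_item_bank()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path) {
  flat <- bank[setdiff(names(bank), "melody")]
  flat$pitches <- vapply(bank$melody, function(m) {
    paste(format(note_pitches(m), trim = TRUE, digits = 12), collapse = ",")
  }, character(1))
  flat$durations <- vapply(bank$melody, function(m) {
    paste(format(note_durations(m), trim = TRUE, digits = 12), collapse = ",")
  }, character(1))
  num <- vapply(flat, is.numeric, logical(1)) & !vapply(flat, is.integer, logical(1))
  flat[num] <- lapply(flat[num], function(x) format(x, digits = 12, trim = TRUE))
  utils::write.table(flat, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an item bank written by [write_item_bank()]
#'
#' @param path file path.
#' @return an `"item_bank"` data frame with the `melody` list column
#'   reconstructed (items are re-read as uniform-onset melodies from the
#'   stored pitch/duration lists).
#' @export
read_item_bank <- function(path) {
  flat <- utils::read.delim(path, stringsAsFactors = FALSE)
  flat$melody <- lapply(seq_len(nrow(flat)), function(i) {
    p <- as.numeric(strsplit(flat$pitches[i], ",")[[1]])
    d <- as.numeric(strsplit(flat$durations[i], ",")[[1]])
    melody(p, duration = d)
  })
  flat$pitches <- NULL
  flat$durations <- NULL
  class(flat) <- c("item_bank", "data.frame")
  flat
}

#' Sample one item per requested length from a bank, in a vocal range
#'
#' Draws (deterministically under a seed) one item of each requested length
#' and transposes it into the given vocal range with [transpose_to_range()].
#'
#' @param bank an `"item_bank"`.
#' @param lengths note counts to sample, one item each.
#' @param range a [vocal_range()], or `NULL` for no transposition.
#' @param seed optional RNG seed.
#' @return list of [melody()] objects.
#' @export
sample_items <- function(bank, lengths, range = NULL, seed = NULL) {
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  lapply(lengths, function(len) {
    idx <- which(bank$N == len)
    if (!length(idx)) stop("sample_items(): no items of length ", len, call. = FALSE)
    m <- bank$melody[[idx[sample.int(length(idx), 1)]]]
    if (!is.null(range)) m <- transpose_to_range(m, range) else m
  })
}
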