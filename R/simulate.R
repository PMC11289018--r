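# Synthetic singer and synthetic study generators. Every stochastic
# operation is a pure function of its inputs and seed, which makes all
# scoring and modelling stages testable without recorded audio.

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    suppressWarnings(rm(".Random.seed", envir = globalenv()))
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(seed)
  }
  expr
}

#' Parameters of the synthetic singer
#'
#' The error structure the scoring measures are designed to detect: Gaussian
#' pitch noise per note (cents), note deletions and insertions, and
#' lognormal duration jitter.
#'
#' @param pitch_sd SD of per-note pitch error in cents (>= 0).
#' @param p_delete,p_insert per-note deletion/insertion probabilities.
#' @param duration_jitter_sd SD of the log duration multiplier.
#' @param seed optional RNG seed; the same seed reproduces the same recall.
#' @return an object of class `"singer_params"`.
#' @export
singer_params <- function(pitch_sd = 50, p_delete = 0.05, p_insert = 0.05,
                          duration_jitter_sd = 0.1, seed = NULL) {
  stopifnot(pitch_sd >= 0, p_delete >= 0, p_delete <= 1,
            p_insert >= 0, p_insert <= 1, duration_jitter_sd >= 0)
  structure(list(pitch_sd = pitch_sd, p_delete = p_delete,
                 p_insert = p_insert,
                 duration_jitter_sd = duration_jitter_sd, seed = seed),
            class = "singer_params")
}

#' Simulate a sung recall of a target melody
#'
#' Per target note: the note is deleted with probability `p_delete`;
#' otherwise it is emitted with Gaussian pitch error (`pitch_sd` cents,
#' clamped to the MIDI range) and its duration multiplied by a lognormal
#' jitter. After each emitted note, a spurious neighbour note (within +/- 3
#' semitones) is inserted with probability `p_insert`. Onsets are rebuilt
#' sequentially from the jittered durations. If every note is deleted the
#' draw is retried once, then signalled.
#'
#' @param target target [melody()].
#' @param params a [singer_params()].
#' @return the simulated recall [melody()].
#' @export
simulate_recall <- function(target, params = singer_params()) {
  .with_seed(params$seed, {
    draw <- function() {
      pitches <- numeric(0); durs <- numeric(0)
      for (i in seq_len(n_notes(target))) {
        if (stats::runif(1) < params$p_delete) next
        p <- note_pitches(target)[i] + stats::rnorm(1, 0, params$pitch_sd) / 100
        d <- note_durations(target)[i] *
          exp(stats::rnorm(1, 0, params$duration_jitter_sd))
        pitches <- c(pitches, p); durs <- c(durs, d)
        if (stats::runif(1) < params$p_insert) {
          off <- sample(c(-3:-1, 1:3), 1)
          pitches <- c(pitches, p + off)
          durs <- c(durs, d)
        }
      }
      list(pitches = pmin(pmax(pitches, 0), 127), durs = durs)
    }
    res <- draw()
    if (!length(res$pitches)) res <- draw()
    if (!length(res$pitches)) {
      stop("simulate_recall(): all notes deleted twice in a row", call. = FALSE)
    }
    melody(res$pitches, duration = res$durs,
           id = paste0(attr(target, "id"), "_recall"),
           is_rhythmic = attr(target, "is_rhythmic"))
  })
}

#' Parameters of the synthetic sustained note
#'
#' A long-note pitch track in cents around the target is generated as
#' `drift * t - scoop_depth * exp(-t / scoop_tau) +
#'  vibrato_amp * sin(2 * pi * vibrato_rate * t) + N(0, noise_sd)`,
#' then converted to Hz. The exponential term emulates an onset "scoop"
#' (starting flat and gliding up to pitch).
#'
#' @param target_midi target pitch (integer MIDI).
#' @param duration track length in seconds (protocol default 5).
#' @param frame_rate frames per second.
#' @param noise_sd frame noise SD in cents.
#' @param drift linear drift in cents per second.
#' @param scoop_depth onset scoop depth in cents.
#' @param scoop_tau scoop time constant in seconds.
#' @param vibrato_amp vibrato amplitude in cents.
#' @param vibrato_rate vibrato rate in Hz.
#' @param seed optional RNG seed.
#' @return an object of class `"long_note_params"`.
#' @export
long_note_params <- function(target_midi = 60, duration = 5, frame_rate = 100,
                             noise_sd = 10, drift = 0, scoop_depth = 0,
                             scoop_tau = 0.3, vibrato_amp = 0,
                             vibrato_rate = 5.5, seed = NULL) {
  stopifnot(duration > 0, frame_rate > 0)
  structure(list(target_midi = target_midi, duration = duration,
                 frame_rate = frame_rate, noise_sd = noise_sd, drift = drift,
                 scoop_depth = scoop_depth, scoop_tau = scoop_tau,
                 vibrato_amp = vibrato_amp, vibrato_rate = vibrato_rate,
                 seed = seed),
            class = "long_note_params")
}

#' Simulate a sustained-note pitch track
#'
#' @param params a [long_note_params()].
#' @return a [pitch_track()].
#' @export
simulate_long_note <- function(params = long_note_params()) {
  .with_seed(params$seed, {
    t <- seq(0, params$duration, by = 1 / params$frame_rate)
    dev <- params$drift * t -
      params$scoop_depth * exp(-t / params$scoop_tau) +
      params$vibrato_amp * sin(2 * pi * params$vibrato_rate * t) +
      stats::rnorm(length(t), 0, params$noise_sd)
    pitch_track(t, midi_to_hz(params$target_midi + dev / 100))
  })
}

.linpred <- function(features, beta) {
  terms <- setdiff(names(beta), "intercept")
  vals <- vapply(terms, function(nm) {
    v <- features[[nm]]
    if (is.null(v) || is.na(v)) 0 else as.numeric(v)
  }, numeric(1))
  unname(beta["intercept"] + sum(beta[terms] * vals))
}

# truncated-normal draw on [0, 1] via the inverse CDF
.rtrunc01 <- function(mu, sd) {
  if (sd == 0) return(pmin(pmax(mu, 0), 1))
  lo <- stats::pnorm((0 - mu) / sd)
  hi <- stats::pnorm((1 - mu) / sd)
  mu + sd * stats::qnorm(stats::runif(length(mu), lo, hi))
}

#' Simulate a study of sung-recall trials
#'
#' Generates one trial per participant x item under the explanatory item
#' response structure the trial models assume: participant abilities are
#' drawn `N(0, ability_sd)`, the expected outcome is the feature linear
#' predictor plus ability, clipped to \[0, 1\], and the observed outcome
#' adds truncated-normal noise within \[0, 1\] (keeping the linear-model
#' assumption of the downstream analysis rather than introducing an
#' unmodelled link).
#'
#' @param n_participants number of participants.
#' @param items an item bank data frame ([build_item_bank()]) annotated with
#'   the features `betas` names.
#' @param ability_sd SD of the latent ability distribution.
#' @param betas named coefficient vector (see [difficulty_model()]);
#'   defaults to the arhythmic set.
#' @param noise_sd residual outcome noise SD.
#' @param trial_type label stored on the trials.
#' @param seed optional RNG seed.
#' @return data frame of trial records: `participant_id`, `item_id`,
#'   `trial_type`, `attempt`, the item feature columns, `true_ability`
#'   (the simulated ground truth) and `outcome`.
#' @export
simulate_study <- function(n_participants, items, ability_sd = 0.1,
                           betas = difficulty_model()$arhythmic,
                           noise_sd = 0.1,
                           trial_type = c("arhythmic", "rhythmic"),
                           seed = NULL) {
  trial_type <- match.arg(trial_type)
  .with_seed(seed, {
    abilities <- stats::rnorm(n_participants, 0, ability_sd)
    feat_cols <- intersect(
      c("N", "i_entropy", "d_entropy", "tonalness", "step_cont_loc_var",
        "log_freq"), names(items))
    mu_item <- vapply(seq_len(nrow(items)), function(i) {
      .linpred(items[i, ], betas)
    }, numeric(1))
    grid <- expand.grid(p = seq_len(n_participants), i = seq_len(nrow(items)))
    mu <- pmin(pmax(mu_item[grid$i] + abilities[grid$p], 0), 1)
    out <- data.frame(
      participant_id = sprintf("p%03d", grid$p),
      item_id = items$item_id[grid$i],
      trial_type = trial_type,
      attempt = 1L,
      stringsAsFactors = FALSE
    )
    out <- cbind(out, items[grid$i, feat_cols, drop = FALSE])
    out$true_ability <- abilities[grid$p]
    out$outcome <- .rtrunc01(mu, noise_sd)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a battery of long-note measures driven by three latent processes
#'
#' Generates per-participant values of the six retained long-note measures
#' from three independent latent processes -- pitch volatility, pitch
#' accuracy and onset scoop -- with the block loading structure the
#' long-note composite pipeline is designed to recover: accuracy loads the
#' accuracy and DTW measures, volatility the autocorrelation (positively)
#' and runs-test (negatively) measures, and scoop the second-changepoint
#' time, with the changepoint count cross-loading on volatility and scoop.
#' Unique variances are set to one minus the squared loadings so each
#' indicator has unit variance.
#'
#' @param n number of participants (rows).
#' @param seed optional RNG seed.
#' @return data frame of the six measures with the generating loading matrix
#'   attached as attribute `"true_loadings"` (columns `volatility`,
#'   `accuracy`, `scoop`).
#' @export
simulate_longnote_battery <- function(n, seed = NULL) {
  .with_seed(seed, {
    L <- rbind(
      accuracy                 = c(0.00,  0.93,  0.00),
      dtw_distance             = c(0.20,  0.88,  0.10),
      autocorrelation_mean     = c(0.84,  0.19, -0.18),
      run_test                 = c(-0.90, 0.02,  0.00),
      no_cpts                  = c(0.52,  0.05, -0.78),
      beginning_of_second_cpt  = c(0.05,  0.07,  0.95)
    )
    colnames(L) <- c("volatility", "accuracy", "scoop")
    Z <- matrix(stats::rnorm(n * 3), n, 3)
    u <- sqrt(pmax(1 - rowSums(L^2), 0.01))
    E <- matrix(stats::rnorm(n * nrow(L)), n, nrow(L)) %*% diag(u)
    X <- Z %*% t(L) + E
    colnames(X) <- rownames(L)
    structure(as.data.frame(X), true_loadings = L)
  })
}
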