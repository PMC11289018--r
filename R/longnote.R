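# Seven sustained-note measures computed from a frame-level pitch track:
# accuracy (cents), pitch variance (Hz^2), path-normalized DTW distance to an
# ideal flat track, mean autocorrelation, Wald-Wolfowitz runs-test z,
# changepoint count (PELT mean-shift), and the time of the second changepoint
# (an indicator of onset "scoop").

#' Running-median smoothing of a pitch track
#'
#' Approximates a smoothed f0 track with a running median (default 5 frames)
#' over the voiced frames; unvoiced frames stay missing. Robust to isolated
#' octave-error frames and fully deterministic.
#'
#' @param track a [pitch_track()].
#' @param k odd window length in frames.
#' @return a smoothed [pitch_track()].
#' @export
smooth_pitch_track <- function(track, k = 5) {
  v <- !is.na(track$freq)
  f <- track$freq
  if (sum(v) >= k) {
    f[v] <- as.numeric(stats::runmed(f[v], k, endrule = "median"))
  }
  pitch_track(track$time, f)
}

#' Dynamic time warping distance between two series
#'
#' Classic DTW with absolute-difference local cost and symmetric steps
#' (diagonal, horizontal, vertical). Returns the accumulated cost divided by
#' the warping-path length, removing the trivial dependence on trial
#' duration.
#'
#' @param x,y numeric series.
#' @return list with `distance` (path-normalized), `cost` (raw accumulated
#'   cost) and `path_length`.
#' @export
dtw_distance <- function(x, y) {
  n <- length(x); m <- length(y)
  stopifnot(n > 0, m > 0)
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  step <- matrix(0L, n + 1L, m + 1L)  # 1 diag, 2 up (i-1), 3 left (j-1)
  for (i in seq_len(n)) {
    cost_row <- abs(x[i] - y)
    for (j in seq_len(m)) {
      choices <- c(D[i, j], D[i, j + 1L], D[i + 1L, j])
      k <- which.min(choices)
      D[i + 1L, j + 1L] <- cost_row[j] + choices[k]
      step[i + 1L, j + 1L] <- k
    }
  }
  # backtrack to count path cells
  i <- n + 1L; j <- m + 1L; len <- 0L
  while (i > 1L || j > 1L) {
    len <- len + 1L
    k <- step[i, j]
    if (k == 1L) { i <- i - 1L; j <- j - 1L }
    else if (k == 2L) i <- i - 1L
    else j <- j - 1L
  }
  list(distance = D[n + 1L, m + 1L] / len, cost = D[n + 1L, m + 1L],
       path_length = len)
}

#' Wald-Wolfowitz runs-test z statistic
#'
#' Dichotomizes the series about its median (values equal to the median are
#' dropped), counts sign runs and returns the large-sample z statistic.
#' Approximately N(0, 1) for an i.i.d. series; strongly negative values
#' indicate slow drifts (too few runs), positive values rapid alternation.
#'
#' @param x numeric series.
#' @return z statistic, or `NA` when fewer than two distinct signs remain.
#' @export
runs_test_z <- function(x) {
  s <- sign(x - stats::median(x))
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  if (n1 == 0 || n2 == 0) return(NA_real_)
  R <- 1L + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / n + 1
  sigma2 <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (sigma2 <= 0) return(NA_real_)
  (R - mu) / sqrt(sigma2)
}

#' PELT mean-shift changepoint detection
#'
#' Penalized exact linear-time segmentation of a series into constant-mean
#' segments. The cost of a segment is its residual sum of squares scaled by
#' a robust noise variance estimate (median absolute successive difference),
#' and each additional changepoint pays an MBIC-style penalty of
#' `3 * log(n)` by default, matching the defaults of the standard mean-shift
#' changepoint routine this mirrors.
#'
#' @param x numeric series.
#' @param penalty penalty per changepoint; default `3 * log(length(x))`.
#' @param min_seg_len minimum segment length in frames.
#' @param noise_lag lag used for the robust noise-scale estimate (median
#'   absolute difference at this lag). Series that have been smoothed are
#'   autocorrelated at short lags, so their lag-1 differences understate the
#'   marginal noise; pass a lag at least the smoothing window.
#' @return integer vector of changepoint indices (the last index of each
#'   segment except the final one); empty when no change is detected.
#' @export
pelt_mean_cpts <- function(x, penalty = NULL, min_seg_len = 2L,
                           noise_lag = 1L) {
  n <- length(x)
  if (n < 2L * min_seg_len) return(integer(0))
  if (is.null(penalty)) penalty <- 3 * log(n)
  noise_lag <- min(noise_lag, n - 1L)
  # centre first: the cumulative-sum cost cancels catastrophically otherwise
  x <- x - mean(x)
  spread <- stats::sd(x)
  if (spread <= .Machine$double.eps^0.5 * (abs(mean(x)) + 1)) {
    return(integer(0))  # constant series: nothing to segment
  }
  sigma <- stats::median(abs(diff(x, lag = noise_lag))) / (0.6745 * sqrt(2))
  if (!is.finite(sigma) || sigma <= spread * 1e-8) {
    # (near-)noiseless series: any true step still dominates
    sigma <- spread * 1e-3
  }
  s1 <- c(0, cumsum(x)); s2 <- c(0, cumsum(x^2))
  segcost <- function(a, b) {  # cost of x[a..b], scaled
    len <- b - a + 1L
    max((s2[b + 1L] - s2[a]) - (s1[b + 1L] - s1[a])^2 / len, 0) / sigma^2
  }
  FF <- rep(Inf, n + 1L); FF[1L] <- -penalty
  last <- integer(n + 1L)
  cands <- 0L
  for (t in seq_len(n)) {
    if (t < min_seg_len) next
    mature <- t - cands >= min_seg_len
    ok <- cands[mature]
    if (!length(ok)) next
    vals <- vapply(ok, function(tau) FF[tau + 1L] + segcost(tau + 1L, t) + penalty,
                   numeric(1))
    k <- which.min(vals)
    FF[t + 1L] <- vals[k]
    last[t + 1L] <- ok[k]
    keep <- vals - penalty <= FF[t + 1L]
    cands <- c(ok[keep], cands[!mature], t)
  }
  cpts <- integer(0)
  t <- n
  while (t > 0L) {
    tau <- last[t + 1L]
    if (tau > 0L) cpts <- c(tau, cpts)
    t <- tau
  }
  cpts
}

#' Long-note measures for a sustained-note pitch track
#'
#' Computes, over the voiced frames of the (by default smoothed) track:
#' * `accuracy`: mean absolute deviation from the target pitch, in cents;
#' * `var`: variance of the f0 series in Hz^2;
#' * `dtw_distance`: path-normalized DTW distance between the cents-deviation
#'   series and an ideal all-zero series of equal length;
#' * `autocorrelation_mean`: mean sample autocorrelation over lags
#'   `1..floor(L/2)`;
#' * `run_test`: Wald-Wolfowitz runs-test z about the track median
#'   (`NA` for a constant track);
#' * `no_cpts`: number of mean-shift changepoints found by PELT;
#' * `beginning_of_second_cpt`: the time (s) at which the second changed
#'   segment begins, `NA` when fewer than two changepoints exist. An early
#'   second changepoint can indicate an onset "scoop".
#'
#' @param track a [pitch_track()] with at least `min_voiced` voiced frames.
#' @param target_midi integer MIDI number of the target tone.
#' @param smooth apply [smooth_pitch_track()] first (default `TRUE`).
#' @param smooth_k smoothing window in frames.
#' @param min_voiced minimum number of voiced frames required.
#' @param cpt_penalty penalty forwarded to [pelt_mean_cpts()].
#' @return an object of class `"long_note_measures"`: a one-row data frame
#'   with the seven columns above; changepoint times (s) are attached as
#'   attribute `"cpt_times"`.
#' @export
long_note_measures <- function(track, target_midi, smooth = TRUE,
                               smooth_k = 5, min_voiced = 10,
                               cpt_penalty = NULL) {
  if (smooth) track <- smooth_pitch_track(track, smooth_k)
  v <- voiced_frames(track)
  L <- nrow(v)
  if (L < min_voiced) {
    stop("long_note_measures(): only ", L, " voiced frames (need >= ",
         min_voiced, ")", call. = FALSE)
  }
  dev <- cents_deviation(v$freq, target_midi)
  accuracy <- mean(abs(dev))
  f0_var <- stats::var(v$freq)
  dtw <- dtw_distance(dev, numeric(L))$distance
  ac_mean <- if (stats::sd(v$freq) > 0) {
    a <- stats::acf(v$freq, lag.max = floor(L / 2), plot = FALSE,
                    demean = TRUE)$acf[-1]
    mean(a)
  } else NA_real_
  z <- runs_test_z(dev)
  cpts <- pelt_mean_cpts(v$freq, penalty = cpt_penalty,
                         min_seg_len = max(2L, if (smooth) smooth_k else 2L),
                         noise_lag = if (smooth) smooth_k + 1L else 1L)
  cpt_times <- if (length(cpts)) v$time[pmin(cpts + 1L, L)] else numeric(0)
  second <- if (length(cpts) >= 2) cpt_times[2] else NA_real_
  structure(
    data.frame(accuracy = accuracy, var = f0_var, dtw_distance = dtw,
               autocorrelation_mean = ac_mean, run_test = z,
               no_cpts = length(cpts), beginning_of_second_cpt = second),
    cpt_times = cpt_times,
    class = c("long_note_measures", "data.frame")
  )
}

#' Average long-note measures over trials
#'
#' Field-wise mean over a list of per-trial measures, ignoring missing
#' values; the number of contributing trials per field is attached as the
#' `"n_trials"` attribute.
#'
#' @param per_trial non-empty list of [long_note_measures()] results.
#' @return a one-row `"long_note_measures"` data frame of means.
#' @export
average_over_trials <- function(per_trial) {
  if (!length(per_trial)) stop("average_over_trials(): empty trial list", call. = FALSE)
  tab <- do.call(rbind, lapply(per_trial, as.data.frame))
  means <- vapply(tab, function(col) mean(col, na.rm = TRUE), numeric(1))
  means[is.nan(means)] <- NA_real_
  n_contrib <- vapply(tab, function(col) sum(!is.na(col)), integer(1))
  structure(as.data.frame(as.list(means)), n_trials = n_contrib,
            class = c("long_note_measures", "data.frame"))
}
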