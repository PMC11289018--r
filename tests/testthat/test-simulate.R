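test_that("a zero-error singer reproduces the target exactly", {
  target <- melody(c(60, 62, 64, 65), duration = c(0.25, 0.5, 0.25, 1))
  p <- singer_params(pitch_sd = 0, p_delete = 0, p_insert = 0,
                     duration_jitter_sd = 0, seed = 1)
  rec <- simulate_recall(target, p)
  expect_equal(note_pitches(rec), note_pitches(target))
  expect_equal(note_durations(rec), note_durations(target))
  expect_equal(opti3(target, rec)$opti3, 1)
  expect_equal(accuracy_measures(target, rec)$proportion_of_correct_note_events, 1)
})

test_that("simulated recalls are pure functions of their seed", {
  target <- melody(c(60, 62, 64, 65, 67))
  p <- singer_params(pitch_sd = 80, p_delete = 0.2, p_insert = 0.2,
                     duration_jitter_sd = 0.3, seed = 99)
  r1 <- simulate_recall(target, p)
  r2 <- simulate_recall(target, p)
  expect_identical(note_pitches(r1), note_pitches(r2))
  expect_identical(note_durations(r1), note_durations(r2))
  t1 <- simulate_long_note(long_note_params(noise_sd = 30, seed = 7))
  t2 <- simulate_long_note(long_note_params(noise_sd = 30, seed = 7))
  expect_identical(t1$freq, t2$freq)
  s1 <- simulate_study(5, data.frame(item_id = "i1", N = 5), seed = 3)
  s2 <- simulate_study(5, data.frame(item_id = "i1", N = 5), seed = 3)
  expect_identical(s1$outcome, s2$outcome)
})

test_that("the seeded simulators do not disturb the global RNG stream", {
  set.seed(5)
  a <- runif(1)
  set.seed(5)
  invisible(simulate_recall(melody(c(60, 62, 64)), singer_params(seed = 1)))
  invisible(simulate_long_note(long_note_params(seed = 2)))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("huge pitch noise drives correctness to the analytic chance level", {
  target <- melody(c(60, 62, 64))
  sd_st <- 20  # 2000 cents in semitones
  props <- vapply(1:200, function(i) {
    r <- simulate_recall(target, singer_params(pitch_sd = 2000, p_delete = 0,
                                               p_insert = 0, seed = 5000 + i))
    proportion_of_correct_note_events(target, r)
  }, numeric(1))
  # P(round(p0 + e) in {60, 62, 64}) for e ~ N(0, 20 semitones)
  chance_per_note <- vapply(note_pitches(target), function(p0) {
    sum(vapply(c(60, 62, 64), function(s) {
      pnorm((s + 0.5 - p0) / sd_st) - pnorm((s - 0.5 - p0) / sd_st)
    }, numeric(1)))
  }, numeric(1))
  analytic <- mean(chance_per_note)
  mc_se <- sd(props) / sqrt(length(props))
  expect_lt(abs(mean(props) - analytic), 4 * mc_se + 0.005)
})

test_that("an error-free long note is constant at the target", {
  tr <- simulate_long_note(long_note_params(noise_sd = 0, seed = 1))
  expect_equal(unique(tr$freq), midi_to_hz(60))
  expect_equal(long_note_measures(tr, 60)$accuracy, 0)
})

test_that("frame noise calibrates to the folded-normal mean", {
  sd_cents <- 25
  devs <- vapply(1:200, function(i) {
    tr <- simulate_long_note(long_note_params(noise_sd = sd_cents,
                                              duration = 2, seed = 800 + i))
    mean(abs(cents_deviation(tr$freq, 60)))
  }, numeric(1))
  expect_equal(mean(devs), sd_cents * sqrt(2 / pi), tolerance = 0.03)
})

test_that("scoop tracks start flat and glide up to pitch", {
  tr <- simulate_long_note(long_note_params(noise_sd = 0, scoop_depth = 200,
                                            scoop_tau = 0.3, seed = 1))
  dev <- cents_deviation(tr$freq, 60)
  expect_equal(dev[1], -200, tolerance = 1e-6)
  expect_gt(dev[length(dev)], -1)
  expect_true(all(diff(dev) > 0))
})

test_that("a noiseless study equals the clipped linear predictor", {
  items <- data.frame(item_id = c("a", "b"), N = c(3, 30),
                      step_cont_loc_var = c(0.1, 0.5), tonalness = c(0.9, 0.2),
                      log_freq = c(-2, -9))
  trials <- simulate_study(4, items, ability_sd = 0, noise_sd = 0, seed = 11)
  beta <- difficulty_model()$arhythmic
  expected <- vapply(seq_len(nrow(trials)), function(i) {
    r <- trials[i, ]
    min(max(beta[["intercept"]] + beta[["N"]] * r$N +
              beta[["step_cont_loc_var"]] * r$step_cont_loc_var +
              beta[["tonalness"]] * r$tonalness +
              beta[["log_freq"]] * r$log_freq, 0), 1)
  }, numeric(1))
  expect_equal(trials$outcome, expected, tolerance = 1e-12)
  expect_true(all(trials$attempt == 1))
})

test_that("study outcomes stay inside [0, 1] under heavy noise", {
  items <- data.frame(item_id = sprintf("i%d", 1:5), N = c(3, 6, 9, 12, 15))
  trials <- simulate_study(30, items, ability_sd = 0.5, noise_sd = 0.5,
                           seed = 12)
  expect_true(all(trials$outcome >= 0 & trials$outcome <= 1))
})

test_that("the long-note battery has the declared latent block structure", {
  dat <- simulate_longnote_battery(2000, seed = 3)
  expect_equal(dim(dat), c(2000L, 6L))
  truth <- attr(dat, "true_loadings")
  expect_equal(rownames(truth)[1], "accuracy")
  # indicators have roughly unit variance and the declared pairwise structure
  expect_true(all(abs(apply(dat, 2, sd) - 1) < 0.1))
  expect_gt(cor(dat$accuracy, dat$dtw_distance), 0.6)       # shared accuracy
  expect_lt(cor(dat$autocorrelation_mean, dat$run_test), -0.6)  # volatility
  expect_lt(cor(dat$no_cpts, dat$beginning_of_second_cpt), -0.5)  # scoop
})
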