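sim_items <- function(n_items = 20, seed = 1) {
  set.seed(seed)
  data.frame(
    item_id = sprintf("item%03d", seq_len(n_items)),
    N = sample(3:15, n_items, replace = TRUE),
    step_cont_loc_var = runif(n_items, 0.02, 0.6),
    tonalness = runif(n_items, 0.2, 0.95),
    log_freq = runif(n_items, -9, -2),
    d_entropy = runif(n_items, 0, 0.8),
    i_entropy = runif(n_items, 0.1, 0.9)
  )
}

test_that("Nakagawa R2 matches its closed form and ordering constraints", {
  r2 <- nakagawa_r2(1, 1, 2)
  expect_equal(unname(r2), c(0.25, 0.50))
  expect_equal(unname(nakagawa_r2(3, 0, 1)),
               rep(3 / 4, 2))                    # no random variance: R2m = R2c
  expect_equal(unname(nakagawa_r2(0, 2, 2)[1]), 0)  # no fixed effects: R2m = 0
  set.seed(201)
  for (rep in 1:20) {
    v <- runif(3)
    r2 <- nakagawa_r2(v[1], v[2], v[3])
    expect_lte(r2[["r2_marginal"]], r2[["r2_conditional"]])
    expect_lte(r2[["r2_conditional"]], 1)
    expect_gte(r2[["r2_marginal"]], 0)
  }
})

test_that("the trial model recovers simulated structure and is row-order invariant", {
  items <- sim_items(20)
  trials <- simulate_study(60, items, ability_sd = 0.08,
                           betas = difficulty_model()$arhythmic,
                           noise_sd = 0.08, seed = 42)
  fit <- fit_trial_model(trials, "arhythmic")
  expect_s4_class(fit$fit, "lmerMod")
  expect_true(all(c("N", "step_cont_loc_var", "tonalness", "log_freq") %in%
                    fit$coefficients$term))
  # row-order invariance
  fit2 <- fit_trial_model(trials[sample(nrow(trials)), ], "arhythmic")
  expect_equal(fit2$coefficients$estimate, fit$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(fit2$r2_conditional, fit$r2_conditional, tolerance = 1e-6)
  # with near-zero noise the conditional R2 approaches 1
  quiet <- simulate_study(40, items, ability_sd = 0.08,
                          noise_sd = 0.002, seed = 43)
  fitq <- fit_trial_model(quiet, "arhythmic")
  expect_gt(fitq$r2_conditional, 0.99)
  expect_error(fit_trial_model(trials[trials$participant_id == "p001", ],
                               "arhythmic"), "2 participants")
})

test_that("ability scores track the simulated abilities and shrink correctly", {
  items <- sim_items(20)
  trials <- simulate_study(80, items, ability_sd = 0.08, noise_sd = 0.08,
                           seed = 44)
  fit <- fit_trial_model(trials, "arhythmic")
  ab <- ability_scores(fit)
  truth <- unique(trials[c("participant_id", "true_ability")])
  merged <- merge(ab, truth)
  expect_gt(cor(merged$ability, merged$true_ability), 0.7)
  # shuffling participant labels destroys the correlation; the fit may even
  # go singular (zero random-intercept variance), the extreme no-signal case
  set.seed(441)
  shuffled <- trials
  shuffled$participant_id <- sample(shuffled$participant_id)
  fs <- fit_trial_model(shuffled, "arhythmic")
  ms <- merge(ability_scores(fs), truth)
  cc <- suppressWarnings(cor(ms$ability, ms$true_ability))
  expect_true(is.na(cc) || abs(cc) < 0.25)
  # zero ability variance: intercepts shrink toward 0
  flat <- simulate_study(40, items, ability_sd = 0, noise_sd = 0.08, seed = 45)
  ff <- fit_trial_model(flat, "arhythmic")
  expect_lt(sd(ability_scores(ff)$ability), 0.02)
})

test_that("the combined specification carries the trial-type interaction", {
  items <- sim_items(16)
  arh <- simulate_study(30, items, betas = difficulty_model()$arhythmic,
                        trial_type = "arhythmic", seed = 46)
  rhy <- simulate_study(30, items, betas = difficulty_model()$rhythmic,
                        trial_type = "rhythmic", seed = 47)
  rhy$participant_id <- paste0("r", rhy$participant_id)
  fit <- fit_trial_model(rbind(arh, rhy), "combined")
  expect_true(any(grepl("melody_typerhythmic$", fit$coefficients$term)))
  expect_true(any(grepl("melody_type.*d_entropy", fit$coefficients$term)))
})

test_that("parallel analysis counts real components, not noise", {
  set.seed(211)
  noise <- matrix(rnorm(200 * 6), 200, 6)
  expect_lte(parallel_analysis(noise, seed = 1), 1)
  # three strong orthogonal factors
  Z <- matrix(rnorm(200 * 3), 200, 3)
  X3 <- cbind(Z[, 1] + rnorm(200, 0, 0.4), Z[, 1] + rnorm(200, 0, 0.4),
              Z[, 2] + rnorm(200, 0, 0.4), Z[, 2] + rnorm(200, 0, 0.4),
              Z[, 3] + rnorm(200, 0, 0.4), Z[, 3] + rnorm(200, 0, 0.4))
  expect_equal(as.integer(parallel_analysis(X3, seed = 2)), 3L)
  # six noisy copies of one factor
  f <- rnorm(200)
  X1 <- sapply(1:6, function(i) f + rnorm(200, 0, 0.4))
  expect_equal(as.integer(parallel_analysis(X1, seed = 3)), 1L)
  expect_error(parallel_analysis(cbind(X1[, 1:2], 0)), "constant")
  expect_error(parallel_analysis(X1[, 1:2]), ">= 3 variables")
  # seeded: reproducible thresholds
  expect_identical(attr(parallel_analysis(X3, seed = 9), "thresholds"),
                   attr(parallel_analysis(X3, seed = 9), "thresholds"))
})

test_that("pca_composite rotates, scores and drops low-communality variables", {
  set.seed(221)
  dat <- simulate_longnote_battery(300, seed = 5)
  cm <- pca_composite(dat, 3, rotation = "varimax")
  expect_equal(dim(cm$loadings), c(6L, 3L))
  expect_true(all(cm$h2 >= 0 & cm$h2 <= 1 + 1e-9))
  expect_equal(dim(cm$scores), c(300L, 3L))
  # rotation preserves the communalities / reproduced correlation structure
  cm0 <- pca_composite(dat, 3, rotation = "none")
  expect_equal(tcrossprod(cm$loadings), tcrossprod(cm0$loadings),
               tolerance = 1e-8)
  # unrotated loading columns are orthogonal (weighted eigenvectors)
  off <- crossprod(cm0$loadings)
  expect_equal(off[upper.tri(off)], rep(0, 3), tolerance = 1e-8)
  # a junk variable falls below the communality floor and is dropped
  dat$junk <- rnorm(300)
  cm_drop <- pca_composite(dat, 3, drop_below_h2 = 0.5)
  expect_true("junk" %in% cm_drop$dropped)
  expect_false("junk" %in% cm_drop$variables)
  expect_error(pca_composite(dat[, 1:2], 5), "more components")
})

test_that("composite recovery: rotated loadings match the generating structure", {
  dat <- simulate_longnote_battery(400, seed = 6)
  truth <- attr(dat, "true_loadings")
  cm <- pca_composite(dat, 3, rotation = "varimax")
  phi <- abs(factor_congruence(truth, cm$loadings))
  # each generating process matches exactly one rotated component
  best <- apply(phi, 1, max)
  expect_true(all(best > 0.9))
  expect_equal(length(unique(apply(phi, 1, which.max))), 3L)
})
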