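# Study-level modelling: explanatory item response models (linear mixed
# effects with participant random intercepts), ability-score extraction,
# the Nakagawa-Schielzeth R2 decomposition, Horn parallel analysis, and the
# rotated principal-component composite pipelines used for the long-note and
# melodic-accuracy variable sets.

.model_formulas <- list(
  combined = outcome ~ N + step_cont_loc_var + tonalness + log_freq +
    melody_type + melody_type:d_entropy + (1 | participant_id),
  arhythmic = outcome ~ N + step_cont_loc_var + tonalness + log_freq +
    (1 | participant_id),
  rhythmic = outcome ~ N + step_cont_loc_var + log_freq + d_entropy +
    i_entropy + (1 | participant_id)
)

#' Fit an explanatory item response model to trial data
#'
#' Linear mixed-effects model (REML, via lme4) with melodic features as
#' fixed effects and participant as random intercept. Three published model
#' specifications are available: `"combined"` (both trial types, with a
#' rhythmic indicator and its interaction with duration entropy),
#' `"arhythmic"` (N, step contour variation, tonalness, log frequency) and
#' `"rhythmic"` (N, step contour variation, log frequency, duration and
#' interval entropy). By default only first attempts are modelled.
#'
#' @param trials data frame of trial records with columns `participant_id`,
#'   `item_id`, `trial_type` (`"arhythmic"`/`"rhythmic"`), `attempt`,
#'   `outcome` in \[0, 1\], and the feature columns the chosen specification
#'   needs (`N`, `step_cont_loc_var`, `tonalness`, `log_freq`, `d_entropy`,
#'   `i_entropy`).
#' @param model one of `"combined"`, `"arhythmic"`, `"rhythmic"`.
#' @param first_attempt_only keep only `attempt == 1` rows (default `TRUE`).
#' @return an object of class `"saa_model_fit"`: a list with the fitted
#'   `lmerMod` (`fit`), a coefficient table with Wald 95% CIs
#'   (`coefficients`), the variance components (`varcomp`: fixed-predictor,
#'   random-intercept and residual variance), `r2_marginal`,
#'   `r2_conditional`, and `singular` (singular-fit flag, reported rather
#'   than masked).
#' @export
fit_trial_model <- function(trials, model = c("combined", "arhythmic", "rhythmic"),
                            first_attempt_only = TRUE) {
  model <- match.arg(model)
  if (first_attempt_only && "attempt" %in% names(trials)) {
    trials <- trials[trials$attempt == 1, , drop = FALSE]
  }
  if (model != "combined" && "trial_type" %in% names(trials)) {
    trials <- trials[trials$trial_type == model, , drop = FALSE]
  }
  if (length(unique(trials$participant_id)) < 2) {
    stop("fit_trial_model(): need at least 2 participants", call. = FALSE)
  }
  if (model == "combined") {
    trials$melody_type <- factor(trials$trial_type,
                                 levels = c("arhythmic", "rhythmic"))
  }
  fit <- lme4::lmer(.model_formulas[[model]], data = trials, REML = TRUE)
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se),
                      ci_lower = unname(beta - 1.96 * se),
                      ci_upper = unname(beta + 1.96 * se),
                      row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_random <- sum(vc$vcov[vc$grp != "Residual"])
  var_residual <- vc$vcov[vc$grp == "Residual"]
  var_fixed <- stats::var(stats::predict(fit, re.form = NA))
  r2 <- nakagawa_r2(var_fixed, var_random, var_residual)
  structure(list(model = model, fit = fit, coefficients = coefs,
                 varcomp = c(fixed = var_fixed, random = var_random,
                             residual = var_residual),
                 r2_marginal = r2[["r2_marginal"]],
                 r2_conditional = r2[["r2_conditional"]],
                 singular = lme4::isSingular(fit),
                 n_trials = nrow(trials)),
            class = "saa_model_fit")
}

#' @export
print.saa_model_fit <- function(x, ...) {
  cat(sprintf("<saa_model_fit '%s': %d trials, R2m = %.3f, R2c = %.3f%s>\n",
              x$model, x$n_trials, x$r2_marginal, x$r2_conditional,
              if (x$singular) ", singular" else ""))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Nakagawa-Schielzeth R2 for a mixed-effects model
#'
#' Marginal R2 (variance explained by the fixed effects alone) and
#' conditional R2 (fixed plus random effects):
#' `R2m = vf / (vf + vr + ve)`, `R2c = (vf + vr) / (vf + vr + ve)`,
#' where `vf` is the variance of the fixed-effect linear predictor, `vr` the
#' summed random-effect variances and `ve` the residual variance.
#'
#' Pass either a fitted [fit_trial_model()] object, or the three variance
#' components directly.
#'
#' @param fit a `"saa_model_fit"`, or the fixed-predictor variance.
#' @param var_random,var_residual variance components (when `fit` is numeric).
#' @return named vector `c(r2_marginal, r2_conditional)`.
#' @examples
#' nakagawa_r2(1, 1, 2)  # 0.25, 0.50
#' @export
nakagawa_r2 <- function(fit, var_random = NULL, var_residual = NULL) {
  if (inherits(fit, "saa_model_fit")) {
    v <- fit$varcomp
    vf <- v[["fixed"]]; vr <- v[["random"]]; ve <- v[["residual"]]
  } else {
    vf <- fit; vr <- var_random; ve <- var_residual
  }
  total <- vf + vr + ve
  c(r2_marginal = vf / total, r2_conditional = (vf + vr) / total)
}

#' Participant ability scores from a fitted model
#'
#' The participant random intercepts (conditional modes) of the mixed model,
#' taken to represent latent singing/melodic-recall ability.
#'
#' @param fit a `"saa_model_fit"`.
#' @return data frame with columns `participant_id` and `ability`.
#' @export
ability_scores <- function(fit) {
  re <- lme4::ranef(fit$fit)$participant_id
  data.frame(participant_id = rownames(re), ability = re[["(Intercept)"]],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Horn parallel analysis
#'
#' Retains the leading principal components whose observed
#' correlation-matrix eigenvalues exceed the chosen quantile of eigenvalues
#' obtained from `n_sims` standard-normal datasets of the same shape.
#' Counting stops at the first component that fails the comparison.
#'
#' @param X numeric observation matrix/data frame (>= 3 columns).
#' @param n_sims number of simulated null datasets.
#' @param quantile_prob quantile of the null eigenvalue distribution
#'   (default 0.95).
#' @param seed optional RNG seed.
#' @return number of retained components, with attributes `"eigenvalues"`
#'   (observed) and `"thresholds"` (null quantiles).
#' @export
parallel_analysis <- function(X, n_sims = 100, quantile_prob = 0.95,
                              seed = NULL) {
  X <- as.matrix(X)
  if (ncol(X) < 3) stop("parallel_analysis(): need >= 3 variables", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("parallel_analysis(): constant column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  obs <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
  null_eigs <- t(replicate(n_sims, {
    Z <- matrix(stats::rnorm(nrow(X) * ncol(X)), nrow(X), ncol(X))
    eigen(stats::cor(Z), symmetric = TRUE, only.values = TRUE)$values
  }))
  thresholds <- apply(null_eigs, 2, stats::quantile, probs = quantile_prob)
  exceed <- obs > thresholds
  n_retained <- if (all(exceed)) length(obs) else which(!exceed)[1] - 1L
  structure(as.integer(n_retained), eigenvalues = obs, thresholds = thresholds)
}

#' Rotated principal-component composite model
#'
#' Standardizes the columns of `X` (complete rows only; row-wise deletion),
#' fits a PCA, optionally varimax-rotates the retained component loadings,
#' and iteratively removes variables whose communality (h2) falls below
#' `drop_below_h2`, refitting after each removal (the convention used for
#' the long-note composite at h2 < 0.75 and the melodic-accuracy composite
#' at h2 < 0.30). Component scores use the regression method.
#'
#' @param X numeric observation matrix/data frame.
#' @param n_components number of components to retain.
#' @param rotation `"varimax"` or `"none"`.
#' @param drop_below_h2 communality threshold for iterative variable
#'   removal, or `NULL` to keep all variables.
#' @return an object of class `"composite_model"`: a list with `loadings`
#'   (variables x components), `h2` (communalities), `var_explained`
#'   (proportion per component), `weights` (regression score weights),
#'   `scores` (rows x components), `variables`, `dropped`, `center`/`scale`.
#' @export
pca_composite <- function(X, n_components, rotation = c("varimax", "none"),
                          drop_below_h2 = NULL) {
  rotation <- match.arg(rotation)
  X <- as.data.frame(X)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (n_components > ncol(X)) {
    stop("pca_composite(): more components than variables", call. = FALSE)
  }
  dropped <- character(0)
  repeat {
    Z <- scale(as.matrix(X))
    pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
    L <- pc$rotation[, seq_len(n_components), drop = FALSE] %*%
      diag(pc$sdev[seq_len(n_components)], n_components)
    if (rotation == "varimax" && n_components > 1) {
      vm <- stats::varimax(L)
      L <- unclass(vm$loadings)
    }
    colnames(L) <- paste0("RC", seq_len(n_components))
    h2 <- rowSums(L^2)
    if (!is.null(drop_below_h2) && any(h2 < drop_below_h2) &&
        ncol(X) > n_components + 1) {
      worst <- names(which.min(h2))
      dropped <- c(dropped, worst)
      X[[worst]] <- NULL
      next
    }
    break
  }
  R <- stats::cor(as.matrix(X))
  W <- solve(R, L)                       # regression-method score weights
  scores <- Z %*% W
  structure(list(loadings = L, h2 = h2,
                 var_explained = colSums(L^2) / ncol(X),
                 weights = W, scores = scores,
                 variables = colnames(X), dropped = dropped,
                 n_components = n_components, rotation = rotation,
                 center = attr(Z, "scaled:center"),
                 scale = attr(Z, "scaled:scale")),
            class = "composite_model")
}

#' @export
print.composite_model <- function(x, ...) {
  cat(sprintf("<composite_model: %d components (%s), %d variables%s>\n",
              x$n_components, x$rotation, length(x$variables),
              if (length(x$dropped)) paste0(", dropped: ",
                                            paste(x$dropped, collapse = ", "))
              else ""))
  print(round(cbind(x$loadings, h2 = x$h2), 2))
  invisible(x)
}

#' Tucker congruence coefficients between two loading matrices
#'
#' `phi(a, b) = sum(a*b) / sqrt(sum(a^2) * sum(b^2))` for every column pair;
#' |phi| > 0.9 is the conventional bar for component recovery. Column order
#' and sign are arbitrary after rotation, so recovery checks should take the
#' best |phi| match per column.
#'
#' @param A,B loading matrices with matching rows.
#' @return matrix of congruence coefficients (columns of `A` x columns of
#'   `B`).
#' @export
factor_congruence <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(nrow(A) == nrow(B))
  num <- crossprod(A, B)
  den <- sqrt(outer(colSums(A^2), colSums(B^2)))
  num / den
}
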