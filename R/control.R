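#' Tuning parameters for the boosting algorithm
#'
#' @param nu_l,nu_s Step lengths in (0, 1] scaling each applied longitudinal /
#'   survival coefficient update. 0.1 is the established weak-learner choice;
#'   the baseline hazard and the random-effects step are never scaled.
#' @param m_max_l,m_max_s Iteration caps for the longitudinal and survival
#'   boosting processes.
#' @param grid_l Subset of `1:m_max_l` at which the longitudinal process is
#'   snapshot for tuning (the survival path is cheap, so every
#'   `m_s in 1:m_max_s` is evaluated; the longitudinal grid is coarsened).
#' @param K Number of equidistant baseline-hazard segments on
#'   `[0, max(T)]`; 7--10 gives flexibility well beyond a constant hazard
#'   without inflating the parameter count.
#' @param cv_folds Number of cross-validation folds (subjects are partitioned,
#'   never records).
#' @param criterion Component-selection criterion: `"loglik"` picks the
#'   candidate with the best penalized log-likelihood, `"AIC"`/`"BIC"` the
#'   lowest information criterion (complexity = number of distinct covariates
#'   in the model).
#' @param seed Integer seed controlling fold assignment (and nothing else in
#'   fitting).
#' @param standardize Center and scale covariate columns before fitting
#'   (estimates then refer to standardized covariates). Off by default: the
#'   method is formulated for unit-scale inputs.
#' @param test_random_effects How held-out subjects' random effects are
#'   treated when evaluating the cross-validation likelihood: `"zero"` plugs
#'   in the prior mean, `"posterior"` the per-subject posterior mode given the
#'   subject's longitudinal records only.
#' @param correct_random_effects Apply the correction step to every
#'   random-effects update: the updated random intercepts and slopes are
#'   projected off the subject-level covariate design, so they cannot absorb
#'   fixed-effect structure (cluster confounding). On by default. Turning it
#'   off yields the plain penalized-likelihood alternation, which converges
#'   to the maximum-likelihood fit of the mixed model as iterations grow; the
#'   corrected algorithm deliberately trades a small finite-sample deviation
#'   from ML for covariate-decorrelated random effects.
#' @return A list of class `boost_control`.
#' @export
boost_control <- function(nu_l = 0.1, nu_s = 0.1,
                          m_max_l = 500L, m_max_s = 1000L,
                          grid_l = seq(25L, m_max_l, by = 25L),
                          K = 10L, cv_folds = 10L,
                          criterion = c("loglik", "AIC", "BIC"),
                          seed = 1L, standardize = FALSE,
                          test_random_effects = c("zero", "posterior"),
                          correct_random_effects = TRUE) {
  criterion <- match.arg(criterion)
  test_random_effects <- match.arg(test_random_effects)
  stopifnot(nu_l > 0, nu_l <= 1, nu_s > 0, nu_s <= 1,
            m_max_l >= 0, m_max_s >= 0, K >= 1, cv_folds >= 2)
  grid_l <- sort(unique(as.integer(grid_l)))
  if (length(grid_l) && (min(grid_l) < 1L || max(grid_l) > m_max_l)) {
    abort("grid_l must be a subset of 1:m_max_l", class = "boostjm_config_error")
  }
  structure(list(nu_l = nu_l, nu_s = nu_s,
                 m_max_l = as.integer(m_max_l), m_max_s = as.integer(m_max_s),
                 grid_l = grid_l, K = as.integer(K),
                 cv_folds = as.integer(cv_folds), criterion = criterion,
                 seed = as.integer(seed), standardize = standardize,
                 test_random_effects = test_random_effects,
                 correct_random_effects = isTRUE(correct_random_effects)),
            class = "boost_control")
}
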