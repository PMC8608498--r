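#' Longitudinal log-likelihood
#'
#' Sum of Gaussian log-densities of the repeated measurements around the
#' subject-specific linear trajectory
#' \eqn{\eta_l(t) = \beta_0 + \beta_t t + \beta_l^T x + \gamma_0 + \gamma_t t}
#' with residual variance \eqn{\sigma^2}.
#'
#' @param params A [joint_params()] object.
#' @param data A [joint_data()] object.
#' @return Scalar log-likelihood.
#' @export
long_loglik <- function(params, data) {
  mats <- jd_matrices(data)
  cache <- predictor_cache(params, mats)
  ll_long_from_cache(params, mats, cache)
}

ll_long_from_cache <- function(params, mats, cache) {
  s2 <- params$long$sigma2
  if (!is.finite(s2) || s2 <= 0) {
    abort("sigma2 must be positive and finite", class = "boostjm_numeric_error")
  }
  r <- mats$y - cache$eta_rec
  if (any(!is.finite(r))) abort("non-finite predictor", class = "boostjm_numeric_error")
  -0.5 * mats$N * log(2 * pi * s2) - 0.5 * sum(r^2) / s2
}

#' Penalized longitudinal log-likelihood
#'
#' [long_loglik()] minus the Laplace-approximation random-effects penalty
#' \eqn{\tfrac12 \sum_i \gamma_i^T Q^{-1} \gamma_i}.
#'
#' @inheritParams long_loglik
#' @return Scalar penalized log-likelihood.
#' @export
long_pen_loglik <- function(params, data) {
  long_loglik(params, data) - gamma_penalty(params$long$gamma, params$long$Q)
}

gamma_penalty <- function(gamma, Q) {
  Qinv <- inv2(Q)
  if (any(!is.finite(Qinv))) abort("singular Q", class = "boostjm_numeric_error")
  0.5 * sum((gamma %*% Qinv) * gamma)
}

#' Survival log-likelihood with piecewise-constant baseline hazard
#'
#' Full (not partial) likelihood
#' \eqn{\sum_i \delta_i \log \lambda_i(T_i) - \Lambda_i(T_i)} where the
#' individual hazard is
#' \eqn{\lambda_i(t) = \lambda_0(t) \exp(\eta_s + \alpha \eta_l(t))} and the
#' cumulative hazard is evaluated segment-by-segment in closed form
#' (see [cumulative_hazard()]). The subject's trajectory \eqn{\eta_l(t)} uses
#' the current longitudinal parameters including the random effects.
#'
#' @inheritParams long_loglik
#' @return Scalar log-likelihood.
#' @export
surv_loglik <- function(params, data) {
  mats <- jd_matrices(data)
  cache <- predictor_cache(params, mats)
  ll_surv_from_cache(params$surv, mats, cache)
}

ll_surv_from_cache <- function(sp, mats, cache) {
  if (any(sp$lambda <= 0)) {
    abort("baseline hazard values must be positive", class = "boostjm_numeric_error")
  }
  Lam <- cumulative_hazard(sp, cache$a, cache$b, mats$Ts, cache$eta_s)
  log_haz <- log(baseline_at(sp$knots, sp$lambda, mats$Ts)) + cache$eta_s +
    sp$alpha * (cache$a + cache$b * mats$Ts)
  sum(mats$delta * log_haz) - sum(Lam)
}

#' Joint log-likelihood
#'
#' Sum of the longitudinal log-likelihood (penalized or not) and the survival
#' log-likelihood, the quantity the boosting algorithm maximizes and the
#' cross-validation criterion evaluates on held-out subjects.
#'
#' @inheritParams long_loglik
#' @param penalized If `TRUE`, use the penalized longitudinal term.
#' @return Scalar log-likelihood.
#' @export
joint_loglik <- function(params, data, penalized = FALSE) {
  mats <- jd_matrices(data)
  cache <- predictor_cache(params, mats)
  ll <- ll_long_from_cache(params, mats, cache) +
    ll_surv_from_cache(params$surv, mats, cache)
  if (penalized) ll <- ll - gamma_penalty(params$long$gamma, params$long$Q)
  ll
}
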