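# Longitudinal boosting engine: component-wise Fisher-scoring updates of the
# fixed effects, a corrected random-effects step, and closed-form updates of
# the variance components, iterated m_l times.

#' Initialize joint-model parameters for boosting
#'
#' Coefficients that undergo boosting start at zero
#' (`beta_l = beta_s = 0`, `alpha = 0`); every baseline-hazard segment starts
#' at the constant-hazard estimator `sum(delta) / sum(T)`; and
#' `(beta0, beta_t, gamma, Q, sigma2)` come from the maximum-likelihood fit of
#' the intercept + time random-intercept/random-slope model, computed by the
#' package's internal profile-likelihood optimizer. If that fit fails, the
#' fixed effects fall back to ordinary least squares with `gamma = 0` and
#' `Q = 0.1 I` (a warning is raised).
#'
#' @param data A [joint_data()] object.
#' @param control A [boost_control()] object (supplies `K`).
#' @return A [joint_params()] object.
#' @export
init_params <- function(data, control = boost_control()) {
  mats <- jd_matrices(data)
  lmm <- tryCatch(fit_lmm_ml(data, covariates = character(0)),
                  error = function(e) NULL)
  if (is.null(lmm) || !all(is.finite(c(lmm$beta0, lmm$beta_t, lmm$sigma2)))) {
    warn("initialization LMM failed; falling back to OLS with gamma = 0, Q = 0.1 I")
    fit <- lm(mats$y ~ mats$t)
    cf <- coef(fit)
    cf[!is.finite(cf)] <- 0  # e.g. constant measurement times
    lmm <- list(beta0 = unname(cf[1]), beta_t = unname(cf[2]),
                gamma = matrix(0, mats$n, 2), Q = diag(0.1, 2),
                sigma2 = max(var(stats::residuals(fit)), .EPS))
  }
  lam0 <- sum(mats$delta) / sum(mats$Ts)
  if (lam0 <= 0) {
    warn("no events observed; baseline hazard clamped at 1e-10")
    lam0 <- .EPS
  }
  K <- control$K
  knots <- seq(0, max(mats$Ts), length.out = K + 1L)
  joint_params(
    beta0 = lmm$beta0, beta_t = lmm$beta_t,
    beta_l = stats::setNames(rep(0, length(data$cov_l)), data$cov_l),
    gamma = lmm$gamma, Q = spd_repair(lmm$Q), sigma2 = max(lmm$sigma2, .EPS),
    knots = knots, lambda = rep(lam0, K), alpha = 0,
    beta_s = stats::setNames(rep(0, length(data$cov_s)), data$cov_s))
}

# criterion score for the longitudinal selection step: larger is better
long_criterion <- function(penll, df, N, criterion) {
  switch(criterion,
         loglik = penll,
         AIC = -(-2 * penll + 2 * df),
         BIC = -(-2 * penll + log(N) * df))
}

#' Candidate Fisher-scoring update for one longitudinal covariate
#'
#' Computes the three-dimensional Fisher-scoring step for the coordinate
#' triple `(beta0, beta_t, beta_l[r])` of the penalized longitudinal
#' log-likelihood, holding everything else fixed: `delta = F_r^{-1} s_r` with
#' score `s_r = X_r'(y - eta)/sigma2` and expected information
#' `F_r = X_r'X_r/sigma2` for the record-level design `X_r = [1, t, x_r]`.
#' The intercept and time effect are only ever moved through such triples;
#' time is never itself a selectable component.
#'
#' @param params A [joint_params()] object.
#' @param data A [joint_data()] object.
#' @param r Covariate index in `1:p_l`.
#' @param criterion Selection criterion, see [boost_control()].
#' @return List with `component_index`, `delta` (length 3), and
#'   `criterion_value` (the score after applying the full, unscaled delta;
#'   larger is better).
#' @export
candidate_update <- function(params, data, r, criterion = "loglik") {
  mats <- jd_matrices(data)
  cache <- predictor_cache(params, mats)
  pen <- gamma_penalty(params$long$gamma, params$long$Q)
  candidate_update_impl(params, mats, cache$eta_rec, pen, r, criterion)
}

candidate_update_impl <- function(params, mats, eta_rec, pen, r, criterion) {
  s2 <- params$long$sigma2
  Xr <- cbind(1, mats$t, mats$Xl[, r])
  resid <- mats$y - eta_rec
  s <- crossprod(Xr, resid) / s2
  Fr <- crossprod(Xr) / s2
  delta <- tryCatch(solve(Fr, s), error = function(e) {
    inform("singular information in candidate update; ridge-stabilized")
    solve(Fr + diag(1e-8, 3), s)
  })
  delta <- drop(delta)
  r_new <- resid - drop(Xr %*% delta)
  penll <- -0.5 * mats$N * log(2 * pi * s2) - 0.5 * sum(r_new^2) / s2 - pen
  df <- 2 + sum(params$long$beta_l[-r] != 0) + 1
  list(component_index = r, delta = delta,
       criterion_value = long_criterion(penll, df, mats$N, criterion))
}

#' One component-wise fixed-effect boosting step
#'
#' Evaluates [candidate_update()] for every longitudinal covariate, selects
#' the candidate with the best criterion value (ties broken by lowest index)
#' and applies the step-length-scaled update
#' `(beta0, beta_t, beta_l[r*]) += nu_l * delta`. Unselected coefficients are
#' untouched.
#'
#' @inheritParams candidate_update
#' @param control A [boost_control()] object.
#' @return List with the updated `params` and `selected` (the chosen index,
#'   `NA` if every candidate was non-finite).
#' @export
select_and_update_fixed <- function(params, data, control = boost_control()) {
  mats <- jd_matrices(data)
  cache <- predictor_cache(params, mats)
  pen <- gamma_penalty(params$long$gamma, params$long$Q)
  step_fixed(params, mats, cache$eta_rec, pen, control)
}

step_fixed <- function(params, mats, eta_rec, pen, control) {
  p_l <- ncol(mats$Xl)
  cands <- lapply(seq_len(p_l), function(r)
    candidate_update_impl(params, mats, eta_rec, pen, r, control$criterion))
  scores <- vapply(cands, `[[`, numeric(1), "criterion_value")
  if (!any(is.finite(scores))) {
    warn("all candidate updates non-finite; stopping longitudinal boosting")
    return(list(params = params, selected = NA_integer_))
  }
  r_star <- which.max(scores)  # ties -> lowest index
  d <- control$nu_l * cands[[r_star]]$delta
  params$long$beta0 <- params$long$beta0 + d[1]
  params$long$beta_t <- params$long$beta_t + d[2]
  params$long$beta_l[r_star] <- params$long$beta_l[r_star] + d[3]
  list(params = params, selected = r_star)
}

#' Corrected random-effects update
#'
#' Full (unscaled) Fisher-scoring step for the stacked random effects of the
#' penalized longitudinal log-likelihood. The score and expected information
#' are block-diagonal by subject with 2x2 blocks
#' `F_i = Z_i'Z_i/sigma2 + Q^{-1}`; after the raw step, each random-effect
#' dimension is projected onto the orthogonal complement of the subject-level
#' fixed-effect design (intercept plus every covariate column), so random
#' effects stay empirically uncorrelated with all observed covariates and
#' cannot absorb fixed-effect structure. The per-subject curvature blocks are
#' stored for the subsequent covariance update.
#'
#' @inheritParams candidate_update
#' @param correct Apply the decorrelating projection (see
#'   [boost_control()]'s `correct_random_effects`).
#' @return Updated [joint_params()] (with curvature blocks in
#'   `$long$Fblocks`, rows `(F11, F12, F22)`).
#' @export
update_random_effects <- function(params, data, correct = TRUE) {
  mats <- jd_matrices(data)
  step_random(params, mats, correct)
}

step_random <- function(params, mats, correct = TRUE) {
  s2 <- params$long$sigma2
  Q <- params$long$Q
  Qi <- inv2(Q)
  gamma <- params$long$gamma
  cache <- predictor_cache(params, mats)
  r <- mats$y - cache$eta_rec
  idx <- mats$id_idx
  Zr1 <- rowsum_vec(r, idx, mats$n)
  Zr2 <- rowsum_vec(mats$t * r, idx, mats$n)
  ni <- tabulate(idx, mats$n)
  St <- rowsum_vec(mats$t, idx, mats$n)
  Stt <- rowsum_vec(mats$t^2, idx, mats$n)
  s1 <- Zr1 / s2 - (Qi[1, 1] * gamma[, 1] + Qi[1, 2] * gamma[, 2])
  s2v <- Zr2 / s2 - (Qi[2, 1] * gamma[, 1] + Qi[2, 2] * gamma[, 2])
  f11 <- ni / s2 + Qi[1, 1]
  f12 <- St / s2 + Qi[1, 2]
  f22 <- Stt / s2 + Qi[2, 2]
  det <- f11 * f22 - f12^2
  bad <- !is.finite(det) | det <= .EPS
  if (any(bad)) {
    inform("singular random-effects block; ridge-stabilized")
    f11[bad] <- f11[bad] + 1e-8
    f22[bad] <- f22[bad] + 1e-8
    det <- f11 * f22 - f12^2
  }
  u1 <- (f22 * s1 - f12 * s2v) / det
  u2 <- (f11 * s2v - f12 * s1) / det
  g_new <- cbind(gamma[, 1] + u1, gamma[, 2] + u2)
  if (correct) {
    # correction: project each dimension off the subject-level design [1, X]
    W <- cbind(1, mats$Xl_sub)
    g_new <- g_new - qr.fitted(qr(W), g_new)
  }
  params$long$gamma <- g_new
  params$long$Fblocks <- cbind(f11, f12, f22)
  params
}

#' Update the random-effects covariance
#'
#' Approximate EM step using the posterior curvatures of the last
#' random-effects update:
#' `Q <- (1/n) * sum_i (F_i^{-1} + gamma_i gamma_i')`, symmetrized with
#' eigenvalues clamped at 1e-10.
#'
#' @inheritParams candidate_update
#' @return Updated [joint_params()].
#' @export
update_Q <- function(params, data) {
  gamma <- params$long$gamma
  n <- nrow(gamma)
  Fb <- params$long$Fblocks
  if (is.null(Fb)) {
    abort("update_Q requires curvatures from a preceding random-effects update",
          class = "boostjm_numeric_error")
  }
  det <- Fb[, 1] * Fb[, 3] - Fb[, 2]^2
  q11 <- sum(Fb[, 3] / det + gamma[, 1]^2) / n
  q12 <- sum(-Fb[, 2] / det + gamma[, 1] * gamma[, 2]) / n
  q22 <- sum(Fb[, 1] / det + gamma[, 2]^2) / n
  params$long$Q <- spd_repair(matrix(c(q11, q12, q12, q22), 2, 2))
  params
}

#' Update the residual variance
#'
#' Approximate EM step for `sigma2` using the current residuals
#' `y - eta_l` over all records (denominator N). With `curvature = TRUE`
#' (the default inside the boosting loop, requiring a preceding
#' random-effects update) the posterior-curvature correction
#' `sigma2 <- (||r||^2 + sum_i tr(Z_i F_i^{-1} Z_i')) / N` is used — the
#' same curvatures that drive the covariance update — which makes the
#' algorithm's fixed point agree with the maximum-likelihood variance.
#' With `curvature = FALSE` the plain empirical variance of the residuals is
#' taken. Either way the result is clamped below at 1e-10.
#'
#' @inheritParams candidate_update
#' @param curvature Include the posterior-curvature term (needs
#'   `$long$Fblocks` from [update_random_effects()]).
#' @return Updated [joint_params()].
#' @export
update_sigma2 <- function(params, data, curvature = !is.null(params$long$Fblocks)) {
  mats <- jd_matrices(data)
  cache <- predictor_cache(params, mats)
  r <- mats$y - cache$eta_rec
  if (curvature) {
    Fb <- params$long$Fblocks
    if (is.null(Fb)) {
      abort("curvature-corrected sigma2 update requires a preceding random-effects update",
            class = "boostjm_numeric_error")
    }
    det <- Fb[, 1] * Fb[, 3] - Fb[, 2]^2
    i11 <- Fb[, 3] / det; i12 <- -Fb[, 2] / det; i22 <- Fb[, 1] / det
    idx <- mats$id_idx
    tr_rec <- i11[idx] + 2 * i12[idx] * mats$t + i22[idx] * mats$t^2
    params$long$sigma2 <- max((sum(r^2) + sum(tr_rec)) / mats$N, .EPS)
  } else {
    params$long$sigma2 <- max(mean((r - mean(r))^2), .EPS)
  }
  params
}

#' Run the longitudinal boosting process
#'
#' Repeats `m_l` times: component-wise fixed-effect update, corrected
#' random-effects update, covariance update, residual-variance update
#' (in that order). `m_l = 0` returns the input unchanged.
#'
#' @inheritParams select_and_update_fixed
#' @param m_l Number of boosting iterations.
#' @param snapshot_at Optional sorted iteration numbers at which full
#'   parameter copies are kept (used by the tuning grid).
#' @return List with `params` (after `m_l` iterations), `path` (one row per
#'   iteration: selection and coefficient snapshot) and `snapshots` (named
#'   list of [joint_params()] at the requested iterations).
#' @export
boost_longitudinal <- function(params, data, m_l, control = boost_control(),
                               snapshot_at = NULL) {
  mats <- jd_matrices(data)
  p_l <- ncol(mats$Xl)
  snapshots <- list()
  rows <- vector("list", m_l)
  m <- 0L
  while (m < m_l) {
    cache <- predictor_cache(params, mats)
    pen <- gamma_penalty(params$long$gamma, params$long$Q)
    st <- step_fixed(params, mats, cache$eta_rec, pen, control)
    if (is.na(st$selected)) break
    params <- st$params
    params <- step_random(params, mats, control$correct_random_effects %||% TRUE)
    params <- update_Q(params, data)
    params <- update_sigma2(params, data, curvature = TRUE)
    m <- m + 1L
    rows[[m]] <- tibble::tibble(
      iteration = m, selected = data$cov_l[st$selected],
      beta0 = params$long$beta0, beta_t = params$long$beta_t,
      !!!stats::setNames(as.list(params$long$beta_l), data$cov_l),
      sigma2 = params$long$sigma2,
      q11 = params$long$Q[1, 1], q12 = params$long$Q[1, 2],
      q22 = params$long$Q[2, 2])
    if (m %in% snapshot_at) {
      snap <- params
      snap$long$Fblocks <- NULL
      snapshots[[as.character(m)]] <- snap
    }
  }
  params$long$Fblocks <- NULL
  path <- if (m > 0L) dplyr::bind_rows(rows[seq_len(m)]) else
    tibble::tibble(iteration = integer(), selected = character())
  list(params = params, path = path, snapshots = snapshots)
}
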