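#' Construct a joint-model parameter set
#'
#' Container for every parameter of the joint model: the longitudinal linear
#' mixed model (intercept `beta0`, time effect `beta_t`, covariate effects
#' `beta_l`, per-subject random effects `gamma`, their covariance `Q`,
#' residual variance `sigma2`) and the survival submodel (piecewise-constant
#' baseline hazard on `knots` with segment values `lambda`, association
#' parameter `alpha`, covariate effects `beta_s`).
#'
#' @param beta0,beta_t Scalars: intercept and fixed time effect.
#' @param beta_l Named numeric vector of longitudinal covariate effects.
#' @param gamma Numeric matrix, one row per subject, columns
#'   (random intercept, random slope).
#' @param Q 2x2 symmetric positive-definite random-effects covariance.
#' @param sigma2 Positive residual variance.
#' @param knots Increasing knot sequence `0 = t_0 < ... < t_K`; the K segment
#'   intervals are half-open `[t_{k-1}, t_k)` and the last segment value is
#'   extended beyond `t_K`.
#' @param lambda Positive hazard value per segment (length K).
#' @param alpha Scalar association parameter: effect of the current
#'   longitudinal trajectory value on the log hazard.
#' @param beta_s Named numeric vector of survival covariate effects.
#' @return An object of class `joint_params`.
#' @export
joint_params <- function(beta0, beta_t, beta_l, gamma, Q, sigma2,
                         knots, lambda, alpha, beta_s) {
  stopifnot(is_scalar_number(beta0), is_scalar_number(beta_t),
            is_scalar_number(alpha), is_scalar_number(sigma2), sigma2 > 0)
  gamma <- as.matrix(gamma)
  stopifnot(ncol(gamma) == 2L)
  Q <- as.matrix(Q)
  stopifnot(nrow(Q) == 2L, ncol(Q) == 2L)
  if (any(eigen(Q, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    abort("Q must be positive definite", class = "boostjm_numeric_error")
  }
  knots <- as.numeric(knots)
  lambda <- as.numeric(lambda)
  if (length(knots) != length(lambda) + 1L || knots[1] != 0 ||
      any(diff(knots) <= 0)) {
    abort("knots must be an increasing sequence starting at 0 with one more entry than lambda",
          class = "boostjm_numeric_error")
  }
  if (any(lambda <= 0)) {
    abort("baseline hazard values must be positive", class = "boostjm_numeric_error")
  }
  structure(
    list(long = list(beta0 = beta0, beta_t = beta_t, beta_l = beta_l,
                     gamma = gamma, Q = Q, sigma2 = sigma2),
         surv = list(knots = knots, lambda = lambda, alpha = alpha,
                     beta_s = beta_s)),
    class = "joint_params")
}

#' @export
print.joint_params <- function(x, digits = 4, ...) {
  cat("<joint_params>\n")
  cat("  longitudinal: beta0 =", signif(x$long$beta0, digits),
      " beta_t =", signif(x$long$beta_t, digits),
      " sigma2 =", signif(x$long$sigma2, digits), "\n")
  bl <- x$long$beta_l
  cat("  beta_l nonzero:", sum(bl != 0), "/", length(bl), "\n")
  cat("  Q = [", signif(x$long$Q[1, 1], digits), signif(x$long$Q[1, 2], digits),
      ";", signif(x$long$Q[2, 1], digits), signif(x$long$Q[2, 2], digits), "]\n")
  cat("  survival: alpha =", signif(x$surv$alpha, digits),
      " K =", length(x$surv$lambda), "segments\n")
  bs <- x$surv$beta_s
  cat("  beta_s nonzero:", sum(bs != 0), "/", length(bs), "\n")
  invisible(x)
}

# predictor pieces shared by the likelihood and both boosting engines:
#   a_i = beta0 + beta_l' x_li + gamma_0i   (subject-level trajectory intercept)
#   b_i = beta_t + gamma_ti                 (subject-level trajectory slope)
#   eta_s_i = beta_s' x_si
# so that eta_l(t) = a_i + b_i * t at any time t.
predictor_cache <- function(params, mats, gamma = NULL) {
  lp <- params$long
  gamma <- gamma %||% lp$gamma
  p_l <- length(lp$beta_l)
  base <- if (p_l) drop(mats$Xl_sub %*% lp$beta_l) else rep(0, mats$n)
  a <- lp$beta0 + base + gamma[, 1]
  b <- lp$beta_t + gamma[, 2]
  p_s <- length(params$surv$beta_s)
  eta_s <- if (p_s) drop(mats$Xs %*% params$surv$beta_s) else rep(0, mats$n)
  eta_rec <- a[mats$id_idx] + b[mats$id_idx] * mats$t
  list(a = a, b = b, eta_s = eta_s, eta_rec = eta_rec)
}
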