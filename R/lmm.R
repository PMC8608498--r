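# Internal maximum-likelihood fitter for the linear mixed model
#   y_ij = beta0 + beta_t t_ij + beta_l' x_i + gamma_0i + gamma_ti t_ij + e_ij
# with (gamma_0i, gamma_ti) ~ N(0, Q) and e_ij ~ N(0, sigma2). Used for the
# boosting initialization (covariates = none) and for the two-stage variant's
# unregularized first stage (covariates = all).
#
# The marginal likelihood is profiled over the fixed effects: for a given
# (sigma2, Q) the GLS solution is computed from per-subject Woodbury pieces.
# With Z_i = [1, t_i] every fixed-effect column lies in the column space of
# Z_i scaled by subject constants, so only 2x2 per-subject quantities are
# needed and the whole objective is vectorized over subjects. (sigma, Q) are
# parametrized as log sigma plus the log-Cholesky factor of Q, keeping the
# optimization unconstrained.

fit_lmm_ml <- function(data, covariates = data$cov_l, control = list()) {
  mats <- jd_matrices(data)
  X_sub <- mats$Xl_sub[, covariates, drop = FALSE]
  p <- ncol(X_sub)
  idx <- mats$id_idx

  # per-subject sufficient statistics
  ni <- tabulate(idx, mats$n)
  St <- rowsum_vec(mats$t, idx, mats$n)
  Stt <- rowsum_vec(mats$t^2, idx, mats$n)
  Sy <- rowsum_vec(mats$y, idx, mats$n)
  Sty <- rowsum_vec(mats$t * mats$y, idx, mats$n)
  Syy <- rowsum_vec(mats$y^2, idx, mats$n)

  # Woodbury pieces for one (sigma2, Q): returns per-subject 2x2 components of
  # W = Z'V^{-1}Z, the 2-vector v = Z'V^{-1}y, scalars y'V^{-1}y and log|V|
  pieces <- function(s2, Q) {
    detQ <- Q[1, 1] * Q[2, 2] - Q[1, 2]^2
    if (!is.finite(detQ) || detQ <= 0 || !is.finite(s2) || s2 <= 0) return(NULL)
    Qi <- inv2(Q)
    m11 <- Qi[1, 1] + ni / s2
    m12 <- Qi[1, 2] + St / s2
    m22 <- Qi[2, 2] + Stt / s2
    detM <- m11 * m22 - m12^2
    i11 <- m22 / detM; i12 <- -m12 / detM; i22 <- m11 / detM
    # Z'Z entries
    z11 <- ni; z12 <- St; z22 <- Stt
    # A = Z'Z M^{-1} (2x2 per subject)
    a11 <- z11 * i11 + z12 * i12
    a12 <- z11 * i12 + z12 * i22
    a21 <- z12 * i11 + z22 * i12
    a22 <- z12 * i12 + z22 * i22
    # W = Z'Z/s2 - A Z'Z / s2^2
    W11 <- z11 / s2 - (a11 * z11 + a12 * z12) / s2^2
    W12 <- z12 / s2 - (a11 * z12 + a12 * z22) / s2^2
    W22 <- z22 / s2 - (a21 * z12 + a22 * z22) / s2^2
    # v = Z'y/s2 - Z'Z M^{-1} Z'y / s2^2
    v1 <- Sy / s2 - (a11 * Sy + a12 * Sty) / s2^2
    v2 <- Sty / s2 - (a21 * Sy + a22 * Sty) / s2^2
    yVy <- Syy / s2 - (i11 * Sy^2 + 2 * i12 * Sy * Sty + i22 * Sty^2) / s2^2
    logdetV <- ni * log(s2) + log(detQ) + log(detM)
    list(W11 = W11, W12 = W12, W22 = W22, v1 = v1, v2 = v2,
         yVy = yVy, logdetV = logdetV)
  }

  gls <- function(pc) {
    # assemble S_XX (p+2 square) and S_Xy for columns [1, t, x_1..x_p]
    q <- p + 2L
    S_XX <- matrix(0, q, q)
    S_Xy <- numeric(q)
    S_XX[1, 1] <- sum(pc$W11)
    S_XX[1, 2] <- S_XX[2, 1] <- sum(pc$W12)
    S_XX[2, 2] <- sum(pc$W22)
    S_Xy[1] <- sum(pc$v1)
    S_Xy[2] <- sum(pc$v2)
    if (p > 0L) {
      S_XX[1, 3:q] <- S_XX[3:q, 1] <- colSums(X_sub * pc$W11)
      S_XX[2, 3:q] <- S_XX[3:q, 2] <- colSums(X_sub * pc$W12)
      S_XX[3:q, 3:q] <- crossprod(X_sub, X_sub * pc$W11)
      S_Xy[3:q] <- colSums(X_sub * pc$v1)
    }
    beta <- solve(S_XX, S_Xy)
    list(beta = beta, S_XX = S_XX, S_Xy = S_Xy)
  }

  unpack <- function(theta) {
    # floor keeps the Woodbury algebra well conditioned when the residual
    # variance is driven to zero (e.g. noiseless outcomes)
    s2 <- exp(2 * theta[1]) + 1e-8
    L <- matrix(c(exp(theta[2]), theta[3], 0, exp(theta[4])), 2, 2)
    list(s2 = s2, Q = L %*% t(L))
  }

  negll <- function(theta) {
    par <- unpack(theta)
    pc <- pieces(par$s2, par$Q)
    if (is.null(pc)) return(1e10)
    g <- tryCatch(gls(pc), error = function(e) NULL)
    if (is.null(g)) return(1e10)
    quad <- sum(pc$yVy) - 2 * sum(g$beta * g$S_Xy) +
      drop(crossprod(g$beta, g$S_XX %*% g$beta))
    ll <- -0.5 * (mats$N * log(2 * pi) + sum(pc$logdetV) + quad)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  # starting values from an unclustered least-squares fit
  Xr <- cbind(1, mats$t, mats$Xl[, covariates, drop = FALSE])
  b0 <- qr.solve(Xr, mats$y)
  res <- mats$y - drop(Xr %*% b0)
  s0 <- max(sd(res), 1e-3)
  theta0 <- c(log(s0 * 0.7), log(max(s0, 0.3)), 0, log(0.3))
  opt <- optim(theta0, negll, method = "BFGS",
               control = list(maxit = control$maxit %||% 300, reltol = 1e-12))
  # polish with Nelder-Mead in case BFGS stalled on a kink
  opt2 <- optim(opt$par, negll, method = "Nelder-Mead",
                control = list(maxit = 500, reltol = 1e-12))
  if (opt2$value < opt$value) opt <- opt2

  par <- unpack(opt$par)
  pc <- pieces(par$s2, par$Q)
  g <- gls(pc)
  beta <- g$beta
  # BLUPs: gamma_i = Q (Z'V^{-1} r)_i with Z'V^{-1}r = v - W (G beta)
  mu1 <- beta[1] + if (p > 0L) drop(X_sub %*% beta[3:(p + 2L)]) else 0
  mu2 <- rep(beta[2], mats$n)
  u1 <- pc$v1 - (pc$W11 * mu1 + pc$W12 * mu2)
  u2 <- pc$v2 - (pc$W12 * mu1 + pc$W22 * mu2)
  Q <- par$Q
  gamma <- cbind(Q[1, 1] * u1 + Q[1, 2] * u2,
                 Q[2, 1] * u1 + Q[2, 2] * u2)
  list(beta0 = beta[1], beta_t = beta[2],
       beta_l = if (p > 0L) stats::setNames(beta[3:(p + 2L)], covariates)
                else stats::setNames(numeric(0), character(0)),
       gamma = gamma, Q = Q, sigma2 = par$s2,
       loglik = -opt$value, converged = opt$convergence == 0)
}

rowsum_vec <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}
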