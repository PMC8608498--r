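# Shared fixtures and independent oracles used across the suite. Oracles are
# deliberately written as plain loops / stats::integrate / stats::optim so
# they share no code path with the package internals they check.

# small joint dataset built directly (no simulator) with known structure
toy_joint <- function(n = 6, n_i = 3, p_l = 2, p_s = 2, seed = 1,
                      beta_l = rep(0.5, p_l), beta_s = rep(0.4, p_s),
                      sigma = 0.3) {
  withr::with_seed(seed, {
    xl <- matrix(rnorm(n * p_l), n)
    xs <- matrix(rnorm(n * p_s), n)
    gam <- cbind(rnorm(n, sd = 0.4), rnorm(n, sd = 0.2))
    t <- matrix(runif(n * n_i, 0, 2), n)
    a <- 1 + drop(xl %*% beta_l) + gam[, 1]
    b <- 0.8 + gam[, 2]
    y <- a + b * t + rnorm(n * n_i, sd = sigma)
    Tobs <- runif(n, 0.3, 3)
    delta <- rbinom(n, 1, 0.6)
  })
  long <- data.frame(id = rep(1:n, each = n_i), time = as.vector(t(t)),
                     y = as.vector(t(y)))
  for (j in seq_len(p_l)) long[[paste0("x", j)]] <- rep(xl[, j], each = n_i)
  surv <- data.frame(id = 1:n, time = Tobs, event = delta)
  for (j in seq_len(p_s)) surv[[paste0("w", j)]] <- xs[, j]
  joint_data(long, surv)
}

# parameters with nontrivial values for a given dataset
toy_params <- function(data, K = 3, alpha = 0.3, seed = 2) {
  n <- data$n
  withr::with_seed(seed, {
    gam <- cbind(rnorm(n, sd = 0.5), rnorm(n, sd = 0.3))
    bl <- rnorm(length(data$cov_l), sd = 0.5)
    bs <- rnorm(length(data$cov_s), sd = 0.4)
    lam <- runif(K, 0.2, 1.5)
  })
  maxT <- max(data$surv$time)
  joint_params(beta0 = 0.7, beta_t = 0.9,
               beta_l = stats::setNames(bl, data$cov_l),
               gamma = gam, Q = matrix(c(0.5, 0.1, 0.1, 0.3), 2),
               sigma2 = 0.2,
               knots = seq(0, maxT, length.out = K + 1),
               lambda = lam, alpha = alpha,
               beta_s = stats::setNames(bs, data$cov_s))
}

# quadrature oracle for the cumulative hazard of one subject: integrates the
# hazard segment by segment so discontinuities do not hurt accuracy
quad_cum_hazard <- function(knots, lambda, alpha, a, b, eta_s, time) {
  K <- length(lambda)
  total <- 0
  for (k in seq_len(K)) {
    l <- knots[k]
    u <- if (k < K) min(knots[k + 1], time) else time
    if (time <= l) break
    f <- function(t) lambda[k] * exp(eta_s + alpha * (a + b * t))
    total <- total + stats::integrate(f, l, u, rel.tol = 1e-12,
                                      abs.tol = 1e-13)$value
  }
  total
}

# term-by-term survival log-likelihood oracle using the quadrature hazard
surv_loglik_oracle <- function(params, data) {
  sp <- params$surv
  lp <- params$long
  total <- 0
  for (i in seq_len(data$n)) {
    id <- data$ids[i]
    rows <- data$long[data$long$id == id, , drop = FALSE]
    x_l <- as.numeric(rows[1, data$cov_l, drop = FALSE])
    a <- lp$beta0 + sum(lp$beta_l * x_l) + lp$gamma[i, 1]
    b <- lp$beta_t + lp$gamma[i, 2]
    srow <- data$surv[data$surv$id == id, , drop = FALSE]
    eta_s <- sum(sp$beta_s * as.numeric(srow[1, data$cov_s, drop = FALSE]))
    Ti <- srow$time
    seg <- max(1, min(findInterval(Ti, sp$knots), length(sp$lambda)))
    Lam <- quad_cum_hazard(sp$knots, sp$lambda, sp$alpha, a, b, eta_s, Ti)
    total <- total + srow$event *
      (log(sp$lambda[seg]) + eta_s + sp$alpha * (a + b * Ti)) - Lam
  }
  total
}

# per-record Gaussian log-density summation oracle
long_loglik_oracle <- function(params, data) {
  lp <- params$long
  total <- 0
  for (i in seq_len(data$n)) {
    id <- data$ids[i]
    rows <- data$long[data$long$id == id, , drop = FALSE]
    x_l <- as.numeric(rows[1, data$cov_l, drop = FALSE])
    for (j in seq_len(nrow(rows))) {
      mu <- lp$beta0 + lp$beta_t * rows$time[j] + sum(lp$beta_l * x_l) +
        lp$gamma[i, 1] + lp$gamma[i, 2] * rows$time[j]
      total <- total + dnorm(rows$y[j], mu, sqrt(lp$sigma2), log = TRUE)
    }
  }
  total
}
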