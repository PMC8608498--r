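# a flat longitudinal trajectory (a = b = 0) turns the joint survival model
# into a plain piecewise-exponential proportional hazards model
flat_surv_data <- function(n = 120, beta = 0.7, lam = 0.8, seed = 41,
                           p_s = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p_s), n)
    Tstar <- rexp(n, rate = lam * exp(drop(x %*% rep(beta, p_s))))
    C <- rexp(n, 0.5)
  })
  Tobs <- pmin(Tstar, C)
  delta <- as.numeric(Tstar <= C)
  long <- data.frame(id = 1:n, time = 0, y = 0)
  surv <- data.frame(id = 1:n, time = Tobs, event = delta)
  for (j in seq_len(p_s)) surv[[paste0("w", j)]] <- x[, j]
  joint_data(long, surv)
}

flat_params <- function(jd, K = 1) {
  n <- jd$n
  joint_params(beta0 = 0, beta_t = 0, beta_l = setNames(numeric(0), character(0)),
               gamma = matrix(0, n, 2), Q = diag(2), sigma2 = 1,
               knots = seq(0, max(jd$surv$time), length.out = K + 1),
               lambda = rep(max(sum(jd$surv$event) / sum(jd$surv$time), 1e-4), K),
               alpha = 0,
               beta_s = setNames(rep(0, length(jd$cov_s)), jd$cov_s))
}

test_that("survival candidates are scoring steps with the right fixed points", {
  jd <- flat_surv_data(seed = 42)
  p <- flat_params(jd)
  # at the 1-d partial optimum the step is ~0
  x <- jd$surv$w1; Tobs <- jd$surv$time; delta <- jd$surv$event
  lam <- p$surv$lambda
  nll <- function(b) -(sum(delta * b * x) - lam * sum(Tobs * exp(b * x)))
  bhat <- optimize(nll, c(-3, 3), tol = 1e-12)$minimum
  p1 <- p; p1$surv$beta_s[1] <- bhat
  cand <- surv_candidate(p1, jd, 1)
  expect_lt(abs(cand$delta), 1e-6)

  # flat trajectory and no events: the alpha direction has no information
  jd0 <- jd; jd0$surv$event <- 0
  jd0 <- joint_data(jd0$long, jd0$surv)
  expect_equal(suppressMessages(surv_candidate(flat_params(jd0), jd0, "alpha"))$criterion_value,
               -Inf)

  # repeated full steps converge to the proportional-hazards ML (joint in
  # (beta, lambda)) computed by a direct optimizer
  ctl <- boost_control(nu_s = 1, m_max_s = 150, K = 1, m_max_l = 1, grid_l = 1)
  bs <- suppressMessages(boost_survival(p, jd, 150, ctl))
  nll2 <- function(par) -(sum(delta * (par[2] + par[1] * x)) -
                            exp(par[2]) * sum(Tobs * exp(par[1] * x)))
  o <- optim(c(0, 0), nll2, method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(unname(bs$params$surv$beta_s[1]), o$par[1], tolerance = 1e-5)
  expect_equal(bs$params$surv$lambda, exp(o$par[2]), tolerance = 1e-3)
  expect_identical(bs$params$surv$alpha, 0)  # no information, never selected
})

test_that("the baseline update is the occurrence/exposure conditional ML", {
  jd <- flat_surv_data(n = 80, seed = 43)
  p <- flat_params(jd, K = 3)
  # alpha = 0, beta_s = 0: classical events / person-time per segment
  up <- update_baseline(p, jd)
  knots <- p$surv$knots
  Tobs <- jd$surv$time; delta <- jd$surv$event
  for (k in 1:3) {
    l <- knots[k]; u <- knots[k + 1]
    exposure <- sum(pmin(pmax(Tobs - l, 0), u - l)) +
      if (k == 3) sum(pmax(Tobs - u, 0)) else 0
    seg <- boostjm:::segment_of(knots, Tobs)
    dk <- sum(delta[seg == k])
    expect_equal(up$surv$lambda[k], dk / exposure, tolerance = 1e-12)
  }

  # a segment nobody reaches keeps its value
  p2 <- p
  p2$surv$knots <- c(0, 1, 2, 100 + max(Tobs))
  p2$surv$lambda <- c(0.5, 0.5, 0.123)
  # push the last interior knot beyond follow-up so segment 3 is empty
  p2$surv$knots[3] <- max(Tobs) + 1
  up2 <- update_baseline(p2, jd)
  expect_identical(up2$surv$lambda[3], 0.123)

  # with nonzero alpha/beta the updated value maximizes the likelihood
  # over that segment's hazard (1-d grid oracle)
  jd2 <- toy_joint(n = 20, n_i = 3, seed = 44)
  pp <- toy_params(jd2, K = 3, alpha = 0.4, seed = 45)
  up3 <- update_baseline(pp, jd2)
  for (k in c(1, 3)) {
    lamk <- up3$surv$lambda[k]
    ll_at <- function(v) {
      q <- up3; q$surv$lambda[k] <- v
      surv_loglik(q, jd2)
    }
    grid <- lamk * c(0.85, 0.95, 1, 1.05, 1.15)
    vals <- vapply(grid, ll_at, numeric(1))
    expect_identical(which.max(vals), 3L)
  }
})

test_that("the survival boosting loop honors selection and ascent contracts", {
  jd <- toy_joint(n = 40, n_i = 3, p_l = 2, p_s = 3, seed = 46)
  ctl <- boost_control(m_max_s = 25, K = 3, m_max_l = 1, grid_l = 1)
  init <- init_params(jd, ctl)
  # zero iterations is the identity
  b0 <- boost_survival(init, jd, 0, ctl)
  expect_equal(b0$params, init)
  # path bookkeeping and exact zeros for unselected components
  bs <- boost_survival(init, jd, 25, ctl)
  expect_identical(nrow(bs$path), 25L)
  sel <- unique(bs$path$selected)
  expect_true(all(bs$params$surv$beta_s[setdiff(jd$cov_s, sel)] == 0))
  # survival log-likelihood is non-decreasing across iterations
  expect_true(all(diff(bs$path$surv_loglik) > -1e-8))

  # duplicated survival covariates tie: lowest index selected
  surv2 <- jd$surv; surv2$w2 <- surv2$w1; surv2$w3 <- NULL
  jd2 <- joint_data(jd$long, surv2)
  init2 <- init_params(jd2, ctl)
  b1 <- boost_survival(init2, jd2, 1, ctl)
  expect_true(b1$path$selected[1] %in% c("alpha", "w1"))
})

test_that("early stopping shrinks the association parameter", {
  cfg <- sim_config(n = 150, n_i = 4, p_l = 2, p_s = 2, beta_l = c(1, 1),
                    beta_s = c(1, -1), alpha = 0.5, seed = 47)
  jd <- as_joint_data(simulate_joint(cfg))
  ctl <- boost_control(m_max_s = 400, K = 5, m_max_l = 1, grid_l = 1)
  start <- boostjm:::stage1_two_stage(jd, ctl)
  bs <- boost_survival(start, jd, 400, ctl)
  path_alpha <- abs(bs$path$alpha)
  converged <- tail(path_alpha, 1)
  expect_lt(path_alpha[20], converged)   # early iterates are shrunk
  expect_gt(converged, 0.1)              # and the signal is really there
})
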