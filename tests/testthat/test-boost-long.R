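test_that("initialization sets coefficients, hazard and mixed-model pieces correctly", {
  cfg <- sim_config(n = 50, n_i = 4, p_l = 2, p_s = 2, beta_l = c(1, -1),
                    beta_s = c(1, 0.5), seed = 31)
  sim <- simulate_joint(cfg)
  jd <- as_joint_data(sim)
  ctl <- boost_control(K = 4)
  init <- init_params(jd, ctl)
  # boosted coefficients start at zero
  expect_true(all(init$long$beta_l == 0))
  expect_true(all(init$surv$beta_s == 0))
  expect_identical(init$surv$alpha, 0)
  # every hazard segment equals event count over total follow-up
  expect_equal(unique(init$surv$lambda),
               sum(jd$surv$event) / sum(jd$surv$time))
  expect_length(init$surv$lambda, 4L)

  # noiseless y = 1 + 2 t with no random effects: exact recovery
  long <- data.frame(id = rep(1:20, each = 3),
                     time = rep(c(0.2, 1, 1.7), 20))
  long$y <- 1 + 2 * long$time
  surv <- data.frame(id = 1:20, time = 1, event = rep(c(0, 1), 10))
  jd0 <- joint_data(long, surv)
  init0 <- suppressWarnings(init_params(jd0, ctl))
  expect_equal(init0$long$beta0, 1, tolerance = 1e-6)
  expect_equal(init0$long$beta_t, 2, tolerance = 1e-6)

  # all-censored data: hazard clamped with a warning
  surv$event <- 0
  expect_warning(init_params(joint_data(long, surv), ctl), "clamped")
})

test_that("candidate updates are Fisher-scoring steps with the right fixed points", {
  jd <- toy_joint(n = 30, n_i = 4, p_l = 1, seed = 32)
  ctl <- boost_control(K = 2)
  init <- init_params(jd, ctl)
  # place the triple at its exact OLS optimum with gamma = 0: score vanishes
  p <- init
  p$long$gamma[] <- 0
  X <- cbind(1, jd$long$time, jd$long$x1)
  bhat <- solve(crossprod(X), crossprod(X, jd$long$y))
  p$long$beta0 <- bhat[1]; p$long$beta_t <- bhat[2]; p$long$beta_l[1] <- bhat[3]
  cu <- candidate_update(p, jd, 1)
  expect_lt(max(abs(cu$delta)), 1e-6)

  # away from the optimum the step equals the normal-equations oracle
  p2 <- init; p2$long$gamma[] <- 0
  resid <- jd$long$y - (p2$long$beta0 + p2$long$beta_t * jd$long$time)
  oracle <- solve(crossprod(X), crossprod(X, resid))
  cu2 <- candidate_update(p2, jd, 1)
  expect_equal(cu2$delta, drop(oracle), tolerance = 1e-10)

  # ascent: applying the full delta never decreases the penalized likelihood
  withr::with_seed(33, {
    for (rep in 1:25) {
      pr <- init
      pr$long$beta0 <- rnorm(1); pr$long$beta_t <- rnorm(1)
      pr$long$beta_l[1] <- rnorm(1)
      before <- long_pen_loglik(pr, jd)
      cu3 <- candidate_update(pr, jd, 1)
      pr$long$beta0 <- pr$long$beta0 + cu3$delta[1]
      pr$long$beta_t <- pr$long$beta_t + cu3$delta[2]
      pr$long$beta_l[1] <- pr$long$beta_l[1] + cu3$delta[3]
      expect_gte(long_pen_loglik(pr, jd), before - 1e-10)
    }
  })
})

test_that("selection picks the best candidate with deterministic tie-breaking", {
  # single covariate: forced choice
  jd1 <- toy_joint(n = 10, n_i = 3, p_l = 1, seed = 34)
  ctl <- boost_control(K = 2)
  st <- select_and_update_fixed(init_params(jd1, ctl), jd1, ctl)
  expect_identical(st$selected, 1L)

  # duplicated covariate columns tie exactly: lowest index wins
  long <- jd1$long; long$x2 <- long$x1
  surv <- jd1$surv
  jd2 <- joint_data(long, surv)
  st2 <- select_and_update_fixed(init_params(jd2, ctl), jd2, ctl)
  expect_identical(st2$selected, 1L)

  # only covariate 2 informative: selected in iteration 1, and the choice
  # agrees with directly comparing the candidates' criterion values
  withr::with_seed(35, {
    n <- 40
    x <- matrix(rnorm(3 * n), n)
    tm <- matrix(runif(3 * n, 0, 2), n)
    y <- 0.5 + 1 * tm + 2 * x[, 2] + rnorm(3 * n, sd = 0.2)
  })
  long3 <- data.frame(id = rep(1:n, each = 3), time = as.vector(t(tm)),
                      y = as.vector(t(y)),
                      x1 = rep(x[, 1], each = 3), x2 = rep(x[, 2], each = 3),
                      x3 = rep(x[, 3], each = 3))
  surv3 <- data.frame(id = 1:n, time = 1, event = 1)
  jd3 <- joint_data(long3, surv3)
  init3 <- init_params(jd3, ctl)
  scores <- vapply(1:3, function(r)
    candidate_update(init3, jd3, r)$criterion_value, numeric(1))
  expect_identical(which.max(scores), 2L)
  st3 <- select_and_update_fixed(init3, jd3, ctl)
  expect_identical(st3$selected, 2L)
})

test_that("the corrected random-effects update decorrelates and reaches its fixed point", {
  jd <- toy_joint(n = 25, n_i = 4, p_l = 2, seed = 36)
  ctl <- boost_control(K = 2)
  p <- init_params(jd, ctl)
  p$long$beta_l[] <- c(0.3, -0.2)
  # after one update, random effects are exactly uncorrelated with the
  # intercept and every subject-level covariate column
  p1 <- update_random_effects(p, jd)
  W <- cbind(1, boostjm:::jd_matrices(jd)$Xl_sub)
  expect_lt(max(abs(crossprod(W, p1$long$gamma))), 1e-10)
  # iterating to the constrained fixed point: one more update is a no-op
  for (i in 1:200) p1 <- update_random_effects(p1, jd)
  p2 <- update_random_effects(p1, jd)
  expect_lt(max(abs(p2$long$gamma - p1$long$gamma)), 1e-8)

  # uncorrected single-subject step equals the closed-form solve
  long1 <- jd$long[jd$long$id == 1, ]
  surv1 <- jd$surv[jd$surv$id == 1, ]
  jd1 <- joint_data(long1[, c("id", "time", "y")], surv1[, c("id", "time", "event")])
  pp <- joint_params(beta0 = 0.2, beta_t = 0.1,
                     beta_l = setNames(numeric(0), character(0)),
                     gamma = matrix(0, 1, 2), Q = diag(c(0.5, 0.25)),
                     sigma2 = 0.3, knots = c(0, 2), lambda = 1, alpha = 0,
                     beta_s = setNames(numeric(0), character(0)))
  up <- update_random_effects(pp, jd1, correct = FALSE)
  Z <- cbind(1, long1$time)
  r <- long1$y - (0.2 + 0.1 * long1$time)
  blup <- solve(crossprod(Z) / 0.3 + solve(diag(c(0.5, 0.25))),
                crossprod(Z, r) / 0.3)
  expect_equal(up$long$gamma[1, ], drop(blup), tolerance = 1e-10)
})

test_that("variance-component updates match their closed forms", {
  jd <- toy_joint(n = 8, n_i = 3, seed = 37)
  ctl <- boost_control(K = 2)
  p <- update_random_effects(init_params(jd, ctl), jd)

  # Q update against an explicit summation oracle
  pq <- update_Q(p, jd)
  Fb <- p$long$Fblocks
  acc <- matrix(0, 2, 2)
  for (i in seq_len(jd$n)) {
    Fi <- matrix(c(Fb[i, 1], Fb[i, 2], Fb[i, 2], Fb[i, 3]), 2)
    acc <- acc + solve(Fi) + tcrossprod(p$long$gamma[i, ])
  }
  expect_equal(pq$long$Q, acc / jd$n, tolerance = 1e-12)

  # closed forms: all gamma zero with identity curvature gives Q = I
  p0 <- p; p0$long$gamma[] <- 0
  p0$long$Fblocks <- matrix(rep(c(1, 0, 1), each = jd$n), jd$n)
  expect_equal(update_Q(p0, jd)$long$Q, diag(2))

  # sigma2: plain two-point residual variance is 1
  long <- data.frame(id = c(1, 2), time = 0, y = c(-1, 1))
  surv <- data.frame(id = c(1, 2), time = 1, event = 1)
  jd2 <- joint_data(long, surv)
  ps <- joint_params(beta0 = 0, beta_t = 0, beta_l = setNames(numeric(0), character(0)),
                     gamma = matrix(0, 2, 2), Q = diag(2), sigma2 = 5,
                     knots = c(0, 1), lambda = 1, alpha = 0,
                     beta_s = setNames(numeric(0), character(0)))
  expect_equal(update_sigma2(ps, jd2, curvature = FALSE)$long$sigma2, 1)
  # perfect fit clamps at the floor
  ps2 <- ps; ps2$long$beta0 <- 0
  long2 <- long; long2$y <- 0
  expect_equal(update_sigma2(ps2, joint_data(long2, surv),
                             curvature = FALSE)$long$sigma2, 1e-10)
  # seeded data: plain update equals the direct variance oracle
  pp <- toy_params(jd, seed = 38)
  got <- update_sigma2(pp, jd, curvature = FALSE)$long$sigma2
  mats <- boostjm:::jd_matrices(jd)
  cache <- boostjm:::predictor_cache(pp, mats)
  r <- mats$y - cache$eta_rec
  expect_equal(got, mean((r - mean(r))^2), tolerance = 1e-12)
})

test_that("the longitudinal boosting loop keeps its bookkeeping contracts", {
  jd <- toy_joint(n = 15, n_i = 3, p_l = 3, seed = 39)
  ctl <- boost_control(m_max_l = 6, grid_l = 6, K = 2)
  init <- init_params(jd, ctl)
  # zero iterations is the identity
  b0 <- boost_longitudinal(init, jd, 0, ctl)
  expect_equal(b0$params, init)
  # path length equals the iteration count
  b6 <- boost_longitudinal(init, jd, 6, ctl)
  expect_identical(nrow(b6$path), 6L)
  # unselected coefficients are exactly zero
  sel <- unique(b6$path$selected)
  expect_true(all(b6$params$long$beta_l[setdiff(jd$cov_l, sel)] == 0))
  # ascent of the penalized likelihood across each fixed-effect update
  p <- init
  mats <- boostjm:::jd_matrices(jd)
  for (i in 1:6) {
    before <- long_pen_loglik(p, jd)
    st <- boostjm:::step_fixed(p, mats,
                               boostjm:::predictor_cache(p, mats)$eta_rec,
                               boostjm:::gamma_penalty(p$long$gamma, p$long$Q),
                               ctl)
    expect_gte(long_pen_loglik(st$params, jd), before - 1e-10)
    p <- st$params
    p <- boostjm:::step_random(p, mats, TRUE)
    p <- update_Q(p, jd)
    p <- update_sigma2(p, jd, curvature = TRUE)
  }
})

test_that("without the correction, boosting converges to the mixed-model ML fit", {
  cfg <- sim_config(n = 120, n_i = 5, p_l = 2, p_s = 1, beta_l = c(1, -0.5),
                    beta_s = 1, sigma = 0.5,
                    Q = matrix(c(0.4, 0.05, 0.05, 0.2), 2), seed = 40)
  jd <- as_joint_data(simulate_joint(cfg))
  ctl <- boost_control(nu_l = 1, m_max_l = 1500, grid_l = 1500, K = 3,
                       correct_random_effects = FALSE)
  bl <- boost_longitudinal(init_params(jd, ctl), jd, 1500, ctl)
  m <- lme4::lmer(y ~ time + x_l1 + x_l2 + (1 + time | id), data = jd$long,
                  REML = FALSE)
  est <- c(bl$params$long$beta0, bl$params$long$beta_t,
           unname(bl$params$long$beta_l))
  expect_equal(est, unname(lme4::fixef(m)), tolerance = 1e-3)
  expect_equal(bl$params$long$sigma2, unname(stats::sigma(m))^2,
               tolerance = 1e-2)
  expect_equal(unclass(bl$params$long$Q),
               matrix(as.numeric(lme4::VarCorr(m)$id[1:2, 1:2]), 2),
               tolerance = 1e-2, ignore_attr = TRUE)
})
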