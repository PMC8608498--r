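# Drivers: the full boosting variant (longitudinal boosting to each grid
# value, then a survival boosting path), the two-stage variant (maximum
# likelihood first stage), cross-validated selection of the stopping
# iterations, and selection metrics.

#' Fit the full boosting path over the stopping-iteration grid
#'
#' Runs the longitudinal boosting process once up to `max(grid_l)`, keeping a
#' parameter snapshot at every grid value, and from each snapshot runs a
#' survival boosting path up to `m_max_s`. Because survival boosting records
#' every iteration, this yields the fit at every tuple `(m_l, m_s)` on
#' `grid_l x 1:m_max_s` with no recomputation.
#'
#' @inheritParams select_and_update_fixed
#' @param init Optional initialization (defaults to [init_params()]).
#' @return An object of class `jm_path` from which [params_at()] extracts the
#'   fit at any grid tuple.
#' @export
fit_path <- function(data, control = boost_control(), init = NULL) {
  init <- init %||% init_params(data, control)
  grid <- control$grid_l
  stopifnot(length(grid) >= 1L)
  bl <- boost_longitudinal(init, data, max(grid), control, snapshot_at = grid)
  runs <- purrr::map(grid, function(g) {
    start <- bl$snapshots[[as.character(g)]]
    if (is.null(start)) return(NULL)  # longitudinal boosting stopped early
    start$surv <- init$surv  # survival parameters always start from scratch
    bs <- boost_survival(start, data, control$m_max_s, control)
    list(m_l = g, long_params = start, path = bs$path,
         lambda_path = bs$lambda_path)
  })
  runs <- purrr::compact(runs)
  structure(list(init = init, runs = runs, long_path = bl$path,
                 control = control, cov_l = data$cov_l, cov_s = data$cov_s),
            class = "jm_path")
}

#' Extract the parameters at one stopping tuple from a fitted path
#'
#' @param path A `jm_path` from [fit_path()].
#' @param m_l,m_s Stopping iterations; `m_l` must lie on the fitted grid and
#'   `m_s` in `0:m_max_s` (0 = survival parameters at initialization).
#' @return A [joint_params()] object.
#' @export
params_at <- function(path, m_l, m_s) {
  run <- purrr::detect(path$runs, ~ .x$m_l == m_l)
  if (is.null(run)) abort("m_l not on the fitted grid", class = "boostjm_config_error")
  params <- run$long_params
  if (m_s > nrow(run$path)) abort("m_s beyond the fitted path", class = "boostjm_config_error")
  if (m_s > 0L) {
    row <- run$path[m_s, ]
    params$surv$alpha <- row$alpha
    params$surv$beta_s[] <- as.numeric(row[, path$cov_s, drop = FALSE])
    params$surv$lambda <- run$lambda_path[m_s, ]
  }
  params
}

# posterior mode of a subject's random effects given only its longitudinal
# records (used for held-out subjects when requested)
posterior_gamma <- function(long, mats) {
  s2 <- long$sigma2
  Qi <- inv2(long$Q)
  idx <- mats$id_idx
  p_l <- length(long$beta_l)
  base <- if (p_l) drop(mats$Xl_sub %*% long$beta_l) else rep(0, mats$n)
  eta_fix <- long$beta0 + base[idx] + long$beta_t * mats$t
  r <- mats$y - eta_fix
  Zr1 <- rowsum_vec(r, idx, mats$n)
  Zr2 <- rowsum_vec(mats$t * r, idx, mats$n)
  ni <- tabulate(idx, mats$n)
  St <- rowsum_vec(mats$t, idx, mats$n)
  Stt <- rowsum_vec(mats$t^2, idx, mats$n)
  f11 <- ni / s2 + Qi[1, 1]
  f12 <- St / s2 + Qi[1, 2]
  f22 <- Stt / s2 + Qi[2, 2]
  det <- f11 * f22 - f12^2
  s1 <- Zr1 / s2; s2v <- Zr2 / s2
  cbind((f22 * s1 - f12 * s2v) / det, (f11 * s2v - f12 * s1) / det)
}

# unpenalized joint log-likelihood of held-out data with the stated
# random-effects rule; the survival part is evaluated for every iteration of
# a survival path at once
test_loglik_path <- function(long_params, surv_init, path, lambda_path,
                             test_data, control) {
  mats <- jd_matrices(test_data)
  params <- long_params
  gamma <- switch(control$test_random_effects,
                  zero = matrix(0, mats$n, 2),
                  posterior = posterior_gamma(params$long, mats))
  params$long$gamma <- gamma
  cache <- predictor_cache(params, mats)
  ll_long <- ll_long_from_cache(params, mats, cache)
  M <- nrow(path)
  out <- numeric(M)
  sp <- surv_init
  for (m in seq_len(M)) {
    sp$alpha <- path$alpha[m]
    sp$beta_s[] <- as.numeric(path[m, names(sp$beta_s), drop = FALSE])
    sp$lambda <- lambda_path[m, ]
    cache$eta_s <- if (length(sp$beta_s)) drop(mats$Xs %*% sp$beta_s) else
      rep(0, mats$n)
    st <- surv_state(sp, mats, cache, order = 0L)
    out[m] <- ll_long + surv_ll_state(sp, mats, cache, st)
  }
  out
}

# seeded contiguous-block fold assignment on permuted subject ids
assign_folds <- function(ids, k, seed) {
  perm <- withr::with_seed(seed, sample(ids))
  sizes <- rep(floor(length(ids) / k), k)
  sizes[seq_len(length(ids) - sum(sizes))] <-
    sizes[seq_len(length(ids) - sum(sizes))] + 1L
  fold <- rep(seq_len(k), times = sizes)
  stats::setNames(fold, perm)[as.character(ids)]
}

# two-stage first stage: unregularized ML longitudinal fit + fresh survival
# initialization
stage1_two_stage <- function(data, control) {
  lmm <- fit_lmm_ml(data)
  mats <- jd_matrices(data)
  lam0 <- max(sum(mats$delta) / sum(mats$Ts), .EPS)
  K <- control$K
  joint_params(beta0 = lmm$beta0, beta_t = lmm$beta_t, beta_l = lmm$beta_l,
               gamma = lmm$gamma, Q = spd_repair(lmm$Q),
               sigma2 = max(lmm$sigma2, .EPS),
               knots = seq(0, max(mats$Ts), length.out = K + 1L),
               lambda = rep(lam0, K), alpha = 0,
               beta_s = stats::setNames(rep(0, length(data$cov_s)), data$cov_s))
}

#' Cross-validated selection of the stopping iterations
#'
#' Partitions subjects (never records) into `cv_folds` folds; for each fold
#' fits the boosting path on the training subjects and evaluates the
#' unpenalized joint log-likelihood of the held-out subjects at every grid
#' tuple, with held-out random effects handled per
#' `control$test_random_effects` (prior mean zero by default). Fold surfaces
#' are summed, the maximizing tuple is selected (ties: smallest `m_l`, then
#' smallest `m_s`) and the model is refit on all data at that tuple.
#'
#' @inheritParams select_and_update_fixed
#' @param variant `"full"` boosts both submodels and tunes
#'   `(m_l, m_s)` on `grid_l x 1:m_max_s`; `"two-stage"` fits the
#'   longitudinal submodel by maximum likelihood (no regularization) and
#'   tunes `m_s` only.
#' @return A `jm_boost_fit` object; see [jm_boost()].
#' @export
cross_validate <- function(data, control = boost_control(),
                           variant = c("full", "two-stage")) {
  variant <- match.arg(variant)
  if (isTRUE(control$standardize)) {
    data <- standardize_joint(data)
    control$standardize <- FALSE
  }
  folds <- assign_folds(data$ids, control$cv_folds, control$seed)
  grid <- if (variant == "full") control$grid_l else 0L
  surface <- matrix(0, length(grid), control$m_max_s)
  # shortest survival path seen per grid row: tuples beyond it are not
  # comparable across folds and are excluded from selection
  min_len <- rep(Inf, length(grid))
  used <- 0L
  for (f in seq_len(control$cv_folds)) {
    test_ids <- data$ids[folds == f]
    train_ids <- setdiff(data$ids, test_ids)
    train <- jd_subset(data, train_ids)
    test <- jd_subset(data, test_ids)
    if (sum(train$surv$event) == 0 || sum(test$surv$event) == 0) {
      warn(paste0("fold ", f, " has no events; skipped"))
      next
    }
    if (variant == "full") {
      pf <- fit_path(train, control)
      for (gi in seq_along(grid)) {
        run <- purrr::detect(pf$runs, ~ .x$m_l == grid[gi])
        if (is.null(run)) {
          min_len[gi] <- 0
          next
        }
        ll <- test_loglik_path(run$long_params, pf$init$surv, run$path,
                               run$lambda_path, test, control)
        surface[gi, seq_along(ll)] <- surface[gi, seq_along(ll)] + ll
        min_len[gi] <- min(min_len[gi], length(ll))
      }
    } else {
      start <- stage1_two_stage(train, control)
      bs <- boost_survival(start, train, control$m_max_s, control)
      ll <- test_loglik_path(start, start$surv, bs$path, bs$lambda_path, test,
                             control)
      surface[1, seq_along(ll)] <- surface[1, seq_along(ll)] + ll
      min_len[1] <- min(min_len[1], length(ll))
    }
    used <- used + 1L
  }
  if (used == 0L) abort("no usable folds", class = "boostjm_numeric_error")
  for (gi in seq_along(grid)) {
    if (min_len[gi] < control$m_max_s) {
      surface[gi, seq_len(control$m_max_s) > min_len[gi]] <- -Inf
    }
  }
  surf_tbl <- tidyr::expand_grid(m_l = grid, m_s = seq_len(control$m_max_s)) |>
    dplyr::arrange(.data$m_l, .data$m_s)
  surf_tbl$test_loglik <- as.vector(t(surface))
  best <- surf_tbl |>
    dplyr::filter(.data$test_loglik == max(.data$test_loglik)) |>
    dplyr::arrange(.data$m_l, .data$m_s) |>
    dplyr::slice(1)
  refit_at(data, control, variant,
           m_l = if (variant == "full") best$m_l else NA_integer_,
           m_s = best$m_s, cv_surface = surf_tbl)
}

refit_at <- function(data, control, variant, m_l, m_s, cv_surface = NULL) {
  if (variant == "full") {
    init <- init_params(data, control)
    bl <- boost_longitudinal(init, data, m_l, control)
    start <- bl$params
    start$surv <- init$surv
    path_long <- bl$path
  } else {
    init <- start <- stage1_two_stage(data, control)
    path_long <- tibble::tibble(iteration = integer(), selected = character())
  }
  bs <- boost_survival(start, data, m_s, control)
  structure(
    list(params = bs$params, variant = variant, control = control,
         m_star = c(m_l = m_l, m_s = m_s),
         cv_surface = cv_surface %||%
           tibble::tibble(m_l = integer(), m_s = integer(),
                          test_loglik = numeric()),
         path_long = path_long, path_surv = bs$path,
         lambda_path = bs$lambda_path, init = init,
         cov_l = data$cov_l, cov_s = data$cov_s, n = data$n,
         logLik = joint_loglik(bs$params, data, penalized = FALSE)),
    class = "jm_boost_fit")
}

#' Fit a boosted joint model
#'
#' Main entry point. With `m = NULL` (default), the stopping iterations are
#' selected by k-fold cross-validated joint likelihood ([cross_validate()])
#' and the model is refit on all data at the selected tuple. Supplying
#' `m = c(m_l, m_s)` fits at a fixed tuple without tuning (`m_l` is ignored
#' by the two-stage variant).
#'
#' @inheritParams cross_validate
#' @param m Optional fixed stopping tuple `c(m_l, m_s)`.
#' @return A `jm_boost_fit`: final [joint_params()] in `$params`, the
#'   selected tuple in `$m_star`, per-iteration coefficient paths in
#'   `$path_long` / `$path_surv`, and the cross-validation surface in
#'   `$cv_surface`. Supports [tidy()], [glance()], [autoplot()].
#' @examples
#' \donttest{
#' cfg <- sim_config(n = 60, p_l = 2, p_s = 2, beta_l = c(1, 2),
#'                   beta_s = c(1, -1), seed = 7)
#' sim <- simulate_joint(cfg)
#' fit <- jm_boost(as_joint_data(sim),
#'                 boost_control(m_max_l = 20, m_max_s = 20,
#'                               grid_l = c(10, 20), cv_folds = 2),
#'                 variant = "full")
#' tidy(fit)
#' }
#' @export
jm_boost <- function(data, control = boost_control(),
                     variant = c("full", "two-stage"), m = NULL) {
  variant <- match.arg(variant)
  if (is.null(m)) {
    cross_validate(data, control, variant)
  } else {
    if (isTRUE(control$standardize)) {
      data <- standardize_joint(data)
      control$standardize <- FALSE
    }
    refit_at(data, control, variant,
             m_l = if (variant == "full") as.integer(m[1]) else NA_integer_,
             m_s = as.integer(m[length(m)]))
  }
}

#' Variable-selection metrics against known truth
#'
#' True-positive share and false discovery rate of the fitted coefficient
#' vectors, computed separately for the longitudinal and survival submodels:
#' `TP = #informative with nonzero estimate / #informative`,
#' `FDR = #noninformative nonzero / #nonzero` (0 when nothing is selected).
#' The association parameter and the time effect are not part of either
#' count.
#'
#' @param fit A `jm_boost_fit`.
#' @param truth Truth table as produced by [simulate_joint()]: columns
#'   `submodel` (`"long"`/`"surv"`), `term`, `true_value`, `informative`.
#' @return A tibble with one row per submodel: `tp`, `fdr`, counts.
#' @export
evaluate_selection <- function(fit, truth) {
  est <- list(long = fit$params$long$beta_l, surv = fit$params$surv$beta_s)
  purrr::map_dfr(c("long", "surv"), function(sm) {
    tr <- truth[truth$submodel == sm, ]
    e <- est[[sm]][tr$term]
    nonzero <- e != 0
    n_inf <- sum(tr$informative)
    n_sel <- sum(nonzero)
    tibble::tibble(
      submodel = sm,
      tp = if (n_inf > 0) sum(nonzero & tr$informative) / n_inf else NA_real_,
      fdr = if (n_sel > 0) sum(nonzero & !tr$informative) / n_sel else 0,
      n_informative = n_inf, n_selected = n_sel)
  })
}
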