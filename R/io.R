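#' Write a fitted model to a directory of delimited text files
#'
#' Writes the coefficient paths (`path_long.csv`, `path_surv.csv`, the
#' per-iteration baseline hazard `lambda_path.csv`), the cross-validation
#' surface (`cv_surface.csv`), the per-subject random effects (`gamma.csv`)
#' and a machine-readable summary of the final parameters and stopping tuple
#' (`fit.json`). [read_fit()] restores the fit from such a directory.
#'
#' @param fit A `jm_boost_fit`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_fit <- function(fit, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(paste0("cannot create output directory ", out_dir))
  }
  readr::write_csv(fit$path_long, file.path(out_dir, "path_long.csv"))
  readr::write_csv(fit$path_surv, file.path(out_dir, "path_surv.csv"))
  readr::write_csv(fit$cv_surface, file.path(out_dir, "cv_surface.csv"))
  lam <- tibble::as_tibble(fit$lambda_path, .name_repair = ~ paste0("lambda", seq_along(.x)))
  readr::write_csv(lam, file.path(out_dir, "lambda_path.csv"))
  gam <- tibble::tibble(gamma0 = fit$params$long$gamma[, 1],
                        gammat = fit$params$long$gamma[, 2])
  readr::write_csv(gam, file.path(out_dir, "gamma.csv"))
  lp <- fit$params$long; sp <- fit$params$surv
  summary <- list(
    variant = fit$variant,
    m_star = as.list(fit$m_star),
    params = list(
      beta0 = lp$beta0, beta_t = lp$beta_t,
      beta_l = as.list(lp$beta_l),
      sigma2 = lp$sigma2,
      Q = list(q11 = lp$Q[1, 1], q12 = lp$Q[1, 2], q22 = lp$Q[2, 2]),
      knots = sp$knots, lambda = sp$lambda,
      alpha = sp$alpha, beta_s = as.list(sp$beta_s)),
    logLik = fit$logLik, n = fit$n,
    control = unclass(fit$control))
  jsonlite::write_json(summary, file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Read a fitted model written by [write_fit()]
#'
#' @param out_dir Directory previously written by [write_fit()].
#' @return A `jm_boost_fit` (without the training data).
#' @export
read_fit <- function(out_dir) {
  js <- jsonlite::read_json(file.path(out_dir, "fit.json"), simplifyVector = TRUE)
  p <- js$params
  gam <- readr::read_csv(file.path(out_dir, "gamma.csv"),
                         show_col_types = FALSE, progress = FALSE)
  beta_l <- unlist(p$beta_l) %||% stats::setNames(numeric(0), character(0))
  beta_s <- unlist(p$beta_s) %||% stats::setNames(numeric(0), character(0))
  params <- joint_params(
    beta0 = p$beta0, beta_t = p$beta_t, beta_l = beta_l,
    gamma = unname(as.matrix(gam)), Q = matrix(c(p$Q$q11, p$Q$q12, p$Q$q12, p$Q$q22), 2, 2),
    sigma2 = p$sigma2, knots = p$knots, lambda = p$lambda,
    alpha = p$alpha, beta_s = beta_s)
  read_tbl <- function(f) {
    tb <- readr::read_csv(file.path(out_dir, f), show_col_types = FALSE,
                          progress = FALSE)
    tb
  }
  ctl <- js$control
  control <- boost_control(
    nu_l = ctl$nu_l, nu_s = ctl$nu_s, m_max_l = ctl$m_max_l,
    m_max_s = ctl$m_max_s, grid_l = ctl$grid_l, K = ctl$K,
    cv_folds = ctl$cv_folds, criterion = ctl$criterion, seed = ctl$seed,
    standardize = ctl$standardize,
    test_random_effects = ctl$test_random_effects)
  lam_tbl <- read_tbl("lambda_path.csv")
  structure(
    list(params = params, variant = js$variant, control = control,
         m_star = c(m_l = js$m_star$m_l %||% NA_integer_,
                    m_s = js$m_star$m_s),
         cv_surface = read_tbl("cv_surface.csv"),
         path_long = read_tbl("path_long.csv"),
         path_surv = read_tbl("path_surv.csv"),
         lambda_path = as.matrix(lam_tbl),
         cov_l = names(beta_l), cov_s = names(beta_s),
         n = js$n, logLik = js$logLik),
    class = "jm_boost_fit")
}

#' Write a simulated dataset (and its truth) to delimited text
#'
#' @param sim A `sim_joint` from [simulate_joint()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_sim <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$long, file.path(out_dir, "longitudinal.csv"))
  readr::write_csv(sim$surv, file.path(out_dir, "survival.csv"))
  readr::write_csv(sim$truth, file.path(out_dir, "truth.csv"))
  jsonlite::write_json(list(censor_rate = sim$censor_rate,
                            seed = sim$config$seed),
                       file.path(out_dir, "sim_info.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
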