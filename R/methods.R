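#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @export
print.jm_boost_fit <- function(x, digits = 4, ...) {
  cat("<jm_boost_fit> variant:", x$variant, "\n")
  cat("  stopping tuple: m_l =", x$m_star[["m_l"]],
      " m_s =", x$m_star[["m_s"]], "\n")
  cat("  alpha =", signif(x$params$surv$alpha, digits),
      "  joint logLik =", signif(x$logLik, digits), "\n")
  sel_l <- sum(x$params$long$beta_l != 0)
  sel_s <- sum(x$params$surv$beta_s != 0)
  cat("  selected covariates: longitudinal", sel_l, "/",
      length(x$params$long$beta_l), ", survival", sel_s, "/",
      length(x$params$surv$beta_s), "\n")
  invisible(x)
}

#' Tidy a boosted joint-model fit
#'
#' One row per model term (intercept, time effect, longitudinal covariates,
#' association parameter, survival covariates) with the estimate and whether
#' the term was selected into the model.
#'
#' @param x A `jm_boost_fit`.
#' @param ... Unused.
#' @return A tibble with columns `submodel`, `term`, `estimate`, `selected`.
#' @export
tidy.jm_boost_fit <- function(x, ...) {
  lp <- x$params$long
  sp <- x$params$surv
  dplyr::bind_rows(
    tibble::tibble(submodel = "long",
                   term = c("(Intercept)", "time", names(lp$beta_l)),
                   estimate = c(lp$beta0, lp$beta_t, unname(lp$beta_l)),
                   selected = c(TRUE, TRUE, unname(lp$beta_l) != 0)),
    tibble::tibble(submodel = "surv",
                   term = c("alpha", names(sp$beta_s)),
                   estimate = c(sp$alpha, unname(sp$beta_s)),
                   selected = c(sp$alpha != 0, unname(sp$beta_s) != 0)))
}

#' One-row summary of a boosted joint-model fit
#'
#' @inheritParams tidy.jm_boost_fit
#' @return A tibble with the variant, the stopping tuple, counts of selected
#'   covariates, variance components and the joint log-likelihood.
#' @export
glance.jm_boost_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    m_l = x$m_star[["m_l"]], m_s = x$m_star[["m_s"]],
    n = x$n,
    n_selected_long = sum(x$params$long$beta_l != 0),
    n_selected_surv = sum(x$params$surv$beta_s != 0),
    alpha = x$params$surv$alpha,
    sigma2 = x$params$long$sigma2,
    logLik = x$logLik)
}

#' Coefficient-path plot for a boosted joint-model fit
#'
#' Shows how each covariate effect (and the association parameter) grows over
#' the boosting iterations of the refit at the selected stopping tuple, one
#' panel per submodel. Unselected effects stay on the zero line.
#'
#' @param object A `jm_boost_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.jm_boost_fit <- function(object, ...) {
  paths <- list()
  if (nrow(object$path_long)) {
    paths$long <- object$path_long |>
      dplyr::select("iteration", dplyr::all_of(object$cov_l)) |>
      tidyr::pivot_longer(-"iteration", names_to = "term",
                          values_to = "estimate") |>
      dplyr::mutate(submodel = "longitudinal")
  }
  if (nrow(object$path_surv)) {
    paths$surv <- object$path_surv |>
      dplyr::select("iteration", "alpha", dplyr::all_of(object$cov_s)) |>
      tidyr::pivot_longer(-"iteration", names_to = "term",
                          values_to = "estimate") |>
      dplyr::mutate(submodel = "survival")
  }
  df <- dplyr::bind_rows(paths)
  if (!nrow(df)) abort("fit has no recorded path to plot")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$estimate,
                                   group = .data$term, color = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~submodel, scales = "free") +
    ggplot2::labs(x = "boosting iteration", y = "coefficient",
                  color = "term") +
    ggplot2::theme_minimal()
}

#' Cross-validation surface plot
#'
#' Held-out joint log-likelihood per stopping tuple; for the two-stage
#' variant this is a curve over `m_s`, for the full variant a tile map over
#' the `(m_l, m_s)` grid. The selected tuple is marked.
#'
#' @param fit A `jm_boost_fit` carrying a cross-validation surface.
#' @return A ggplot object.
#' @export
plot_cv_surface <- function(fit) {
  surf <- dplyr::filter(fit$cv_surface, is.finite(.data$test_loglik))
  if (!nrow(surf)) abort("fit carries no cross-validation surface")
  if (length(unique(surf$m_l)) == 1L) {
    ggplot2::ggplot(surf, ggplot2::aes(x = .data$m_s, y = .data$test_loglik)) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = fit$m_star[["m_s"]], linetype = 2) +
      ggplot2::labs(x = "survival stopping iteration",
                    y = "held-out joint log-likelihood") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(surf, ggplot2::aes(x = .data$m_s, y = factor(.data$m_l),
                                       fill = .data$test_loglik)) +
      ggplot2::geom_tile() +
      ggplot2::annotate("point", x = fit$m_star[["m_s"]],
                        y = factor(fit$m_star[["m_l"]],
                                   levels = levels(factor(surf$m_l)))) +
      ggplot2::labs(x = "survival stopping iteration",
                    y = "longitudinal stopping iteration",
                    fill = "held-out\nlog-likelihood") +
      ggplot2::theme_minimal()
  }
}

#' Plot simulated longitudinal trajectories and survival outcome
#'
#' @param object A `sim_joint` from [simulate_joint()].
#' @param n_subjects Number of subjects to draw trajectories for.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sim_joint <- function(object, n_subjects = 20, ...) {
  ids <- head(unique(object$long$id), n_subjects)
  df <- dplyr::filter(object$long, .data$id %in% ids)
  ev <- dplyr::filter(object$surv, .data$id %in% ids)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$y,
                                   group = .data$id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_rug(data = ev,
                      ggplot2::aes(x = .data$time, y = NULL, group = NULL),
                      sides = "b") +
    ggplot2::labs(x = "time", y = "longitudinal outcome") +
    ggplot2::theme_minimal()
}
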