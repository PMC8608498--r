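#' Assemble a joint longitudinal/survival dataset
#'
#' Bundles a long-format longitudinal table and a per-subject survival table
#' into a validated `joint_data` object, the input to all fitting functions.
#'
#' The longitudinal table must contain columns `id`, `time` and `y`; the
#' survival table must contain `id`, `time` and `event`. Every remaining
#' column is treated as a baseline covariate, in file/column order.
#' Longitudinal covariates must be constant within subject (they are baseline
#' covariates measured once); the survival table has exactly one row per
#' subject, and both tables must cover exactly the same set of subjects.
#'
#' @param long Data frame of repeated measurements with columns `id`, `time`
#'   (non-negative), `y`, and zero or more numeric covariate columns.
#' @param surv Data frame with one row per subject: `id`, `time` (positive
#'   follow-up time), `event` (0 = censored, 1 = event), and zero or more
#'   numeric covariate columns.
#' @return An object of class `joint_data`: a list with tibbles `long` and
#'   `surv`, covariate name vectors `cov_l` and `cov_s`, subject ids `ids`
#'   (sorted) and the subject count `n`.
#' @examples
#' long <- data.frame(id = c(1, 1, 2), time = c(0, 1, 0), y = c(0.1, 0.9, 0.4),
#'                    x1 = c(1, 1, -1))
#' surv <- data.frame(id = c(1, 2), time = c(2, 1.5), event = c(1, 0),
#'                    w1 = c(0.3, -0.2))
#' jd <- joint_data(long, surv)
#' jd$n
#' @export
joint_data <- function(long, surv) {
  long <- tibble::as_tibble(long)
  surv <- tibble::as_tibble(surv)

  need_l <- c("id", "time", "y")
  need_s <- c("id", "time", "event")
  if (!all(need_l %in% names(long))) {
    abort(paste0("longitudinal table lacks required column(s): ",
                 paste(setdiff(need_l, names(long)), collapse = ", ")),
          class = "boostjm_schema_error")
  }
  if (!all(need_s %in% names(surv))) {
    abort(paste0("survival table lacks required column(s): ",
                 paste(setdiff(need_s, names(surv)), collapse = ", ")),
          class = "boostjm_schema_error")
  }
  cov_l <- setdiff(names(long), need_l)
  cov_s <- setdiff(names(surv), need_s)
  long <- long[, c(need_l, cov_l)]
  surv <- surv[, c(need_s, cov_s)]

  num_cols <- c(need_l, cov_l)
  for (cl in num_cols) {
    if (!is.numeric(long[[cl]])) {
      abort(paste0("longitudinal column '", cl, "' is not numeric"),
            class = "boostjm_parse_error")
    }
    if (any(!is.finite(long[[cl]]))) {
      abort(paste0("non-finite value in longitudinal column '", cl, "'"),
            class = "boostjm_parse_error")
    }
  }
  for (cl in c(need_s, cov_s)) {
    if (!is.numeric(surv[[cl]])) {
      abort(paste0("survival column '", cl, "' is not numeric"),
            class = "boostjm_parse_error")
    }
    if (any(!is.finite(surv[[cl]]))) {
      abort(paste0("non-finite value in survival column '", cl, "'"),
            class = "boostjm_parse_error")
    }
  }

  if (any(long$time < 0)) {
    abort("longitudinal times must be >= 0", class = "boostjm_consistency_error")
  }
  if (any(surv$time <= 0)) {
    abort("survival times must be > 0", class = "boostjm_consistency_error")
  }
  if (!all(surv$event %in% c(0, 1))) {
    abort("event indicator must be 0 or 1", class = "boostjm_consistency_error")
  }
  if (anyDuplicated(surv$id)) {
    abort("survival table must have exactly one row per subject",
          class = "boostjm_consistency_error")
  }
  ids <- sort(unique(surv$id))
  if (length(ids) < 1L) {
    abort("need at least one subject", class = "boostjm_consistency_error")
  }
  if (!setequal(ids, unique(long$id))) {
    abort("subject ids differ between longitudinal and survival tables",
          class = "boostjm_consistency_error")
  }
  # baseline covariates must not vary within subject
  if (length(cov_l) > 0L) {
    rng <- long |>
      dplyr::group_by(.data$id) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(cov_l),
                                     ~ max(.x) - min(.x)),
                       .groups = "drop")
    if (any(as.matrix(rng[, cov_l]) > 0)) {
      abort("longitudinal covariates must be constant within subject",
            class = "boostjm_consistency_error")
    }
  }

  structure(
    list(long = long,
         surv = surv[match(ids, surv$id), , drop = FALSE],
         cov_l = cov_l, cov_s = cov_s,
         ids = ids, n = length(ids)),
    class = "joint_data")
}

#' Read a joint dataset from delimited text files
#'
#' Reads the longitudinal and survival tables from CSV files and validates
#' them with [joint_data()]. Column conventions are documented there.
#'
#' @param long_path Path to the longitudinal CSV (`id`, `time`, `y`, covariates).
#' @param surv_path Path to the survival CSV (`id`, `time`, `event`, covariates).
#' @return A `joint_data` object.
#' @export
read_joint_data <- function(long_path, surv_path) {
  long <- readr::read_csv(long_path, show_col_types = FALSE, progress = FALSE)
  surv <- readr::read_csv(surv_path, show_col_types = FALSE, progress = FALSE)
  joint_data(long, surv)
}

#' @export
print.joint_data <- function(x, ...) {
  cat("<joint_data> ", x$n, " subjects, ", nrow(x$long), " longitudinal records\n",
      sep = "")
  cat("  longitudinal covariates (", length(x$cov_l), "): ",
      paste(head(x$cov_l, 8), collapse = ", "),
      if (length(x$cov_l) > 8) ", ..." else "", "\n", sep = "")
  cat("  survival covariates (", length(x$cov_s), "): ",
      paste(head(x$cov_s, 8), collapse = ", "),
      if (length(x$cov_s) > 8) ", ..." else "", "\n", sep = "")
  cat("  events: ", sum(x$surv$event), " / ", x$n, "\n", sep = "")
  invisible(x)
}

# Design matrices and index vectors used by the numerical core. Everything is
# aligned to `data$ids` order on the subject level.
jd_matrices <- function(data) {
  long <- data$long
  surv <- data$surv
  id_idx <- match(long$id, data$ids)
  Xl <- as.matrix(long[, data$cov_l, drop = FALSE])
  # subject-level covariate rows (constant within subject): first record wins
  first <- !duplicated(id_idx)
  Xl_sub <- matrix(0, data$n, length(data$cov_l),
                   dimnames = list(NULL, data$cov_l))
  if (length(data$cov_l)) Xl_sub[id_idx[first], ] <- Xl[first, , drop = FALSE]
  list(
    N = nrow(long), n = data$n, id_idx = id_idx,
    t = long$time, y = long$y,
    Xl = Xl, Xl_sub = Xl_sub,
    Ts = surv$time, delta = surv$event,
    Xs = as.matrix(surv[, data$cov_s, drop = FALSE])
  )
}

# center and scale every covariate column (estimates then refer to the
# standardized covariates)
standardize_joint <- function(data) {
  scale_cols <- function(tbl, cols) {
    for (cl in cols) {
      s <- sd(tbl[[cl]])
      tbl[[cl]] <- (tbl[[cl]] - mean(tbl[[cl]])) / if (s > 0) s else 1
    }
    tbl
  }
  long <- scale_cols(data$long, data$cov_l)
  # standardize survival covariates on the subject level
  surv <- scale_cols(data$surv, data$cov_s)
  # longitudinal covariates must stay subject-constant: scaling preserves that
  joint_data(long, surv)
}

# subset a joint_data by subject id (used by cross-validation folds)
jd_subset <- function(data, ids) {
  joint_data(data$long[data$long$id %in% ids, , drop = FALSE],
             data$surv[data$surv$id %in% ids, , drop = FALSE])
}
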