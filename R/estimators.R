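estimate_result <- function(method, estimate, se = NA_real_,
                            ci = c(NA_real_, NA_real_), level = 0.95,
                            retained_per_arm = c(NA_integer_, NA_integer_),
                            p_used = NA_real_, warnings = character(0)) {
  structure(list(method = method,
                 estimate = unname(estimate),
                 se = unname(se),
                 ci = unname(ci),
                 level = level,
                 retained_per_arm = unname(retained_per_arm),
                 p_used = p_used,
                 warnings = warnings),
            class = "tm_estimate")
}

#' @export
print.tm_estimate <- function(x, ...) {
  cat(sprintf("%s estimate of treatment effect: %.4f\n", x$method, x$estimate))
  if (is.finite(x$se)) cat(sprintf("  SE: %.4f\n", x$se))
  if (all(is.finite(x$ci))) {
    cat(sprintf("  %d%% CI: (%.4f, %.4f)\n", round(100 * x$level),
                x$ci[1], x$ci[2]))
  }
  if (is.finite(x$p_used)) cat(sprintf("  trimming fraction used: %.4g\n", x$p_used))
  if (!anyNA(x$retained_per_arm)) {
    cat(sprintf("  retained per arm: %d (comparator), %d (treatment)\n",
                x$retained_per_arm[1], x$retained_per_arm[2]))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

fit_arm_regression <- function(df, covariate_names, method) {
  fml <- stats::reformulate(c("arm", covariate_names), response = "y")
  fit <- stats::lm(fml, data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop(method, ": collinear covariate(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  s <- summary(fit)$coefficients
  list(estimate = cf[["arm"]], se = s["arm", "Std. Error"], fit = fit)
}

#' Complete-case treatment-effect estimate
#'
#' Ordinary least squares of the outcome on the arm indicator (plus optional
#' covariates) among rows with an observed outcome and observed values of all
#' named covariates. Without covariates the estimate is exactly the difference
#' of observed-case arm means.
#'
#' @param data A [trial_data] object.
#' @param covariate_names Character vector of covariate columns to adjust for
#'   (default none).
#' @param level Confidence level for the (model-based) interval.
#' @return A `"tm_estimate"` with method label `"CCA"`.
#' @examples
#' d <- trial_data(arm = rep(0:1, each = 2), y = c(1, 3, 4, 6))
#' cca_fit(d)$estimate  # 3
#' @export
cca_fit <- function(data, covariate_names = NULL, level = 0.95) {
  stopifnot(inherits(data, "trial_data"))
  check_covariates(data, covariate_names)
  keep <- !is.na(data$y)
  for (cv in covariate_names) keep <- keep & !is.na(data[[cv]])
  cc <- as.data.frame(data)[keep, , drop = FALSE]
  n_cc <- vapply(c(0, 1), function(j) sum(cc$arm == j), numeric(1))
  if (any(n_cc < 2)) {
    stop("complete-case analysis needs >= 2 complete cases per arm (found ",
         n_cc[1], " and ", n_cc[2], ")")
  }
  r <- fit_arm_regression(cc, covariate_names, "cca_fit")
  ci <- r$estimate + c(-1, 1) * stats::qt(1 - (1 - level) / 2, stats::df.residual(r$fit)) * r$se
  estimate_result("CCA", r$estimate, r$se, ci, level,
                  retained_per_arm = as.integer(n_cc))
}

check_covariates <- function(data, covariate_names) {
  if (is.null(covariate_names)) return(invisible(TRUE))
  absent <- setdiff(covariate_names, names(data))
  if (length(absent)) {
    stop("covariate column(s) not in dataset: ", paste(absent, collapse = ", "))
  }
  invisible(TRUE)
}

#' Trimmed-means treatment-effect estimate
#'
#' Trims the dataset per `spec` (see [tm_trim()]) and fits least squares of the
#' outcome on arm (plus optional covariates) over the retained rows. Without
#' covariates the estimate equals the difference of trimmed arm means. Retained
#' rows whose outcome is missing (possible only when the dropout count exceeds
#' the trimmed count, i.e. the strong MNAR assumption fails mechanically) are
#' excluded from the regression and a warning is attached to the result.
#'
#' @inheritParams cca_fit
#' @param spec A [trim_spec].
#' @param covariate_missing What to do when a named covariate is missing in
#'   retained rows: `"error"` (default; directs to [impute_covariate()]) or
#'   `"drop"` (complete-case within the trimmed data).
#' @return A `"tm_estimate"` with method label `"TM"`.
#' @examples
#' d <- trial_data(arm = rep(0:1, each = 4), y = c(1, 2, 3, 4, 2, 3, 4, 5))
#' tm_fit(d, trim_spec(0.5))$estimate  # 1
#' @export
tm_fit <- function(data, spec, covariate_names = NULL, level = 0.95,
                   covariate_missing = c("error", "drop")) {
  covariate_missing <- match.arg(covariate_missing)
  check_covariates(data, covariate_names)
  # data that already carries trim metadata (e.g. trimmed then imputed) is
  # used as-is rather than trimmed a second time
  if (!is.null(attr(data, "trim_info"))) {
    trimmed <- data
  } else {
    trimmed <- tm_trim(data, spec)
  }
  ti <- attr(trimmed, "trim_info")
  warnings <- character(0)
  df <- as.data.frame(trimmed)
  if (any(ti$n_missing_retained > 0)) {
    warnings <- c(warnings, sprintf(
      "strong MNAR assumption violated in-sample: %d retained row(s) with missing outcome excluded",
      sum(ti$n_missing_retained)))
    df <- df[!is.na(df$y), , drop = FALSE]
  }
  for (cv in covariate_names) {
    if (anyNA(df[[cv]])) {
      if (covariate_missing == "error") {
        stop("covariate '", cv, "' is missing in retained rows; impute it ",
             "after trimming with impute_covariate() or use covariate_missing = \"drop\"")
      }
      df <- df[!is.na(df[[cv]]), , drop = FALSE]
    }
  }
  r <- fit_arm_regression(df, covariate_names, "tm_fit")
  ci <- r$estimate + c(-1, 1) * stats::qt(1 - (1 - level) / 2, stats::df.residual(r$fit)) * r$se
  res <- estimate_result("TM", r$estimate, r$se, ci, level,
                         retained_per_arm = ti$retained, p_used = ti$p_used,
                         warnings = warnings)
  res$n_used <- nrow(df)
  res
}

#' Adjusted trimmed-means estimate (variance rescaling)
#'
#' Relaxes the location-shift assumption for 50% trimming of normal outcomes.
#' The retained half of the rescaled arm is treated as half-normal: it is
#' mirrored about the trim boundary, giving an artificial full normal centred
#' at the boundary with SD equal to the root-mean-square deviation of the
#' retained outcomes about the boundary. That artificial distribution is then
#' rescaled to the *other* arm's full-sample SD, which is taken directly from
#' the observed outcomes when that arm has no dropout and otherwise
#' extrapolated from its trimmed-fraction SD via sqrt(pi/(pi - 2)).
#'
#' @inheritParams tm_fit
#' @param rescale_arm Which arm to rescale: 0 (comparator) or 1 (treatment).
#'   Rescale the arm for which the strong MNAR assumption is most plausible.
#' @return A `"tm_estimate"` with method label `"TM-adjusted-0"` or
#'   `"TM-adjusted-1"`. The standard error is left `NA`; use
#'   [permutation_ci()] for inference.
#' @export
adjusted_tm_fit <- function(data, spec, rescale_arm = 0) {
  stopifnot(inherits(spec, "trim_spec"), rescale_arm %in% c(0, 1))
  if (spec$mode != "fixed" || abs(spec$fraction - 0.5) > 1e-12) {
    stop("the adjusted TM estimator is defined for fixed 50% trimming only (p = 0.5)")
  }
  trimmed <- tm_trim(data, spec)
  ti <- attr(trimmed, "trim_info")
  warnings <- character(0)
  if (any(ti$n_missing_retained > 0)) {
    warnings <- c(warnings, sprintf(
      "strong MNAR assumption violated in-sample: %d retained row(s) with missing outcome excluded",
      sum(ti$n_missing_retained)))
  }
  g <- rescale_arm
  o <- 1 - g
  y_tg <- trimmed$y[trimmed$arm == g]
  y_tg <- y_tg[!is.na(y_tg)]
  y_to <- trimmed$y[trimmed$arm == o]
  y_to <- y_to[!is.na(y_to)]
  if (length(y_tg) < 2 || length(y_to) < 2) {
    stop("each arm must retain at least 2 observed outcomes after trimming")
  }
  m_g <- ti$boundary[g + 1L]
  sigma_g <- sqrt(mean((y_tg - m_g)^2)) # SD of the mirrored artificial normal
  if (sigma_g < 1e-12) stop("zero trimmed-fraction SD in rescaled arm ", g)
  # other arm's full-sample SD: direct if fully observed, else half-normal extrapolation
  any_dropout_o <- anyNA(data$y[data$arm == o])
  sigma_o <- if (any_dropout_o) {
    s_to <- stats::sd(y_to)
    if (s_to < 1e-12) stop("zero trimmed-fraction SD in arm ", o)
    s_to * half_normal_sd_factor()$inverse
  } else {
    stats::sd(data$y[data$arm == o])
  }
  mu_at_g <- m_g + (mean(y_tg) - m_g) * sigma_o / sigma_g
  est <- if (g == 0) mean(y_to) - mu_at_g else mu_at_g - mean(y_to)
  res <- estimate_result(paste0("TM-adjusted-", g), est,
                         retained_per_arm = ti$retained, p_used = ti$p_used,
                         warnings = warnings)
  res$rescale_arm <- g
  res
}

fit_by_method <- function(data, spec, method, covariate_names, rescale_arm) {
  switch(method,
         cca = cca_fit(data, covariate_names),
         tm = suppressWarnings(tm_fit(data, spec, covariate_names,
                                      covariate_missing = "drop")),
         adjusted = adjusted_tm_fit(data, spec, rescale_arm),
         stop("unknown method: ", method))
}

#' Permutation-based standard error and confidence interval
#'
#' Permutes arm labels across all participants (missingness travelling with
#' its participant), re-runs the complete trim-and-fit pipeline on each
#' permutation, and forms a two-sided interval by shifting the observed
#' estimate by the quantiles of the permutation null distribution (a basic /
#' reflection interval). The SE is the SD of the null distribution. For fixed
#' trimming, a permutation in which an arm's dropout proportion exceeds the
#' specified fraction is trimmed at that permutation's minimum feasible
#' fraction instead.
#'
#' @inheritParams tm_fit
#' @param n_perm Number of permutations, >= 100.
#' @param seed Integer seed; identical seed gives identical output.
#' @param method `"tm"` (default), `"cca"`, or `"adjusted"`.
#' @param rescale_arm Passed to [adjusted_tm_fit()] when `method = "adjusted"`.
#' @return A list with `estimate`, `se`, `ci`, `level`, `n_perm`.
#' @export
permutation_ci <- function(data, spec, n_perm = 1000, seed = NULL,
                           level = 0.95, method = c("tm", "cca", "adjusted"),
                           covariate_names = NULL, rescale_arm = 0) {
  method <- match.arg(method)
  stopifnot(n_perm >= 100)
  if (!is.null(seed)) set.seed(seed)
  obs <- fit_by_method(data, spec, method, covariate_names, rescale_arm)
  null_est <- vapply(seq_len(n_perm), function(b) {
    perm <- data
    perm$arm <- sample(data$arm)
    spec_b <- spec
    if (spec$mode == "fixed") {
      p_min_b <- max(observed_dropout(perm))
      if (p_min_b > spec$fraction) spec_b <- trim_spec(p_min_b, spec$direction)
    }
    fit_by_method(perm, spec_b, method, covariate_names, rescale_arm)$estimate
  }, numeric(1))
  if (stats::sd(null_est) < 1e-12) {
    stop("degenerate permutation distribution: all permuted estimates identical")
  }
  alpha <- 1 - level
  q <- stats::quantile(null_est, c(1 - alpha / 2, alpha / 2), names = FALSE,
                       type = 8)
  list(estimate = obs$estimate,
       se = stats::sd(null_est),
       ci = c(obs$estimate - q[1], obs$estimate - q[2]),
       level = level,
       n_perm = n_perm)
}

#' Stochastic-regression imputation of a covariate
#'
#' Simple normal-linear stochastic regression imputation for a covariate that
#' is missing at random given the predictors, intended to be applied *after*
#' trimming. Each imputation fills missing covariate values with the fitted
#' conditional mean plus Gaussian noise at the residual SD. Point estimates
#' from downstream fits are pooled by averaging ([tm_fit_pooled()]).
#'
#' @param data A [trial_data], typically the output of [tm_trim()].
#' @param covariate Name of the covariate column to complete.
#' @param predictors Columns used as predictors (default arm and outcome).
#' @param n_imputations Number of completed datasets.
#' @param seed Integer seed for reproducibility.
#' @return If the covariate is fully observed, `data` unchanged. Otherwise a
#'   list of completed [trial_data] objects, class `"trial_imputations"`.
#' @export
impute_covariate <- function(data, covariate, predictors = c("arm", "y"),
                             n_imputations = 5, seed = NULL) {
  stopifnot(inherits(data, "trial_data"))
  check_covariates(data, covariate)
  if (!anyNA(data[[covariate]])) return(data)
  for (j in c(0, 1)) {
    if (!any(!is.na(data[[covariate]]) & data$arm == j)) {
      stop("no observed values of '", covariate, "' in arm ", j,
           "; cannot impute")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  df <- as.data.frame(data)
  obs <- stats::complete.cases(df[c(covariate, predictors)])
  fml <- stats::reformulate(predictors, response = covariate)
  fit <- stats::lm(fml, data = df[obs, , drop = FALSE])
  sig <- summary(fit)$sigma
  mis <- which(is.na(df[[covariate]]))
  if (anyNA(df[mis, predictors])) {
    stop("predictors must be observed wherever '", covariate, "' is missing")
  }
  mu <- stats::predict(fit, newdata = df[mis, , drop = FALSE])
  imps <- lapply(seq_len(n_imputations), function(m) {
    out <- data
    out[[covariate]][mis] <- mu + stats::rnorm(length(mis), sd = sig)
    out
  })
  structure(imps, class = "trial_imputations")
}

#' Pooled trimmed-means estimate over imputed datasets
#'
#' Fits [tm_fit()] on each completed dataset and pools: the point estimate is
#' the average of per-imputation estimates; the SE combines within- and
#' between-imputation variance (Rubin's rules).
#'
#' @param imputations A `"trial_imputations"` list from [impute_covariate()]
#'   (or a single [trial_data], in which case this is just [tm_fit()]).
#' @inheritParams tm_fit
#' @return A `"tm_estimate"` with method label `"TM-pooled"`.
#' @export
tm_fit_pooled <- function(imputations, spec, covariate_names = NULL,
                          level = 0.95) {
  if (inherits(imputations, "trial_data")) {
    return(tm_fit(imputations, spec, covariate_names, level))
  }
  stopifnot(inherits(imputations, "trial_imputations"))
  fits <- lapply(imputations, tm_fit, spec = spec,
                 covariate_names = covariate_names, level = level)
  est <- vapply(fits, `[[`, numeric(1), "estimate")
  se2 <- vapply(fits, `[[`, numeric(1), "se")^2
  m <- length(fits)
  within <- mean(se2)
  between <- if (m > 1) stats::var(est) else 0
  total_se <- sqrt(within + (1 + 1 / m) * between)
  pooled <- mean(est)
  z <- stats::qnorm(1 - (1 - level) / 2)
  res <- estimate_result("TM-pooled", pooled, total_se,
                         pooled + c(-1, 1) * z * total_se, level,
                         retained_per_arm = fits[[1]]$retained_per_arm,
                         p_used = fits[[1]]$p_used,
                         warnings = unique(unlist(lapply(fits, `[[`, "warnings"))))
  res$n_imputations <- m
  res
}

#' Write an estimate to JSON and/or a flat text report
#'
#' @param result A `"tm_estimate"` (or a named list of them).
#' @param json_path Optional path for a machine-readable JSON document.
#' @param text_path Optional path for a flat key-value text report.
#' @return `result`, invisibly.
#' @export
write_results <- function(result, json_path = NULL, text_path = NULL) {
  results <- if (inherits(result, "tm_estimate")) list(result) else result
  payload <- lapply(results, function(r) {
    list(method = r$method, estimate = r$estimate, se = r$se,
         ci = r$ci, level = r$level, p_used = r$p_used,
         retained_per_arm = r$retained_per_arm, warnings = r$warnings)
  })
  if (!is.null(json_path)) {
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  if (!is.null(text_path)) {
    lines <- unlist(lapply(payload, function(p) c(
      paste0("method: ", p$method),
      paste0("estimate: ", format(p$estimate, digits = 10)),
      paste0("se: ", format(p$se, digits = 10)),
      paste0("ci: ", paste(format(p$ci, digits = 10), collapse = ", ")),
      paste0("p_used: ", format(p$p_used, digits = 10)),
      paste0("retained_per_arm: ", paste(p$retained_per_arm, collapse = ", ")),
      if (length(p$warnings)) paste0("warning: ", p$warnings) else NULL,
      "")))
    writeLines(lines, text_path)
  }
  invisible(result)
}
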