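#' Crude prevalence ratio from 2x2 cell counts
#'
#' Direct arithmetic oracle for the regression-based estimators:
#' the ratio of outcome prevalence among the exposed, `a / (a + b)`, to
#' prevalence among the unexposed, `c / (c + d)`.
#'
#' @param a,b Counts with/without the outcome among the exposed.
#' @param c,d Counts with/without the outcome among the unexposed.
#' @return The crude prevalence ratio.
#' @examples
#' crude_pr(107, 78, 818, 2587)
#' @export
crude_pr <- function(a, b, c, d) {
  stopifnot(all(c(a, b, c, d) >= 0))
  if (a + b <= 0 || c + d <= 0) abort("empty exposure group")
  if (c == 0) abort("undefined ratio: zero reference risk")
  (a / (a + b)) / (c / (c + d))
}

#' Wald confidence interval for a ratio estimated on the log scale
#'
#' @param log_estimate Point estimate on the log scale.
#' @param log_se Standard error of the log estimate (> 0).
#' @param level Confidence level in (0, 1).
#' @return Numeric vector `c(low, high)` on the ratio scale.
#' @examples
#' wald_interval(0, 0.1, 0.95)
#' @export
wald_interval <- function(log_estimate, log_se, level = 0.95) {
  stopifnot(log_se > 0, level > 0, level < 1)
  z <- qnorm((1 + level) / 2)
  exp(log_estimate + c(-1, 1) * z * log_se)
}

#' Fit an adjusted prevalence-ratio model
#'
#' Estimates prevalence ratios by a log-link binomial GLM, whose
#' coefficients exponentiate directly to PRs. Log-binomial fits are known
#' to fail to converge when fitted risks approach 1; when that happens the
#' model is automatically refit as a log-link Poisson ("modified Poisson")
#' with a robust sandwich variance, and the result is tagged accordingly.
#' Starting values for the log-binomial fit come from the Poisson fit.
#'
#' @param data Data frame of analysis records (see
#'   [build_analysis_table()]).
#' @param outcome Name of the binary outcome column.
#' @param exposure Name of the exposure column (binary 0/1 or a factor
#'   whose first level is the reference).
#' @param covariates Character vector of adjustment columns (default
#'   none).
#' @param weights Optional name of a positive weight column, honored as
#'   frequency weights.
#' @param ci_level Confidence level for Wald intervals (default 0.95).
#' @param method `"auto"` (log-binomial with modified-Poisson fallback),
#'   or force `"log-binomial"` / `"modified-poisson"`.
#' @return A `pr_fit` object; use [tidy()] for the per-level PR table and
#'   [glance()] for the fit summary. The full coefficient vector and
#'   variance matrix are retained for delta-method use.
#' @examples
#' cfg <- sim_config(n = c("30-44" = 2000), seed = 3)
#' d <- generate_records(cfg, raw = FALSE)
#' fit <- fit_pr_model(d, "outcome01", "stress01",
#'                     covariates = c("sex", "education"))
#' tidy(fit)
#' @export
fit_pr_model <- function(data, outcome, exposure, covariates = NULL,
                         weights = NULL, ci_level = 0.95,
                         method = c("auto", "log-binomial",
                                    "modified-poisson")) {
  method <- arg_match(method)
  data <- as_tibble(data)
  stopifnot(ci_level > 0, ci_level < 1)
  for (v in c(outcome, exposure, covariates, weights)) {
    if (!v %in% names(data)) abort(paste0("column not found: ", v))
  }
  if (outcome %in% c(exposure, covariates)) {
    abort("outcome must not appear among the regressors")
  }

  y <- data[[outcome]]
  check_binary(y, outcome)
  if (length(unique(y)) < 2L) abort("degenerate outcome: no variation")
  x <- data[[exposure]]
  if (length(unique(x[!is.na(x)])) < 2L) {
    abort(paste0("degenerate exposure: '", exposure, "' has no variation"))
  }

  f <- reformulate(c(exposure, covariates), response = outcome)
  w <- if (is.null(weights)) NULL else data[[weights]]

  fit_env <- list2env(list(.formula = f, .data = data, .w = w))
  environment(f) <- fit_env
  fit_env$.formula <- f
  pois <- eval(
    quote(glm(.formula, family = poisson(link = "log"), data = .data,
              weights = .w)),
    envir = fit_env
  )

  fitted_method <- "modified-poisson"
  converged <- FALSE
  model <- NULL
  if (method != "modified-poisson") {
    fit_env$.start <- coef(pois)
    lb <- tryCatch(
      suppressWarnings(eval(
        quote(glm(.formula, family = binomial(link = "log"), data = .data,
                  weights = .w, start = .start,
                  control = glm.control(epsilon = 1e-8, maxit = 100))),
        envir = fit_env
      )),
      error = function(e) NULL
    )
    at_bound <- !is.null(lb) && any(lb$fitted.values >= 1 - 1e-8)
    if (!is.null(lb) && lb$converged && !at_bound) {
      model <- lb
      fitted_method <- "log-binomial"
      converged <- TRUE
    } else if (method == "log-binomial") {
      abort("log-binomial fit failed to converge; use method = 'auto' for the modified-Poisson fallback")
    } else if (method == "auto" && (is.null(lb) || !lb$converged || at_bound)) {
      warn("log-binomial fit did not converge cleanly; falling back to modified Poisson with robust variance")
    }
  }
  if (is.null(model)) {
    model <- pois
    fitted_method <- "modified-poisson"
    converged <- pois$converged
  }

  vc <- if (fitted_method == "modified-poisson") {
    sandwich::vcovHC(model, type = "HC0")
  } else {
    vcov(model)
  }

  structure(
    list(
      model = model,
      coef = coef(model),
      vcov = vc,
      n = nrow(data),
      method = fitted_method,
      converged = converged || fitted_method == "log-binomial",
      ci_level = ci_level,
      outcome = outcome,
      exposure = exposure,
      covariates = covariates %||% character()
    ),
    class = "pr_fit"
  )
}

exposure_term_names <- function(fit) {
  x <- fit$model$model[[fit$exposure]]
  if (is.factor(x)) {
    paste0(fit$exposure, levels(x)[-1])
  } else {
    fit$exposure
  }
}

#' @export
print.pr_fit <- function(x, ...) {
  cat("<pr_fit> ", x$outcome, " ~ ", x$exposure,
      if (length(x$covariates)) paste0(" + ", paste(x$covariates, collapse = " + ")),
      "\n  method: ", x$method, " (converged: ", x$converged, "), n = ", x$n,
      "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy a prevalence-ratio fit
#'
#' @param x A `pr_fit` object.
#' @param all_terms Include covariate terms as well as exposure terms?
#' @param ... Unused.
#' @return Tibble with one row per model term: `term`, `pr`, `ci_low`,
#'   `ci_high`, `log_se`, `n`, `method`, `converged`.
#' @export
tidy.pr_fit <- function(x, all_terms = FALSE, ...) {
  terms <- if (all_terms) {
    setdiff(names(x$coef), "(Intercept)")
  } else {
    exposure_term_names(x)
  }
  z <- qnorm((1 + x$ci_level) / 2)
  est <- x$coef[terms]
  se <- sqrt(diag(x$vcov)[terms])
  tibble(
    term = terms,
    pr = exp(unname(est)),
    ci_low = exp(unname(est) - z * unname(se)),
    ci_high = exp(unname(est) + z * unname(se)),
    log_se = unname(se),
    n = x$n,
    method = x$method,
    converged = x$converged
  )
}

#' One-line summary of a prevalence-ratio fit
#'
#' @param x A `pr_fit` object.
#' @param ... Unused.
#' @return One-row tibble: `n`, `method`, `converged`, `deviance`,
#'   `df_residual`, `ci_level`.
#' @export
glance.pr_fit <- function(x, ...) {
  tibble(
    n = x$n,
    method = x$method,
    converged = x$converged,
    deviance = x$model$deviance,
    df_residual = x$model$df.residual,
    ci_level = x$ci_level
  )
}
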