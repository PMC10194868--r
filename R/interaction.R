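#' Joint exposure category for a stress x low-capital pair
#'
#' Codes the four cells of the 2x2 joint exposure with a shared reference:
#' `ref` = low stress & high capital (0,0), `s10` = high stress only,
#' `s01` = low capital only, `s11` = both. Using one four-level factor per
#' stratum means the three non-reference prevalence ratios share a single
#' reference cell, which the additive interaction contrast requires.
#'
#' @param stress01 Binary high-stress indicator.
#' @param lowcap01 Binary low-capital indicator.
#' @return Factor with levels `ref`, `s10`, `s01`, `s11`.
#' @export
joint_category <- function(stress01, lowcap01) {
  check_binary(stress01, "stress01")
  check_binary(lowcap01, "lowcap01")
  code <- dplyr::case_when(
    stress01 == 0 & lowcap01 == 0 ~ "ref",
    stress01 == 1 & lowcap01 == 0 ~ "s10",
    stress01 == 0 & lowcap01 == 1 ~ "s01",
    stress01 == 1 & lowcap01 == 1 ~ "s11"
  )
  factor(code, levels = c("ref", "s10", "s01", "s11"))
}

#' Relative excess risk due to interaction
#'
#' RERI = PR11 - PR10 - PR01 + 1, the departure of the joint effect from
#' additivity of the two separate effects on the prevalence-ratio scale.
#' Zero means exact additivity; a positive value means the doubly exposed
#' group carries more risk than the sum of the single exposures.
#'
#' @param pr11 PR in the doubly exposed cell (both exposures).
#' @param pr10 PR for the first exposure alone.
#' @param pr01 PR for the second exposure alone.
#' @return The RERI (vectorized).
#' @examples
#' reri(1.79, 1.31, 1.26)
#' @export
reri <- function(pr11, pr10, pr01) {
  stopifnot(all(pr11 > 0), all(pr10 > 0), all(pr01 > 0))
  pr11 - pr10 - pr01 + 1
}

#' Attributable proportion due to interaction
#'
#' AP = RERI / PR11: the proportion of the outcome prevalence in the
#' doubly exposed group attributable to the interaction of the two
#' exposures. Following the published convention, a negative RERI yields
#' the sentinel `NA` (rendered as "N/A") rather than a negative
#' proportion.
#'
#' @param reri_val RERI value(s).
#' @param pr11 PR in the doubly exposed cell (> 0).
#' @return Proportion in `[0, 1]`, or `NA` when `reri_val < 0`
#'   (vectorized). Use [format_ap()] for the percent rendering.
#' @examples
#' attributable_proportion(0.22, 1.79)
#' attributable_proportion(-0.11, 1.50)
#' @export
attributable_proportion <- function(reri_val, pr11) {
  stopifnot(all(pr11 > 0))
  dplyr::if_else(reri_val >= 0, reri_val / pr11, NA_real_)
}

#' Format an attributable proportion as a percent string
#'
#' @param ap Proportion from [attributable_proportion()] (`NA` allowed).
#' @param digits Decimal places of the percent (default 1).
#' @return Character vector like `"12.3%"`, with `"N/A"` for `NA`.
#' @export
format_ap <- function(ap, digits = 1) {
  dplyr::if_else(is.na(ap), "N/A",
                 paste0(formatC(100 * ap, format = "f", digits = digits), "%"))
}

#' Adjusted joint-exposure prevalence ratios within an age stratum
#'
#' Fits a single model of the outcome on the four-level joint stress x
#' low-capital category, adjusted for covariates and restricted to one age
#' stratum, so PR10, PR01 and PR11 share the (low stress, high capital)
#' reference cell. The log-scale coefficient triple and its covariance
#' are retained for the delta-method RERI interval.
#'
#' @param data Analysis table (see [build_analysis_table()]).
#' @param modifier Name of the binary low-capital indicator column.
#' @param stratum Age-stratum label, or `NULL` to use all rows.
#' @param covariates Adjustment columns (default sex, education, country
#'   of birth, as in the published stratified tables).
#' @param ci_level Confidence level (default 0.95).
#' @param method Passed to [fit_pr_model()].
#' @return A `joint_prs` object: `tidy()` gives one row per non-reference
#'   cell; attributes carry the coefficient triple, covariance, cell
#'   counts, n and method.
#' @export
joint_prs <- function(data, modifier, stratum = NULL,
                      covariates = c("sex", "education", "country_of_birth"),
                      ci_level = 0.95, method = "auto") {
  data <- as_tibble(data)
  if (!modifier %in% names(data)) {
    abort(paste0("modifier column not found: ", modifier))
  }
  sub <- restrict_stratum(data, stratum)
  sub$joint <- joint_category(sub$stress01, sub[[modifier]])

  counts <- dplyr::count(sub, .data$joint, .drop = FALSE)
  empty <- as.character(counts$joint[counts$n == 0L])
  if (length(empty) > 0L) {
    abort(paste0("empty joint exposure cell(s) in stratum '",
                 stratum %||% "all", "': ", paste(empty, collapse = ", ")))
  }

  fit <- fit_pr_model(sub, "outcome01", "joint", covariates = covariates,
                      ci_level = ci_level, method = method)
  terms <- paste0("joint", c("s10", "s01", "s11"))
  coef3 <- setNames(fit$coef[terms], c("s10", "s01", "s11"))
  vcov3 <- fit$vcov[terms, terms]
  dimnames(vcov3) <- list(names(coef3), names(coef3))

  cell_tab <- sub |>
    group_by(.data$joint) |>
    summarise(n_with = sum(.data$outcome01 == 1L),
              n_without = sum(.data$outcome01 == 0L), .groups = "drop")

  structure(
    list(
      fit = fit,
      coef = coef3,
      vcov = vcov3,
      cells = cell_tab,
      modifier = modifier,
      stratum = stratum,
      n = nrow(sub),
      ci_level = ci_level
    ),
    class = "joint_prs"
  )
}

restrict_stratum <- function(data, stratum) {
  if (is.null(stratum)) return(data)
  if (!"age_stratum" %in% names(data)) abort("no 'age_stratum' column")
  sub <- filter(data, .data$age_stratum == stratum)
  if (nrow(sub) == 0L) abort(paste0("no records in age stratum '", stratum, "'"))
  sub
}

#' @export
print.joint_prs <- function(x, ...) {
  cat("<joint_prs> modifier = ", x$modifier,
      ", stratum = ", x$stratum %||% "all",
      ", n = ", x$n, ", method = ", x$fit$method, "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy joint-exposure prevalence ratios
#'
#' @param x A `joint_prs` object.
#' @param ... Unused.
#' @return Tibble with one row per non-reference joint cell (`s10`,
#'   `s01`, `s11`): `cell`, `pr`, `ci_low`, `ci_high`, `log_se`, cell
#'   counts with/without the outcome, `n`, `method`.
#' @export
tidy.joint_prs <- function(x, ...) {
  td <- tidy(x$fit)
  td$cell <- sub("^joint", "", td$term)
  cells <- x$cells
  cells$cell <- as.character(cells$joint)
  td |>
    left_join(select(cells, "cell", "n_with", "n_without"), by = "cell") |>
    select("cell", "pr", "ci_low", "ci_high", "log_se",
           "n_with", "n_without", "n", "method")
}

#' Stress prevalence ratios within strata of a capital indicator
#'
#' Fits the stress-outcome prevalence ratio separately among respondents
#' with high capital (`modifier == 0`) and low capital (`modifier == 1`),
#' each adjusted for the covariates, within one age stratum. These are
#' the "PR within strata of capital" columns of a Knol-VanderWeele
#' presentation.
#'
#' @inheritParams joint_prs
#' @return Tibble with two rows (`capital = "high"`, `"low"`): `pr`,
#'   `ci_low`, `ci_high`, `log_se`, `n`, `method`.
#' @export
stress_pr_within_strata <- function(data, modifier, stratum = NULL,
                                    covariates = c("sex", "education",
                                                   "country_of_birth"),
                                    ci_level = 0.95, method = "auto") {
  data <- as_tibble(data)
  if (!modifier %in% names(data)) {
    abort(paste0("modifier column not found: ", modifier))
  }
  sub <- restrict_stratum(data, stratum)
  if (length(unique(sub[[modifier]])) < 2L) {
    abort(paste0("modifier '", modifier, "' has no variation in stratum '",
                 stratum %||% "all", "'"))
  }
  one <- function(side, label) {
    d <- filter(sub, .data[[modifier]] == side)
    fit <- fit_pr_model(d, "outcome01", "stress01", covariates = covariates,
                        ci_level = ci_level, method = method)
    mutate(tidy(fit), capital = label, .before = 1)
  }
  bind_rows(one(0L, "high"), one(1L, "low")) |>
    select("capital", "pr", "ci_low", "ci_high", "log_se", "n", "method")
}

#' Delta-method confidence interval for the RERI
#'
#' Propagates the covariance of the three log-scale joint-exposure
#' coefficients through RERI = exp(g11) - exp(g10) - exp(g01) + 1. The
#' gradient is (-exp(g10), -exp(g01), exp(g11)) in the (s10, s01, s11)
#' coefficient order. The published analysis reports no RERI interval;
#' this (and the bootstrap in [reri_boot_ci()]) is an extension of the
#' point estimator.
#'
#' @param coefficients Named log-scale coefficient triple
#'   `c(s10 = , s01 = , s11 = )`, or a `joint_prs` object.
#' @param covariance 3x3 covariance matrix of the triple (ignored when a
#'   `joint_prs` is supplied).
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(low, high)` with attributes `reri` (point
#'   estimate) and `se`.
#' @export
reri_delta_ci <- function(coefficients, covariance = NULL, level = 0.95) {
  if (inherits(coefficients, "joint_prs")) {
    covariance <- coefficients$vcov
    coefficients <- coefficients$coef
  }
  stopifnot(length(coefficients) == 3L, is.matrix(covariance),
            all(dim(covariance) == 3L), level > 0, level < 1)
  co <- align_triple(coefficients)
  covariance <- align_vcov(covariance)
  if (max(abs(covariance - t(covariance))) > 1e-8) {
    abort("covariance matrix must be symmetric")
  }
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    abort("covariance matrix must be positive semi-definite")
  }
  point <- reri(exp(co["s11"]), exp(co["s10"]), exp(co["s01"]))
  grad <- c(s10 = -exp(unname(co["s10"])),
            s01 = -exp(unname(co["s01"])),
            s11 = exp(unname(co["s11"])))
  se <- sqrt(drop(t(grad) %*% covariance %*% grad))
  z <- qnorm((1 + level) / 2)
  structure(unname(point) + c(-1, 1) * z * se,
            reri = unname(point), se = se)
}

align_triple <- function(x) {
  nm <- c("s10", "s01", "s11")
  if (!is.null(names(x)) && all(nm %in% names(x))) x[nm] else setNames(x, nm)
}

align_vcov <- function(v) {
  nm <- c("s10", "s01", "s11")
  if (!is.null(dimnames(v)) && all(nm %in% rownames(v)) &&
      all(nm %in% colnames(v))) {
    v[nm, nm]
  } else {
    dimnames(v) <- list(nm, nm)
    v
  }
}

#' Percentile-bootstrap confidence interval for the RERI
#'
#' Resamples records with replacement within the stratum, refits the
#' joint-exposure model and takes percentile limits of the replicate RERI
#' distribution. Seeded for reproducibility.
#'
#' @inheritParams joint_prs
#' @param B Number of bootstrap replicates (default 999).
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return Numeric `c(low, high)` with attributes `reri` (point estimate
#'   from the original fit), `replicates` (the replicate values) and
#'   `n_failed` (replicates where the refit failed).
#' @export
reri_boot_ci <- function(data, modifier, stratum = NULL,
                         covariates = c("sex", "education",
                                        "country_of_birth"),
                         B = 999, seed = 1, level = 0.95, method = "auto") {
  data <- as_tibble(data)
  sub <- restrict_stratum(data, stratum)
  base <- joint_prs(sub, modifier, stratum = NULL, covariates = covariates,
                    method = method)
  point <- attr(reri_delta_ci(base, level = level), "reri")
  reps <- withr::with_seed(seed, {
    vapply(seq_len(B), function(i) {
      idx <- sample.int(nrow(sub), replace = TRUE)
      jp <- tryCatch(
        suppressWarnings(joint_prs(sub[idx, , drop = FALSE], modifier,
                                   stratum = NULL, covariates = covariates,
                                   method = method)),
        error = function(e) NULL
      )
      if (is.null(jp)) return(NA_real_)
      reri(exp(jp$coef[["s11"]]), exp(jp$coef[["s10"]]),
           exp(jp$coef[["s01"]]))
    }, numeric(1))
  })
  ok <- reps[!is.na(reps)]
  if (length(ok) < 2L) abort("bootstrap failed: too few successful replicates")
  alpha <- (1 - level) / 2
  ci <- unname(quantile(ok, c(alpha, 1 - alpha), type = 7))
  structure(ci, reri = point, replicates = reps,
            n_failed = sum(is.na(reps)))
}
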