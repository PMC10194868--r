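#' Effect-measure-modification analysis over modifiers and age strata
#'
#' Runs the full additive-interaction workup for every combination of
#' capital indicator and age stratum: the joint-exposure prevalence
#' ratios from one four-level model per stratum ([joint_prs()]), the
#' stress PRs within the high- and low-capital subsets
#' ([stress_pr_within_strata()]), the RERI with a confidence interval,
#' and the attributable proportion. Output rows are ordered by modifier
#' (in the order given) and then stratum.
#'
#' @param data Analysis table (see [build_analysis_table()]).
#' @param modifiers Character vector of binary low-capital indicator
#'   columns (default all five, [modifier_names()]).
#' @param strata Age-stratum labels (default: the levels present in
#'   `data$age_stratum`).
#' @param covariates Adjustment columns (default sex, education, country
#'   of birth).
#' @param ci_level Confidence level (default 0.95).
#' @param rounding `"full"` computes RERI and AP from the unrounded PR
#'   estimates; `"as-published"` computes them from PRs rounded to 2
#'   decimals, matching the arithmetic shown in published tables.
#' @param ci_method `"delta"` (default) or `"bootstrap"` for the RERI
#'   interval.
#' @param boot_B,seed Bootstrap replicates and seed (used when
#'   `ci_method = "bootstrap"`).
#' @param method Passed to [fit_pr_model()].
#' @return An `emm_tbl` tibble: one row per (modifier, stratum) with the
#'   joint-cell counts and PRs, within-capital stress PRs, `reri`,
#'   `reri_low`, `reri_high`, `ap`, `n` and `method`.
#' @examples
#' cfg <- sim_config(n = c("30-44" = 4000), seed = 9)
#' d <- generate_records(cfg, raw = FALSE)
#' emm_analysis(d, modifiers = "low_belonging", strata = "30-44")
#' @export
emm_analysis <- function(data, modifiers = modifier_names(), strata = NULL,
                         covariates = c("sex", "education",
                                        "country_of_birth"),
                         ci_level = 0.95,
                         rounding = c("full", "as-published"),
                         ci_method = c("delta", "bootstrap"),
                         boot_B = 999, seed = 1, method = "auto") {
  rounding <- arg_match(rounding)
  ci_method <- arg_match(ci_method)
  data <- as_tibble(data)
  if (length(modifiers) == 0L) {
    return(new_emm_tbl(tibble(), ci_level, rounding))
  }
  if (is.null(strata)) {
    strata <- if ("age_stratum" %in% names(data)) {
      as.character(sort(unique(data$age_stratum)))
    } else {
      abort("supply 'strata' or an 'age_stratum' column")
    }
  }

  grid <- tidyr::expand_grid(modifier = modifiers, stratum = strata)
  rows <- pmap(grid, function(modifier, stratum) {
    withCallingHandlers(
      emm_one(data, modifier, stratum, covariates, ci_level, rounding,
              ci_method, boot_B, seed, method),
      error = function(e) {
        abort(paste0("EMM analysis failed for modifier '", modifier,
                     "', stratum '", stratum, "'"), parent = e)
      }
    )
  })
  new_emm_tbl(bind_rows(rows), ci_level, rounding)
}

new_emm_tbl <- function(x, ci_level, rounding) {
  structure(as_tibble(x), class = c("emm_tbl", class(as_tibble(x))),
            ci_level = ci_level, rounding = rounding)
}

emm_one <- function(data, modifier, stratum, covariates, ci_level, rounding,
                    ci_method, boot_B, seed, method) {
  jp <- joint_prs(data, modifier, stratum, covariates, ci_level, method)
  within <- stress_pr_within_strata(data, modifier, stratum, covariates,
                                    ci_level, method)
  td <- tidy(jp)
  get <- function(cell, col) td[[col]][td$cell == cell]
  ref <- jp$cells[jp$cells$joint == "ref", ]

  pr <- c(s10 = get("s10", "pr"), s01 = get("s01", "pr"),
          s11 = get("s11", "pr"))
  pr_used <- if (rounding == "as-published") round(pr, 2) else pr
  reri_val <- reri(pr_used[["s11"]], pr_used[["s10"]], pr_used[["s01"]])
  ap_val <- attributable_proportion(reri_val, pr_used[["s11"]])

  ci <- if (ci_method == "delta") {
    reri_delta_ci(jp, level = ci_level)
  } else {
    reri_boot_ci(restrict_stratum(data, stratum), modifier,
                 covariates = covariates, B = boot_B, seed = seed,
                 level = ci_level, method = method)
  }

  hi <- within[within$capital == "high", ]
  lo <- within[within$capital == "low", ]

  tibble(
    modifier = modifier,
    age_stratum = stratum,
    ref_with = ref$n_with, ref_without = ref$n_without,
    s10_with = get("s10", "n_with"), s10_without = get("s10", "n_without"),
    s01_with = get("s01", "n_with"), s01_without = get("s01", "n_without"),
    s11_with = get("s11", "n_with"), s11_without = get("s11", "n_without"),
    pr10 = pr[["s10"]],
    pr10_low = get("s10", "ci_low"), pr10_high = get("s10", "ci_high"),
    pr01 = pr[["s01"]],
    pr01_low = get("s01", "ci_low"), pr01_high = get("s01", "ci_high"),
    pr11 = pr[["s11"]],
    pr11_low = get("s11", "ci_low"), pr11_high = get("s11", "ci_high"),
    pr_stress_high_capital = hi$pr,
    pr_stress_high_capital_low = hi$ci_low,
    pr_stress_high_capital_high = hi$ci_high,
    pr_stress_low_capital = lo$pr,
    pr_stress_low_capital_low = lo$ci_low,
    pr_stress_low_capital_high = lo$ci_high,
    reri = unname(reri_val),
    reri_low = ci[[1]], reri_high = ci[[2]],
    ap = unname(ap_val),
    n = jp$n,
    method = jp$fit$method
  )
}

#' Plot an EMM analysis as a forest of joint-exposure PRs and RERIs
#'
#' Two panels: the three joint-exposure prevalence ratios (with the
#' reference cell at PR = 1) per modifier and age stratum, and the RERI
#' with its interval. Dashed guides mark PR = 1 and RERI = 0.
#'
#' @param object An `emm_tbl` from [emm_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.emm_tbl <- function(object, ...) {
  if (nrow(object) == 0L) abort("empty EMM table")
  prs <- object |>
    select("modifier", "age_stratum",
           dplyr::matches("^pr(10|01|11)(_low|_high)?$")) |>
    tidyr::pivot_longer(-c("modifier", "age_stratum"),
                        names_to = c("cell", "bound"),
                        names_pattern = "pr(10|01|11)(?:_(low|high))?",
                        values_to = "value") |>
    mutate(bound = dplyr::coalesce(.data$bound, "pr")) |>
    tidyr::pivot_wider(names_from = "bound", values_from = "value") |>
    mutate(cell = factor(paste0("PR", .data$cell),
                         levels = c("PR10", "PR01", "PR11")))
  ggplot2::ggplot(prs, ggplot2::aes(x = .data$age_stratum,
                                    y = .data$pr,
                                    colour = .data$cell)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$low,
                                          ymax = .data$high),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~modifier) +
    ggplot2::labs(x = "age stratum", y = "prevalence ratio",
                  colour = "joint cell")
}

#' Plot RERI estimates with intervals per modifier and age stratum
#'
#' @param emm An `emm_tbl` from [emm_analysis()].
#' @return A ggplot object.
#' @export
plot_reri <- function(emm) {
  if (nrow(emm) == 0L) abort("empty EMM table")
  ggplot2::ggplot(emm, ggplot2::aes(x = .data$age_stratum, y = .data$reri)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$reri_low,
                                          ymax = .data$reri_high)) +
    ggplot2::facet_wrap(~modifier) +
    ggplot2::labs(x = "age stratum", y = "RERI")
}
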