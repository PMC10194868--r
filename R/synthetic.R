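canonical_strata <- c("30-44", "45-59", "60-74")

# Per-stratum default truth and baseline risks for the paper-mirroring
# scenario: joint PRs echo the published sense-of-belonging blocks and the
# baseline (reference-cell) risks echo the reconstructed reference-cell
# prevalences.
default_truth_pr <- list(
  "30-44" = c(pr10 = 1.31, pr01 = 1.30, pr11 = 1.57),
  "45-59" = c(pr10 = 1.31, pr01 = 1.26, pr11 = 1.79),
  "60-74" = c(pr10 = 1.65, pr01 = 1.40, pr11 = 2.36)
)
default_base_risk <- c("30-44" = 0.340, "45-59" = 0.308, "60-74" = 0.240)

default_modifier_margins <- c(
  low_belonging = 0.291, living_alone = 0.302, low_income = 0.221,
  no_insurance = 0.341, renter = 0.231
)

default_covariate_dists <- function() {
  list(
    sex = c(male = 0.48, female = 0.52),
    education = c("less than secondary" = 0.066, "secondary" = 0.168,
                  "post-secondary" = 0.766),
    country_of_birth = c(Canada = 0.77, other = 0.23)
  )
}

default_covariate_coefs <- function() {
  list(
    sex = c(male = 0, female = log(1.05)),
    education = c("less than secondary" = log(1.12),
                  "secondary" = log(1.05), "post-secondary" = 0),
    country_of_birth = c(Canada = 0, other = log(1.05))
  )
}

#' Specify a synthetic cross-sectional survey population
#'
#' Defines a CCHS-like population with fully known truth: per age
#' stratum, the 2x2 stress x low-capital cell probabilities, categorical
#' covariate distributions, and a log-risk outcome model
#' `log P(outcome) = b0 + b_s stress + b_m lowcap + b_sm stress*lowcap +
#' covariate terms`. Because the link is logarithmic and no
#' covariate-exposure interaction is modelled, the true adjusted
#' prevalence ratios are closed-form: PR10 = exp(b_s), PR01 = exp(b_m),
#' PR11 = exp(b_s + b_m + b_sm) (see [truth_from_config()]).
#'
#' Defaults mirror the published study: three age strata of 8,587, 8,412
#' and 5,730 respondents; a 22.2% high-stress margin and per-indicator
#' low-capital margins from the published sample description; per-stratum
#' joint PRs echoing the sense-of-belonging blocks; baseline risks from
#' the reconstructed reference cells. The configuration is validated by
#' enumerating the finite covariate space: every reachable risk must
#' satisfy `exp(linear predictor) <= 1`, and an out-of-bound
#' configuration is an error, never silently clipped.
#'
#' @param n Named integer vector: records per age stratum.
#' @param modifier Which low-capital indicator carries the interaction
#'   (one of [modifier_names()]).
#' @param stress_margin Marginal probability of high stress (used when
#'   `cell_probs` is not given).
#' @param modifier_margin Marginal probability of the focal low-capital
#'   indicator; defaults to the indicator's published margin.
#' @param cell_probs Optional probabilities of the four joint cells, a
#'   numeric vector named `ref`, `s10`, `s01`, `s11` summing to 1
#'   (default: independent product of the two margins).
#' @param b0,b_s,b_m,b_sm Log-risk intercept and coefficients, each a
#'   scalar or a vector named by stratum. Defaults: per-stratum values of
#'   the paper-mirroring scenario (available for the canonical strata
#'   only).
#' @param covariate_dists,covariate_coefs Named lists (sex, education,
#'   country_of_birth) of level probabilities and log-risk coefficients.
#' @param other_modifier_margins Marginal probabilities of the
#'   non-focal indicators (drawn independently).
#' @param component_probs Probabilities of each outcome component
#'   (bleeding gums, fair/poor oral health, oral pain) conditional on the
#'   composite outcome being present; components are drawn jointly,
#'   truncated to "at least one present".
#' @param missing_rate MCAR missingness rate applied per raw variable
#'   (scalar, default 0).
#' @param seed Integer seed; generation is reproducible given the
#'   configuration.
#' @return A validated `sim_config` object.
#' @examples
#' cfg <- sim_config(n = c("45-59" = 1000), seed = 7)
#' truth_from_config(cfg)
#' @export
sim_config <- function(n = c("30-44" = 8587, "45-59" = 8412,
                             "60-74" = 5730),
                       modifier = "low_belonging",
                       stress_margin = 0.222,
                       modifier_margin = NULL,
                       cell_probs = NULL,
                       b0 = NULL, b_s = NULL, b_m = NULL, b_sm = NULL,
                       covariate_dists = default_covariate_dists(),
                       covariate_coefs = default_covariate_coefs(),
                       other_modifier_margins = default_modifier_margins,
                       component_probs = c(bleeding = 0.60, poor_oh = 0.33,
                                           pain = 0.35),
                       missing_rate = 0,
                       seed = 1) {
  if (is.null(names(n)) || any(names(n) == "")) {
    abort("'n' must be a named vector: records per age stratum")
  }
  stopifnot(all(n >= 1), length(modifier) == 1L)
  if (!modifier %in% modifier_names()) {
    abort(paste0("unknown modifier '", modifier, "'"))
  }
  strata <- names(n)

  if (is.null(modifier_margin)) {
    modifier_margin <- default_modifier_margins[[modifier]]
  }
  if (is.null(cell_probs)) {
    cell_probs <- c(
      ref = (1 - stress_margin) * (1 - modifier_margin),
      s10 = stress_margin * (1 - modifier_margin),
      s01 = (1 - stress_margin) * modifier_margin,
      s11 = stress_margin * modifier_margin
    )
  }
  if (is.null(names(cell_probs)) ||
      !setequal(names(cell_probs), c("ref", "s10", "s01", "s11"))) {
    abort("'cell_probs' must be named ref, s10, s01, s11")
  }
  cell_probs <- cell_probs[c("ref", "s10", "s01", "s11")]
  if (any(cell_probs < 0) || abs(sum(cell_probs) - 1) > 1e-8) {
    abort("'cell_probs' must be non-negative and sum to 1")
  }

  per_stratum <- function(x, default_fn, what) {
    if (is.null(x)) {
      if (!all(strata %in% canonical_strata)) {
        abort(paste0("no default '", what, "' for stratum(s) ",
                     paste(setdiff(strata, canonical_strata), collapse = ", "),
                     "; supply it explicitly"))
      }
      return(vapply(strata, default_fn, numeric(1)))
    }
    if (length(x) == 1L && is.null(names(x))) {
      return(setNames(rep(as.numeric(x), length(strata)), strata))
    }
    if (!all(strata %in% names(x))) {
      abort(paste0("'", what, "' must name every stratum"))
    }
    x[strata]
  }
  b0 <- per_stratum(b0, function(s) log(default_base_risk[[s]]), "b0")
  b_s <- per_stratum(b_s, function(s) log(default_truth_pr[[s]][["pr10"]]),
                     "b_s")
  b_m <- per_stratum(b_m, function(s) log(default_truth_pr[[s]][["pr01"]]),
                     "b_m")
  b_sm <- per_stratum(
    b_sm,
    function(s) {
      tr <- default_truth_pr[[s]]
      log(tr[["pr11"]]) - log(tr[["pr10"]]) - log(tr[["pr01"]])
    },
    "b_sm"
  )

  for (v in names(default_covariate_dists())) {
    d <- covariate_dists[[v]]
    k <- covariate_coefs[[v]]
    if (is.null(d) || is.null(k) || !setequal(names(d), names(k))) {
      abort(paste0("covariate '", v, "' needs matching distribution and ",
                   "coefficient level sets"))
    }
    if (any(d < 0) || abs(sum(d) - 1) > 1e-8) {
      abort(paste0("covariate '", v, "' distribution must sum to 1"))
    }
  }
  stopifnot(all(component_probs > 0), all(component_probs < 1),
            missing_rate >= 0, missing_rate < 1)

  cfg <- structure(
    list(
      n = n, strata = strata, modifier = modifier, cell_probs = cell_probs,
      b0 = b0, b_s = b_s, b_m = b_m, b_sm = b_sm,
      covariate_dists = covariate_dists, covariate_coefs = covariate_coefs,
      other_modifier_margins = other_modifier_margins,
      component_probs = component_probs,
      missing_rate = missing_rate, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_risk_bound(cfg)
  cfg
}

# Enumerate the finite covariate space x 4 joint cells per stratum and
# require every reachable risk to stay at or below 1.
validate_risk_bound <- function(cfg) {
  coef_sums <- Reduce(
    function(acc, k) as.vector(outer(acc, k, `+`)),
    cfg$covariate_coefs, accumulate = FALSE, init = 0
  )
  cell_lp <- c(ref = 0, s10 = NA, s01 = NA, s11 = NA)
  for (s in cfg$strata) {
    cells <- c(0, cfg$b_s[[s]], cfg$b_m[[s]],
               cfg$b_s[[s]] + cfg$b_m[[s]] + cfg$b_sm[[s]])
    worst <- cfg$b0[[s]] + max(cells) + max(coef_sums)
    if (exp(worst) > 1 + 1e-12) {
      abort(sprintf(
        "risk bound violated in stratum '%s': max reachable risk %.3f > 1",
        s, exp(worst)))
    }
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> strata: ",
      paste(sprintf("%s (n=%d)", x$strata, x$n), collapse = ", "),
      "\n  modifier: ", x$modifier,
      "\n  cell probs: ", paste(sprintf("%s=%.3f", names(x$cell_probs),
                                        x$cell_probs), collapse = ", "),
      "\n  seed: ", x$seed, "\n", sep = "")
  print(truth_from_config(x))
  invisible(x)
}

#' Closed-form truth of a synthetic population
#'
#' Under the log-link structural model with no covariate-exposure
#' interaction, covariate terms cancel from the prevalence ratios, so the
#' true adjusted joint PRs — and hence the true RERI — follow exactly
#' from the coefficients, with no simulation.
#'
#' @param config A [sim_config()].
#' @return Tibble with one row per stratum: `pr10 = exp(b_s)`,
#'   `pr01 = exp(b_m)`, `pr11 = exp(b_s + b_m + b_sm)` and
#'   `reri = pr11 - pr10 - pr01 + 1`.
#' @export
truth_from_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tibble(
    age_stratum = config$strata,
    pr10 = exp(unname(config$b_s)),
    pr01 = exp(unname(config$b_m)),
    pr11 = exp(unname(config$b_s + config$b_m + config$b_sm))
  ) |>
    mutate(reri = reri(.data$pr11, .data$pr10, .data$pr01))
}

sample_level <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE,
                          prob = unname(probs))]
}

# Joint draw of the three outcome components conditional on the composite:
# independent Bernoulli(component_probs) truncated to "at least one".
draw_components <- function(n1, p) {
  grid <- expand.grid(bleeding = 0:1, poor_oh = 0:1, pain = 0:1)
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  w <- apply(grid, 1, function(g) {
    prod(ifelse(g == 1, p, 1 - p))
  })
  idx <- sample.int(nrow(grid), n1, replace = TRUE, prob = w)
  grid[idx, , drop = FALSE]
}

#' Generate synthetic survey records
#'
#' Draws individual records from a [sim_config()]: covariates
#' independently per record, the (stress, low-capital) cell from the
#' joint cell probabilities, and the composite outcome as
#' Bernoulli(exp(linear predictor)). The three outcome components are
#' then drawn conditional on the composite so that [compose_outcome()]
#' recovers it exactly. With `raw = TRUE` (default) records are emitted
#' as raw categorical survey responses (e.g. a high-stress record
#' receives "quite a bit stressful" or "extremely stressful", low income
#' is a numeric dollar amount below $40,000), so the recoding pipeline is
#' exercised end to end; `raw = FALSE` emits recoded analysis records
#' directly, which is faster for simulation studies of the estimators.
#'
#' @param config A [sim_config()].
#' @param raw Emit raw categorical records (`TRUE`) or analysis-format
#'   records (`FALSE`).
#' @return A tibble; reproducible given the config (including its seed).
#' @export
generate_records <- function(config, raw = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    strata_tabs <- map(config$strata, function(s) {
      generate_stratum(config, s)
    })
    out <- bind_rows(strata_tabs)
    if (raw) out <- to_raw_records(out, config)
    out
  })
}

generate_stratum <- function(config, s) {
  n <- config$n[[s]]
  covs <- imap(config$covariate_dists, function(p, v) sample_level(n, p))
  cell <- sample_level(n, config$cell_probs)
  stress01 <- as.integer(cell %in% c("s10", "s11"))
  focal01 <- as.integer(cell %in% c("s01", "s11"))

  lp <- config$b0[[s]] + config$b_s[[s]] * stress01 +
    config$b_m[[s]] * focal01 + config$b_sm[[s]] * stress01 * focal01
  for (v in names(config$covariate_coefs)) {
    lp <- lp + unname(config$covariate_coefs[[v]][covs[[v]]])
  }
  outcome01 <- rbinom(n, 1L, exp(lp))

  comp <- matrix(0L, nrow = n, ncol = 3,
                 dimnames = list(NULL, c("bleeding01", "poor_oh01", "pain01")))
  n1 <- sum(outcome01 == 1L)
  if (n1 > 0L) {
    comp[outcome01 == 1L, ] <- as.matrix(
      draw_components(n1, config$component_probs))
  }

  others <- config$other_modifier_margins[
    setdiff(modifier_names(), config$modifier)]
  other_cols <- imap(others, function(p, nm) rbinom(n, 1L, p))

  tab <- tibble(
    age_stratum = s,
    sex = covs$sex,
    education = covs$education,
    country_of_birth = covs$country_of_birth,
    stress01 = stress01,
    outcome01 = outcome01,
    bleeding01 = comp[, "bleeding01"],
    poor_oh01 = comp[, "poor_oh01"],
    pain01 = comp[, "pain01"]
  )
  tab[[config$modifier]] <- focal01
  for (nm in names(other_cols)) tab[[nm]] <- other_cols[[nm]]
  tab[, c("age_stratum", "sex", "education", "country_of_birth",
          "stress01", modifier_names(), "bleeding01", "poor_oh01",
          "pain01", "outcome01")]
}

# Fixed within-side level frequencies used when emitting raw categories;
# they only shape the raw records, never the recoded analysis variables.
raw_side_levels <- list(
  stress = list(
    high = c("quite a bit stressful" = 0.85, "extremely stressful" = 0.15),
    low = c("not at all stressful" = 0.25, "not very stressful" = 0.35,
            "a bit stressful" = 0.40)
  ),
  belonging = list(
    high = c("somewhat weak" = 0.7, "very weak" = 0.3),
    low = c("very strong" = 0.45, "somewhat strong" = 0.55)
  ),
  living_arrangement = list(
    high = c("unattached individual living alone" = 1),
    low = c("individual living with spouse/partner" = 0.52,
            "parent living with spouse/partner and child(ren)" = 0.25,
            "unattached individual living with others" = 0.07,
            "single parent living with child(ren)" = 0.08,
            "other" = 0.08)
  ),
  dental_insurance = list(high = c(no = 1), low = c(yes = 1)),
  dwelling = list(high = c(rented = 1),
                  low = c("owned by member of household" = 1)),
  bleeding_gums = list(high = c(often = 0.3, sometimes = 0.7),
                       low = c(rarely = 0.35, never = 0.65)),
  perceived_oral_health = list(
    high = c(poor = 0.3, fair = 0.7),
    low = c(good = 0.40, "very good" = 0.35, excellent = 0.25)
  ),
  oral_pain = list(high = c(often = 0.25, sometimes = 0.75),
                   low = c(rarely = 0.3, never = 0.7))
)

emit_raw <- function(x01, var) {
  sides <- raw_side_levels[[var]]
  out <- character(length(x01))
  hi <- x01 == 1L
  out[hi] <- sample_level(sum(hi), sides$high)
  out[!hi] <- sample_level(sum(!hi), sides$low)
  out
}

to_raw_records <- function(tab, config) {
  n <- nrow(tab)
  raw <- tibble(
    age_group = tab$age_stratum,
    sex = tab$sex,
    education = tab$education,
    country_of_birth = tab$country_of_birth,
    stress = emit_raw(tab$stress01, "stress"),
    belonging = emit_raw(tab$low_belonging, "belonging"),
    living_arrangement = emit_raw(tab$living_alone, "living_arrangement"),
    household_income = ifelse(tab$low_income == 1L,
                              round(runif(n, 15000, 39999)),
                              round(runif(n, 40000, 150000))),
    dental_insurance = emit_raw(tab$no_insurance, "dental_insurance"),
    dwelling = emit_raw(tab$renter, "dwelling"),
    bleeding_gums = emit_raw(tab$bleeding01, "bleeding_gums"),
    perceived_oral_health = emit_raw(tab$poor_oh01, "perceived_oral_health"),
    oral_pain = emit_raw(tab$pain01, "oral_pain")
  )
  if (config$missing_rate > 0) {
    for (v in setdiff(names(raw), "age_group")) {
      gone <- runif(n) < config$missing_rate
      raw[[v]][gone] <- NA
    }
  }
  raw
}

#' Reconstruct analysis records from published cell counts
#'
#' Expands per-cell with/without-outcome counts of a 2x2 joint exposure
#' into individual covariate-free analysis records, so crude estimates on
#' the reconstruction reproduce direct arithmetic on the cells.
#'
#' @param cells Data frame with columns `stress01`, `modifier01`,
#'   `n_with`, `n_without` (one row per joint cell), or a row of
#'   [published_tables()] (its eight count columns are used).
#' @param modifier_name Column name given to the binary modifier in the
#'   output (default `"modifier01"`).
#' @return Tibble of analysis records: `stress01`, the modifier column
#'   and `outcome01`.
#' @examples
#' block <- published_tables()[5, ]  # 60-74, sense of belonging
#' rec <- records_from_cell_counts(block)
#' nrow(rec)
#' @export
records_from_cell_counts <- function(cells, modifier_name = "modifier01") {
  cells <- as_tibble(cells)
  if (all(c("ref_with", "s11_without") %in% names(cells))) {
    if (nrow(cells) != 1L) abort("supply a single published-table row")
    cells <- tibble(
      stress01 = c(0L, 1L, 0L, 1L),
      modifier01 = c(0L, 0L, 1L, 1L),
      n_with = c(cells$ref_with, cells$s10_with, cells$s01_with,
                 cells$s11_with),
      n_without = c(cells$ref_without, cells$s10_without, cells$s01_without,
                    cells$s11_without)
    )
  }
  stopifnot(all(c("stress01", "modifier01", "n_with", "n_without") %in%
                  names(cells)))
  if (any(cells$n_with < 0 | cells$n_without < 0)) {
    abort("cell counts must be non-negative")
  }
  if (sum(cells$n_with + cells$n_without) == 0) {
    abort("all cell counts are zero")
  }
  long <- tidyr::pivot_longer(cells, c("n_with", "n_without"),
                              names_to = "status", values_to = "n") |>
    mutate(outcome01 = as.integer(.data$status == "n_with")) |>
    select("stress01", "modifier01", "outcome01", "n") |>
    tidyr::uncount(.data$n)
  names(long)[names(long) == "modifier01"] <- modifier_name
  as_tibble(long)
}
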