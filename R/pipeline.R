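fmt2 <- function(x) formatC(x, format = "f", digits = 2)

fmt_ci <- function(pr, lo, hi) {
  dplyr::if_else(is.na(pr) | is.na(lo) | is.na(hi), "—",
                 sprintf("%s (%s, %s)", fmt2(pr), fmt2(lo), fmt2(hi)))
}

fmt_n <- function(with, without) {
  dplyr::if_else(is.na(with) | is.na(without), "—",
                 sprintf("%d/%d", as.integer(with), as.integer(without)))
}

#' Render an EMM analysis as Knol-VanderWeele Markdown tables
#'
#' One block per (modifier, age stratum): the four joint-cell
#' with/without-outcome counts and PRs (the reference cell fixed at
#' 1.00), the stress PRs within the high- and low-capital subsets, a
#' "RERI (additive scale)" line showing the arithmetic on 2-decimal PRs,
#' and an "Attributable proportion" line in percent (1 decimal), printed
#' as "N/A" when the RERI is negative. Missing cells render as an em
#' dash with a warning.
#'
#' @param results An `emm_tbl` from [emm_analysis()] (or the same
#'   columns re-read from CSV).
#' @return Character vector of Markdown lines (one element per line).
#' @export
render_kv_table <- function(results) {
  results <- as_tibble(results)
  if (nrow(results) == 0L) abort("empty EMM result list")
  # a missing AP is the published "N/A" convention, not a missing cell
  num_cols <- setdiff(names(results),
                      c("modifier", "age_stratum", "method", "ap", "version"))
  if (any(is.na(as.matrix(results[num_cols])))) {
    warn("missing cells rendered as —")
  }
  blocks <- map(seq_len(nrow(results)), function(i) {
    r <- results[i, ]
    pr10 <- round(r$pr10, 2); pr01 <- round(r$pr01, 2)
    pr11 <- round(r$pr11, 2)
    reri_line <- if (any(is.na(c(pr10, pr01, pr11)))) {
      "RERI (additive scale): —"
    } else {
      sprintf("RERI (additive scale): %s – %s – %s + 1 = %s",
              fmt2(pr11), fmt2(pr10), fmt2(pr01), fmt2(r$reri))
    }
    ap_line <- if (is.na(r$ap)) {
      "Attributable proportion: N/A"
    } else {
      sprintf("Attributable proportion: %s/%s = %s",
              fmt2(r$reri), fmt2(pr11), format_ap(r$ap))
    }
    c(
      sprintf("### %s, %s years (n = %s, %s)", r$modifier, r$age_stratum,
              r$n, r$method),
      "",
      paste("| capital | N with/without outcome, low stress | PR (95% CI),",
            "low stress | N with/without outcome, high stress | PR (95% CI),",
            "high stress | stress PR (95% CI) within capital stratum |"),
      "|---|---|---|---|---|---|",
      sprintf("| high capital | %s | 1.00 (Ref) | %s | %s | %s |",
              fmt_n(r$ref_with, r$ref_without),
              fmt_n(r$s10_with, r$s10_without),
              fmt_ci(r$pr10, r$pr10_low, r$pr10_high),
              fmt_ci(r$pr_stress_high_capital, r$pr_stress_high_capital_low,
                     r$pr_stress_high_capital_high)),
      sprintf("| low capital | %s | %s | %s | %s | %s |",
              fmt_n(r$s01_with, r$s01_without),
              fmt_ci(r$pr01, r$pr01_low, r$pr01_high),
              fmt_n(r$s11_with, r$s11_without),
              fmt_ci(r$pr11, r$pr11_low, r$pr11_high),
              fmt_ci(r$pr_stress_low_capital, r$pr_stress_low_capital_low,
                     r$pr_stress_low_capital_high)),
      "",
      reri_line,
      ap_line,
      ""
    )
  })
  unlist(blocks)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes recode, the headline stress-outcome prevalence-ratio model
#' (adjusted for age stratum, sex, education and country of birth), the
#' EMM analysis per modifier and age stratum, and — when a fixture of
#' published values is supplied — the as-published verification, writing
#' an artifact bundle to the output directory: recoded records CSV,
#' recode log, tidy headline and EMM CSVs, rendered Knol-VanderWeele
#' Markdown tables, optional verification CSV, and a run log recording
#' seed and package version. Partial outputs are removed when any stage
#' fails.
#'
#' @param config A list, or path to a YAML file, with elements:
#'   `input` (either `list(file = path, mapping = path-or-NULL)` or
#'   `list(synthetic = )` a [sim_config()] or a list of its arguments);
#'   `modifiers` (default all five); `strata` (default: observed);
#'   `covariates` (default sex, education, country_of_birth);
#'   `ci_level` (default 0.95); `rounding` (`"full"` or
#'   `"as-published"`); `out_dir` (required); `seed` (default 1;
#'   overrides the synthetic config's seed); `fixture` (`TRUE` for the
#'   shipped published values, a CSV path, or `NULL` to skip). A config
#'   with a `fixture` but no `input` performs a verification-only run.
#' @return Invisibly, a list with the analysis table, headline tidy
#'   tibble, `emm_tbl`, optional verification report, and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) abort("config$out_dir is required")
  input <- config$input
  fixture_only <- is.null(input) && !is.null(config$fixture)
  if (!fixture_only &&
      (is.null(input) ||
       sum(!is.null(input$file), !is.null(input$synthetic)) != 1L)) {
    abort("config$input must supply exactly one of 'file' or 'synthetic' (or only a fixture for a verification-only run)")
  }

  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create out_dir: ", out_dir))
  written <- character()
  note <- function(path) { written <<- c(written, path); path }
  seed <- config$seed %||% 1L

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      abort(paste0("pipeline stage '", stage, "' failed"), parent = e)
    })
  }

  records <- if (fixture_only) NULL else run_stage("input", {
    if (!is.null(input$file)) {
      if (!is.null(input$mapping) && !file.exists(input$mapping)) {
        abort(paste0("mapping file not found: ", input$mapping))
      }
      read_respondent_csv(input$file, mapping = input$mapping)
    } else {
      cfg <- input$synthetic
      if (!inherits(cfg, "sim_config")) {
        cfg <- do.call(sim_config, c(cfg, list(seed = seed)))
      }
      generate_records(cfg)
    }
  })

  analysis <- if (fixture_only) NULL else run_stage("recode", {
    a <- build_analysis_table(records)
    readr::write_csv(a, note(file.path(out_dir, "analysis_records.csv")))
    write_recode_log(recode_log(a),
                     note(file.path(out_dir, "recode_log.txt")))
    a
  })

  covariates <- config$covariates %||% c("sex", "education",
                                         "country_of_birth")
  ci_level <- config$ci_level %||% 0.95
  rounding <- config$rounding %||% "full"

  headline <- if (fixture_only) NULL else run_stage("headline", {
    age_cov <- if (length(unique(analysis$age_stratum)) > 1L) "age_stratum"
    fit <- fit_pr_model(analysis, "outcome01", "stress01",
                        covariates = c(age_cov, covariates),
                        ci_level = ci_level)
    td <- mutate(tidy(fit), stratum = "all",
                 version = as.character(packageVersion("stressemm")))
    readr::write_csv(td, note(file.path(out_dir, "headline_pr.csv")))
    td
  })

  emm <- if (fixture_only) NULL else run_stage("emm", {
    e <- emm_analysis(analysis,
                      modifiers = config$modifiers %||% modifier_names(),
                      strata = config$strata,
                      covariates = covariates, ci_level = ci_level,
                      rounding = rounding, seed = seed)
    out <- mutate(e, version = as.character(packageVersion("stressemm")))
    readr::write_csv(out, note(file.path(out_dir, "emm_results.csv")))
    writeLines(render_kv_table(e),
               note(file.path(out_dir, "emm_tables.md")))
    e
  })

  check <- NULL
  if (!is.null(config$fixture)) {
    check <- run_stage("verify", {
      printed <- if (isTRUE(config$fixture)) {
        published_tables()
      } else {
        readr::read_csv(config$fixture, show_col_types = FALSE, na = "NA")
      }
      v <- as_published_check(printed)
      readr::write_csv(v, note(file.path(out_dir, "as_published_check.csv")))
      v
    })
  }

  run_stage("log", {
    writeLines(c(
      sprintf("stressemm version: %s", packageVersion("stressemm")),
      sprintf("seed: %s", seed),
      if (fixture_only) "verification-only run" else
        sprintf("records in: %d, complete cases: %d", nrow(records),
                nrow(analysis)),
      sprintf("rounding: %s, ci_level: %s", rounding, ci_level),
      sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
    ), note(file.path(out_dir, "run_log.txt")))
  })

  invisible(list(analysis = analysis, headline = headline, emm = emm,
                 check = check, paths = written))
}
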