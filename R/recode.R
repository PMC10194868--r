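#' Canonical level sets for the analysis covariates
#'
#' @return Named list of character vectors: the allowed levels of
#'   `age_group`, `sex`, `education` and `country_of_birth`, in reference
#'   order (the first level is the regression reference).
#' @export
covariate_levels <- function() {
  list(
    age_group = c("30-44", "45-59", "60-74"),
    sex = c("male", "female"),
    education = c("less than secondary", "secondary", "post-secondary"),
    country_of_birth = c("Canada", "other")
  )
}

# Analysis names of the five capital indicators, with the raw column each
# one is recoded from. 1 = low capital throughout.
modifier_sources <- c(
  low_belonging = "belonging",
  living_alone = "living_arrangement",
  low_income = "household_income",
  no_insurance = "dental_insurance",
  renter = "dwelling"
)

#' Names of the five binary low-capital indicators
#'
#' @return Character vector: `low_belonging`, `living_alone`, `low_income`,
#'   `no_insurance`, `renter`.
#' @export
modifier_names <- function() names(modifier_sources)

#' Recode raw survey records into the binary analysis table
#'
#' Converts one-row-per-respondent raw categorical data into the analysis
#' table used by every downstream model: a binary high-stress exposure,
#' five binary low-capital indicators, the composite inadequate-oral-health
#' outcome, and the categorical covariates (sex, education, country of
#' birth) plus the age stratum. Rows missing any analysis variable are
#' dropped listwise, yielding a single complete-case analytic sample; the
#' per-variable missingness bookkeeping is attached as the recode log
#' (see [recode_log()]).
#'
#' Required raw columns: `age_group`, `sex`, `education`,
#' `country_of_birth`, `stress`, `belonging`, `living_arrangement`,
#' `household_income` (numeric dollars or the pre-binned two-level
#' category), `dental_insurance`, `dwelling`, `bleeding_gums`,
#' `perceived_oral_health`, `oral_pain`. Optional: `weight` (positive
#' sampling weight), `household_size` (accepted and ignored).
#'
#' @param records Data frame of raw respondent records.
#' @param maps Named list of [dichotomy_map()] objects; defaults to
#'   [default_dichotomy_maps()].
#' @return A tibble with columns `stress01`, the five indicators named by
#'   [modifier_names()], `bleeding01`, `poor_oh01`, `pain01`, `outcome01`,
#'   `sex`, `education`, `country_of_birth`, `age_stratum` and (when
#'   supplied) `weight`; recode log attached as attribute `recode_log`.
#' @examples
#' cfg <- sim_config(n = c("30-44" = 300), seed = 42)
#' raw <- generate_records(cfg)
#' analysis <- build_analysis_table(raw)
#' recode_log(analysis)
#' @export
build_analysis_table <- function(records, maps = default_dichotomy_maps()) {
  records <- as_tibble(records)
  required_raw <- c("age_group", "sex", "education", "country_of_birth",
                    "stress", names(modifier_sources_raw()),
                    "bleeding_gums", "perceived_oral_health", "oral_pain")
  missing_cols <- setdiff(required_raw, names(records))
  if (length(missing_cols) > 0L) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  required_maps <- c("stress", "belonging", "living_arrangement",
                     "dental_insurance", "dwelling", "bleeding_gums",
                     "perceived_oral_health", "oral_pain")
  if (!all(required_maps %in% names(maps))) {
    abort(paste0("maps must cover: ",
                 paste(setdiff(required_maps, names(maps)), collapse = ", ")))
  }

  out <- tibble(
    stress01 = map_binary(records$stress, maps$stress),
    low_belonging = map_binary(records$belonging, maps$belonging),
    living_alone = map_binary(records$living_arrangement,
                              maps$living_arrangement),
    low_income = recode_income(records$household_income, maps),
    no_insurance = map_binary(records$dental_insurance, maps$dental_insurance),
    renter = map_binary(records$dwelling, maps$dwelling),
    bleeding01 = map_binary(records$bleeding_gums, maps$bleeding_gums),
    poor_oh01 = map_binary(records$perceived_oral_health,
                           maps$perceived_oral_health),
    pain01 = map_binary(records$oral_pain, maps$oral_pain)
  )

  lv <- covariate_levels()
  for (v in c("age_group", "sex", "education", "country_of_birth")) {
    vals <- as.character(records[[v]])
    bad <- setdiff(unique(vals[!is.na(vals)]), lv[[v]])
    if (length(bad) > 0L) {
      abort(paste0("unknown level(s) for variable '", v, "': ",
                   paste(sQuote(bad), collapse = ", ")))
    }
    out[[v]] <- factor(vals, levels = lv[[v]])
  }
  out <- rename(out, age_stratum = "age_group")

  has_weight <- "weight" %in% names(records)
  if (has_weight) {
    w <- as.numeric(records$weight)
    if (any(w <= 0, na.rm = TRUE)) abort("weights must be positive")
    out$weight <- w
  }

  analysis_vars <- setdiff(names(out), "weight")
  n_missing <- vapply(out[analysis_vars], function(x) sum(is.na(x)), 0L)
  complete <- stats::complete.cases(out)
  kept <- filter(out, complete)
  kept <- mutate(
    kept,
    outcome01 = compose_outcome(.data$bleeding01, .data$poor_oh01, .data$pain01),
    .after = "pain01"
  )
  if (nrow(kept) == 0L) abort("no complete cases")

  log <- list(
    n_input = nrow(records),
    n_complete = nrow(kept),
    n_dropped = nrow(records) - nrow(kept),
    missing_by_variable = tibble(variable = analysis_vars,
                                 n_missing = unname(n_missing))
  )
  attr(kept, "recode_log") <- log
  kept
}

modifier_sources_raw <- function() {
  setNames(unname(modifier_sources), unname(modifier_sources))
}

recode_income <- function(income, maps) {
  if (is.numeric(income)) {
    dichotomize_income(income)
  } else {
    map_binary(income, maps$household_income)
  }
}

#' Retrieve the recode log of an analysis table
#'
#' @param analysis A table produced by [build_analysis_table()].
#' @return List with `n_input`, `n_complete`, `n_dropped` and a tibble
#'   `missing_by_variable`.
#' @export
recode_log <- function(analysis) {
  log <- attr(analysis, "recode_log")
  if (is.null(log)) abort("no recode log attached; not a recoded table?")
  log
}

#' Write a recode log as plain text
#'
#' @param log A recode log from [recode_log()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recode_log <- function(log, path) {
  lines <- c(
    sprintf("rows in: %d", log$n_input),
    sprintf("complete cases: %d", log$n_complete),
    sprintf("rows dropped (listwise): %d", log$n_dropped),
    "missing by variable:",
    sprintf("  %-22s %d", log$missing_by_variable$variable,
            log$missing_by_variable$n_missing)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read raw respondent records from a delimited file
#'
#' Reads a CSV/TSV of raw survey responses and optionally applies a column
#' and level mapping so files with arbitrary headers and response codes
#' can be fed to [build_analysis_table()].
#'
#' @param path File path (CSV by default; TSV when the name ends in
#'   `.tsv`).
#' @param mapping Either `NULL`, a mapping list (see
#'   [read_column_mapping()]) or a path to a YAML/JSON mapping file.
#' @return Tibble of raw respondent records in canonical columns.
#' @export
read_respondent_csv <- function(path, mapping = NULL) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  records <- reader(path, show_col_types = FALSE, progress = FALSE)
  if (is.character(mapping)) mapping <- read_column_mapping(mapping)
  if (!is.null(mapping)) records <- apply_column_mapping(records, mapping)
  records
}

#' Read a column/level mapping file
#'
#' The mapping file (YAML or JSON) may contain two blocks: `columns`, a
#' dictionary of canonical variable name to the column name used in the
#' input file, and `levels`, a per-variable dictionary translating raw
#' input codes to the canonical level strings used by the shipped
#' dichotomy maps.
#'
#' @param path Path to a YAML or JSON mapping file.
#' @return Mapping list with elements `columns` and `levels`.
#' @export
read_column_mapping <- function(path) {
  if (!file.exists(path)) abort(paste0("mapping file not found: ", path))
  mapping <- yaml::read_yaml(path)
  if (!is.list(mapping)) abort("mapping file must define a dictionary")
  mapping
}

apply_column_mapping <- function(records, mapping) {
  cols <- mapping$columns
  if (!is.null(cols)) {
    for (canonical in names(cols)) {
      src <- cols[[canonical]]
      if (!src %in% names(records)) {
        abort(paste0("mapped column '", src, "' (for '", canonical,
                     "') not present in input"))
      }
      names(records)[names(records) == src] <- canonical
    }
  }
  lvl <- mapping$levels
  if (!is.null(lvl)) {
    for (v in names(lvl)) {
      if (!v %in% names(records)) next
      dict <- unlist(lvl[[v]])
      vals <- as.character(records[[v]])
      hit <- vals %in% names(dict)
      vals[hit] <- unname(dict[vals[hit]])
      records[[v]] <- vals
    }
  }
  records
}
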