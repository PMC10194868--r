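#' Define a dichotomization rule for a categorical survey variable
#'
#' A dichotomy map partitions the full level set of a categorical survey
#' response into the levels recoded to 1 ("high" in the analysis sense:
#' high stress, low capital, adverse oral-health indicator) and the levels
#' recoded to 0. The two sets must be disjoint and together cover the whole
#' level set, so every observed value has a defined recode.
#'
#' @param name Variable name the map applies to (used in error messages).
#' @param high_levels Character vector of raw levels recoded to 1.
#' @param low_levels Character vector of raw levels recoded to 0.
#' @return An object of class `dichotomy_map`.
#' @examples
#' m <- dichotomy_map("stress",
#'   high_levels = c("quite a bit stressful", "extremely stressful"),
#'   low_levels  = c("not at all stressful", "not very stressful",
#'                   "a bit stressful"))
#' map_binary(c("a bit stressful", "extremely stressful"), m)
#' @export
dichotomy_map <- function(name, high_levels, low_levels) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(high_levels), is.character(low_levels))
  if (length(intersect(high_levels, low_levels)) > 0L) {
    abort(paste0("dichotomy map '", name, "': high and low level sets overlap: ",
                 paste(intersect(high_levels, low_levels), collapse = ", ")))
  }
  if (anyDuplicated(c(high_levels, low_levels))) {
    abort(paste0("dichotomy map '", name, "': duplicated levels"))
  }
  structure(
    list(name = name, high_levels = high_levels, low_levels = low_levels),
    class = "dichotomy_map"
  )
}

#' @export
print.dichotomy_map <- function(x, ...) {
  cat("<dichotomy_map> ", x$name, "\n",
      "  1: ", paste(x$high_levels, collapse = ", "), "\n",
      "  0: ", paste(x$low_levels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Default dichotomization rules for the CCHS-style variables
#'
#' Returns the nine shipped maps covering the exposure (perceived life
#' stress), the five capital indicators (sense of belonging, living
#' arrangement, pre-binned household income, dental insurance, dwelling
#' ownership) and the three oral-health outcome components (bleeding gums,
#' perceived oral health, oral pain). For every map the value 1 denotes
#' high stress, low capital, or an adverse oral-health indicator.
#'
#' Numeric household income is handled separately by
#' [dichotomize_income()]; the `household_income` map here covers inputs
#' already binned to the two-level category.
#'
#' @return Named list of [dichotomy_map()] objects.
#' @export
default_dichotomy_maps <- function() {
  list(
    stress = dichotomy_map(
      "stress",
      high_levels = c("quite a bit stressful", "extremely stressful"),
      low_levels  = c("not at all stressful", "not very stressful",
                      "a bit stressful")
    ),
    belonging = dichotomy_map(
      "belonging",
      high_levels = c("somewhat weak", "very weak"),
      low_levels  = c("very strong", "somewhat strong")
    ),
    living_arrangement = dichotomy_map(
      "living_arrangement",
      high_levels = "unattached individual living alone",
      low_levels  = c(
        "unattached individual living with others",
        "individual living with spouse/partner",
        "parent living with spouse/partner and child(ren)",
        "single parent living with child(ren)",
        "child living with a single parent with or without siblings",
        "child living with two parents with or without siblings",
        "other"
      )
    ),
    household_income = dichotomy_map(
      "household_income",
      high_levels = "less than $40,000",
      low_levels  = "$40,000 or more"
    ),
    dental_insurance = dichotomy_map(
      "dental_insurance",
      high_levels = "no",
      low_levels  = "yes"
    ),
    dwelling = dichotomy_map(
      "dwelling",
      high_levels = "rented",
      low_levels  = "owned by member of household"
    ),
    bleeding_gums = dichotomy_map(
      "bleeding_gums",
      high_levels = c("often", "sometimes"),
      low_levels  = c("rarely", "never")
    ),
    perceived_oral_health = dichotomy_map(
      "perceived_oral_health",
      high_levels = c("poor", "fair"),
      low_levels  = c("good", "very good", "excellent")
    ),
    oral_pain = dichotomy_map(
      "oral_pain",
      high_levels = c("often", "sometimes"),
      low_levels  = c("rarely", "never")
    )
  )
}

#' Recode raw categorical values to a binary indicator
#'
#' Applies a [dichotomy_map()] to a vector of raw responses. Missing values
#' stay missing; a non-missing value outside the map's level set is an
#' error naming the variable and the offending level.
#'
#' @param value Character or factor vector of raw responses.
#' @param map A [dichotomy_map()].
#' @return Integer vector of 0/1 (with `NA` preserved).
#' @export
map_binary <- function(value, map) {
  stopifnot(inherits(map, "dichotomy_map"))
  value <- as.character(value)
  known <- c(map$high_levels, map$low_levels)
  bad <- setdiff(unique(value[!is.na(value)]), known)
  if (length(bad) > 0L) {
    abort(paste0("unknown level(s) for variable '", map$name, "': ",
                 paste(sQuote(bad), collapse = ", ")))
  }
  out <- rep(NA_integer_, length(value))
  out[value %in% map$high_levels] <- 1L
  out[value %in% map$low_levels] <- 0L
  out
}

#' Dichotomize annual household income at $40,000
#'
#' Household income is classified as low income (1) when it falls below
#' $40,000 per annum and middle/high (0) otherwise. The boundary follows
#' the published low/middle-high split of household income, motivated by
#' Ontario low-income cut-offs of roughly $31,800-$32,600 for typical
#' family and community sizes: a single clean threshold at $40,000.
#'
#' @param income Numeric vector of annual household incomes (dollars).
#' @return Integer vector of 0/1 (`NA` preserved).
#' @examples
#' dichotomize_income(c(32554, 40000, 0))
#' @export
dichotomize_income <- function(income) {
  stopifnot(is.numeric(income))
  if (any(income < 0, na.rm = TRUE)) {
    abort("negative household income is not allowed")
  }
  as.integer(income < 40000)
}

#' Composite inadequate-oral-health outcome
#'
#' The binary outcome is 1 when a respondent reports at least one of the
#' three adverse indicators: bleeding gums (often/sometimes), fair/poor
#' self-rated oral health, or persistent oral pain (often/sometimes).
#'
#' @param bleeding01,poor_oh01,pain01 Binary 0/1 vectors (recoded
#'   components).
#' @return Integer vector: the element-wise logical OR.
#' @examples
#' compose_outcome(c(0, 1, 0), c(0, 0, 0), c(0, 1, 1))
#' @export
compose_outcome <- function(bleeding01, poor_oh01, pain01) {
  check_binary(bleeding01, "bleeding01")
  check_binary(poor_oh01, "poor_oh01")
  check_binary(pain01, "pain01")
  as.integer(bleeding01 == 1L | poor_oh01 == 1L | pain01 == 1L)
}

check_binary <- function(x, name) {
  if (!is.numeric(x) || any(!x[!is.na(x)] %in% c(0, 1))) {
    abort(paste0("'", name, "' must be binary 0/1"))
  }
  invisible(x)
}
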