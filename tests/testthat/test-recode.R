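test_that("complete-case filtering drops exactly the rows with missingness", {
  raw <- tiny_raw(10)
  raw$stress[c(2, 5)] <- NA
  a <- build_analysis_table(raw)
  expect_equal(nrow(a), 8)
  log <- recode_log(a)
  expect_equal(log$n_input, 10)
  expect_equal(log$n_dropped, 2)
  expect_equal(
    log$missing_by_variable$n_missing[
      log$missing_by_variable$variable == "stress01"], 2)
})

test_that("recoding an already-complete table drops zero rows", {
  a1 <- build_analysis_table(tiny_raw(8))
  expect_equal(recode_log(a1)$n_dropped, 0)
})

test_that("economic indicators recode jointly from one row", {
  raw <- tiny_raw(2)
  raw$household_income <- c(35000, 90000)
  raw$dental_insurance <- c("no", "yes")
  raw$dwelling <- c("rented", "owned by member of household")
  a <- build_analysis_table(raw)
  expect_equal(a$low_income, c(1L, 0L))
  expect_equal(a$no_insurance, c(1L, 0L))
  expect_equal(a$renter, c(1L, 0L))
})

test_that("pre-binned income categories pass through the income map", {
  raw <- tiny_raw(2)
  raw$household_income <- c("less than $40,000", "$40,000 or more")
  a <- build_analysis_table(raw)
  expect_equal(a$low_income, c(1L, 0L))
})

test_that("the composite outcome is the OR of the recoded components", {
  a <- build_analysis_table(tiny_raw(6))
  expect_identical(a$outcome01,
                   compose_outcome(a$bleeding01, a$poor_oh01, a$pain01))
})

test_that("degenerate inputs fail loudly", {
  raw <- tiny_raw(4)
  raw$bleeding_gums <- NA_character_
  raw$perceived_oral_health <- NA_character_
  raw$oral_pain <- NA_character_
  expect_error(build_analysis_table(raw), "no complete cases")
  raw2 <- tiny_raw(3)
  raw2$sex[1] <- "unknown"
  expect_error(build_analysis_table(raw2), "sex.*unknown")
  expect_error(build_analysis_table(tiny_raw(3)[, -5]), "missing required")
})

test_that("column and level mappings translate arbitrary input dialects", {
  raw <- tiny_raw(4)
  names(raw)[names(raw) == "stress"] <- "GEN_020"
  raw$GEN_020 <- c("3", "5", "3", "5")
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(raw, csv)
  map_file <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    columns = list(stress = "GEN_020"),
    levels = list(stress = list(
      "3" = "a bit stressful", "5" = "extremely stressful"))
  ), map_file)
  rec <- read_respondent_csv(csv, mapping = map_file)
  expect_true("stress" %in% names(rec))
  a <- build_analysis_table(rec)
  expect_equal(a$stress01, c(0L, 1L, 0L, 1L))
})

test_that("positive weights are kept and non-positive weights rejected", {
  raw <- tiny_raw(4)
  raw$weight <- c(1.5, 2, 1, 3)
  a <- build_analysis_table(raw)
  expect_equal(a$weight, c(1.5, 2, 1, 3))
  raw$weight[2] <- 0
  expect_error(build_analysis_table(raw), "positive")
})
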