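test_that("the shipped fixture covers every indicator-stratum block", {
  pub <- published_tables()
  expect_equal(nrow(pub), 15)
  expect_setequal(unique(pub$modifier), modifier_names())
  expect_equal(unname(table(pub$age_stratum)), rep(5L, 3),
               ignore_attr = TRUE)
  # stratum totals match the published stratum sizes
  totals <- rowSums(pub[, c("ref_with", "ref_without", "s10_with",
                            "s10_without", "s01_with", "s01_without",
                            "s11_with", "s11_without")])
  bel <- pub$modifier == "low_belonging"
  expect_equal(totals[bel][order(pub$age_stratum[bel])],
               c(8305, 7821, 4845), ignore_attr = TRUE)
})

test_that("consistent printed rows pass and the inconsistent row flags", {
  report <- as_published_check()
  expect_equal(sum(report$verdict == "PASS"), 14)
  flagged <- report[report$verdict == "FLAG", ]
  expect_equal(nrow(flagged), 1)
  expect_identical(flagged$modifier, "low_belonging")
  expect_identical(flagged$age_stratum, "60-74")
  expect_equal(flagged$recomputed_reri, 0.31, tolerance = 1e-9)
  expect_equal(flagged$printed_reri, 0.71)
  # the printed AP equals printed_reri / pr11, exposing the inconsistency
  expect_equal(100 * flagged$printed_reri / flagged$pr11, 30.1,
               tolerance = 0.05)
})

test_that("single synthetic rows verify or flag as constructed", {
  pass_row <- tibble::tibble(
    modifier = "x", age_stratum = "45-59",
    pr11 = 1.94, pr10 = 1.34, pr01 = 1.31,
    printed_reri = 0.29, printed_ap_pct = 14.9)
  expect_identical(as_published_check(pass_row)$verdict, "PASS")
  expect_true(as_published_check(pass_row)$ap_consistent)

  flag_row <- tibble::tibble(
    modifier = "x", age_stratum = "60-74",
    pr11 = 2.36, pr10 = 1.65, pr01 = 1.40,
    printed_reri = 0.71, printed_ap_pct = 30.1)
  expect_identical(as_published_check(flag_row)$verdict, "FLAG")

  na_row <- tibble::tibble(
    modifier = "x", age_stratum = "45-59",
    pr11 = 1.50, pr10 = 1.45, pr01 = 1.16,
    printed_reri = -0.11, printed_ap_pct = NA_real_)
  out <- as_published_check(na_row)
  expect_identical(out$verdict, "PASS")
  expect_true(out$ap_consistent)
  expect_true(is.na(out$recomputed_ap_pct))
})

test_that("malformed rows error with the row identifier", {
  bad <- tibble::tibble(
    modifier = "broken", age_stratum = "45-59",
    pr11 = NA_real_, pr10 = 1.34, pr01 = 1.31,
    printed_reri = 0.29, printed_ap_pct = 14.9)
  expect_error(as_published_check(bad), "broken")
  expect_error(as_published_check(tibble::tibble(modifier = "x")),
               "lacks column")
})
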