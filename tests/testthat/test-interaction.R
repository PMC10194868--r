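test_that("joint categories encode the four stress x capital cells", {
  got <- joint_category(c(0, 1, 0, 1), c(0, 0, 1, 1))
  expect_identical(as.character(got), c("ref", "s10", "s01", "s11"))
  expect_identical(levels(got), c("ref", "s10", "s01", "s11"))
})

test_that("reri reproduces the published worked arithmetic", {
  expect_equal(reri(1.79, 1.31, 1.26), 0.22)
  expect_equal(reri(1, 1, 1), 0)
  expect_equal(reri(1.50, 1.45, 1.16), -0.11)
  expect_error(reri(0, 1, 1))
})

test_that("attributable proportion divides by PR11 and is N/A when negative", {
  expect_equal(attributable_proportion(0.22, 1.79), 0.22 / 1.79)
  expect_identical(format_ap(attributable_proportion(0.22, 1.79)), "12.3%")
  expect_equal(attributable_proportion(0, 2), 0)
  expect_true(is.na(attributable_proportion(-0.11, 1.50)))
  expect_identical(format_ap(attributable_proportion(-0.11, 1.50)), "N/A")
})

test_that("ap stays in [0, 1] and is zero only at exact additivity", {
  withr::with_seed(42, {
    pr10 <- runif(500, 0.5, 3)
    pr01 <- runif(500, 0.5, 3)
    pr11 <- runif(500, 0.5, 6)
    r <- reri(pr11, pr10, pr01)
    ap <- attributable_proportion(r, pr11)
    expect_true(all(is.na(ap) | (ap >= 0 & ap <= 1)))
    expect_true(all((ap == 0) == (r == 0), na.rm = TRUE))
  })
})

test_that("covariate-free joint PRs reproduce crude cell arithmetic", {
  block <- published_tables()
  block <- block[block$modifier == "low_belonging" &
                   block$age_stratum == "60-74", ]
  rec <- records_from_cell_counts(block)
  jp <- joint_prs(rec, "modifier01", covariates = NULL)
  td <- tidy(jp)
  expect_equal(td$pr[td$cell == "s11"], crude_pr(107, 78, 818, 2587),
               tolerance = 1e-6)
  expect_equal(td$pr[td$cell == "s10"], crude_pr(149, 226, 818, 2587),
               tolerance = 1e-6)
  expect_equal(td$pr[td$cell == "s01"], crude_pr(297, 583, 818, 2587),
               tolerance = 1e-6)
})

test_that("an empty joint cell is an error naming the cell", {
  rec <- records_from_cell_counts(tibble::tibble(
    stress01 = c(0L, 1L, 0L), modifier01 = c(0L, 0L, 1L),
    n_with = c(10, 10, 10), n_without = c(30, 20, 25)
  ))
  expect_error(joint_prs(rec, "modifier01", covariates = NULL), "s11")
})

test_that("within-capital stress PRs reproduce crude subset arithmetic", {
  block <- published_tables()
  block <- block[block$modifier == "low_belonging" &
                   block$age_stratum == "60-74", ]
  rec <- records_from_cell_counts(block, modifier_name = "low_belonging")
  within <- stress_pr_within_strata(rec, "low_belonging", covariates = NULL)
  expect_equal(within$pr[within$capital == "low"],
               (107 / 185) / (297 / 880), tolerance = 1e-3)
  expect_equal(within$pr[within$capital == "high"],
               (149 / 375) / (818 / 3405), tolerance = 1e-6)
  rec0 <- rec
  rec0$low_belonging <- 0L
  expect_error(stress_pr_within_strata(rec0, "low_belonging",
                                       covariates = NULL), "no variation")
})

test_that("emm results satisfy the RERI identity and the N/A rule", {
  cfg <- sim_config(n = c("30-44" = 4000, "45-59" = 4000), seed = 21)
  d <- generate_records(cfg, raw = FALSE)
  e <- emm_analysis(d, modifiers = c("low_belonging"),
                    strata = c("30-44", "45-59"))
  expect_equal(nrow(e), 2)
  expect_equal(e$reri - (e$pr11 - e$pr10 - e$pr01 + 1), rep(0, 2),
               tolerance = 1e-12)
  expect_true(all(is.na(e$ap) | e$ap <= 1))
  neg <- e$reri < 0
  expect_identical(is.na(e$ap), neg)
})

test_that("as-published rounding computes RERI from 2-decimal PRs", {
  cfg <- belonging_truth_config(n = 8000, seed = 13)
  d <- generate_records(cfg, raw = FALSE)
  full <- emm_analysis(d, "low_belonging", "45-59")
  pub <- emm_analysis(d, "low_belonging", "45-59", rounding = "as-published")
  expect_equal(pub$reri,
               round(full$pr11, 2) - round(full$pr10, 2) -
                 round(full$pr01, 2) + 1)
  expect_equal(full$reri, full$pr11 - full$pr10 - full$pr01 + 1)
})

test_that("emm_analysis is ordered modifier-major and handles empty input", {
  cfg <- sim_config(n = c("30-44" = 3000, "45-59" = 3000), seed = 31)
  d <- generate_records(cfg, raw = FALSE)
  e <- emm_analysis(d, modifiers = c("renter", "low_belonging"))
  expect_identical(e$modifier, rep(c("renter", "low_belonging"), each = 2))
  expect_identical(e$age_stratum, rep(c("30-44", "45-59"), 2))
  e0 <- emm_analysis(d, modifiers = character())
  expect_equal(nrow(e0), 0)
})

test_that("errors carry the (modifier, stratum) context", {
  cfg <- sim_config(n = c("30-44" = 500), seed = 7)
  d <- generate_records(cfg, raw = FALSE)
  d$renter <- 0L
  expect_error(emm_analysis(d, modifiers = "renter", strata = "30-44"),
               "modifier 'renter', stratum '30-44'")
})
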