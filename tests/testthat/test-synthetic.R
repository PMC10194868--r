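test_that("generation is deterministic given the config", {
  cfg <- sim_config(n = c("30-44" = 1000), seed = 7)
  expect_identical(generate_records(cfg), generate_records(cfg))
  expect_identical(generate_records(cfg, raw = FALSE),
                   generate_records(cfg, raw = FALSE))
  cfg2 <- sim_config(n = c("30-44" = 1000), seed = 8)
  expect_false(identical(generate_records(cfg2), generate_records(cfg)))
})

test_that("closed-form truth follows the log-risk coefficients exactly", {
  cfg <- belonging_truth_config(n = 100)
  tr <- truth_from_config(cfg)
  expect_equal(tr$pr10, 1.31)
  expect_equal(tr$pr01, 1.26)
  expect_equal(tr$pr11, 1.79)
  expect_equal(tr$reri, 0.22)
  expect_equal(tr$reri, tr$pr11 - tr$pr10 - tr$pr01 + 1)

  null <- sim_config(n = c("45-59" = 100), b0 = log(0.3),
                     b_s = 0, b_m = 0, b_sm = 0)
  expect_equal(truth_from_config(null)[, c("pr10", "pr01", "pr11", "reri")],
               tibble::tibble(pr10 = 1, pr01 = 1, pr11 = 1, reri = 0))

  mult <- sim_config(n = c("45-59" = 100), b0 = log(0.2),
                     b_s = log(1.4), b_m = log(1.3), b_sm = 0)
  expect_equal(truth_from_config(mult)$reri, (1.4 - 1) * (1.3 - 1))
})

test_that("null coefficients give equal empirical risks in all four cells", {
  cfg <- sim_config(n = c("45-59" = 30000), b0 = log(0.3),
                    b_s = 0, b_m = 0, b_sm = 0, seed = 12)
  d <- generate_records(cfg, raw = FALSE)
  d$joint <- joint_category(d$stress01, d$low_belonging)
  risks <- tapply(d$outcome01, d$joint, mean)
  # 4 sd of a cell proportion at the smallest cell (~2000 records)
  expect_true(all(abs(risks - 0.3) < 4 * sqrt(0.3 * 0.7 / 1500)))
})

test_that("empirical margins match the configured published margins", {
  cfg <- sim_config(n = c("45-59" = 100000), stress_margin = 0.222,
                    modifier_margin = 0.291, seed = 6)
  d <- generate_records(cfg, raw = FALSE)
  expect_lt(abs(mean(d$stress01) - 0.222), 0.01)
  expect_lt(abs(mean(d$low_belonging) - 0.291), 0.01)
})

test_that("components recompose to the generated composite for every record", {
  cfg <- sim_config(n = c("30-44" = 5000), seed = 3)
  d <- generate_records(cfg, raw = FALSE)
  expect_identical(compose_outcome(d$bleeding01, d$poor_oh01, d$pain01),
                   d$outcome01)
  # and survives the raw round trip through the recode module
  a <- build_analysis_table(generate_records(cfg))
  expect_identical(compose_outcome(a$bleeding01, a$poor_oh01, a$pain01),
                   a$outcome01)
})

test_that("raw records recode back to the generated analysis variables", {
  cfg <- sim_config(n = c("30-44" = 4000), seed = 19)
  fast <- generate_records(cfg, raw = FALSE)
  a <- build_analysis_table(generate_records(cfg))
  expect_equal(nrow(a), 4000)
  for (v in c("stress01", "outcome01", modifier_names())) {
    expect_identical(a[[v]], fast[[v]])
  }
})

test_that("an out-of-bound risk configuration errors at validation", {
  expect_error(
    sim_config(n = c("45-59" = 100), b0 = log(0.9), b_s = log(1.5),
               b_m = 0, b_sm = 0),
    "risk bound violated"
  )
})

test_that("MCAR missingness appears and is dropped by the recode", {
  cfg <- sim_config(n = c("30-44" = 2000), missing_rate = 0.03, seed = 4)
  raw <- generate_records(cfg)
  expect_gt(sum(is.na(raw$stress)), 0)
  a <- build_analysis_table(raw)
  expect_lt(nrow(a), 2000)
  expect_equal(recode_log(a)$n_dropped, 2000 - nrow(a))
})

test_that("cell-count reconstruction expands to the published totals", {
  block <- published_tables()
  block <- block[block$modifier == "low_belonging" &
                   block$age_stratum == "60-74", ]
  rec <- records_from_cell_counts(block)
  expect_equal(nrow(rec), 818 + 2587 + 149 + 226 + 297 + 583 + 107 + 78)

  one <- records_from_cell_counts(tibble::tibble(
    stress01 = 1L, modifier01 = 1L, n_with = 1L, n_without = 0L))
  expect_equal(nrow(one), 1)
  expect_equal(one$outcome01, 1L)

  living <- published_tables()
  living <- living[living$modifier == "living_alone" &
                     living$age_stratum == "30-44", ]
  rl <- records_from_cell_counts(living)
  s11 <- rl[rl$stress01 == 1 & rl$modifier01 == 1, ]
  ref <- rl[rl$stress01 == 0 & rl$modifier01 == 0, ]
  crude <- mean(s11$outcome01) / mean(ref$outcome01)
  expect_equal(crude, 1.3835, tolerance = 1e-3)

  expect_error(records_from_cell_counts(tibble::tibble(
    stress01 = 0L, modifier01 = 0L, n_with = 0L, n_without = 0L)),
    "all cell counts are zero")
})
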