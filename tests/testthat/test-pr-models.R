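test_that("crude_pr reproduces direct arithmetic on published cell counts", {
  expect_equal(crude_pr(107, 78, 818, 2587), 2.4076, tolerance = 1e-4)
  expect_equal(crude_pr(5, 5, 5, 5), 1)
  expect_equal(crude_pr(0, 10, 5, 5), 0)
  expect_error(crude_pr(5, 5, 0, 5), "undefined ratio")
  expect_error(crude_pr(0, 0, 5, 5), "empty")
})

test_that("wald_interval matches the closed form and centers the estimate", {
  expect_equal(wald_interval(0, 0.1, 0.95), c(0.8219, 1.2167),
               tolerance = 1e-3)
  ci <- wald_interval(log(2), 0.3, 0.9)
  expect_true(ci[1] < 2 && 2 < ci[2])
  narrow <- wald_interval(log(2), 0.3, 1e-12)
  expect_equal(narrow, c(2, 2), tolerance = 1e-6)
  expect_error(wald_interval(0, -1, 0.95))
})

test_that("a covariate-free saturated fit equals the crude ratio", {
  rec <- records_from_cell_counts(tibble::tibble(
    stress01 = c(0L, 1L), modifier01 = c(0L, 0L),
    n_with = c(818, 107), n_without = c(2587, 78)
  ))
  fit <- fit_pr_model(rec, "outcome01", "stress01")
  expect_equal(tidy(fit)$pr, crude_pr(107, 78, 818, 2587),
               tolerance = 1e-6)

  mp <- fit_pr_model(rec, "outcome01", "stress01",
                     method = "modified-poisson")
  expect_equal(tidy(mp)$pr, tidy(fit)$pr, tolerance = 1e-6)
  expect_identical(tidy(mp)$method, "modified-poisson")
  expect_identical(tidy(fit)$method, "log-binomial")
})

test_that("duplicating every record leaves the PR unchanged, CI narrower", {
  cfg <- belonging_truth_config(n = 3000, seed = 4)
  d <- generate_records(cfg, raw = FALSE)
  f1 <- tidy(fit_pr_model(d, "outcome01", "stress01",
                          covariates = c("sex", "education")))
  f2 <- tidy(fit_pr_model(dplyr::bind_rows(d, d), "outcome01", "stress01",
                          covariates = c("sex", "education")))
  expect_equal(f2$pr, f1$pr, tolerance = 1e-8)
  expect_lt(f2$ci_high - f2$ci_low, f1$ci_high - f1$ci_low)
})

test_that("frequency weights reproduce record duplication", {
  cfg <- belonging_truth_config(n = 2000, seed = 8)
  d <- generate_records(cfg, raw = FALSE)
  d$w <- rep(c(1, 2), length.out = nrow(d))
  dup <- d[rep(seq_len(nrow(d)), d$w), ]
  fw <- suppressWarnings(
    tidy(fit_pr_model(d, "outcome01", "stress01", weights = "w")))
  fd <- tidy(fit_pr_model(dup, "outcome01", "stress01"))
  expect_equal(fw$pr, fd$pr, tolerance = 1e-8)
})

test_that("degenerate inputs are rejected", {
  cfg <- belonging_truth_config(n = 500, seed = 2)
  d <- generate_records(cfg, raw = FALSE)
  d0 <- d; d0$outcome01 <- 1L
  expect_error(fit_pr_model(d0, "outcome01", "stress01"), "degenerate outcome")
  d1 <- d; d1$stress01 <- 0L
  expect_error(fit_pr_model(d1, "outcome01", "stress01"),
               "degenerate exposure")
  expect_error(fit_pr_model(d, "outcome01", "outcome01"), "regressors")
  expect_error(fit_pr_model(d, "outcome01", "nope"), "column not found")
})

test_that("the log-PR estimator recovers simulated truth with near-nominal CIs", {
  reps <- 40
  true_pr <- 1.5
  hits <- 0
  logs <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- sim_config(n = c("45-59" = 8000), b0 = log(0.25),
                      b_s = log(true_pr), b_m = 0, b_sm = 0, seed = 100 + r)
    d <- generate_records(cfg, raw = FALSE)
    td <- tidy(fit_pr_model(d, "outcome01", "stress01",
                            covariates = c("sex", "education",
                                           "country_of_birth")))
    logs[r] <- log(td$pr)
    hits <- hits + (td$ci_low <= true_pr && true_pr <= td$ci_high)
  }
  expect_lt(abs(mean(logs) - log(true_pr)), 0.02)
  expect_gte(hits / reps, 0.85)
})

test_that("glance reports the fit metadata", {
  cfg <- belonging_truth_config(n = 1000, seed = 3)
  d <- generate_records(cfg, raw = FALSE)
  g <- glance(fit_pr_model(d, "outcome01", "stress01"))
  expect_identical(g$method, "log-binomial")
  expect_true(g$converged)
  expect_equal(g$n, 1000)
})
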