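# Small raw-record table with explicit values, for recode tests.
tiny_raw <- function(n = 6) {
  tibble::tibble(
    age_group = rep(c("30-44", "45-59", "60-74"), length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    education = rep(c("secondary", "post-secondary"), length.out = n),
    country_of_birth = rep(c("Canada", "other"), length.out = n),
    stress = rep(c("a bit stressful", "extremely stressful"),
                 length.out = n),
    belonging = rep(c("very strong", "somewhat weak"), length.out = n),
    living_arrangement = rep(c("individual living with spouse/partner",
                               "unattached individual living alone"),
                             length.out = n),
    household_income = rep(c(90000, 35000), length.out = n),
    dental_insurance = rep(c("yes", "no"), length.out = n),
    dwelling = rep(c("owned by member of household", "rented"),
                   length.out = n),
    bleeding_gums = rep(c("never", "sometimes"), length.out = n),
    perceived_oral_health = rep(c("excellent", "fair"), length.out = n),
    oral_pain = rep(c("rarely", "often"), length.out = n)
  )
}

# One-stratum scenario with the mid-age published joint PRs as truth.
belonging_truth_config <- function(n = 40000, seed = 1) {
  sim_config(
    n = setNames(n, "45-59"),
    modifier = "low_belonging",
    b0 = log(0.308),
    b_s = log(1.31), b_m = log(1.26),
    b_sm = log(1.79 / (1.31 * 1.26)),
    seed = seed
  )
}

# Simulate `reps` datasets under `make_config(seed)` and return per-replicate
# RERI estimates and delta-method interval coverage of `true_reri`.
simulate_reri <- function(make_config, reps, true_reri,
                          modifier = "low_belonging", stratum = NULL) {
  out <- purrr::map_dfr(seq_len(reps), function(r) {
    cfg <- make_config(r)
    d <- generate_records(cfg, raw = FALSE)
    jp <- joint_prs(d, modifier, stratum)
    ci <- reri_delta_ci(jp)
    tibble::tibble(
      reri = attr(ci, "reri"),
      covered = ci[1] <= true_reri && true_reri <= ci[2]
    )
  })
  out
}
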