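test_that("base-case cohorts reproduce the published event counts", {
  nb <- run_cohort(transition_matrix(base_no_boost()), 10000, 96)
  b <- run_cohort(transition_matrix(base_boost()), 10000, 96)
  k <- 97
  expect_equal(nb$cumulative_infections[[k]], 650)   # 10000 * 0.26 * 0.25
  expect_equal(b$cumulative_infections[[k]], 260)    # 10000 * 0.26 * 0.10
  expect_equal(nb$cumulative_infection_deaths[[k]], 650 * 0.125)
  ev <- averted_events(nb, b)
  expect_equal(ev$infections_averted, 390)
  expect_equal(ev$infection_deaths_averted, 48.75)
})

test_that("cohort mass is conserved and counters are monotone", {
  set.seed(23)
  for (i in 1:10) {
    split <- stats::runif(2); split <- split / max(1, sum(split))
    pars <- strategy_params(
      p_neutropenia = stats::runif(1),
      p_infection_given_neutropenia = split[1],
      p_recovery_given_neutropenia = split[2],
      p_infection_death = stats::runif(1),
      p_relapse_monthly = stats::runif(1),
      p_relapse_death_monthly = stats::runif(1))
    tr <- run_cohort(transition_matrix(pars), 10000, 48)
    expect_true(all(abs(rowSums(tr$occupancy) - 10000) <= 1e-6))
    for (ctr in c("cumulative_infections", "cumulative_infection_deaths",
                  "cumulative_relapse_deaths", "cumulative_relapses")) {
      expect_true(all(diff(tr[[ctr]]) >= -1e-12))
    }
    expect_lte(tr$cumulative_infection_deaths[[49]],
               tr$cumulative_infections[[49]] + 1e-12)
  }
})

test_that("inflow accounting agrees with an independent matrix-powering oracle", {
  pars <- strategy_params(p_recovery_given_neutropenia = 0.60,
                          p_infection_given_neutropenia = 0.15)
  P <- transition_matrix(pars)
  tr <- run_cohort(P, 10000, 96)
  for (st in c("infection", "death_infection", "death_relapse", "relapse")) {
    field <- switch(st, infection = "cumulative_infections",
                    death_infection = "cumulative_infection_deaths",
                    death_relapse = "cumulative_relapse_deaths",
                    relapse = "cumulative_relapses")
    expect_equal(tr[[field]][[97]],
                 cumulative_inflow_by_powering(unclass(P), 10000, 96, st))
  }
})

test_that("overall survival is 1 at baseline, closed-form without relapse deaths, and monotone", {
  tr <- run_cohort(transition_matrix(base_no_boost()), 10000, 96)
  expect_equal(overall_survival(tr, 0), 1)
  # only infection deaths when relapse mortality is switched off:
  # 1 - 0.26 * 0.25 * 0.125 once all episodes have resolved (by cycle 12)
  pars0 <- strategy_params(p_relapse_death_monthly = 0)
  tr0 <- run_cohort(transition_matrix(pars0), 10000, 96)
  expect_equal(overall_survival(tr0, 12), 1 - 0.26 * 0.25 * 0.125)
  os <- vapply(0:96, function(t) overall_survival(tr, t), numeric(1))
  expect_true(all(diff(os) <= 1e-15))
  expect_error(overall_survival(tr, 97), "cycle")
})

test_that("an absorbing initial state stays put with zero events", {
  tr <- run_cohort(transition_matrix(base_no_boost()), 500, 24,
                   initial_state = "death_relapse")
  expect_true(all(tr$occupancy[, "death_relapse"] == 500))
  expect_equal(max(tr$cumulative_infections), 0)
  expect_equal(max(tr$cumulative_relapses), 0)
  # survival reads the absorbing mass: everyone counted dead throughout
  expect_equal(overall_survival(tr, 24), 0)
})

test_that("infection count is linear in the infection probability under a zero-residual split", {
  probs <- seq(0.05, 0.30, by = 0.05)
  counts <- vapply(probs, function(p) {
    pars <- strategy_params(p_infection_given_neutropenia = p,
                            p_recovery_given_neutropenia = 1 - p)
    tr <- run_cohort(transition_matrix(pars), 10000, 96)
    tr$cumulative_infections[[97]]
  }, numeric(1))
  expect_equal(counts, 10000 * 0.26 * probs)
})

test_that("traces with mismatched cohorts or invalid inputs are rejected", {
  P <- transition_matrix(base_no_boost())
  a <- run_cohort(P, 1000, 12)
  b <- run_cohort(P, 2000, 12)
  expect_error(averted_events(a, b), "cohort size")
  expect_error(run_cohort(P, 1000, 0), "n_cycles")
  bad <- unclass(P); bad[1, 1] <- 0.5
  expect_error(run_cohort(bad, 1000, 12), "sums to")
})

test_that("trace data frame export carries occupancy and counters per cycle", {
  tr <- run_cohort(transition_matrix(base_no_boost()), 1000, 12)
  df <- as.data.frame(tr)
  expect_equal(nrow(df), 13)
  expect_true(all(c("cycle", health_states(), "cumulative_infections") %in%
                    names(df)))
  expect_equal(df$cumulative_infections[13], tr$cumulative_infections[[13]])
})
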