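test_that("base-case matrices encode the published state graph", {
  P <- transition_matrix(base_no_boost())
  expect_equal(P["car_t", "neutropenia"], 0.26)
  expect_equal(P["car_t", "recovery"], 0.74)
  # neutropenia resolves fully: 75% recover, 25% infected, no residual stay
  expect_equal(P["neutropenia", "recovery"], 0.75)
  expect_equal(P["neutropenia", "infection"], 0.25)
  expect_equal(P["neutropenia", "neutropenia"], 0)
  expect_equal(P["infection", "death_infection"], 0.125)
  expect_equal(P["infection", "recovery"], 0.875)
  expect_equal(P["recovery", "relapse"], 0.023)
  expect_equal(P["relapse", "death_relapse"], 0.03)

  B <- transition_matrix(base_boost())
  expect_equal(B["neutropenia", "recovery"], 0.90)
  expect_equal(B["neutropenia", "infection"], 0.10)
  # the arms differ only in the neutropenia row
  keep <- setdiff(health_states(), "neutropenia")
  expect_identical(unclass(P)[keep, ], unclass(B)[keep, ])
})

test_that("rows are stochastic to 1e-12 and death states absorbing, across parameter draws", {
  set.seed(11)
  for (i in 1:50) {
    split <- stats::runif(2)
    split <- split / max(1, sum(split))     # consistent pair
    pars <- strategy_params(
      p_neutropenia = stats::runif(1),
      p_infection_given_neutropenia = split[1],
      p_recovery_given_neutropenia = split[2],
      p_infection_death = stats::runif(1),
      p_relapse_monthly = stats::runif(1),
      p_relapse_death_monthly = stats::runif(1)
    )
    P <- unclass(transition_matrix(pars))
    expect_true(all(abs(rowSums(P) - 1) <= 1e-12))
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(P["death_infection", "death_infection"], 1)
    expect_equal(P["death_relapse", "death_relapse"], 1)
    # absorbing persistence: death mass non-decreasing under repeated application
    occ <- c(1, 0, 0, 0, 0, 0, 0)
    dead_prev <- 0
    for (t in 1:20) {
      occ <- drop(occ %*% P)
      dead <- occ[6] + occ[7]
      expect_gte(dead, dead_prev - 1e-15)
      dead_prev <- dead
    }
  }
})

test_that("a stress draw leaves residual neutropenia mass", {
  pars <- strategy_params(p_recovery_given_neutropenia = 0.60,
                          p_infection_given_neutropenia = 0.15)
  P <- transition_matrix(pars)
  expect_equal(P["neutropenia", "neutropenia"], 0.25)  # 1 - 0.60 - 0.15
  expect_equal(P["neutropenia", "recovery"], 0.60)
  expect_equal(P["neutropenia", "infection"], 0.15)
})

test_that("zero event probabilities give a deathless chain", {
  pars <- strategy_params(p_neutropenia = 0, p_infection_given_neutropenia = 0,
                          p_recovery_given_neutropenia = 1,
                          p_infection_death = 0, p_relapse_monthly = 0,
                          p_relapse_death_monthly = 0)
  P <- transition_matrix(pars)
  expect_equal(P["car_t", "recovery"], 1)
  expect_equal(P["recovery", "recovery"], 1)
  expect_equal(P["relapse", "relapse"], 1)
  tr <- run_cohort(P, 100, 24)
  expect_equal(overall_survival(tr, 24), 1)
})

test_that("an inconsistent neutropenia split errors unless renormalized", {
  pars <- strategy_params(p_infection_given_neutropenia = 0.6,
                          p_recovery_given_neutropenia = 0.7)
  expect_error(transition_matrix(pars), "p_infection_given_neutropenia")
  P <- transition_matrix(pars, renormalize = TRUE)
  expect_equal(P["neutropenia", "infection"], 0.6 / 1.3)
  expect_equal(P["neutropenia", "recovery"], 0.7 / 1.3)
  expect_equal(P["neutropenia", "neutropenia"], 0)
  expect_true(all(abs(rowSums(unclass(P)) - 1) <= 1e-12))
})

test_that("probabilities outside [0, 1] are rejected at construction", {
  expect_error(strategy_params(p_neutropenia = -0.1), "probability")
  expect_error(strategy_params(p_relapse_monthly = 1.2), "probability")
  expect_error(cost_params(hospitalization_cost_usd = -1), "non-negative")
})

test_that("matrix CSV export round-trips values and labels", {
  f <- withr::local_tempfile(fileext = ".csv")
  P <- transition_matrix(base_no_boost())
  write_transition_matrix(P, f)
  back <- utils::read.csv(f, row.names = 1)
  expect_identical(rownames(back), health_states())
  expect_identical(colnames(back), health_states())
  expect_equal(as.matrix(back), unclass(P), ignore_attr = TRUE)
})
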