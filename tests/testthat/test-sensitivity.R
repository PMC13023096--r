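test_that("one-way DSA ranges match analytic linearity in the cost inputs", {
  d <- run_dsa()
  df <- as.data.frame(d)
  # reserve cost is charged one-for-one to every boost patient
  expect_equal(df$range[df$parameter == "reserve_cost"], 4000)
  # hospitalization acts through the 390-infection difference per 10,000
  expect_equal(df$range[df$parameter == "hospitalization_cost"],
               (390 / 10000) * 8000)
  # neutropenia splits act through 0.26 * delta-p * cost per 10,000 patients
  expect_equal(df$range[df$parameter == "noboost_neutropenia_split"],
               0.26 * 0.10 * 64012, tolerance = 1e-9)
  # sorted descending by range, ties alphabetical
  expect_true(all(diff(df$range) <= 1e-9))
  tied <- df$parameter[abs(df$range - max(df$range[df$range < max(df$range)])) < 1e-9]
  expect_equal(tied, sort(tied))
})

test_that("the boost arm stays costlier with fewer infections across the whole DSA grid", {
  d <- run_dsa()
  expect_true(all(as.data.frame(d)$direction_preserved))
  cells <- attr(d, "cells")
  expect_equal(nrow(cells), 3 * 3 * 3 * 3)
  expect_true(all(cells$incremental > 0))
  expect_true(all(cells$infections_boost < cells$infections_noboost))
})

test_that("a degenerate grid pinned at base case yields zero ranges", {
  grid <- list(
    noboost_neutropenia_split = list(recovery = 0.75, infection = 0.25),
    boost_neutropenia_split = list(recovery = 0.90, infection = 0.10),
    hospitalization_cost = 64012,
    reserve_cost = 17918
  )
  d <- run_dsa(grid = grid)
  expect_equal(as.data.frame(d)$range, rep(0, 4))
})

test_that("non-complementary DSA split pairs are rejected", {
  grid <- dsa_grid_default()
  grid$noboost_neutropenia_split$infection <- c(0.28, 0.25, 0.20)
  expect_error(run_dsa(grid = grid), "complementary")
})

test_that("stress-test draws stay in range, are seed-reproducible, and favor no-boost", {
  psa <- run_psa(n_draws = 500, seed = 101)
  r <- psa_ranges_default()
  for (nm in names(r)) {
    expect_true(all(psa$draws[[nm]] >= r[[nm]][1] & psa$draws[[nm]] <= r[[nm]][2]))
  }
  expect_identical(psa$draws, run_psa(n_draws = 500, seed = 101)$draws)
  expect_gt(psa$fraction_positive, 0.95)
  expect_equal(psa$draws$savings, -psa$draws$incremental)
  # stability across seeds: fraction within 2/500 of the first seed's value
  f2 <- run_psa(n_draws = 500, seed = 202)$fraction_positive
  expect_lte(abs(f2 - psa$fraction_positive), 2 / 500)
})

test_that("point ranges reproduce the base case and inverted ranges error", {
  point <- list(nb_recovery = c(0.75, 0.75), nb_infection = c(0.25, 0.25),
                b_recovery = c(0.90, 0.90), b_infection = c(0.10, 0.10),
                hosp_cost = c(64012, 64012), reserve_cost = c(17918, 17918))
  psa <- run_psa(point, n_draws = 10, seed = 1)
  base_inc <- 17918 + (260 - 650) * 64012 / 10000
  expect_equal(psa$draws$incremental, rep(base_inc, 10))
  bad <- psa_ranges_default(); bad$hosp_cost <- c(70000, 50000)
  expect_error(run_psa(bad, n_draws = 5, seed = 1), "degenerate")
})

test_that("key-driver slopes match analytic partial derivatives on targeted draw sets", {
  # vary only hospitalization cost: savings slope = (650 - 260) / 10,000
  hosp_only <- list(nb_recovery = c(0.75, 0.75), nb_infection = c(0.25, 0.25),
                    b_recovery = c(0.90, 0.90), b_infection = c(0.10, 0.10),
                    hosp_cost = c(50000, 70000),
                    reserve_cost = c(17918, 17918))
  kd <- suppressWarnings(
    key_driver_regression(run_psa(hosp_only, n_draws = 50, seed = 8)))
  expect_equal(kd$coefficient[kd$parameter == "hosp_cost"], 0.039,
               tolerance = 1e-9)
  # vary only reserve cost: each reserve dollar reduces savings by a dollar
  res_only <- hosp_only
  res_only$hosp_cost <- c(64012, 64012)
  res_only$reserve_cost <- c(14000, 22000)
  kd2 <- suppressWarnings(
    key_driver_regression(run_psa(res_only, n_draws = 50, seed = 8)))
  expect_equal(kd2$coefficient[kd2$parameter == "reserve_cost"], -1,
               tolerance = 1e-9)
})

test_that("key-driver signs on full draws are as the economics dictates", {
  kd <- key_driver_regression(run_psa(n_draws = 300, seed = 55))
  co <- function(p) kd$coefficient[kd$parameter == p]
  expect_gt(co("hosp_cost"), 0)
  expect_lt(co("reserve_cost"), 0)
  expect_gt(co("nb_infection"), 0)
  expect_lt(co("b_infection"), 0)
  expect_equal(kd$rank, seq_len(nrow(kd)))
  expect_true(all(diff(abs(kd$standardized)) <= 1e-12))
})

test_that("degenerate regression designs are refused or reduced with a warning", {
  point <- list(nb_recovery = c(0.75, 0.75), nb_infection = c(0.25, 0.25),
                b_recovery = c(0.90, 0.90), b_infection = c(0.10, 0.10),
                hosp_cost = c(64012, 64012), reserve_cost = c(17918, 17918))
  psa <- run_psa(point, n_draws = 10, seed = 2)
  expect_error(key_driver_regression(psa), "constant")
  partial <- point; partial$hosp_cost <- c(50000, 70000)
  expect_warning(kd <- key_driver_regression(run_psa(partial, n_draws = 10, seed = 2)),
                 "dropping constant")
  expect_equal(kd$parameter, "hosp_cost")
})
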