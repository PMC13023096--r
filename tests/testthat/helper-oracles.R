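# Independent oracles used across test files.

# Probability that a patient ever develops a severe infection, by
# enumerating the episode tree: neutropenia, then a geometric number of
# "stay" cycles before the episode resolves to infection or recovery.
infection_prob_by_enumeration <- function(p_neut, p_inf, p_rec,
                                          max_stay = 500) {
  p_stay <- 1 - p_inf - p_rec
  p_neut * sum(p_stay^(0:max_stay) * p_inf)
}

# Expected cumulative event counts by brute-force matrix powering,
# independent of the package's inflow accounting.
cumulative_inflow_by_powering <- function(P, n_patients, n_cycles,
                                          into, start = "car_t") {
  s <- boostcea::health_states()
  occ <- setNames(numeric(7), s)
  occ[start] <- n_patients
  total <- 0
  for (t in seq_len(n_cycles)) {
    total <- total + sum(occ[s != into] * P[s != into, into])
    occ <- drop(occ %*% P)
  }
  total
}

base_no_boost <- function() strategy_params()
base_boost <- function() strategy_params(boost_available = TRUE)
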