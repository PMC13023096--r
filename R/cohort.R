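#' Propagate a cohort through the Markov model
#'
#' Deterministic cohort propagation: the expected state occupancy is
#' multiplied through the transition matrix once per monthly cycle. Events
#' are counted as expected inflows — occupancy mass moving into a state
#' from a different state during the cycle — so the one-cycle infection
#' state contributes exactly one event per episode, and no half-cycle
#' correction is applied (counts are of events, not person-time).
#'
#' @param P A [transition_matrix()] (or a matrix passing
#'   [validate_transition_matrix()]).
#' @param n_patients Cohort size (> 0; expected counts scale linearly).
#' @param n_cycles Number of monthly cycles (>= 1); the base case is 96
#'   (8 years).
#' @param initial_state State holding the whole cohort at cycle 0;
#'   `"car_t"` by default.
#' @return An object of class `cohort_trace`: a list with `occupancy`
#'   (a `(n_cycles + 1) x 7` matrix of expected counts, rows `cycle0` ...),
#'   per-cycle cumulative event counters `cumulative_infections`,
#'   `cumulative_infection_deaths`, `cumulative_relapse_deaths`,
#'   `cumulative_relapses` (each a vector over cycles 0..n_cycles),
#'   `n_patients` and `n_cycles`.
#' @export
#' @examples
#' P <- transition_matrix(strategy_params())
#' tr <- run_cohort(P, n_patients = 10000, n_cycles = 96)
#' max(tr$cumulative_infections)   # 650 expected severe infections
run_cohort <- function(P, n_patients = 10000, n_cycles = 96,
                       initial_state = "car_t") {
  validate_transition_matrix(unclass(P))
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients <= 0) {
    stop("n_patients must be a positive number", call. = FALSE)
  }
  if (!is.numeric(n_cycles) || length(n_cycles) != 1L || n_cycles < 1) {
    stop("n_cycles must be at least 1", call. = FALSE)
  }
  n_cycles <- as.integer(n_cycles)
  s <- health_states()
  initial_state <- match.arg(initial_state, s)
  P <- unclass(P)

  occ <- matrix(0, n_cycles + 1L, 7L,
                dimnames = list(paste0("cycle", 0:n_cycles), s))
  occ[1L, initial_state] <- n_patients

  # inflow into state j at cycle t+1: mass arriving from other states
  counted <- c(infections = "infection",
               infection_deaths = "death_infection",
               relapse_deaths = "death_relapse",
               relapses = "relapse")
  cum <- matrix(0, n_cycles + 1L, length(counted),
                dimnames = list(NULL, names(counted)))
  for (t in seq_len(n_cycles)) {
    prev <- occ[t, ]
    occ[t + 1L, ] <- prev %*% P
    inflow <- vapply(counted, function(j) {
      sum(prev[s != j] * P[s != j, j])
    }, numeric(1))
    cum[t + 1L, ] <- cum[t, ] + inflow
  }

  structure(list(
    occupancy = occ,
    cumulative_infections = cum[, "infections"],
    cumulative_infection_deaths = cum[, "infection_deaths"],
    cumulative_relapse_deaths = cum[, "relapse_deaths"],
    cumulative_relapses = cum[, "relapses"],
    n_patients = n_patients,
    n_cycles = n_cycles
  ), class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  k <- x$n_cycles + 1L
  cat(sprintf("Cohort trace: %s patients, %d monthly cycles\n",
              format(x$n_patients, big.mark = ","), x$n_cycles))
  cat(sprintf("  cumulative severe infections   %10.2f\n",
              x$cumulative_infections[k]))
  cat(sprintf("  cumulative infection deaths    %10.2f\n",
              x$cumulative_infection_deaths[k]))
  cat(sprintf("  cumulative relapses            %10.2f\n",
              x$cumulative_relapses[k]))
  cat(sprintf("  cumulative relapse deaths      %10.2f\n",
              x$cumulative_relapse_deaths[k]))
  cat(sprintf("  overall survival at end        %10.4f\n",
              overall_survival(x, x$n_cycles)))
  invisible(x)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  data.frame(cycle = 0:x$n_cycles,
             unclass(x$occupancy),
             cumulative_infections = x$cumulative_infections,
             cumulative_infection_deaths = x$cumulative_infection_deaths,
             cumulative_relapses = x$cumulative_relapses,
             cumulative_relapse_deaths = x$cumulative_relapse_deaths,
             row.names = NULL)
}

#' Overall survival at a given cycle
#'
#' One minus the fraction of the cohort in either absorbing death state.
#'
#' @param trace A [run_cohort()] result.
#' @param cycle Cycle index in `0:n_cycles`.
#' @return Survival fraction in \[0, 1\]; non-increasing in `cycle`.
#' @export
#' @examples
#' tr <- run_cohort(transition_matrix(strategy_params()))
#' overall_survival(tr, 12)
overall_survival <- function(trace, cycle) {
  stopifnot(inherits(trace, "cohort_trace"))
  if (!is.numeric(cycle) || length(cycle) != 1L || cycle < 0 ||
      cycle > trace$n_cycles) {
    stop(sprintf("cycle must lie in 0..%d", trace$n_cycles), call. = FALSE)
  }
  dead <- sum(trace$occupancy[cycle + 1L, absorbing_states()])
  1 - dead / trace$n_patients
}

#' Events averted by the boost strategy
#'
#' Differences in cumulative expected events, no-boost minus boost.
#'
#' @param trace_noboost,trace_boost [run_cohort()] results for the two arms
#'   with identical cohort size and horizon.
#' @return A list with `infections_averted`, `infection_deaths_averted` and
#'   `relapse_deaths_averted`.
#' @export
#' @examples
#' nb <- run_cohort(transition_matrix(strategy_params()))
#' b  <- run_cohort(transition_matrix(strategy_params(boost_available = TRUE)))
#' averted_events(nb, b)   # 390 infections, 48.75 infection deaths
averted_events <- function(trace_noboost, trace_boost) {
  stopifnot(inherits(trace_noboost, "cohort_trace"),
            inherits(trace_boost, "cohort_trace"))
  if (trace_noboost$n_patients != trace_boost$n_patients ||
      trace_noboost$n_cycles != trace_boost$n_cycles) {
    stop("traces must share cohort size and horizon", call. = FALSE)
  }
  k <- trace_noboost$n_cycles + 1L
  list(
    infections_averted = trace_noboost$cumulative_infections[[k]] -
      trace_boost$cumulative_infections[[k]],
    infection_deaths_averted = trace_noboost$cumulative_infection_deaths[[k]] -
      trace_boost$cumulative_infection_deaths[[k]],
    relapse_deaths_averted = trace_noboost$cumulative_relapse_deaths[[k]] -
      trace_boost$cumulative_relapse_deaths[[k]]
  )
}
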