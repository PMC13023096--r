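#' Simulate individual patient trajectories
#'
#' Seeded microsimulation through the same state graph as [run_cohort()]:
#' each patient starts in CAR T and advances each cycle by sampling the
#' current state's transition-matrix row. All randomness comes from a
#' single user-supplied seed; the per-patient, per-cycle uniform draws are
#' laid out as a matrix generated in one pass, so each patient owns a
#' deterministic substream and results do not depend on iteration order.
#' Identical seed and parameters give bit-identical output.
#'
#' @param params A [strategy_params()] object.
#' @param n_patients Number of simulated patients.
#' @param n_cycles Number of monthly cycles.
#' @param seed Integer seed; required (no hidden global randomness — the
#'   caller's RNG state is restored on exit).
#' @param costs Optional [cost_params()]; when supplied, per-patient
#'   accrued cost is computed (hospitalization per infection episode plus
#'   the reserve charge in the boost arm).
#' @param keep_trajectories Keep the full `n_patients x (n_cycles + 1)`
#'   state matrix (memory guard; aggregates are always produced).
#' @param renormalize Passed to [transition_matrix()].
#' @return An object of class `microsim_result`: per-patient data frame
#'   `patients` (final state, event flags `had_infection`,
#'   `died_of_infection`, `relapsed`, `died_of_relapse`, `cost`), aggregate
#'   counters named as in `cohort_trace` (`cumulative_infections` etc.,
#'   totals over the horizon), `n_patients`, `n_cycles`, `seed`, and
#'   optionally `trajectories` (states coded by [health_states()] index).
#' @export
#' @examples
#' ms <- simulate_patients(strategy_params(), n_patients = 500,
#'                         n_cycles = 24, seed = 1)
#' ms$cumulative_infections
simulate_patients <- function(params, n_patients, n_cycles, seed,
                              costs = NULL, keep_trajectories = FALSE,
                              renormalize = FALSE) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("an explicit integer seed is required", call. = FALSE)
  }
  stopifnot(n_patients >= 1, n_cycles >= 1)
  n_patients <- as.integer(n_patients)
  n_cycles <- as.integer(n_cycles)
  P <- transition_matrix(params, renormalize = renormalize)
  s <- health_states()
  cumP <- t(apply(unclass(P), 1L, cumsum))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  # patient i's substream is row i; filled column-minor by matrix() so the
  # layout is fixed by (i, t), not by loop order
  U <- matrix(stats::runif(n_patients * n_cycles), n_patients, n_cycles)

  state <- rep.int(1L, n_patients)                 # all start in car_t
  traj <- if (keep_trajectories) {
    m <- matrix(1L, n_patients, n_cycles + 1L)
    m
  } else NULL
  had_infection <- logical(n_patients)
  relapsed <- logical(n_patients)

  for (t in seq_len(n_cycles)) {
    u <- U[, t]
    nxt <- state
    for (from in which(tabulate(state, 7L) > 0L)) {
      idx <- which(state == from)
      nxt[idx] <- findInterval(u[idx], cumP[from, ], left.open = TRUE) + 1L
    }
    had_infection <- had_infection | (nxt == 3L & state != 3L)
    relapsed <- relapsed | (nxt == 5L & state != 5L)
    state <- nxt
    if (keep_trajectories) traj[, t + 1L] <- state
  }

  died_of_infection <- state == 6L
  died_of_relapse <- state == 7L
  cost <- patient_costs(costs, params, had_infection, n_patients)
  patients <- data.frame(
    patient = seq_len(n_patients),
    final_state = s[state],
    had_infection = had_infection,
    died_of_infection = died_of_infection,
    relapsed = relapsed,
    died_of_relapse = died_of_relapse,
    cost = cost
  )
  out <- list(
    patients = patients,
    cumulative_infections = sum(had_infection),
    cumulative_infection_deaths = sum(died_of_infection),
    cumulative_relapses = sum(relapsed),
    cumulative_relapse_deaths = sum(died_of_relapse),
    n_patients = n_patients,
    n_cycles = n_cycles,
    seed = as.integer(seed)
  )
  if (keep_trajectories) out$trajectories <- traj
  structure(out, class = "microsim_result")
}

patient_costs <- function(costs, params, had_infection, n_patients) {
  if (is.null(costs)) return(rep(0, n_patients))
  stopifnot(inherits(costs, "cost_params"))
  had_infection * costs$hospitalization_cost_usd +
    if (params$boost_available) costs$reserve_collection_cost_usd else 0
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf("Microsimulation: %s patients, %d cycles (seed %d)\n",
              format(x$n_patients, big.mark = ","), x$n_cycles, x$seed))
  cat(sprintf("  severe infections  %d\n", x$cumulative_infections))
  cat(sprintf("  infection deaths   %d\n", x$cumulative_infection_deaths))
  cat(sprintf("  relapses           %d\n", x$cumulative_relapses))
  cat(sprintf("  relapse deaths     %d\n", x$cumulative_relapse_deaths))
  invisible(x)
}

#' @export
as.data.frame.microsim_result <- function(x, ...) x$patients
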