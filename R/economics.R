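#' Accumulate costs for one strategy arm
#'
#' The infection component is the cumulative expected number of severe
#' infections multiplied by the hospitalization cost, spread over the
#' cohort; the reserve component is the per-patient collection cost,
#' charged once at cycle 0 to every boost-arm patient (zero in the
#' no-boost arm). No discounting is applied.
#'
#' @param trace A [run_cohort()] result.
#' @param costs A [cost_params()] object.
#' @param boost_available Logical; charge the universal reserve cost.
#' @param strategy Label for reporting (defaults from `boost_available`).
#' @return An object of class `econ_summary` with per-patient cost
#'   components, per-patient total, cohort total, cohort size and label.
#' @export
#' @examples
#' tr <- run_cohort(transition_matrix(strategy_params()))
#' accumulate_costs(tr, cost_params(), boost_available = FALSE)
accumulate_costs <- function(trace, costs, boost_available,
                             strategy = if (boost_available) "boost" else "no_boost") {
  stopifnot(inherits(trace, "cohort_trace"), inherits(costs, "cost_params"),
            is.logical(boost_available), length(boost_available) == 1L)
  infections <- trace$cumulative_infections[[trace$n_cycles + 1L]]
  infection_pp <- infections * costs$hospitalization_cost_usd / trace$n_patients
  reserve_pp <- if (boost_available) costs$reserve_collection_cost_usd else 0
  total_pp <- infection_pp + reserve_pp
  structure(list(
    strategy = strategy,
    infection_hospitalization_cost_per_patient = infection_pp,
    reserve_cost_per_patient = reserve_pp,
    total_cost_per_patient = total_pp,
    total_cohort_cost = total_pp * trace$n_patients,
    n_patients = trace$n_patients
  ), class = "econ_summary")
}

#' @export
print.econ_summary <- function(x, ...) {
  cat(sprintf("Cost summary, %s arm (USD per patient)\n", x$strategy))
  cat(sprintf("  infection hospitalization %12.2f\n",
              x$infection_hospitalization_cost_per_patient))
  cat(sprintf("  reserve collection        %12.2f\n", x$reserve_cost_per_patient))
  cat(sprintf("  total                     %12.2f\n", x$total_cost_per_patient))
  invisible(x)
}

#' Incremental per-patient cost of the boost strategy
#'
#' Boost minus no-boost total per-patient cost; positive when universal
#' reserve collection is costlier than the hospitalizations it avoids.
#'
#' @param boost,noboost [accumulate_costs()] summaries for the two arms,
#'   from cohorts of the same size.
#' @return Incremental cost in USD per patient.
#' @export
incremental_cost <- function(boost, noboost) {
  stopifnot(inherits(boost, "econ_summary"), inherits(noboost, "econ_summary"))
  if (boost$n_patients != noboost$n_patients) {
    stop("summaries must come from cohorts of the same size", call. = FALSE)
  }
  boost$total_cost_per_patient - noboost$total_cost_per_patient
}

#' Cost breakdown table
#'
#' One row per strategy with reserve, infection and total per-patient
#' costs — the stacked-bar decomposition, ready for CSV export.
#'
#' @param ... `econ_summary` objects.
#' @return A data frame with columns `strategy`, `reserve`, `infection`,
#'   `total`.
#' @export
cost_breakdown <- function(...) {
  xs <- list(...)
  stopifnot(all(vapply(xs, inherits, logical(1), "econ_summary")))
  data.frame(
    strategy = vapply(xs, `[[`, character(1), "strategy"),
    reserve = vapply(xs, `[[`, numeric(1), "reserve_cost_per_patient"),
    infection = vapply(xs, `[[`, numeric(1),
                       "infection_hospitalization_cost_per_patient"),
    total = vapply(xs, `[[`, numeric(1), "total_cost_per_patient")
  )
}
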