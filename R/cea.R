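#' Evaluate the boost versus no-boost cost-effectiveness model
#'
#' The package's central function: builds the transition matrix for each
#' strategy arm, propagates a cohort through both, accumulates costs, and
#' returns a classed object holding the full comparison. `print` and
#' `summary` report the headline numbers (infections per arm, deaths
#' averted, per-patient and incremental costs), `plot` draws the overall
#' survival trajectories or the cost decomposition, and `simulate` runs the
#' seeded microsimulation under the fitted parameters.
#'
#' @param no_boost,boost [strategy_params()] for the two arms.
#' @param costs A [cost_params()] object.
#' @param n_patients Cohort size (default 10,000).
#' @param n_cycles Monthly cycles (default 96, an 8-year horizon).
#' @return An object of class `boost_cea` with components `params`
#'   (both arms), `costs`, `traces` (both `cohort_trace`s), `economics`
#'   (both `econ_summary`s), `incremental_cost`, `events`
#'   (from [averted_events()]), `n_patients`, `n_cycles`.
#' @seealso [run_dsa()], [run_psa()], [calibrate_relapse_mortality()]
#' @export
#' @examples
#' fit <- boost_cea()
#' fit
#' summary(fit)
boost_cea <- function(no_boost = strategy_params(),
                      boost = strategy_params(boost_available = TRUE),
                      costs = cost_params(),
                      n_patients = 10000, n_cycles = 96) {
  stopifnot(inherits(no_boost, "strategy_params"),
            inherits(boost, "strategy_params"),
            inherits(costs, "cost_params"))
  tr_nb <- run_cohort(transition_matrix(no_boost), n_patients, n_cycles)
  tr_b <- run_cohort(transition_matrix(boost), n_patients, n_cycles)
  ec_nb <- accumulate_costs(tr_nb, costs, boost_available = FALSE)
  ec_b <- accumulate_costs(tr_b, costs, boost_available = TRUE)
  structure(list(
    params = list(no_boost = no_boost, boost = boost),
    costs = costs,
    traces = list(no_boost = tr_nb, boost = tr_b),
    economics = list(no_boost = ec_nb, boost = ec_b),
    incremental_cost = incremental_cost(ec_b, ec_nb),
    events = averted_events(tr_nb, tr_b),
    n_patients = n_patients,
    n_cycles = n_cycles
  ), class = "boost_cea")
}

#' @export
print.boost_cea <- function(x, ...) {
  k <- x$n_cycles + 1L
  cat("Stem-cell boost cost-effectiveness model\n")
  cat(sprintf("  cohort: %s patients over %d monthly cycles\n\n",
              format(x$n_patients, big.mark = ","), x$n_cycles))
  cat(sprintf("  severe infections:  %8.2f (no-boost)  %8.2f (boost)\n",
              x$traces$no_boost$cumulative_infections[k],
              x$traces$boost$cumulative_infections[k]))
  cat(sprintf("  infection deaths:   %8.2f (no-boost)  %8.2f (boost)\n",
              x$traces$no_boost$cumulative_infection_deaths[k],
              x$traces$boost$cumulative_infection_deaths[k]))
  cat(sprintf("  deaths averted by boost: %.2f\n\n",
              x$events$infection_deaths_averted))
  cat(sprintf("  cost per patient:   %8.2f (no-boost)  %8.2f (boost) USD\n",
              x$economics$no_boost$total_cost_per_patient,
              x$economics$boost$total_cost_per_patient))
  cat(sprintf("  incremental cost (boost - no-boost): %.2f USD/patient\n",
              x$incremental_cost))
  invisible(x)
}

#' @export
summary.boost_cea <- function(object, ...) {
  k <- object$n_cycles + 1L
  tab <- data.frame(
    strategy = c("no_boost", "boost"),
    infections = c(object$traces$no_boost$cumulative_infections[k],
                   object$traces$boost$cumulative_infections[k]),
    infection_deaths = c(object$traces$no_boost$cumulative_infection_deaths[k],
                         object$traces$boost$cumulative_infection_deaths[k]),
    relapse_deaths = c(object$traces$no_boost$cumulative_relapse_deaths[k],
                       object$traces$boost$cumulative_relapse_deaths[k]),
    os_12m = c(overall_survival(object$traces$no_boost, min(12, object$n_cycles)),
               overall_survival(object$traces$boost, min(12, object$n_cycles))),
    os_final = c(overall_survival(object$traces$no_boost, object$n_cycles),
                 overall_survival(object$traces$boost, object$n_cycles)),
    cost_per_patient = c(object$economics$no_boost$total_cost_per_patient,
                         object$economics$boost$total_cost_per_patient)
  )
  structure(list(table = tab,
                 incremental_cost = object$incremental_cost,
                 events = object$events,
                 n_patients = object$n_patients,
                 n_cycles = object$n_cycles),
            class = "summary.boost_cea")
}

#' @export
print.summary.boost_cea <- function(x, ...) {
  cat(sprintf("Cohort of %s patients, %d monthly cycles\n\n",
              format(x$n_patients, big.mark = ","), x$n_cycles))
  print(x$table, row.names = FALSE, digits = 6)
  cat(sprintf("\nInfections averted: %.2f; infection deaths averted: %.2f\n",
              x$events$infections_averted, x$events$infection_deaths_averted))
  cat(sprintf("Incremental cost (boost - no-boost): %.2f USD/patient\n",
              x$incremental_cost))
  invisible(x)
}

#' @param type `"survival"` for overall-survival trajectories of both arms,
#'   `"costs"` for the stacked per-patient cost decomposition.
#' @rdname boost_cea
#' @export
plot.boost_cea <- function(x, type = c("survival", "costs"), ...) {
  type <- match.arg(type)
  if (type == "survival") {
    cyc <- 0:x$n_cycles
    os_nb <- vapply(cyc, function(t) overall_survival(x$traces$no_boost, t),
                    numeric(1))
    os_b <- vapply(cyc, function(t) overall_survival(x$traces$boost, t),
                   numeric(1))
    graphics::plot(cyc, os_nb, type = "l", ylim = c(0, 1), lwd = 2,
                   xlab = "Month", ylab = "Overall survival",
                   main = "Overall survival by strategy", ...)
    graphics::lines(cyc, os_b, col = "steelblue", lwd = 2, lty = 2)
    graphics::legend("bottomleft", c("no boost", "boost"),
                     col = c("black", "steelblue"), lty = c(1, 2), lwd = 2)
  } else {
    bd <- cost_breakdown(x$economics$no_boost, x$economics$boost)
    graphics::barplot(t(as.matrix(bd[, c("infection", "reserve")])),
                      names.arg = bd$strategy,
                      legend.text = c("infection hospitalization", "reserve collection"),
                      ylab = "USD per patient",
                      main = "Per-patient cost decomposition", ...)
  }
  invisible(x)
}

#' Simulate patient-level trajectories from a fitted model
#'
#' Runs the seeded microsimulation ([simulate_patients()]) for each arm of
#' a [boost_cea()] object.
#'
#' @param object A `boost_cea` object.
#' @param nsim Number of patients to simulate (defaults to the object's
#'   cohort size).
#' @param seed Integer seed; required.
#' @param ... Passed to [simulate_patients()].
#' @return A list with `microsim_result`s `no_boost` and `boost` (the boost
#'   arm uses `seed + 1` so the arms are independent).
#' @export
simulate.boost_cea <- function(object, nsim = object$n_patients, seed, ...) {
  if (missing(seed)) stop("an explicit integer seed is required", call. = FALSE)
  list(
    no_boost = simulate_patients(object$params$no_boost, nsim,
                                 object$n_cycles, seed = seed,
                                 costs = object$costs, ...),
    boost = simulate_patients(object$params$boost, nsim,
                              object$n_cycles, seed = seed + 1,
                              costs = object$costs, ...)
  )
}
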