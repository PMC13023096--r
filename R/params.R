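#' Health states of the model
#'
#' Returns the fixed, documented ordering of the seven health states. The
#' two death states are cause-split absorbing states (infection-related
#' versus relapse-related death); their sum defines overall mortality.
#'
#' @return Character vector of the seven state labels, in matrix order:
#'   `car_t`, `neutropenia`, `infection`, `recovery`, `relapse`,
#'   `death_infection`, `death_relapse`.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("car_t", "neutropenia", "infection", "recovery", "relapse",
    "death_infection", "death_relapse")
}

# states with no outgoing transitions
absorbing_states <- function() c("death_infection", "death_relapse")

#' Per-cycle transition probabilities for one strategy arm
#'
#' Bundles the six per-cycle (monthly) transition probabilities that define
#' one arm of the model. Defaults are the base case: prolonged grade 3-4
#' neutropenia occurs in 26% of CAR T recipients; among neutropenic
#' patients the no-boost arm recovers in 75% and develops a severe
#' infection in 25%, while the boost arm recovers in 90% and is infected in
#' 10%; severe infection carries a 12.5% case fatality; recovered patients
#' relapse at 2.3% per month and relapsing patients die at 3% per month.
#'
#' @param p_neutropenia Probability of prolonged neutropenia after CAR T
#'   (first cycle only; the remainder move directly to recovery).
#' @param p_infection_given_neutropenia Per-cycle probability that a
#'   neutropenic patient develops a severe infection.
#' @param p_recovery_given_neutropenia Per-cycle probability that a
#'   neutropenic patient recovers. Any residual mass
#'   (1 - infection - recovery) remains neutropenic; it is zero in the
#'   base case.
#' @param p_infection_death Case fatality of a severe infection (death in
#'   the cycle after infection onset; survivors return to recovery).
#' @param p_relapse_monthly Monthly relapse probability from recovery.
#' @param p_relapse_death_monthly Monthly relapse-related mortality.
#' @param boost_available Logical; selects the arm. Affects the defaults of
#'   the neutropenia split and whether the reserve-collection cost is
#'   charged (see [accumulate_costs()]); the model structure is identical.
#'
#' @return An object of class `strategy_params` (named list).
#' @seealso [transition_matrix()], [boost_cea()]
#' @export
#' @examples
#' strategy_params()                       # no-boost base case
#' strategy_params(boost_available = TRUE) # boost base case
strategy_params <- function(p_neutropenia = 0.26,
                            p_infection_given_neutropenia = if (boost_available) 0.10 else 0.25,
                            p_recovery_given_neutropenia = if (boost_available) 0.90 else 0.75,
                            p_infection_death = 0.125,
                            p_relapse_monthly = 0.023,
                            p_relapse_death_monthly = 0.03,
                            boost_available = FALSE) {
  stopifnot(is.logical(boost_available), length(boost_available) == 1L)
  p <- list(
    p_neutropenia = p_neutropenia,
    p_infection_given_neutropenia = p_infection_given_neutropenia,
    p_recovery_given_neutropenia = p_recovery_given_neutropenia,
    p_infection_death = p_infection_death,
    p_relapse_monthly = p_relapse_monthly,
    p_relapse_death_monthly = p_relapse_death_monthly,
    boost_available = boost_available
  )
  for (nm in setdiff(names(p), "boost_available")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("'%s' must be a single probability in [0, 1], got %s",
                   nm, format(v)), call. = FALSE)
    }
  }
  structure(p, class = "strategy_params")
}

#' @export
print.strategy_params <- function(x, ...) {
  cat(sprintf("Strategy parameters (%s arm)\n",
              if (x$boost_available) "boost" else "no-boost"))
  for (nm in setdiff(names(x), "boost_available")) {
    cat(sprintf("  %-32s %.4f\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' Cost inputs
#'
#' Hospitalization cost per severe-infection admission (2024 USD) and the
#' per-patient cost of collecting and storing an extra stem-cell reserve
#' (2025 USD). The reserve cost is charged once, at cycle 0, to every
#' patient in the boost arm regardless of whether neutropenia develops.
#'
#' @param hospitalization_cost_usd Cost per severe-infection admission.
#' @param reserve_collection_cost_usd Per-patient reserve collection and
#'   storage cost.
#' @return An object of class `cost_params`.
#' @export
#' @examples
#' cost_params()
cost_params <- function(hospitalization_cost_usd = 64012,
                        reserve_collection_cost_usd = 17918) {
  if (!is.numeric(hospitalization_cost_usd) || hospitalization_cost_usd < 0 ||
      !is.numeric(reserve_collection_cost_usd) || reserve_collection_cost_usd < 0) {
    stop("costs must be non-negative numbers", call. = FALSE)
  }
  structure(list(hospitalization_cost_usd = hospitalization_cost_usd,
                 reserve_collection_cost_usd = reserve_collection_cost_usd),
            class = "cost_params")
}

#' @export
print.cost_params <- function(x, ...) {
  cat("Cost parameters (USD)\n")
  cat(sprintf("  hospitalization per admission  %10.2f\n", x$hospitalization_cost_usd))
  cat(sprintf("  reserve collection per patient %10.2f\n", x$reserve_collection_cost_usd))
  invisible(x)
}
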