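# evaluate both arms once and return incremental cost + infections per arm
evaluate_scenario <- function(nb_infection, nb_recovery, b_infection,
                              b_recovery, hosp_cost, reserve_cost,
                              base_noboost, base_boost,
                              n_patients = 10000, n_cycles = 96,
                              renormalize = FALSE) {
  nb <- base_noboost
  nb$p_infection_given_neutropenia <- nb_infection
  nb$p_recovery_given_neutropenia <- nb_recovery
  b <- base_boost
  b$p_infection_given_neutropenia <- b_infection
  b$p_recovery_given_neutropenia <- b_recovery
  costs <- cost_params(hospitalization_cost_usd = hosp_cost,
                       reserve_collection_cost_usd = reserve_cost)
  tr_nb <- run_cohort(transition_matrix(nb, renormalize = renormalize),
                      n_patients, n_cycles)
  tr_b <- run_cohort(transition_matrix(b, renormalize = renormalize),
                     n_patients, n_cycles)
  ec_nb <- accumulate_costs(tr_nb, costs, boost_available = FALSE)
  ec_b <- accumulate_costs(tr_b, costs, boost_available = TRUE)
  list(incremental = incremental_cost(ec_b, ec_nb),
       infections_noboost = tr_nb$cumulative_infections[[n_cycles + 1L]],
       infections_boost = tr_b$cumulative_infections[[n_cycles + 1L]])
}

#' Default one-way sensitivity grid
#'
#' The published deterministic grid: no-boost neutropenia recovery at
#' 0.70/0.75/0.80 with complementary infection 0.30/0.25/0.20; boost
#' recovery 0.85/0.90/0.95 with infection 0.15/0.10/0.05; hospitalization
#' cost 60,000-68,000 USD; reserve cost 16,000-20,000 USD.
#'
#' @return A named list of grids; neutropenia splits are supplied as
#'   complementary (recovery, infection) pairs.
#' @export
dsa_grid_default <- function() {
  list(
    noboost_neutropenia_split = list(recovery = c(0.70, 0.75, 0.80),
                                     infection = c(0.30, 0.25, 0.20)),
    boost_neutropenia_split = list(recovery = c(0.85, 0.90, 0.95),
                                   infection = c(0.15, 0.10, 0.05)),
    hospitalization_cost = c(60000, 64012, 68000),
    reserve_cost = c(16000, 17918, 20000)
  )
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Varies each parameter group across its grid extremes while holding all
#' others at base case, and records the incremental cost at each extreme.
#' Neutropenia splits move as complementary (recovery, infection) pairs —
#' a non-complementary pair is rejected, since the base-case structure has
#' no residual neutropenia mass. Results are sorted by descending absolute
#' range, ties broken alphabetically by parameter name.
#'
#' @param base_noboost,base_boost [strategy_params()] for the two arms.
#' @param costs Base-case [cost_params()].
#' @param grid A grid as from [dsa_grid_default()].
#' @param n_patients,n_cycles Cohort size and horizon.
#' @return A data frame of class `dsa_result`: `parameter`, `low`, `high`
#'   (for splits, the infection probability at each end), `incremental_low`,
#'   `incremental_high`, `range`, and `direction_preserved` (incremental
#'   cost positive at both extremes). The attribute `cells` holds the full
#'   factorial evaluation over the grid.
#' @export
run_dsa <- function(base_noboost = strategy_params(),
                    base_boost = strategy_params(boost_available = TRUE),
                    costs = cost_params(),
                    grid = dsa_grid_default(),
                    n_patients = 10000, n_cycles = 96) {
  for (nm in c("noboost_neutropenia_split", "boost_neutropenia_split")) {
    g <- grid[[nm]]
    if (any(abs(g$recovery + g$infection - 1) > 1e-9)) {
      stop(sprintf("%s: recovery and infection values must be complementary pairs",
                   nm), call. = FALSE)
    }
    if (any(g$recovery < 0 | g$recovery > 1 | g$infection < 0 | g$infection > 1)) {
      stop(sprintf("%s: probabilities must lie in [0, 1]", nm), call. = FALSE)
    }
  }
  base_args <- list(
    nb_infection = base_noboost$p_infection_given_neutropenia,
    nb_recovery = base_noboost$p_recovery_given_neutropenia,
    b_infection = base_boost$p_infection_given_neutropenia,
    b_recovery = base_boost$p_recovery_given_neutropenia,
    hosp_cost = costs$hospitalization_cost_usd,
    reserve_cost = costs$reserve_collection_cost_usd
  )
  eval_args <- function(args) {
    do.call(evaluate_scenario,
            c(args, list(base_noboost = base_noboost, base_boost = base_boost,
                         n_patients = n_patients, n_cycles = n_cycles)))
  }
  at_split <- function(args, which_arm, i, grid_part) {
    if (which_arm == "noboost") {
      args$nb_recovery <- grid_part$recovery[i]
      args$nb_infection <- grid_part$infection[i]
    } else {
      args$b_recovery <- grid_part$recovery[i]
      args$b_infection <- grid_part$infection[i]
    }
    args
  }
  rows <- list()
  for (arm in c("noboost", "boost")) {
    nm <- paste0(arm, "_neutropenia_split")
    g <- grid[[nm]]
    ord <- order(g$infection)
    lo_i <- ord[1L]; hi_i <- ord[length(ord)]
    r_lo <- eval_args(at_split(base_args, arm, lo_i, g))
    r_hi <- eval_args(at_split(base_args, arm, hi_i, g))
    rows[[nm]] <- data.frame(parameter = nm,
                             low = g$infection[lo_i], high = g$infection[hi_i],
                             incremental_low = r_lo$incremental,
                             incremental_high = r_hi$incremental)
  }
  for (nm in c("hospitalization_cost", "reserve_cost")) {
    g <- range(grid[[nm]])
    arg <- if (nm == "hospitalization_cost") "hosp_cost" else "reserve_cost"
    args_lo <- base_args; args_lo[[arg]] <- g[1L]
    args_hi <- base_args; args_hi[[arg]] <- g[2L]
    rows[[nm]] <- data.frame(parameter = nm, low = g[1L], high = g[2L],
                             incremental_low = eval_args(args_lo)$incremental,
                             incremental_high = eval_args(args_hi)$incremental)
  }
  out <- do.call(rbind, rows)
  out$range <- abs(out$incremental_high - out$incremental_low)
  out$direction_preserved <- out$incremental_low > 0 & out$incremental_high > 0
  out <- out[order(-out$range, out$parameter), ]
  rownames(out) <- NULL
  attr(out, "cells") <- dsa_full_factorial(grid, base_noboost, base_boost,
                                           n_patients, n_cycles)
  class(out) <- c("dsa_result", class(out))
  out
}

# every combination of the DSA grid, with infections per arm per cell
dsa_full_factorial <- function(grid, base_noboost, base_boost,
                               n_patients, n_cycles) {
  combos <- expand.grid(
    nb = seq_along(grid$noboost_neutropenia_split$infection),
    b = seq_along(grid$boost_neutropenia_split$infection),
    hosp = grid$hospitalization_cost,
    reserve = grid$reserve_cost
  )
  res <- lapply(seq_len(nrow(combos)), function(i) {
    r <- evaluate_scenario(
      nb_infection = grid$noboost_neutropenia_split$infection[combos$nb[i]],
      nb_recovery = grid$noboost_neutropenia_split$recovery[combos$nb[i]],
      b_infection = grid$boost_neutropenia_split$infection[combos$b[i]],
      b_recovery = grid$boost_neutropenia_split$recovery[combos$b[i]],
      hosp_cost = combos$hosp[i], reserve_cost = combos$reserve[i],
      base_noboost = base_noboost, base_boost = base_boost,
      n_patients = n_patients, n_cycles = n_cycles)
    data.frame(nb_infection = grid$noboost_neutropenia_split$infection[combos$nb[i]],
               b_infection = grid$boost_neutropenia_split$infection[combos$b[i]],
               hospitalization_cost = combos$hosp[i],
               reserve_cost = combos$reserve[i],
               incremental = r$incremental,
               infections_noboost = r$infections_noboost,
               infections_boost = r$infections_boost)
  })
  do.call(rbind, res)
}

#' @export
plot.dsa_result <- function(x, base_incremental = NULL, ...) {
  op <- graphics::par(mar = c(4, 12, 2, 1)); on.exit(graphics::par(op))
  n <- nrow(x)
  ord <- rev(seq_len(n))   # widest bar on top
  lo <- pmin(x$incremental_low, x$incremental_high)[ord]
  hi <- pmax(x$incremental_low, x$incremental_high)[ord]
  graphics::plot(NULL, xlim = range(c(lo, hi)), ylim = c(0.5, n + 0.5),
                 yaxt = "n", ylab = "", xlab = "Incremental cost (USD/patient)",
                 main = "One-way sensitivity (tornado)", ...)
  graphics::rect(lo, seq_len(n) - 0.3, hi, seq_len(n) + 0.3, col = "steelblue")
  graphics::axis(2, at = seq_len(n), labels = x$parameter[ord], las = 1)
  if (!is.null(base_incremental)) graphics::abline(v = base_incremental, lty = 2)
  invisible(x)
}

#' Default probabilistic stress-test ranges
#'
#' The published stress ranges: no-boost recovery 0.60-0.85 and infection
#' 0.15-0.35; boost recovery 0.80-1.00 and infection 0.00-0.20;
#' hospitalization cost 50,000-70,000 USD; reserve cost 14,000-22,000 USD.
#'
#' @return Named list of `c(low, high)` ranges.
#' @export
psa_ranges_default <- function() {
  list(nb_recovery = c(0.60, 0.85), nb_infection = c(0.15, 0.35),
       b_recovery = c(0.80, 1.00), b_infection = c(0.00, 0.20),
       hosp_cost = c(50000, 70000), reserve_cost = c(14000, 22000))
}

#' Probabilistic stress testing
#'
#' Samples every parameter independently and uniformly over its range (the
#' least-assumption reading of stress testing over stated bounds), runs
#' both arms through the cohort engine for each draw, and records the
#' incremental cost. A sampled neutropenia (recovery, infection) pair
#' summing to more than 1 is proportionally renormalized; when the sum is
#' below 1 the residual mass remains neutropenic.
#'
#' @param ranges Ranges as from [psa_ranges_default()].
#' @param n_draws Number of draws (default 500).
#' @param seed Integer seed; required for reproducibility.
#' @param base_noboost,base_boost Base [strategy_params()] supplying the
#'   parameters that are not stress-tested.
#' @param n_patients,n_cycles Cohort size and horizon.
#' @return An object of class `psa_result`: `draws` (one row per draw with
#'   sampled values, incremental cost, savings = no-boost minus boost, and
#'   infections per arm), `fraction_positive` (share of draws with positive
#'   incremental cost), `n_draws`, `seed`.
#' @export
#' @examples
#' psa <- run_psa(n_draws = 20, seed = 1)
#' psa$fraction_positive
run_psa <- function(ranges = psa_ranges_default(), n_draws = 500, seed,
                    base_noboost = strategy_params(),
                    base_boost = strategy_params(boost_available = TRUE),
                    n_patients = 10000, n_cycles = 96) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("an explicit integer seed is required", call. = FALSE)
  }
  stopifnot(n_draws >= 1)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1L] > r[2L]) {
      stop(sprintf("range '%s' is degenerate (low > high)", nm), call. = FALSE)
    }
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  draws <- as.data.frame(lapply(ranges, function(r) {
    stats::runif(n_draws, r[1L], r[2L])
  }))
  res <- lapply(seq_len(n_draws), function(i) {
    evaluate_scenario(
      nb_infection = draws$nb_infection[i], nb_recovery = draws$nb_recovery[i],
      b_infection = draws$b_infection[i], b_recovery = draws$b_recovery[i],
      hosp_cost = draws$hosp_cost[i], reserve_cost = draws$reserve_cost[i],
      base_noboost = base_noboost, base_boost = base_boost,
      n_patients = n_patients, n_cycles = n_cycles, renormalize = TRUE)
  })
  draws$incremental <- vapply(res, `[[`, numeric(1), "incremental")
  draws$savings <- -draws$incremental   # no-boost minus boost
  draws$infections_noboost <- vapply(res, `[[`, numeric(1), "infections_noboost")
  draws$infections_boost <- vapply(res, `[[`, numeric(1), "infections_boost")
  structure(list(draws = draws,
                 fraction_positive = mean(draws$incremental > 0),
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("Probabilistic stress test: %d draws (seed %d)\n",
              x$n_draws, x$seed))
  cat(sprintf("  draws with positive incremental cost: %.1f%%\n",
              100 * x$fraction_positive))
  cat(sprintf("  incremental cost (USD/patient): median %.0f, range [%.0f, %.0f]\n",
              stats::median(x$draws$incremental),
              min(x$draws$incremental), max(x$draws$incremental)))
  invisible(x)
}

#' @export
plot.psa_result <- function(x, ...) {
  # Fig-5 convention: the histogram shows savings = no-boost minus boost
  graphics::hist(x$draws$savings, breaks = 30, col = "grey70",
                 main = "Incremental cost across probabilistic draws",
                 xlab = "Incremental cost, no-boost minus boost (USD/patient)",
                 ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Key-driver linear regression
#'
#' Ordinary least squares of cost savings (no-boost minus boost, the
#' published dependent variable) on the six sampled parameters. Constant
#' columns are dropped with a warning; a design with no varying parameter
#' is refused. Standardized coefficients rescale each slope by
#' sd(x)/sd(y) so drivers are comparable across units.
#'
#' @param psa A [run_psa()] result, or its `draws` data frame.
#' @return A data frame of class `key_driver_result` with `parameter`,
#'   `coefficient` (raw, per unit of the parameter), `standardized`, and
#'   `rank` by absolute standardized coefficient.
#' @export
key_driver_regression <- function(psa) {
  draws <- if (inherits(psa, "psa_result")) psa$draws else psa
  vars <- c("nb_recovery", "nb_infection", "b_recovery", "b_infection",
            "hosp_cost", "reserve_cost")
  stopifnot(all(vars %in% names(draws)), "savings" %in% names(draws))
  varying <- vars[vapply(draws[vars], function(v) length(unique(v)) > 1L,
                         logical(1))]
  if (length(varying) == 0L) {
    stop("all parameters are constant across draws; regression is undefined",
         call. = FALSE)
  }
  if (length(varying) < length(vars)) {
    warning(sprintf("dropping constant parameter(s): %s",
                    paste(setdiff(vars, varying), collapse = ", ")),
            call. = FALSE)
  }
  if (nrow(draws) < length(varying) + 2L) {
    stop("need at least two more draws than varying parameters", call. = FALSE)
  }
  fit <- stats::lm(stats::reformulate(varying, response = "savings"),
                   data = draws)
  coefs <- stats::coef(fit)[varying]
  sdy <- stats::sd(draws$savings)
  std <- coefs * vapply(draws[varying], stats::sd, numeric(1)) /
    if (sdy > 0) sdy else NA_real_
  out <- data.frame(parameter = varying, coefficient = unname(coefs),
                    standardized = unname(std))
  out <- out[order(-abs(out$standardized), out$parameter), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "model") <- fit
  class(out) <- c("key_driver_result", class(out))
  out
}
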