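#' Build the per-cycle transition matrix for one strategy arm
#'
#' Encodes the state graph: CAR T resolves entirely in its first cycle
#' (neutropenia with `p_neutropenia`, otherwise direct recovery);
#' neutropenia leads to infection, recovery, or persists with the residual
#' mass; infection resolves in exactly one cycle (death with the case
#' fatality, otherwise back to recovery); recovered patients relapse at the
#' monthly relapse probability; relapsing patients die of relapse at the
#' monthly relapse mortality; both death states are absorbing.
#'
#' If the neutropenia split sums to more than 1 the pair is either rejected
#' (default) or, with `renormalize = TRUE`, scaled proportionally so it
#' sums to 1 — the behaviour used when sampling the split independently in
#' probabilistic stress testing.
#'
#' @param params A [strategy_params()] object.
#' @param renormalize Logical; proportionally rescale an infection/recovery
#'   pair that sums to more than 1 instead of raising an error.
#' @param tol Tolerance above 1 before the pair is considered inconsistent.
#' @return A 7 x 7 row-stochastic matrix with `dimnames` set to
#'   [health_states()], of class `transition_matrix`.
#' @export
#' @examples
#' P <- transition_matrix(strategy_params())
#' P["neutropenia", ]        # 0.25 to infection, 0.75 to recovery
#' rowSums(P)                # all exactly 1
transition_matrix <- function(params, renormalize = FALSE, tol = 1e-9) {
  if (!inherits(params, "strategy_params")) {
    params <- do.call(strategy_params, as.list(params))
  }
  s <- health_states()
  p_inf <- params$p_infection_given_neutropenia
  p_rec <- params$p_recovery_given_neutropenia
  excess <- p_inf + p_rec - 1
  if (excess > tol && !renormalize) {
    stop(sprintf(paste0("p_infection_given_neutropenia (%.4f) + ",
                        "p_recovery_given_neutropenia (%.4f) exceeds 1; ",
                        "supply a consistent pair or set renormalize = TRUE"),
                 p_inf, p_rec), call. = FALSE)
  }
  p_stay <- 1 - p_inf - p_rec
  if (p_stay < 0) {   # proportional rescaling (exceeds 1 at most by tol here
    total <- p_inf + p_rec   # unless renormalize = TRUE)
    p_inf <- p_inf / total
    p_rec <- p_rec / total
    p_stay <- 0
  }
  P <- matrix(0, 7, 7, dimnames = list(s, s))
  P["car_t", "neutropenia"] <- params$p_neutropenia
  P["car_t", "recovery"] <- 1 - params$p_neutropenia
  P["neutropenia", "infection"] <- p_inf
  P["neutropenia", "recovery"] <- p_rec
  P["neutropenia", "neutropenia"] <- p_stay
  P["infection", "death_infection"] <- params$p_infection_death
  P["infection", "recovery"] <- 1 - params$p_infection_death
  P["recovery", "relapse"] <- params$p_relapse_monthly
  P["recovery", "recovery"] <- 1 - params$p_relapse_monthly
  P["relapse", "death_relapse"] <- params$p_relapse_death_monthly
  P["relapse", "relapse"] <- 1 - params$p_relapse_death_monthly
  P["death_infection", "death_infection"] <- 1
  P["death_relapse", "death_relapse"] <- 1
  validate_transition_matrix(P)
  class(P) <- c("transition_matrix", class(P))
  P
}

#' Validate a transition matrix
#'
#' Checks squareness, state labelling, entries in \[0, 1\], row sums equal
#' to 1 within `1e-12`, and absorbing death rows.
#'
#' @param P A square numeric matrix with [health_states()] dimnames.
#' @return `P`, invisibly; errors describe the first violated property.
#' @export
validate_transition_matrix <- function(P) {
  s <- health_states()
  if (!is.matrix(P) || nrow(P) != 7L || ncol(P) != 7L) {
    stop("transition matrix must be 7 x 7", call. = FALSE)
  }
  if (!identical(rownames(P), s) || !identical(colnames(P), s)) {
    stop("transition matrix must be labelled with health_states() in order",
         call. = FALSE)
  }
  if (any(P < 0) || any(P > 1)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-12)) {
    bad <- s[which.max(abs(rs - 1))]
    stop(sprintf("row '%s' sums to %.15f, not 1", bad, rs[bad]), call. = FALSE)
  }
  for (d in absorbing_states()) {
    if (P[d, d] != 1) stop(sprintf("state '%s' must be absorbing", d),
                           call. = FALSE)
  }
  invisible(P)
}

#' @export
print.transition_matrix <- function(x, digits = 4, ...) {
  cat("Per-cycle transition matrix (rows = from, columns = to)\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Write a transition matrix to CSV
#'
#' State labels form the header row and first column.
#'
#' @param P A `transition_matrix`.
#' @param file Path to write.
#' @return `file`, invisibly.
#' @export
write_transition_matrix <- function(P, file) {
  validate_transition_matrix(unclass(P))
  utils::write.csv(as.data.frame(unclass(P)), file, row.names = TRUE)
  invisible(file)
}
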