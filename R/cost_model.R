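#' Policy expenditure trajectory
#'
#' The continuous expenditure rate P(s): zero for the baseline, and the
#' step \code{p_unit * I(s - tau)} for all active policies. Adaptive-nudge
#' impulse costs are events, not rates; they are carried separately by the
#' \code{\link{adaptive_record}} and added to the cumulative integral by
#' \code{\link{cumulative_cost}}.
#'
#' @param scenario a \code{\link{scenario_config}}.
#' @param activations an \code{\link{adaptive_record}} (unused here beyond
#'   validation; impulses enter the cumulative cost).
#' @param params a \code{\link{model_parameters}}.
#' @return A \code{\link{trajectory}} of the expenditure rate in
#'   model-cost/yr.
#' @export
policy_expenditure <- function(scenario, activations = adaptive_record(),
                               params = default_parameters()) {
  validate_inputs(params, scenario)
  stopifnot(inherits(activations, "adaptive_record"))
  times <- time_grid(params)
  if (scenario$shape == "baseline") {
    vals <- rep(0, length(times))
    left <- vals
  } else {
    on <- times >= scenario$tau - 1e-12
    vals <- params$p_unit * on
    left <- params$p_unit * (times > scenario$tau + 1e-12)
  }
  trajectory(times, vals, values_left = left)
}

#' Instantaneous cost decomposition
#'
#' Evaluates the four components of the instantaneous cost
#' \eqn{c(s) = \alpha D(s) + \beta A(s)^2 + \gamma P(s) + \lambda H(s)}
#' on the shared grid, together with their sum and its discounted value
#' \eqn{e^{-\rho s} c(s)}. With the default \code{lam = 0} the health term
#' vanishes and costs reflect direct healthcare expenditure only.
#'
#' @param severity,adherence,policy \code{\link{trajectory}} objects on the
#'   same grid (severity from \code{\link{severity_coupled}}).
#' @param scenario a \code{\link{scenario_config}} (supplies gamma).
#' @param params a \code{\link{model_parameters}}.
#' @param health optional \code{\link{trajectory}} H(s); zero if omitted.
#' @return An object of class \code{cost_breakdown}: list with fields
#'   \code{times}, \code{disease}, \code{adherence}, \code{policy},
#'   \code{health}, \code{total}, \code{discounted_total} (model-cost/yr).
#' @export
cost_decomposition <- function(severity, adherence, policy, scenario,
                               params, health = NULL) {
  for (tr in list(severity, adherence, policy))
    stopifnot(inherits(tr, "trajectory"))
  if (!same_grid(severity, adherence) || !same_grid(severity, policy))
    stop("trajectories are not on a common grid")
  if (!is.null(health) && !same_grid(severity, health))
    stop("health trajectory grid mismatch")
  times <- severity$times
  H <- if (is.null(health)) rep(0, length(times)) else health$values
  disease <- params$alpha * severity$values
  adher <- params$beta * adherence$values^2
  pol <- scenario$gamma * policy$values
  hlth <- params$lam * H
  total <- disease + adher + pol + hlth
  # left-limits at grid points (adherence and policy may jump at the
  # grid-aligned policy start; severity and health are continuous), so the
  # cumulative quadrature can treat the jump exactly
  total_left <- disease + params$beta * values_left_of(adherence)^2 +
    scenario$gamma * values_left_of(policy) + hlth
  disc <- exp(-params$rho * times)
  structure(list(times = times, disease = disease, adherence = adher,
                 policy = pol, health = hlth, total = total,
                 discounted_total = disc * total,
                 discounted_total_left = disc * total_left),
            class = "cost_breakdown")
}

#' Discounted cumulative cost
#'
#' Accumulates \eqn{C(t) = \omega (C_0 + \int_0^t e^{-\rho s} c(s) ds)}
#' by the trapezoid rule on the grid (each step averages the right-limit
#' at its left endpoint with the left-limit at its right endpoint, so
#' grid-aligned jumps in the integrand are integrated exactly), plus, for
#' adaptive scenarios, a
#' discounted impulse \eqn{e^{-\rho t_e} \gamma \cdot \mathrm{nudge\_cost}}
#' at each re-activation time. Returned in dollars via the \code{omega}
#' scale (with the default \code{omega = 1} the units are model-cost).
#'
#' @param breakdown a \code{\link{cost_decomposition}} result.
#' @param params a \code{\link{model_parameters}}.
#' @param scenario optional \code{\link{scenario_config}} (needed for
#'   impulse costs).
#' @param activations optional \code{\link{adaptive_record}}.
#' @return A \code{\link{trajectory}} of C(t) in USD.
#' @export
cumulative_cost <- function(breakdown, params, scenario = NULL,
                            activations = NULL) {
  stopifnot(inherits(breakdown, "cost_breakdown"))
  times <- breakdown$times
  g <- breakdown$discounted_total
  g_left <- breakdown$discounted_total_left
  if (is.null(g_left)) g_left <- g
  h <- params$grid_step
  n <- length(times)
  integral <- c(0, cumsum(0.5 * h * (g[-n] + g_left[-1])))
  if (!is.null(activations) && activations$count > 0) {
    if (is.null(scenario)) stop("scenario needed to price activations")
    for (te in activations$activation_times) {
      imp <- exp(-params$rho * te) * scenario$gamma * scenario$nudge_cost
      integral <- integral + imp * (times >= te - 1e-12)
    }
  }
  trajectory(times, params$omega * (params$C0 + integral))
}

#' Monetize averted health outcomes
#'
#' Linear valuation of health gains, e.g. averted DALYs at a stated dollar
#' value per DALY.
#'
#' @param outcomes_averted number of outcome units averted (e.g. DALYs).
#' @param value_per_outcome USD per outcome unit (>= 0).
#' @return USD benefit (the product).
#' @examples
#' monetize_health_outcomes(0.05, 50000)  # 2500
#' @export
monetize_health_outcomes <- function(outcomes_averted, value_per_outcome) {
  if (any(value_per_outcome < 0)) stop("value_per_outcome must be >= 0")
  outcomes_averted * value_per_outcome
}

#' Inflate policy implementation costs
#'
#' Scales the per-unit policy cost \code{gamma} and the adaptive
#' \code{nudge_cost} by a common factor (e.g. 1.2 for 20\% inflation),
#' leaving everything else untouched.
#'
#' @param scenario a \code{\link{scenario_config}}.
#' @param factor positive multiplier.
#' @return A modified \code{\link{scenario_config}} copy.
#' @export
inflate_costs <- function(scenario, factor) {
  if (factor <= 0) stop("factor must be positive")
  scenario$gamma <- factor * scenario$gamma
  scenario$nudge_cost <- factor * scenario$nudge_cost
  scenario
}

#' Simulate one policy scenario end-to-end
#'
#' Builds the adherence trajectory, integrates coupled severity, prices the
#' policy, decomposes instantaneous cost and accumulates the discounted
#' cumulative cost.
#'
#' @param scenario a \code{\link{scenario_config}}.
#' @param params a \code{\link{model_parameters}}.
#' @return An object of class \code{simulation_result}: list with fields
#'   \code{scenario} (name), \code{config}, \code{adherence},
#'   \code{severity}, \code{policy} (trajectories), \code{breakdown},
#'   \code{cumulative_cost} (trajectory, USD), \code{total_cost}
#'   (C(horizon), USD), and \code{activations}.
#' @examples
#' res <- simulate_scenario(scenario_table()$early, default_parameters())
#' res$total_cost
#' @export
simulate_scenario <- function(scenario, params = default_parameters()) {
  validate_inputs(params, scenario)
  adh <- adherence_trajectory(scenario, params)
  sev <- severity_coupled(adh$adherence, params)
  pol <- policy_expenditure(scenario, adh$activations, params)
  bd <- cost_decomposition(sev, adh$adherence, pol, scenario, params)
  cc <- cumulative_cost(bd, params, scenario, adh$activations)
  structure(list(scenario = scenario$name, config = scenario,
                 adherence = adh$adherence, severity = sev, policy = pol,
                 breakdown = bd, cumulative_cost = cc,
                 total_cost = cc$values[length(cc$values)],
                 activations = adh$activations),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Simulation '%s': C(%g yr) = %.2f USD", x$scenario,
              max(x$cumulative_cost$times), x$total_cost))
  if (x$activations$count > 0)
    cat(sprintf(" (%d nudge activations)", x$activations$count))
  cat("\n")
  invisible(x)
}

#' Export a simulation result as a CSV table
#'
#' Writes one row per grid point with columns time, adherence, severity,
#' policy_rate, cost_disease, cost_adherence, cost_policy, cost_total,
#' cumulative_cost.
#'
#' @param result a \code{\link{simulate_scenario}} result.
#' @param path output file path.
#' @return Invisibly, the exported data frame.
#' @export
write_simulation_csv <- function(result, path) {
  stopifnot(inherits(result, "simulation_result"))
  df <- data.frame(time = result$breakdown$times,
                   adherence = result$adherence$values,
                   severity = result$severity$values,
                   policy_rate = result$policy$values,
                   cost_disease = result$breakdown$disease,
                   cost_adherence = result$breakdown$adherence,
                   cost_policy = result$breakdown$policy,
                   cost_total = result$breakdown$total,
                   cumulative_cost = result$cumulative_cost$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
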