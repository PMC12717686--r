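#' Return on investment of a policy versus baseline
#'
#' \deqn{ROI = 100 (C_{baseline} - C_{policy}) / C_{policy}}
#' Percent relative cost savings of the policy scenario against the
#' no-intervention counterfactual, with the policy scenario's total cost as
#' denominator. Positive ROI means net savings.
#'
#' @param c_baseline total discounted baseline cost (USD).
#' @param c_policy total discounted policy-scenario cost (USD, > 0).
#' @return ROI in percent.
#' @examples
#' roi(3953.07, 3602.26)  # ~9.7
#' @export
roi <- function(c_baseline, c_policy) {
  if (any(c_policy <= 0)) stop("c_policy must be positive")
  100 * (c_baseline - c_policy) / c_policy
}

# Baseline counterfactual matching a policy template (same A0 and baseline
# adherence decay, no policy).
baseline_of <- function(template) {
  scenario_config("Baseline", "baseline", tau = 0, delta = 0, gamma = 0,
                  A0 = template$A0,
                  baseline_decay_rate = template$baseline_decay_rate)
}

# Simulate a template at a given (delta, gamma) and return ROI against its
# matched baseline; baseline cost may be passed in to avoid recomputation.
scenario_roi <- function(delta, gamma, template, params,
                         c_baseline = NULL) {
  sc <- template
  sc$delta <- delta
  sc$gamma <- gamma
  if (is.null(c_baseline))
    c_baseline <- simulate_scenario(baseline_of(template), params)$total_cost
  roi(c_baseline, simulate_scenario(sc, params)$total_cost)
}

#' Payback time (years to net savings)
#'
#' First grid time t > 0 at which the cumulative discounted policy cost
#' falls strictly below the cumulative baseline cost; \code{Inf} if the
#' policy never pays back within the horizon. No interpolation between
#' grid points.
#'
#' @param c_baseline,c_policy \code{\link{trajectory}} objects of
#'   cumulative cost on a common grid.
#' @return Payback time in years, or \code{Inf}.
#' @export
payback_time <- function(c_baseline, c_policy) {
  stopifnot(inherits(c_baseline, "trajectory"),
            inherits(c_policy, "trajectory"))
  if (!same_grid(c_baseline, c_policy)) stop("grid mismatch")
  idx <- which(c_policy$values < c_baseline$values & c_baseline$times > 0)
  if (length(idx) == 0) Inf else c_baseline$times[idx[1]]
}

#' Break-even policy cost scale
#'
#' The largest policy cost scale gamma* at which ROI remains non-negative
#' for a given adherence gain delta, found by bisection on [0, gamma_max]
#' (ROI decreases monotonically in gamma). If ROI is still positive at
#' \code{gamma_max} the bound itself is returned, flagged unbounded.
#'
#' @param delta adherence gain.
#' @param template a \code{\link{scenario_config}} whose delta/gamma are
#'   overridden during the search.
#' @param params a \code{\link{model_parameters}}.
#' @param gamma_max upper search bound (model scale).
#' @param tol bisection tolerance on |ROI| in percentage points.
#' @return List with \code{gamma_star}, \code{roi_at_star}, and
#'   \code{bounded} (FALSE when gamma* hit \code{gamma_max}).
#' @export
breakeven_gamma <- function(delta, template, params = default_parameters(),
                            gamma_max = 10, tol = 1e-4) {
  c_base <- simulate_scenario(baseline_of(template), params)$total_cost
  f <- function(g) scenario_roi(delta, g, template, params, c_base)
  r0 <- f(0)
  if (r0 < 0) stop("no break-even exists: ROI at zero cost is negative")
  if (r0 <= tol)
    return(list(gamma_star = 0, roi_at_star = r0, bounded = TRUE))
  r_hi <- f(gamma_max)
  if (r_hi > 0)
    return(list(gamma_star = gamma_max, roi_at_star = r_hi,
                bounded = FALSE))
  lo <- 0; hi <- gamma_max
  r_mid <- r_hi
  for (it in 1:200) {
    mid <- 0.5 * (lo + hi)
    r_mid <- f(mid)
    if (abs(r_mid) <= tol) break
    if (r_mid > 0) lo <- mid else hi <- mid
  }
  list(gamma_star = 0.5 * (lo + hi), roi_at_star = r_mid, bounded = TRUE)
}

#' Local ROI sensitivity to policy cost
#'
#' Central finite-difference slope of ROI with respect to gamma at a design
#' point (falls back to a forward difference when gamma - h would be
#' negative).
#'
#' @param delta adherence gain.
#' @param gamma policy cost scale.
#' @param template a \code{\link{scenario_config}}.
#' @param params a \code{\link{model_parameters}}.
#' @param h difference step (> 0).
#' @param roi_fn ROI function of (delta, gamma); defaults to simulating the
#'   template. Exposed so analytic surfaces can be differentiated in tests.
#' @return Slope in percent per unit gamma.
#' @export
roi_gamma_slope <- function(delta, gamma, template,
                            params = default_parameters(), h = 0.05,
                            roi_fn = NULL) {
  if (h <= 0) stop("h must be positive")
  if (is.null(roi_fn)) {
    c_base <- simulate_scenario(baseline_of(template), params)$total_cost
    roi_fn <- function(d, g) scenario_roi(d, g, template, params, c_base)
  }
  if (gamma - h < 0)
    (roi_fn(delta, gamma + h) - roi_fn(delta, gamma)) / h
  else
    (roi_fn(delta, gamma + h) - roi_fn(delta, gamma - h)) / (2 * h)
}

#' Calibrate the dollar scale to two cost anchors
#'
#' The model accumulates cost in dimensionless model-cost units; published
#' dollar figures pin down the affine map to USD. Given the printed total
#' costs of the baseline and one policy scenario, this solves the 2x2
#' linear system
#' \deqn{C_{0,USD} + \omega I_{base} = anchor_{base}, \quad
#'       C_{0,USD} + \omega I_{policy} = anchor_{policy}}
#' where \eqn{I} are the model-unit discounted cost integrals under the
#' current parameters, and stores \code{omega} and \code{C0 = C0_USD/omega}
#' so both anchors are reproduced exactly.
#'
#' @param anchor_baseline,anchor_policy printed total discounted costs
#'   (USD, > 0).
#' @param template the policy \code{\link{scenario_config}} the second
#'   anchor refers to.
#' @param params a \code{\link{model_parameters}}.
#' @return An updated \code{\link{model_parameters}} with calibrated
#'   \code{C0} and \code{omega}.
#' @export
calibrate_to_anchors <- function(anchor_baseline, anchor_policy, template,
                                 params = default_parameters()) {
  if (anchor_baseline <= 0 || anchor_policy <= 0)
    stop("anchors must be positive")
  raw <- params
  raw$C0 <- 0
  raw$omega <- 1
  I_base <- simulate_scenario(baseline_of(template), raw)$total_cost
  I_pol <- simulate_scenario(template, raw)$total_cost
  if (abs(I_base - I_pol) < 1e-12)
    stop("singular system: baseline and policy model integrals coincide")
  omega <- (anchor_baseline - anchor_policy) / (I_base - I_pol)
  if (omega <= 0)
    stop(sprintf(paste0("calibration failed: omega = %.6g <= 0 ",
                        "(anchor ordering conflicts with the model's ",
                        "cost ordering)"), omega))
  C0_usd <- anchor_baseline - omega * I_base
  params$omega <- omega
  params$C0 <- C0_usd / omega
  params
}
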