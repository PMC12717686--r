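#' Global model parameters
#'
#' Constructs the parameter record for the cost model
#' \deqn{c(s) = \alpha D(s) + \beta A(s)^2 + \gamma P(s) + \lambda H(s)}
#' with discounted cumulative cost
#' \eqn{C(t) = \omega (C_0 + \int_0^t e^{-\rho s} c(s)\, ds)}.
#' Disease severity follows a logistic curve
#' \eqn{D(s) = D_{max} / (1 + e^{-k(s - s_0)})}, optionally slowed by
#' adherence through the coupling strength \code{eta} (see
#' \code{\link{severity_coupled}}).
#'
#' Costs are accumulated in dimensionless model-cost units and mapped to
#' dollars by \code{omega} (and offset \code{C0}); see
#' \code{\link{calibrate_to_anchors}}.
#'
#' @param C0 baseline cost offset, in model-cost units (dollars once
#'   \code{omega} is calibrated). The default of 1 model-cost unit (one
#'   year of baseline disease care) keeps total cost positive across the
#'   default design ranges, as the ROI denominator requires.
#' @param rho continuous annual discount rate (1/yr).
#' @param alpha disease cost weight (model-cost/yr per unit severity).
#' @param D_max severity ceiling (dimensionless).
#' @param k logistic progression rate (1/yr).
#' @param s0 logistic progression midpoint (yr).
#' @param beta adherence cost weight (model-cost/yr); negative values mean
#'   adherence effort saves money.
#' @param lam health-outcome cost weight (USD per outcome unit); 0 restricts
#'   the model to direct healthcare expenditure.
#' @param eta adherence-to-progression coupling strength (dimensionless).
#' @param p_unit policy expenditure rate while a policy is active
#'   (model-cost/yr).
#' @param omega model-cost to USD scale (USD per model-cost unit).
#' @param horizon simulation end time T (yr).
#' @param grid_step integration step h (yr); must divide \code{horizon}.
#' @return An object of class \code{model_parameters} (a named list).
#' @seealso \code{\link{default_parameters}}, \code{\link{validate_inputs}}
#' @export
model_parameters <- function(C0 = 1, rho = 0.03, alpha = 1.0, D_max = 1.0,
                             k = 0.7, s0 = 5.0 / 0.7, beta = -0.3, lam = 0.0,
                             eta = 0.8, p_unit = 0.05, omega = 1.0,
                             horizon = 10, grid_step = 0.01) {
  p <- list(C0 = C0, rho = rho, alpha = alpha, D_max = D_max, k = k, s0 = s0,
            beta = beta, lam = lam, eta = eta, p_unit = p_unit, omega = omega,
            horizon = horizon, grid_step = grid_step)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("parameter '%s' must be a single finite number", nm))
    p[[nm]] <- as.numeric(v)
  }
  structure(p, class = "model_parameters")
}

#' Default model parameters
#'
#' The documented default parameter set: 3\% continuous discounting over a
#' 10-year horizon, unit severity ceiling, progression rate k = 0.7/yr with
#' midpoint s0 = 5/0.7 yr, adherence savings weight beta = -0.3, coupling
#' strength eta = 0.8, and policy expenditure rate 0.05 model-cost/yr.
#'
#' @return A \code{\link{model_parameters}} record.
#' @examples
#' p <- default_parameters()
#' p$rho      # 0.03
#' p$horizon  # 10
#' @export
default_parameters <- function() model_parameters()

#' Policy scenario configuration
#'
#' Describes one policy design: when it starts (\code{tau}), how much it
#' lifts adherence (\code{delta}), what it costs (\code{gamma} scaling the
#' expenditure rate), and the shape of the induced adherence trajectory.
#'
#' Shapes:
#' \describe{
#'   \item{baseline}{no intervention; constant adherence \code{A0}, or
#'     \code{A0 e^{-\theta_b s}} when \code{baseline_decay_rate} > 0.}
#'   \item{step}{\eqn{A(s) = A_0 + \delta I(s - \tau)} (sustained gain).}
#'   \item{low_impact}{same step form, conventionally with small
#'     \code{delta} and large \code{gamma}.}
#'   \item{decay}{\eqn{A(s) = A_0 + \delta e^{-\theta (s-\tau)} I(s-\tau)}
#'     (regressive adherence).}
#'   \item{adaptive}{decaying form reset to \eqn{A_0 + \delta} whenever
#'     adherence would fall below \code{A_thresh}; each re-activation incurs
#'     an impulse cost \code{nudge_cost}.}
#' }
#' The indicator convention is \eqn{I(x) = 1} for \eqn{x \ge 0}.
#'
#' @param name scenario label.
#' @param shape one of \code{"baseline"}, \code{"step"}, \code{"decay"},
#'   \code{"adaptive"}, \code{"low_impact"}.
#' @param tau policy start time (yr); ignored by the baseline shape.
#' @param delta adherence gain (dimensionless).
#' @param gamma policy cost scale (dimensionless, >= 0).
#' @param A0 baseline adherence in [0, 1].
#' @param theta adherence decay rate (1/yr), used by decay/adaptive shapes.
#' @param A_thresh re-engagement threshold (adaptive shape only).
#' @param nudge_cost impulse expenditure per re-activation, model-cost
#'   units (adaptive shape only).
#' @param baseline_decay_rate decay rate of the counterfactual baseline
#'   adherence (1/yr); 0 gives the flat baseline.
#' @return An object of class \code{scenario_config}.
#' @seealso \code{\link{scenario_table}} for the canonical six-scenario set.
#' @export
scenario_config <- function(name, shape, tau = 2, delta = 0, gamma = 0,
                            A0 = 0.5, theta = 0.5, A_thresh = 0.75,
                            nudge_cost = 0.25, baseline_decay_rate = 0) {
  shapes <- c("baseline", "step", "decay", "adaptive", "low_impact")
  if (!is.character(shape) || length(shape) != 1L || !shape %in% shapes)
    stop("shape must be one of: ", paste(shapes, collapse = ", "))
  sc <- list(name = as.character(name), shape = shape, tau = as.numeric(tau),
             delta = as.numeric(delta), gamma = as.numeric(gamma),
             A0 = as.numeric(A0), theta = as.numeric(theta),
             A_thresh = as.numeric(A_thresh),
             nudge_cost = as.numeric(nudge_cost),
             baseline_decay_rate = as.numeric(baseline_decay_rate))
  num <- sc[!(names(sc) %in% c("name", "shape"))]
  bad <- names(num)[!vapply(num, function(v) length(v) == 1L && is.finite(v),
                            logical(1))]
  if (length(bad))
    stop("scenario field(s) must be single finite numbers: ",
         paste(bad, collapse = ", "))
  structure(sc, class = "scenario_config")
}

#' Canonical six-scenario policy registry
#'
#' The standard comparison set: a no-intervention baseline plus five policy
#' designs spanning early proactive engagement, late reactive response,
#' decaying (regressive) adherence, adaptive re-engagement nudges, and a
#' high-cost low-impact program.
#'
#' @return A named list of six \code{\link{scenario_config}} records, in
#'   order: baseline, early, delayed, regressive, adaptive, low_impact.
#' @examples
#' tab <- scenario_table()
#' tab$early$tau     # 2
#' tab$early$delta   # 0.3
#' @export
scenario_table <- function() {
  list(
    baseline   = scenario_config("Baseline", "baseline", tau = 0,
                                 delta = 0, gamma = 0),
    early      = scenario_config("Early Adherence", "step", tau = 2,
                                 delta = 0.3, gamma = 1.5),
    delayed    = scenario_config("Delayed Intervention", "step", tau = 5,
                                 delta = 0.3, gamma = 1.5),
    regressive = scenario_config("Regressive Adherence", "decay", tau = 2,
                                 delta = 0.3, gamma = 1.2),
    adaptive   = scenario_config("Adaptive Nudges", "adaptive", tau = 2,
                                 delta = 0.3, gamma = 2.0),
    low_impact = scenario_config("Low-Impact Policy", "low_impact", tau = 2,
                                 delta = 0.05, gamma = 3.0)
  )
}

#' Specification of the stochastic adherence gain
#'
#' Describes the distribution of the adherence gain delta used in Monte
#' Carlo propagation: a degenerate point mass, a Beta distribution, a
#' normal distribution truncated to [0, 1], or a two-point high/low
#' responder mixture.
#'
#' @param kind one of \code{"point"}, \code{"beta"}, \code{"truncnorm"},
#'   \code{"two_point"}.
#' @param delta location: the point value, or the (untruncated) mean of the
#'   truncated normal.
#' @param a,b Beta shape parameters.
#' @param sigma truncated-normal standard deviation.
#' @param p probability of the high-responder value.
#' @param delta_hi,delta_lo the two responder values.
#' @return An object of class \code{delta_spec}.
#' @seealso \code{\link{sample_delta}}
#' @export
delta_spec <- function(kind = c("point", "beta", "truncnorm", "two_point"),
                       delta = 0.3, a = 2, b = 5, sigma = 0.05,
                       p = 0.5, delta_hi = 0.3, delta_lo = 0.1) {
  kind <- match.arg(kind)
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (sigma < 0) stop("sigma must be non-negative")
  if (a <= 0 || b <= 0) stop("Beta shape parameters must be positive")
  for (v in c(delta, delta_hi, delta_lo))
    if (v < 0 || v > 1) stop("delta values must lie in [0, 1]")
  structure(list(kind = kind, delta = delta, a = a, b = b, sigma = sigma,
                 p = p, delta_hi = delta_hi, delta_lo = delta_lo),
            class = "delta_spec")
}

#' Validate a parameter/scenario pair
#'
#' Checks every invariant of the model: positive rates and grid, grid step
#' dividing the horizon, admissible adherence range, policy start within
#' the horizon, non-negative cost scale and decay rates, and that the
#' coupled progression rate \eqn{k (1 - \eta (A - A_{0,ref}))} stays
#' non-negative for any admissible adherence level.
#'
#' Validation is idempotent: it returns its inputs unchanged.
#'
#' @param params a \code{\link{model_parameters}} record.
#' @param scenario a \code{\link{scenario_config}} record, or NULL to check
#'   only the global parameters.
#' @return Invisibly, \code{list(params = params, scenario = scenario)}.
#' @export
validate_inputs <- function(params, scenario = NULL) {
  stopifnot(inherits(params, "model_parameters"))
  if (params$rho < 0) stop("rho must be non-negative")
  if (params$D_max <= 0) stop("D_max must be positive")
  if (params$k <= 0) stop("k must be positive")
  if (params$horizon <= 0) stop("horizon must be positive")
  if (params$grid_step <= 0) stop("grid_step must be positive")
  m <- params$horizon / params$grid_step
  if (abs(m - round(m)) > 1e-9)
    stop("grid_step must divide horizon to within 1e-9")
  if (params$p_unit < 0) stop("p_unit must be non-negative")
  if (params$omega <= 0) stop("omega must be positive")
  # effective progression rate k*(1 - eta*(A - A0_ref)) must stay >= 0 for
  # the worst admissible adherence A = 1 against the reference A0_ref = 0.5
  if (params$eta > 0 && params$eta * (1 - 0.5) > 1)
    stop("eta too large: effective progression rate can turn negative")
  if (!is.null(scenario)) {
    stopifnot(inherits(scenario, "scenario_config"))
    if (scenario$A0 < 0 || scenario$A0 > 1) stop("A0 must lie in [0, 1]")
    if (scenario$delta < 0) stop("delta must be non-negative")
    # A0 + delta > 1 is admissible: adherence is clipped to [0, 1]
    if (scenario$shape != "baseline") {
      if (scenario$tau < 0) stop("tau must be non-negative")
      if (scenario$tau > params$horizon) stop("tau exceeds horizon")
    }
    if (scenario$gamma < 0) stop("gamma must be non-negative")
    if (scenario$theta < 0) stop("theta must be non-negative")
    if (scenario$baseline_decay_rate < 0)
      stop("baseline_decay_rate must be non-negative")
    if (scenario$shape == "adaptive" &&
        scenario$A_thresh >= scenario$A0 + scenario$delta)
      stop("threshold unreachable: A_thresh must be below A0 + delta")
  }
  invisible(list(params = params, scenario = scenario))
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Model parameters (cost model over", x$horizon, "yr, step",
      x$grid_step, "yr)\n")
  flds <- unlist(x)
  print(round(flds, 6))
  invisible(x)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario '%s' [%s]: tau=%g delta=%g gamma=%g A0=%g\n",
              x$name, x$shape, x$tau, x$delta, x$gamma, x$A0))
  invisible(x)
}

# Replace fields of a parameters/scenario record, revalidating types.
modify_record <- function(record, ...) {
  upd <- list(...)
  for (nm in names(upd)) {
    if (!nm %in% names(record))
      stop("unknown field: ", nm)
    record[[nm]] <- upd[[nm]]
  }
  record
}
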