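#' Closed-form logistic disease severity
#'
#' The uncoupled severity curve
#' \eqn{D(s) = D_{max} / (1 + e^{-k(s - s_0)})}: an S-shaped worsening from
#' near 0 toward the ceiling \code{D_max}, with midpoint \code{s0} and rate
#' \code{k}.
#'
#' @param s time (yr), vectorized.
#' @param params a \code{\link{model_parameters}}.
#' @return Severity value(s) in (0, D_max).
#' @examples
#' pars <- default_parameters()
#' severity_logistic(pars$s0, pars)  # D_max / 2
#' @export
severity_logistic <- function(s, params) {
  params$D_max / (1 + exp(-params$k * (s - params$s0)))
}

#' Adherence-coupled disease severity
#'
#' Integrates the logistic growth law with its rate modulated by adherence
#' relative to the reference level \eqn{A_{0,ref} = 0.5}:
#' \deqn{dD/ds = k (1 - \eta (A(s) - A_{0,ref})) \, D (1 - D / D_{max})}
#' with \eqn{D(0)} on the closed-form logistic curve, so that constant
#' adherence at the reference level reproduces
#' \code{\link{severity_logistic}} exactly (to integration tolerance).
#' Higher adherence slows progression; \code{eta = 0} decouples the two.
#'
#' Integration is a fixed-step explicit 4th-order Runge-Kutta sweep on the
#' simulation grid (deterministic; no adaptive stepping). Within each step
#' the stages evaluate adherence using the right-limit at the left endpoint
#' and the left-limit at the right endpoint, so grid-aligned jumps in A(s)
#' (policy starts, nudge re-activations) are handled exactly for
#' piecewise-constant adherence.
#'
#' @param adherence a \code{\link{trajectory}} of A(s) on the standard grid
#'   (as produced by \code{\link{adherence_trajectory}}).
#' @param params a \code{\link{model_parameters}}.
#' @param A0_ref reference adherence of the uncoupled logistic (0.5).
#' @return A \code{\link{trajectory}} of severity values in (0, D_max).
#' @export
severity_coupled <- function(adherence, params, A0_ref = 0.5) {
  stopifnot(inherits(adherence, "trajectory"))
  times <- adherence$times
  A <- adherence$values
  A_left <- values_left_of(adherence)
  h <- params$grid_step
  if (length(times) > 1 && abs(diff(times)[1] - h) > 1e-9)
    stop("adherence trajectory is not on the standard grid")
  k <- params$k; eta <- params$eta; Dmax <- params$D_max

  rate <- function(a) k * (1 - eta * (a - A0_ref))
  r_right <- rate(A)        # valid on [t_i, t_{i+1})
  r_left <- rate(A_left)    # left-limit at t_i
  if (min(c(r_right, r_left)) < -1e-9)
    stop("effective progression rate is negative; reduce eta or adherence")

  n <- length(times)
  D <- numeric(n)
  D[1] <- Dmax / (1 + exp(params$k * params$s0))
  f <- function(d, r) r * d * (1 - d / Dmax)
  for (i in seq_len(n - 1L)) {
    r0 <- r_right[i]                      # at t_i (right-limit)
    r1 <- 0.5 * (r_right[i] + r_left[i + 1L])  # midpoint, linear in s
    r2 <- r_left[i + 1L]                  # at t_{i+1}^- (left-limit)
    d <- D[i]
    k1 <- f(d, r0)
    k2 <- f(d + 0.5 * h * k1, r1)
    k3 <- f(d + 0.5 * h * k2, r1)
    k4 <- f(d + h * k3, r2)
    D[i + 1L] <- d + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  trajectory(times, pmin(pmax(D, 0), Dmax))
}

#' Accelerated disease progression
#'
#' Compresses the disease time axis by a stated fraction, emulating
#' populations that reach severe states sooner (earlier complications or
#' comorbid decline): a 15\% shortening maps \code{k} to \code{k / 0.85}
#' and \code{s0} to \code{0.85 * s0}. Costs and discounting are unchanged.
#'
#' @param params a \code{\link{model_parameters}}.
#' @param shortening fraction in [0, 1) by which progression intervals
#'   shrink.
#' @return A modified \code{\link{model_parameters}} copy.
#' @examples
#' p <- accelerate_progression(default_parameters(), 0.15)
#' p$k   # 0.7 / 0.85
#' @export
accelerate_progression <- function(params, shortening) {
  if (shortening < 0 || shortening >= 1)
    stop("shortening must lie in [0, 1)")
  params$k <- params$k / (1 - shortening)
  params$s0 <- (1 - shortening) * params$s0
  params
}
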